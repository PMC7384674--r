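test_that("axon compartment counts follow the morphology pattern", {
  m2 <- axon_morphology(5.7, n_ranvier = 2)
  ax <- build_axon(m2)
  expect_equal(nrow(ax$coords), 12)            # n + (n-1)*10
  m21 <- axon_morphology(5.7, n_ranvier = 21)
  ax21 <- build_axon(m21)
  expect_equal(nrow(ax21$coords), 221)
  expect_equal(length(ax21$types), 21 + 20 * 10)
  # total length = (n-1) * node spacing
  span <- sqrt(sum((ax21$coords[221, ] - ax21$coords[1, ])^2))
  expect_equal(span, 20 * 0.5, tolerance = 1e-9)   # 500 um in mm
  # internodal pattern sums to the node spacing for every diameter
  tab <- dbsvcm:::.axon_morphology_table()
  expect_equal(tab$node_length + 2 * tab$mysa_length +
                 2 * tab$flut_length + 6 * tab$stin_length,
               tab$node_spacing, tolerance = 1e-9)
  expect_error(axon_morphology(6.5), "available")
  expect_error(build_axon(m2, direction = c(0, 0, 0)), "non-zero")
})

test_that("ordered arrays enumerate grid x orientations deterministically", {
  mo <- axon_morphology(5.7, 2)
  p1 <- build_ordered_array(mo, n = c(1, 1, 1))
  expect_length(p1$axons, 1)
  p54 <- build_ordered_array(mo, n = c(3, 3, 3), spacing = 0.7,
                             orientations = list(c(1, 0, 0), c(0, 0, 1)))
  expect_length(p54$axons, 54)
  # centroid of all compartment coordinates equals the requested centre
  ctr <- colMeans(do.call(rbind, lapply(p54$axons, `[[`, "coords")))
  expect_equal(unname(ctr), c(0, 0, 0), tolerance = 1e-9)
  p2 <- build_ordered_array(mo, center = c(1, 2, 3), n = c(2, 2, 2))
  ctr2 <- colMeans(do.call(rbind, lapply(p2$axons, `[[`, "coords")))
  expect_equal(unname(ctr2), c(1, 2, 3), tolerance = 1e-9)
})

test_that("population filtering applies every exclusion rule", {
  m <- fix_electrode_mesh()
  vol <- fix_pocket_volume()
  mm <- map_tissue_to_cells(m, vol, "grey_matter")
  mo <- axon_morphology(5.7, 2)
  # interior grey-matter axon survives
  ok <- build_ordered_array(mo, center = c(0, 2.5, 0), n = c(1, 1, 1),
                            orientations = list(c(0, 1, 0)))
  ok <- filter_population(ok, mm, vol)
  expect_true(ok$survived[1])
  # an axon with one compartment in an encapsulation cell is excluded
  # with that reason (compartment placed at an actual sheath centroid)
  enc_cell <- which(mm$region == "encapsulation")[1]
  ctr <- cell_centroids(mm)[enc_cell, ]
  enc <- structure(list(
    axons = list(list(coords = rbind(c(0, 2.5, 0), c(0, 2.4, 0), ctr),
                      types = c("node", "mysa", "node"),
                      source = "imported")),
    survived = TRUE, reason = NA_character_, morph = NULL),
    class = "axon_population")
  enc <- filter_population(enc, mm, vol)
  expect_false(enc$survived[1])
  expect_equal(enc$reason[1], "encapsulation")
  # axon leaving the domain
  out <- build_ordered_array(mo, center = c(0, 3.9, 0), n = c(1, 1, 1),
                             orientations = list(c(0, 1, 0)))
  out <- filter_population(out, mm, vol)
  expect_equal(out$reason[1], "outside_domain")
  # axon through the CSF pocket
  csf <- build_ordered_array(mo, center = c(1.5, 0, 0), n = c(1, 1, 1),
                             orientations = list(c(1, 0, 0)))
  csf <- filter_population(csf, mm, vol)
  expect_equal(csf$reason[1], "csf")
})

test_that("filtering matches the exhaustive per-compartment oracle", {
  m <- fix_electrode_mesh()
  vol <- fix_pocket_volume()
  mm <- map_tissue_to_cells(m, vol, "grey_matter")
  mo <- axon_morphology(5.7, 2)
  set.seed(13)
  pop <- build_ordered_array(mo, center = c(1, 0, 0.5), n = c(4, 3, 3),
                             spacing = 0.9,
                             orientations = list(c(0, 0, 1), c(1, 1, 0)))
  got <- filter_population(pop, mm, vol)
  csf_code <- as.integer(names(vol$legend)[vol$legend == "csf"])
  for (a in seq_along(pop$axons)) {
    pts <- pop$axons[[a]]$coords
    bad <- FALSE
    for (i in seq_len(nrow(pts))) {
      cc <- tryCatch(dbsvcm:::.locate_points(mm, pts[i, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(cc)) { bad <- TRUE; break }
      if (mm$region[cc$cell] %in% c("encapsulation", "floating_conductor") ||
          !is.na(mm$contact_cell[cc$cell])) { bad <- TRUE; break }
      vi <- round(drop(solve(vol$affine) %*% c(pts[i, ], 1))[1:3])
      vi <- pmin(pmax(vi, 0), dim(vol$labels) - 1)
      if (vol$labels[matrix(vi + 1, 1)] == csf_code) { bad <- TRUE; break }
    }
    expect_equal(got$survived[a], !bad, info = paste("axon", a))
  }
  # idempotence and monotone exclusion
  again <- filter_population(got, mm, vol)
  expect_identical(again$survived, got$survived)
  wider <- filter_population(pop, mm, vol,
                             excluded_labels = c("csf", "white_matter"))
  expect_true(all(got$survived | !wider$survived | !got$survived))
  expect_lte(sum(wider$survived), sum(got$survived))
})

test_that("activating function vanishes for constant and linear fields", {
  mo <- axon_morphology(5.7, 4)
  ax <- build_axon(mo, c(0, 0, 0), c(1, 0, 0))
  pop <- structure(list(axons = list(c(ax, source = "generated_array")),
                        survived = TRUE, reason = NA_character_,
                        morph = mo), class = "axon_population")
  n <- nrow(ax$coords)
  # constant potential
  courses <- list("1" = matrix(2, 3, n))
  r0 <- activation_by_threshold(pop, "activating_function", 0.5,
                                courses = courses)
  expect_equal(r0$peak_af, 0)
  expect_false(r0$activated)
  # linear potential along the axon
  s <- c(0, cumsum(sqrt(rowSums(diff(ax$coords)^2))))
  courses <- list("1" = matrix(rep(3 * s, each = 2), 2, byrow = FALSE))
  r1 <- activation_by_threshold(pop, "activating_function", 1e-9,
                                courses = courses)
  expect_equal(r1$peak_af, 0, tolerance = 1e-9)
})

test_that("point-source activating function peaks at the closest node and
          matches the brute-force second difference", {
  mo <- axon_morphology(5.7, 7)
  ax <- build_axon(mo, c(-1.5, 0.3, 0), c(1, 0, 0))
  pop <- structure(list(axons = list(c(ax, source = "generated_array")),
                        survived = TRUE, reason = NA_character_,
                        morph = mo), class = "axon_population")
  # potential of a point source at the origin, 0.3 mm off the axon
  phi <- 1 / sqrt(rowSums(ax$coords^2))
  courses <- list("1" = matrix(phi, 1, byrow = TRUE))
  res <- activation_by_threshold(pop, "activating_function", 1e9,
                                 courses = courses)
  nodes <- which(ax$types == "node")
  s <- c(0, cumsum(sqrt(rowSums(diff(ax$coords)^2))))[nodes]
  pn <- phi[nodes]
  af <- rep(-Inf, length(nodes))
  for (i in 2:(length(nodes) - 1)) {
    h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
    af[i] <- 2 * (pn[i - 1] / (h1 * (h1 + h2)) - pn[i] / (h1 * h2) +
                    pn[i + 1] / (h2 * (h1 + h2)))
  }
  expect_equal(res$peak_af, max(af), tolerance = 1e-12)
  # a positive point source depolarizes the flanks: the most negative
  # second difference sits at the closest node, the positive peaks at
  # its immediate neighbours
  closest <- unname(which.min(rowSums(ax$coords[nodes, ]^2)))
  interior <- af[2:(length(nodes) - 1)]
  expect_equal(unname(which.min(interior)) + 1L, closest)
  expect_equal(abs(unname(which.max(af)) - closest), 1L)
  # monotone in threshold
  r_lo <- activation_by_threshold(pop, "activating_function", max(af) * 0.9,
                                  courses = courses)
  r_hi <- activation_by_threshold(pop, "activating_function", max(af) * 1.1,
                                  courses = courses)
  expect_true(r_lo$activated)
  expect_false(r_hi$activated)
})

test_that("compartment time courses separate for non-dispersive media", {
  m <- fix_box()
  tt <- const_table(0.1, eps_r = 0)
  sig <- stim_signal("rectangular", amplitude = 1, pulse_width = 60e-6)
  spec <- fourier_coefficients(sig, 1e6)
  spec <- truncate_spectrum(spec, truncation_scheme("sequential",
                                                    n_components = 40))
  freqs <- solve_frequencies(spec)
  mo <- axon_morphology(5.7, 2)
  ax <- build_axon(mo, c(1, 1, 1), c(1, 0, 0))
  pop <- structure(list(axons = list(c(ax, source = "generated_array")),
                        survived = TRUE, reason = NA_character_,
                        morph = mo), class = "axon_population")
  sols <- lapply(freqs[freqs > 0], function(f)
    solve_eqs(m, tt, NULL, f, 1, qs_mode = TRUE))
  dc <- solve_eqs(m, tt, NULL, 0, 1)
  times <- seq(0, 1 / 130, length.out = 80) + 1e-7
  tc <- compartment_time_courses(pop, sols, spec, times, dc_solution = dc)
  # constant sigma + QS: course = static profile x band-limited waveform
  prof <- Re(probe_potential(dc, ax$coords))
  wave <- reconstruct_time_course(spec, 1 + 0i, times)
  expect_equal(tc[["1"]], outer(wave, prof), tolerance = 1e-6)
  # single-frequency spectrum gives a pure sinusoid
  one <- truncate_spectrum(spec, truncation_scheme("sequential",
                                                   n_components = 2))
  tc1 <- compartment_time_courses(pop, sols[1], one, times,
                                  dc_solution = dc)
  c1 <- one$coefficients[2]
  expected <- prof[1] * (Re(one$coefficients[1]) +
                           2 * Re(c1 * exp(2i * pi * 130 * times)))
  expect_equal(tc1[["1"]][, 1], expected, tolerance = 1e-8)
})

test_that("population CSV round trip preserves geometry", {
  mo <- axon_morphology(8.7, 3)
  pop <- build_ordered_array(mo, n = c(2, 1, 1))
  f <- tempfile(fileext = ".csv")
  write_population_csv(pop, f)
  pop2 <- read_population_csv(f)
  expect_length(pop2$axons, 2)
  expect_equal(pop2$axons[[1]]$coords, unname(pop$axons[[1]]$coords),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(pop2$axons[[2]]$types, pop$axons[[2]]$types)
  unlink(f)
})
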