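test_that("electrode domain build tags contacts, hole and regions", {
  m <- fix_electrode_mesh()
  expect_setequal(unique(m$region),
                  c("ROI", "contact_vicinity", "ROT", "encapsulation",
                    "floating_conductor"))
  # exactly two contact facet groups plus an outer boundary group
  expect_gt(nrow(contact_facets(m, 1)), 0)
  expect_gt(nrow(contact_facets(m, 2)), 0)
  expect_error(contact_facets(m, 9), "unknown contact")
  expect_gt(length(m$surf_nodes$outer), 0)
  # encapsulation cells hug the lead surface within thickness + local h
  el <- m$electrode
  enc <- which(m$region == "encapsulation")
  cent <- cell_centroids(m)[enc, , drop = FALSE]
  rel <- sweep(cent, 2, el$tip_position)
  z <- rel %*% el$direction
  rho <- sqrt(pmax(rowSums(rel^2) - z^2, 0))
  h <- cell_longest_edges(m, enc)
  expect_true(all(rho - el$lead_radius <= el$encapsulation_thickness + h))
})

test_that("electrode placement and thickness are validated", {
  bad <- electrode_spec(tip_position = c(0, 0, 30))
  expect_error(build_domain_mesh(domain = list(shape = "sphere",
                                               diameter = 10),
                                 electrode = bad),
               "outside the domain")
  expect_error(electrode_spec(encapsulation_thickness = 0), "thickness")
  expect_error(electrode_spec(contacts = data.frame(
    id = 1:2, z_start = c(0, 0.5), z_end = c(1, 1.5),
    role = c("active", "ground"), value = c(1, 0))), "overlap")
})

test_that("coarser target edges give monotonically fewer nodes", {
  el <- electrode_spec(lead_radius = 0.6, tip_position = c(0, 0, -2))
  fine <- build_domain_mesh(domain = list(shape = "sphere", diameter = 8),
                            electrode = el,
                            target_edges = list(roi = 0.7, vicinity = 0.6,
                                                rot = 0.9),
                            base_edge = 0.6)
  coarse <- build_domain_mesh(domain = list(shape = "sphere", diameter = 8),
                              electrode = el,
                              target_edges = list(roi = 1.4, vicinity = 1.2,
                                                  rot = 1.8),
                              base_edge = 0.6)
  expect_gt(nrow(fine$nodes), nrow(coarse$nodes))
})

test_that("tissue mapping: uniform, half-space oracle, local coverage", {
  m <- fix_box()
  uni <- make_synthetic_tissue_volume("uniform", n = 16, voxel_size = 0.4)
  # shift the volume over the box (box spans [0,4]x[0,2]x[0,2])
  uni$affine[1:3, 4] <- uni$affine[1:3, 4] + c(2, 1, 1)
  m1 <- map_tissue_to_cells(m, uni, "unknown")
  expect_true(all(m1$tissue == "grey_matter"))
  # idempotence
  m2 <- map_tissue_to_cells(m1, uni, "unknown")
  expect_identical(m2$tissue, m1$tissue)

  hs <- make_synthetic_tissue_volume("half_space", n = 16, voxel_size = 0.4)
  hs$affine[1:3, 4] <- hs$affine[1:3, 4] + c(2, 1, 1)
  m3 <- map_tissue_to_cells(m, hs, "unknown")
  # brute-force oracle: majority vote over all voxel centres, using an
  # independent point-in-tet predicate; nearest voxel as fallback
  idx <- as.matrix(expand.grid(i = 0:15, j = 0:15, k = 0:15))
  ctr <- cbind(idx, 1) %*% t(hs$affine)
  labs <- hs$legend[as.character(as.vector(hs$labels))]
  set.seed(3)
  for (cc in sample(nrow(m$cells), 40)) {
    vv <- m$nodes[m$cells[cc, ], ]
    near <- which(ctr[, 1] > min(vv[, 1]) - 0.5 & ctr[, 1] < max(vv[, 1]) + 0.5 &
                  ctr[, 2] > min(vv[, 2]) - 0.5 & ctr[, 2] < max(vv[, 2]) + 0.5 &
                  ctr[, 3] > min(vv[, 3]) - 0.5 & ctr[, 3] < max(vv[, 3]) + 0.5)
    ins <- near[vapply(near, function(i)
      oracle_point_in_tet(ctr[i, 1:3], vv[1, ], vv[2, ], vv[3, ], vv[4, ]),
      logical(1))]
    if (length(ins)) {
      tab <- sort(table(labs[ins]), decreasing = TRUE)
      expect_equal(m3$tissue[cc], names(tab)[1])
    } else {
      cen <- colMeans(vv)
      d <- colSums((t(ctr[, 1:3]) - cen)^2)
      expect_equal(m3$tissue[cc], unname(labs[which.min(d)]))
    }
  }

  # volume covering only a sub-box: cells outside get the default
  sub <- make_synthetic_tissue_volume("uniform", n = 6, voxel_size = 0.2)
  sub$affine[1:3, 4] <- sub$affine[1:3, 4] + c(0.6, 1, 1)
  m4 <- map_tissue_to_cells(m, sub, "white_matter")
  cent <- cell_centroids(m4)
  outside <- cent[, 1] > 2
  expect_true(all(m4$tissue[outside] == "white_matter"))
})

test_that("tensor mapping: identity, unit-trace scaling, nearest oracle", {
  m <- fix_box()
  tv <- make_synthetic_tensor_volume(n = 12, voxel_size = 0.5, axis = 1,
                                     ratio = 1)   # identity everywhere
  tv$affine[1:3, 4] <- tv$affine[1:3, 4] + c(2, 1, 1)
  m1 <- map_tensors_to_cells(m, tv)
  expect_true(all(abs(m1$tensor - matrix(c(1, 0, 0, 1, 0, 1),
                                         nrow(m1$tensor), 6,
                                         byrow = TRUE)) < 1e-12))
  # unit-trace normalization is scale invariant: diag(3,0,0)*c -> diag(3,0,0)
  comp <- array(0, c(2, 2, 2, 6))
  comp[, , , 1] <- 3 * 7.5   # Dxx, arbitrary positive scale
  tv2 <- tensor_volume(comp, diag(c(2, 2, 2, 1)))
  tv2$affine[1:3, 4] <- c(1, 0.5, 0.5)
  m2 <- map_tensors_to_cells(m, tv2, "unit_trace")
  expect_equal(unname(m2$tensor[1, ]), c(3, 0, 0, 0, 0, 0), tolerance = 1e-12)
  # anisotropic half-space: nearest-voxel oracle
  comp3 <- array(0, c(8, 4, 4, 6))
  comp3[, , , 1] <- 1; comp3[, , , 4] <- 1; comp3[, , , 6] <- 1
  comp3[5:8, , , 1] <- 2          # x-weight doubled for x-half
  tv3 <- tensor_volume(comp3, {
    A <- diag(c(0.5, 0.5, 0.5, 1)); A[1:3, 4] <- c(0.25, 0.25, 0.25); A
  })
  m3 <- map_tensors_to_cells(m, tv3)
  cent <- cell_centroids(m3)
  for (cc in seq(1, nrow(cent), by = 17)) {
    ci <- round((cent[cc, ] - c(0.25, 0.25, 0.25)) / 0.5)
    ci <- pmin(pmax(ci, 0), c(7, 3, 3))
    expect_equal(m3$tensor[cc, 1], comp3[ci[1] + 1, ci[2] + 1, ci[3] + 1, 1])
  }
})

test_that("degenerate tensors are clipped to PSD", {
  m <- fix_box()
  comp <- array(0, c(2, 2, 2, 6))
  comp[, , , 1] <- 1; comp[, , , 4] <- -0.5; comp[, , , 6] <- 1
  tv <- tensor_volume(comp, {
    A <- diag(c(2, 1, 1, 1)); A[1:3, 4] <- c(1, 0.5, 0.5); A
  })
  expect_warning(m1 <- map_tensors_to_cells(m, tv), "clipped")
  D <- matrix(c(m1$tensor[1, 1], m1$tensor[1, 2], m1$tensor[1, 3],
                m1$tensor[1, 2], m1$tensor[1, 4], m1$tensor[1, 5],
                m1$tensor[1, 3], m1$tensor[1, 5], m1$tensor[1, 6]), 3)
  expect_true(all(eigen(D, symmetric = TRUE)$values >= -1e-12))
})

test_that("CSF refinement candidates obey the triple predicate", {
  m <- fix_electrode_mesh()
  vol <- fix_pocket_volume()
  m <- map_tissue_to_cells(m, vol, "grey_matter")
  pts <- rbind(c(1.5, 0, 0), c(2, 0, 1))
  got <- csf_cells_near_neurons(m, vol, pts, radius = 1.5, max_edge = 0.4)
  # brute-force scan: all three predicates evaluated independently
  csf_code <- as.integer(names(vol$legend)[vol$legend == "csf"])
  idx <- as.matrix(expand.grid(i = 0:19, j = 0:19, k = 0:19))
  ctr <- cbind(idx, 1) %*% t(vol$affine)
  iscsf <- as.vector(vol$labels) == csf_code
  cent <- cell_centroids(m)
  edges <- cell_longest_edges(m)
  expected <- integer(0)
  cand <- which(edges > 0.4)
  for (cc in cand) {
    d <- min(sqrt(colSums((t(pts) - cent[cc, ])^2)))
    if (d > 1.5) next
    vv <- m$nodes[m$cells[cc, ], ]
    near <- which(iscsf &
                  ctr[, 1] > min(vv[, 1]) - 1e-9 & ctr[, 1] < max(vv[, 1]) + 1e-9 &
                  ctr[, 2] > min(vv[, 2]) - 1e-9 & ctr[, 2] < max(vv[, 2]) + 1e-9 &
                  ctr[, 3] > min(vv[, 3]) - 1e-9 & ctr[, 3] < max(vv[, 3]) + 1e-9)
    if (any(vapply(near, function(i)
      oracle_point_in_tet(ctr[i, 1:3], vv[1, ], vv[2, ], vv[3, ], vv[4, ]),
      logical(1)))) expected <- c(expected, cc)
  }
  expect_setequal(got, expected)
  # degenerate gates
  expect_length(csf_cells_near_neurons(m, vol, pts, 1.5, max_edge = 10), 0)
  nocsf <- make_synthetic_tissue_volume("uniform", n = 10, voxel_size = 1)
  nocsf$legend <- c(nocsf$legend, "3" = "csf")  # csf in legend, none present
  expect_length(csf_cells_near_neurons(m, nocsf, pts, 1.5, 0.4), 0)
})

test_that("voxel volume text round trip and NIfTI reader agree", {
  vol <- make_synthetic_tissue_volume("layered_sphere", n = 10,
                                      voxel_size = 0.8)
  f <- tempfile(fileext = ".txt")
  write_voxel_volume_txt(vol, f)
  vol2 <- read_voxel_volume(f)
  expect_equal(vol2$labels, vol$labels)
  expect_equal(vol2$affine, vol$affine, tolerance = 1e-12)
  expect_equal(unlist(vol2$legend), vol$legend)
  unlink(c(f, paste0(f, ".json")))
  skip_if_not_installed("RNifti")
  fn <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(as.numeric(vol$labels), dim = dim(vol$labels)))
  img <- RNifti::`pixdim<-`(img, c(0.8, 0.8, 0.8))
  RNifti::writeNifti(img, fn)
  vol3 <- read_voxel_volume(fn, legend = vol$legend)
  expect_equal(vol3$labels, vol$labels)
  unlink(fn)
})
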