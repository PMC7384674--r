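test_that("deviation measures match their definitions and brute force", {
  expect_equal(csf_deviation(c(1 + 0i, 2i), c(1 + 0i, 2i), 1), 0)
  expect_equal(csf_deviation(0.51 + 0i, 0.5 + 0i, 1), 0.01, tolerance = 1e-12)
  expect_error(csf_deviation(1 + 0i, 1 + 0i, 0), "V_drop")
  expect_error(csf_deviation(complex(3), complex(2), 1), "length")
  set.seed(5)
  for (rep in 1:5) {
    a <- complex(real = rnorm(50), imaginary = rnorm(50))
    b <- complex(real = rnorm(50), imaginary = rnorm(50))
    vd <- runif(1, 0.5, 3)
    brute <- max(vapply(seq_along(a), function(i)
      abs(Mod(a[i]) - Mod(b[i])) / vd, 1))
    expect_equal(csf_deviation(a, b, vd), brute, tolerance = 1e-12)
    expect_equal(potential_deviation(a, b, vd), brute, tolerance = 1e-12)
    # homogeneity: scaling fields and V_drop together is invariant
    expect_equal(potential_deviation(3 * a, 3 * b, 3 * vd), brute,
                 tolerance = 1e-12)
  }
})

test_that("field criterion marks exactly the cells over threshold", {
  E <- matrix(complex(real = 1), 4, 3)
  expect_length(field_deviation_mark(E, E, 0.1), 0)
  E2 <- E; E2[2, ] <- 2 * E[2, ]   # 100% relative change at cell 2
  expect_equal(field_deviation_mark(E2, E, 0.4), 2L)
  # zero-field guard
  E0 <- matrix(0 + 0i, 2, 3)
  expect_length(field_deviation_mark(E0, E0 + 1, 0.01), 0)
  set.seed(6)
  for (rep in 1:5) {
    En <- matrix(complex(real = rnorm(90), imaginary = rnorm(90)), 30)
    Eo <- En + matrix(complex(real = 0.2 * rnorm(90)), 30)
    th <- runif(1, 0.05, 0.3)
    brute <- which(vapply(1:30, function(i) {
      nn <- sqrt(sum(Mod(En[i, ])^2))
      nn >= 1e-12 && sqrt(sum(Mod(En[i, ] - Eo[i, ])^2)) / nn > th
    }, logical(1)))
    expect_equal(field_deviation_mark(En, Eo, th), brute)
  }
})

test_that("current criterion gates small currents and matches brute force", {
  # children exactly partition the parent current: nothing marked
  expect_length(current_deviation_mark(c(1, 2), c(1, 2), 0.01), 0)
  # below the skip fraction: not marked even with mismatch
  expect_length(current_deviation_mark(c(1e-6, 1), c(2e-6, 1), 0.5,
                                       skip_fraction = 1e-3), 0)
  set.seed(7)
  for (rep in 1:5) {
    pj <- runif(40, 0, 1)
    cj <- pj * runif(40, 0.8, 1.25)
    th <- runif(1, 0.02, 0.2); sf <- 10^runif(1, -4, -2)
    tot <- sum(pj)
    brute <- which(vapply(1:40, function(i)
      pj[i] >= sf * tot && abs(cj[i] - pj[i]) / cj[i] > th, logical(1)))
    expect_equal(current_deviation_mark(pj, cj, th, sf), brute)
  }
})

test_that("criterion evaluators are pure (identical inputs, identical marks)", {
  set.seed(8)
  En <- matrix(complex(real = rnorm(30)), 10)
  Eo <- matrix(complex(real = rnorm(30)), 10)
  expect_identical(field_deviation_mark(En, Eo, 0.1),
                   field_deviation_mark(En, Eo, 0.1))
  pj <- runif(10); cj <- runif(10)
  expect_identical(current_deviation_mark(pj, cj, 0.05),
                   current_deviation_mark(pj, cj, 0.05))
})

test_that("infinite thresholds leave the mesh unchanged", {
  m <- fix_box()
  cfg <- refinement_config(theta_csf = Inf, theta_phi = Inf,
                           theta_E = Inf, theta_J = Inf, max_iterations = 2)
  res <- run_refinement(m, const_table(), NULL, 130,
                        rbind(c(2, 1, 1), c(3, 1, 1)), cfg, vol = NULL)
  expect_equal(nrow(res$mesh$cells), nrow(m$cells))
  expect_true(res$converged)
})

test_that("refinement never unrefines and reports its decision path", {
  m <- fix_box()
  cfg <- refinement_config(theta_phi = 1e-4, theta_E = 0.02,
                           max_iterations = 2)
  res <- run_refinement(m, const_table(), NULL, 130,
                        rbind(c(2, 1, 1)), cfg, vol = NULL)
  expect_gte(nrow(res$mesh$cells), nrow(m$cells))
  expect_true(all(c("stage", "region", "iteration", "criterion",
                    "converged") %in% names(res$report)))
  f <- tempfile(fileext = ".json")
  write_refinement_report(res, f)
  rep2 <- jsonlite::read_json(f)
  expect_equal(rep2$n_cells, nrow(res$mesh$cells))
  unlink(f)
})

test_that("configuration validation rejects bad thresholds", {
  expect_error(refinement_config(theta_csf = 0), "thresholds")
  expect_error(refinement_config(max_iterations = 0), "max_iterations")
})
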