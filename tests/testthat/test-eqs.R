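test_that("slab with plate contacts reproduces the affine solution exactly", {
  m <- fix_box()
  tt <- const_table()
  for (ord in 1:2) {
    sol <- solve_eqs(m, tt, NULL, f = 0, order = ord)
    pts <- rbind(c(2, 1, 1), c(1, 0.5, 1.5), c(3.5, 1.7, 0.3))
    expect_equal(Re(probe_potential(sol, pts)), 1 - pts[, 1] / 4,
                 tolerance = 1e-10)
    # Dirichlet values matched exactly at constrained nodes
    expect_equal(unname(Mod(sol$phi[m$surf_nodes$contact_1])),
                 rep(1, length(m$surf_nodes$contact_1)), tolerance = 1e-12)
    # discrete maximum principle
    expect_lte(max(Mod(sol$phi)), 1 + 1e-8)
  }
})

test_that("solution is exactly linear in the Dirichlet data", {
  m <- fix_box()
  tt <- const_table()
  s1 <- solve_eqs(m, tt, boundary_spec(m$contacts, c(1, 0)), 0, 1)
  s3 <- solve_eqs(m, tt, boundary_spec(m$contacts, c(3, 0)), 0, 1)
  expect_equal(s3$phi, 3 * s1$phi, tolerance = 1e-12)
})

test_that("quasistatic mode equals EQS with zero permittivity", {
  m <- fix_electrode_mesh()
  tt <- const_table(0.1, eps_r = 0)
  a <- solve_eqs(m, tt, NULL, f = 520, order = 1, qs_mode = FALSE)
  b <- solve_eqs(m, tt, NULL, f = 520, order = 1, qs_mode = TRUE)
  expect_equal(a$phi, b$phi, tolerance = 1e-12)
})

test_that("missing Dirichlet data raises a singular-system error", {
  expect_error(
    boundary_spec(data.frame(id = 1:2, role = c("floating", "floating"),
                             value = c(0, 0)), outer = "insulated"),
    "Dirichlet")
})

test_that("concentric spheres match the closed-form solution", {
  m <- fix_shell()
  inner <- which(sqrt(rowSums(cell_centroids(m)^2)) < 1.2)
  m <- refine_cells(m, inner)
  tt <- const_table(0.1)
  sol <- solve_eqs(m, tt, NULL, f = 0, order = 2)
  set.seed(11)
  pts <- matrix(rnorm(3 * 100), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(100, 1, 3)
  r <- sqrt(rowSums(pts^2))
  ana <- (1 / r - 1 / 5) / (1 / 0.5 - 1 / 5)
  num <- Re(probe_potential(sol, pts))
  expect_lt(max(abs(num - ana) / ana), 0.03)
  # analytic spreading conductance; the volume-consistent flux is tight
  G <- 4 * pi * 0.1 / (1 / 0.5 - 1 / 5) * 1e-3
  Jr <- contact_current_residual(sol, 1)
  expect_lt(abs(Mod(Jr$J) - G) / G, 0.02)
  expect_equal(Im(Jr$J), 0, tolerance = 1e-12 * Mod(Jr$J))  # QS: purely real
  # facet flux agrees with the conservative flux on this resolution
  Jf <- contact_current(sol, 1)
  expect_lt(Mod(Jf$J - Jr$J) / Mod(Jr$J), 0.05)
  # volume-consistent two-contact balance is exact
  Jr2 <- contact_current_residual(sol, 2)
  expect_lt(Mod(Jr$J + Jr2$J) / Mod(Jr$J), 1e-9)
  # impedance: Re(Z) = (1/r0 - 1/R) / (4 pi sigma)
  Z <- impedance(sol, Jr)
  expect_lt(abs(Re(Z) - 1 / G) / (1 / G), 0.02)
  # doubling sigma halves the impedance
  sol2 <- solve_eqs(m, const_table(0.2), NULL, 0, 2)
  Z2 <- impedance(sol2, contact_current_residual(sol2, 1))
  expect_equal(Mod(Z2), Mod(Z) / 2, tolerance = 1e-9)
})

test_that("probing errors name the offending point", {
  m <- fix_box()
  sol <- solve_eqs(m, const_table(), NULL, 0, 1)
  expect_error(probe_potential(sol, c(99, 0, 0)), "99")
})

test_that("scale_to_current rescales to the target current exactly", {
  m <- fix_shell()
  tt <- const_table(0.1)
  sol <- solve_eqs(m, tt, NULL, f = 0, order = 2)
  J <- contact_current_residual(sol, 1)
  # identity
  s1 <- scale_to_current(sol, J, J$J)
  expect_equal(s1$phi, sol$phi, tolerance = 1e-12)
  # 1 A target re-evaluates to 1 A
  s2 <- scale_to_current(sol, J, 1)
  expect_equal(Mod(contact_current_residual(s2, 1)$J), 1, tolerance = 1e-8)
  # sign flip
  s3 <- scale_to_current(sol, J, -J$J)
  expect_equal(s3$phi, -sol$phi, tolerance = 1e-12)
  expect_error(scale_to_current(sol, list(J = 0 + 0i), 1), "zero")
})

test_that("EQS impedance is below QS impedance for dispersive tissue", {
  m <- fix_shell()
  tt <- tissue_table()
  eqs <- solve_eqs(m, tt, NULL, 130, 2)
  qs <- solve_eqs(m, tt, NULL, 130, 2, qs_mode = TRUE)
  Zeqs <- impedance(eqs, contact_current_residual(eqs, 1))
  Zqs <- impedance(qs, contact_current_residual(qs, 1))
  expect_lte(Mod(Zeqs), Mod(Zqs))
  expect_lt(abs(Im(Zqs)), 1e-9 * Mod(Zqs))   # QS current purely real
  expect_gt(abs(Im(Zeqs)), 0)
})

test_that("floating conductors are near-equipotential and reciprocal", {
  m <- fix_electrode_mesh()
  tt <- const_table(0.1)
  # contact 2 floating, grounded outer boundary carries the return
  bc <- boundary_spec(data.frame(id = 1:2, role = c("active", "floating")),
                      c(1, 0), outer = "grounded")
  sol <- solve_eqs(m, tt, bc, f = 1000, order = 1)
  n2 <- unique(as.vector(m$cells[which(!is.na(m$contact_cell) &
                                         m$contact_cell == 2), ]))
  spread <- max(Mod(sol$phi[n2])) - min(Mod(sol$phi[n2]))
  expect_lt(spread, 1e-3 * sol$V_drop)
  # reciprocity of the two-contact transfer impedance
  bc2 <- boundary_spec(data.frame(id = 1:2, role = c("floating", "active")),
                       c(0, 1), outer = "grounded")
  sol2 <- solve_eqs(m, tt, bc2, f = 1000, order = 1)
  J1 <- contact_current_residual(sol, 1)$J
  J2 <- contact_current_residual(sol2, 2)$J
  Z12 <- mean(sol$phi[n2]) / J1
  n1 <- unique(as.vector(m$cells[which(!is.na(m$contact_cell) &
                                         m$contact_cell == 1), ]))
  Z21 <- mean(sol2$phi[n1]) / J2
  expect_lt(Mod(Z12 - Z21) / Mod(Z12), 0.01)
})

test_that("multicontact current mode reduces to scaling for one source", {
  m <- fix_electrode_mesh()
  tt <- const_table(0.1)
  mc <- multicontact_current_mode(m, tt, c("1" = 1e-4), ground_id = 2,
                                  f = 130, order = 2)
  expect_equal(Mod(mc$achieved[["1"]]), 1e-4, tolerance = 1e-6)
  # equivalent direct scaling
  sol <- solve_eqs(m, tt, NULL, 130, 2)
  s <- scale_to_current(sol, contact_current_residual(sol, 1), 1e-4)
  expect_equal(mc$solution$phi, s$phi, tolerance = 1e-6)
})

test_that("anisotropic weighting shifts current along the favored axis", {
  m <- fix_box()
  M <- nrow(m$cells)
  tt <- const_table(0.1)
  iso <- solve_eqs(m, tt, NULL, 0, 1)
  m$tensor <- matrix(rep(c(2, 0, 0, 0.5, 0, 0.5), each = M), M, 6)
  ani <- solve_eqs(m, tt, NULL, 0, 1)
  # slab field along x: doubling Dxx doubles the through current
  Ji <- contact_current_residual(iso, 1)$J
  Ja <- contact_current_residual(ani, 1)$J
  expect_equal(Re(Ja) / Re(Ji), 2, tolerance = 1e-9)
})
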