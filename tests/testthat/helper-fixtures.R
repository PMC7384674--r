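# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# constant-conductivity tissue table (sigma = 0.1 S/m, dispersionless)
const_table <- function(sigma = 0.1, eps_r = 0)
  tissue_table(overrides = list(
    grey_matter = list(sigma = sigma, eps_r = eps_r),
    white_matter = list(sigma = sigma / 2, eps_r = eps_r),
    unknown = list(sigma = sigma, eps_r = eps_r)))

# small box slab: plates at x = 0 (1 V) and x = 4 (0 V)
fix_box <- function() fixture("box", function()
  mesh_box(c(4, 2, 2), c(8, 4, 4)))

# coarse concentric-spheres shell (r0 = 0.5, R = 5)
fix_shell <- function() fixture("shell", function()
  mesh_spherical_shell(0.5, 5, subdiv = 2, n_layers = 8))

# two-contact electrode in an 8 mm sphere, constant grey tissue
fix_electrode_mesh <- function() fixture("electrode", function() {
  el <- electrode_spec(tip_position = c(0, 0, -2), direction = c(0, 0, 1),
                       lead_radius = 0.5,
                       contacts = data.frame(id = 1:2,
                                             z_start = c(0.5, 2.5),
                                             z_end = c(1.5, 3.5),
                                             role = c("active", "ground"),
                                             value = c(1, 0)),
                       encapsulation_thickness = 0.2)
  m <- build_domain_mesh(domain = list(shape = "sphere", diameter = 8),
                         electrode = el,
                         target_edges = list(roi = 0.8, vicinity = 0.5,
                                             rot = 1.2),
                         base_edge = 0.5)
  m$tissue <- rep("grey_matter", nrow(m$cells))
  m
})

# csf_pocket phantom matching the electrode mesh extent
fix_pocket_volume <- function() fixture("pocket", function()
  make_synthetic_tissue_volume("csf_pocket", n = 20, voxel_size = 0.5,
                               pocket_center = c(1.5, 0, 0),
                               pocket_semiaxes = c(1.0, 0.7, 0.7)))

# independent point-in-tetrahedron test used by brute-force oracles
# (determinant sign method, distinct from the package's barycentric path)
oracle_point_in_tet <- function(p, a, b, c, d) {
  s <- function(p1, p2, p3, p4)
    sign(det(rbind(p2 - p1, p3 - p1, p4 - p1)))
  s0 <- s(a, b, c, d)
  all(c(s(p, b, c, d), s(a, p, c, d), s(a, b, p, d), s(a, b, c, p)) *
        s0 >= -1e-12)
}

# tiny simulation config for pipeline tests
small_sim_config <- function(outdir, workers = 1) {
  cfg <- default_simulation_config()
  cfg$mesh$target_edges <- list(roi = 1.0, vicinity = 0.6, rot = 1.4)
  cfg$mesh$base_edge <- 0.6
  cfg$truncation$n_components <- 3
  cfg$axons$n <- c(2, 1, 1)
  cfg$axons$n_ranvier <- 2
  cfg$times$n <- 64
  cfg$output_dir <- outdir
  cfg$workers <- workers
  cfg
}
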