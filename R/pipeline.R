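# Workflow orchestration: a JSON-configurable pipeline from domain
# construction through tissue mapping, axon placement, adaptive
# refinement, per-frequency field solves (dispatchable to parallel
# workers, results identical to serial execution), optional CPE
# correction, time-course reconstruction and activation estimation. Every
# step writes a metadata record so an interrupted run resumes after the
# last completed step.

#' Default simulation configuration
#'
#' Returns the fully populated default configuration (a named list
#' mirroring the JSON schema) for the bundled two-layer phantom study;
#' override any entry via `modifyList` or a JSON file.
#'
#' @return a named list of class `simulation_config`.
#' @export
default_simulation_config <- function() {
  structure(list(
    signal = list(shape = "rectangular", amplitude = 1, pulse_width = 60e-6,
                  repetition_rate = 130, phase_shift = 0, mode = "voltage"),
    physics = list(qs_mode = FALSE, cpe = FALSE,
                   cpe_K_S_area = 1.06, cpe_alpha = 0.7, f_max = 1e6,
                   floating_eps = 1e9, order = 2),
    domain = list(shape = "sphere", diameter = 8),
    electrode = list(tip_position = c(0, 0, -2), direction = c(0, 0, 1),
                     lead_radius = 0.5,
                     contacts = list(
                       list(id = 1, z_start = 0.5, z_end = 1.5,
                            role = "active", value = 1),
                       list(id = 2, z_start = 2.5, z_end = 3.5,
                            role = "ground", value = 0)),
                     encapsulation_thickness = 0.2),
    mesh = list(target_edges = list(roi = 0.8, vicinity = 0.5, rot = 1.2),
                base_edge = 0.5),
    volume = list(kind = "csf_pocket", n = 20, voxel_size = 0.5,
                  pocket_center = c(1.5, 0, 0),
                  pocket_semiaxes = c(1.0, 0.7, 0.7)),
    tissue = list(encapsulation_scale = 0.5, overrides = list()),
    anisotropy = list(enabled = FALSE, axis = 3, ratio = 2,
                      normalization = "unit_trace"),
    refinement = list(enabled = FALSE, theta_csf = 0.01, theta_phi = 0.01,
                      theta_E = 0.05, theta_J = 0.01, skip_fraction = 1e-3,
                      max_iterations = 8, csf_max_edge = NULL,
                      csf_radius = 2),
    truncation = list(method = "sequential", n_components = 6,
                      octave_start_frequency = NULL),
    axons = list(fiber_diameter = 5.7, n_ranvier = 3,
                 center = c(2, 0, 0), n = c(2, 2, 1), spacing = 0.8,
                 orientations = list(c(0, 0, 1)),
                 excluded_labels = "csf"),
    thresholds = list(criterion = "activating_function", value = 0.1),
    times = list(n = 200, span = 1 / 130),
    output_dir = NULL, seed = 1, workers = 1
  ), class = "simulation_config")
}

#' Read and validate a simulation configuration from JSON
#'
#' Entries missing from the file take their defaults from
#' [default_simulation_config].
#'
#' @param path JSON file.
#' @return a validated `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(unclass(default_simulation_config()), user)
  validate_simulation_config(structure(cfg, class = "simulation_config"))
}

#' Validate a simulation configuration
#' @param cfg a `simulation_config` (named list).
#' @return the config, invisibly, after checks; errors name the offending
#'   entry.
#' @export
validate_simulation_config <- function(cfg) {
  sig <- cfg$signal
  if (!sig$shape %in% c("rectangular", "centered_triangular", "ramp"))
    stop("config signal.shape: unknown shape '", sig$shape, "'")
  if (!sig$mode %in% c("voltage", "current"))
    stop("config signal.mode must be voltage or current")
  if (sig$pulse_width >= 1 / sig$repetition_rate)
    stop("config signal.pulse_width must be below the period")
  if (isTRUE(cfg$physics$cpe) && sig$mode == "current")
    message("note: CPE correction is ignored in current mode ",
            "(interface in series does not affect the field)")
  if (!cfg$truncation$method %in% c("sequential", "magnitude_ranked",
                                    "octave_band"))
    stop("config truncation.method invalid")
  if (cfg$workers < 1) stop("config workers must be >= 1")
  invisible(cfg)
}

# content hash for step records (base tools only)
.hash_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  # drop the serialization header (R version stamp) from the digest input
  unname(tools::md5sum(f))
}

.step_paths <- function(outdir, name) {
  list(record = file.path(outdir, "steps", paste0(name, ".json")),
       state = file.path(outdir, "steps", paste0(name, ".rds")))
}

# run one pipeline step with resume support
.run_step <- function(outdir, name, input_hash, fun, records) {
  p <- .step_paths(outdir, name)
  if (file.exists(p$record) && file.exists(p$state)) {
    rec <- jsonlite::read_json(p$record)
    if (identical(rec$input_hash, input_hash) &&
        identical(rec$status, "completed")) {
      records[[name]] <- utils::modifyList(rec, list(status = "skipped"))
      return(list(value = readRDS(p$state), records = records))
    }
  }
  value <- tryCatch(fun(), error = function(e) {
    rec <- list(step = name, input_hash = input_hash,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                status = "failed", error = conditionMessage(e))
    dir.create(dirname(p$record), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(rec, p$record, auto_unbox = TRUE)
    stop("pipeline step '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  dir.create(dirname(p$record), recursive = TRUE, showWarnings = FALSE)
  saveRDS(value, p$state, version = 2)
  rec <- list(step = name, input_hash = input_hash,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              status = "completed", state = p$state)
  jsonlite::write_json(rec, p$record, auto_unbox = TRUE)
  records[[name]] <- rec
  list(value = value, records = records)
}

#' Run the full simulation pipeline
#'
#' Executes mesh construction, tissue/tensor mapping, axon placement and
#' filtering, optional adaptive refinement at the lowest retained
#' frequency, the per-frequency EQS solves (over `cfg$workers` parallel
#' workers; results are identical to a serial run), optional CPE
#' correction, current-mode scaling, compartment time courses and
#' threshold activation. Each step writes a metadata record under
#' `output_dir/steps/`; re-running with an unchanged configuration skips
#' completed steps.
#'
#' @param cfg a `simulation_config` (see [default_simulation_config]).
#' @return a results bundle (list) with the mesh, population, spectrum,
#'   per-frequency impedances, time courses, activation table, step
#'   records and artifact paths.
#' @export
run_simulation <- function(cfg) {
  cfg <- validate_simulation_config(cfg)
  outdir <- cfg$output_dir
  if (is.null(outdir)) outdir <- tempfile("dbsvcm_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  records <- list()
  h0 <- .hash_of(cfg[c("domain", "electrode", "mesh")])

  # 1: domain mesh
  st <- .run_step(outdir, "mesh_build", h0, function() {
    el <- cfg$electrode
    contacts <- do.call(rbind, lapply(el$contacts, as.data.frame))
    build_domain_mesh(domain = cfg$domain,
                      electrode = electrode_spec(
                        tip_position = unlist(el$tip_position),
                        direction = unlist(el$direction),
                        lead_radius = el$lead_radius,
                        contacts = contacts,
                        encapsulation_thickness = el$encapsulation_thickness),
                      target_edges = cfg$mesh$target_edges,
                      base_edge = cfg$mesh$base_edge,
                      roi_center = cfg$axons$center,
                      roi_radius = max(unlist(cfg$axons$n) *
                                         unlist(cfg$axons$spacing)) / 2 + 1)
  }, records)
  mesh <- st$value; records <- st$records

  # 2: tissue volume + mapping
  h1 <- .hash_of(list(h0, cfg$volume, cfg$tissue))
  st <- .run_step(outdir, "tissue_map", h1, function() {
    vol <- if (!is.null(cfg$volume$path))
      read_voxel_volume(cfg$volume$path, cfg$volume$legend)
    else make_synthetic_tissue_volume(
      kind = cfg$volume$kind, n = unlist(cfg$volume$n),
      voxel_size = cfg$volume$voxel_size, seed = cfg$seed,
      pocket_center = unlist(cfg$volume$pocket_center),
      pocket_semiaxes = unlist(cfg$volume$pocket_semiaxes))
    list(vol = vol, mesh = map_tissue_to_cells(mesh, vol, "grey_matter"))
  }, records)
  vol <- st$value$vol; mesh <- st$value$mesh; records <- st$records

  # 3: anisotropy tensors
  if (isTRUE(cfg$anisotropy$enabled)) {
    h2 <- .hash_of(list(h1, cfg$anisotropy))
    st <- .run_step(outdir, "tensor_map", h2, function() {
      tv <- make_synthetic_tensor_volume(n = unlist(cfg$volume$n),
                                         voxel_size = cfg$volume$voxel_size,
                                         axis = cfg$anisotropy$axis,
                                         ratio = cfg$anisotropy$ratio)
      map_tensors_to_cells(mesh, tv, cfg$anisotropy$normalization)
    }, records)
    mesh <- st$value; records <- st$records
  }

  # 4: axon placement + filtering
  h3 <- .hash_of(list(h1, cfg$axons))
  st <- .run_step(outdir, "axon_place", h3, function() {
    ax <- cfg$axons
    morph <- axon_morphology(ax$fiber_diameter, ax$n_ranvier)
    pop <- build_ordered_array(morph, unlist(ax$center), unlist(ax$n),
                               unlist(ax$spacing),
                               lapply(ax$orientations, unlist))
    pop <- filter_population(pop, mesh, vol, ax$excluded_labels)
    write_population_csv(pop, file.path(outdir, "population.csv"))
    pop
  }, records)
  pop <- st$value; records <- st$records
  compartments <- do.call(rbind, lapply(pop$axons[pop$survived],
                                        function(a) a$coords))

  # spectrum and truncation
  signal <- stim_signal(cfg$signal$shape, cfg$signal$amplitude,
                        cfg$signal$pulse_width, cfg$signal$repetition_rate,
                        cfg$signal$phase_shift, cfg$signal$mode)
  spec <- fourier_coefficients(signal, cfg$physics$f_max)
  scheme <- truncation_scheme(cfg$truncation$method,
                              cfg$truncation$n_components,
                              cfg$truncation$octave_start_frequency)
  spec <- truncate_spectrum(spec, scheme)
  freqs <- solve_frequencies(spec)
  f_ref <- min(freqs[freqs > 0])

  # 5: adaptive refinement at the lowest retained frequency
  if (isTRUE(cfg$refinement$enabled) && !is.null(compartments)) {
    h4 <- .hash_of(list(h3, cfg$refinement, f_ref))
    st <- .run_step(outdir, "refine", h4, function() {
      rc <- refinement_config(cfg$refinement$theta_csf,
                              cfg$refinement$theta_phi,
                              cfg$refinement$theta_E, cfg$refinement$theta_J,
                              cfg$refinement$skip_fraction,
                              cfg$refinement$max_iterations,
                              cfg$refinement$csf_max_edge)
      rr <- run_refinement(mesh, .materials_of(cfg), NULL, f_ref,
                           compartments, rc, vol,
                           current_mode = cfg$signal$mode == "current",
                           csf_radius = cfg$refinement$csf_radius,
                           order = cfg$physics$order)
      write_refinement_report(rr, file.path(outdir, "refinement.json"))
      rr$mesh
    }, records)
    mesh <- st$value; records <- st$records
  }

  # 6: per-frequency solves (parallelizable; deterministic merge order)
  h5 <- .hash_of(list(h3, cfg$physics, cfg$signal, cfg$truncation, freqs))
  st <- .run_step(outdir, "solve_spectrum", h5, function() {
    solve_one <- function(f) {
      res <- .solve_frequency(mesh, cfg, f, compartments)
      res
    }
    out <- if (cfg$workers > 1)
      parallel::mclapply(freqs, solve_one, mc.cores = cfg$workers,
                         mc.preschedule = TRUE)
    else lapply(freqs, solve_one)
    names(out) <- as.character(freqs)
    bad <- vapply(out, function(o) !is.list(o) || is.null(o$Z),
                  logical(1))
    if (any(bad)) stop("frequency solve failed at ",
                       paste(freqs[bad], collapse = ", "), " Hz")
    imp <- data.frame(frequency_hz = freqs,
                      Z_re = vapply(out, function(o) Re(o$Z), numeric(1)),
                      Z_im = vapply(out, function(o) Im(o$Z), numeric(1)))
    utils::write.csv(imp, file.path(outdir, "impedance.csv"),
                     row.names = FALSE)
    out
  }, records)
  persolve <- st$value; records <- st$records

  # 7: compartment time courses
  times <- seq(0, cfg$times$span, length.out = cfg$times$n + 1)[-(cfg$times$n + 1)]
  h6 <- .hash_of(list(h5, cfg$times))
  st <- .run_step(outdir, "time_courses", h6, function() {
    if (is.null(compartments)) return(list())
    probes <- lapply(persolve, function(o) o$probe)
    nsurv <- which(pop$survived)
    offsets <- c(0, cumsum(vapply(pop$axons[nsurv],
                                  function(a) nrow(a$coords), 1L)))
    courses <- list()
    for (s in seq_along(nsurv)) {
      rng <- (offsets[s] + 1):offsets[s + 1]
      H <- vapply(probes, function(p) p[rng], complex(length(rng)))
      H <- matrix(H, nrow = length(rng))
      tc <- vapply(seq_len(nrow(H)), function(i)
        reconstruct_time_course(spec, H[i, ], times),
        numeric(length(times)))
      courses[[as.character(nsurv[s])]] <- matrix(tc, nrow = length(times))
    }
    courses
  }, records)
  courses <- st$value; records <- st$records

  # 8: activation
  h7 <- .hash_of(list(h6, cfg$thresholds))
  st <- .run_step(outdir, "activation", h7, function() {
    if (!sum(pop$survived)) {
      act <- data.frame(axon = integer(0), peak_field = numeric(0),
                        peak_af = numeric(0), activated = logical(0))
    } else if (cfg$thresholds$criterion == "activating_function") {
      act <- activation_by_threshold(pop, "activating_function",
                                     cfg$thresholds$value, courses = courses)
    } else {
      solref <- .solve_frequency(mesh, cfg, f_ref, NULL)$solution
      act <- activation_by_threshold(pop, "field_magnitude",
                                     cfg$thresholds$value, solution = solref)
    }
    utils::write.csv(act, file.path(outdir, "activation.csv"),
                     row.names = FALSE)
    act
  }, records)
  act <- st$value; records <- st$records

  structure(list(config = cfg, output_dir = outdir, mesh = mesh,
                 volume = vol, population = pop, spectrum = spec,
                 frequencies = freqs,
                 impedance = data.frame(
                   frequency_hz = freqs,
                   Z = vapply(persolve, function(o) o$Z, complex(1))),
                 times = times, courses = courses, activation = act,
                 steps = records),
            class = "simulation_bundle")
}

# materials table from config
.materials_of <- function(cfg) {
  tissue_table(encapsulation_scale = cfg$tissue$encapsulation_scale,
               overrides = cfg$tissue$overrides)
}

# one-frequency solve honoring mode, CPE and scaling; returns probes at
# the compartments, the contact current and the tissue impedance
.solve_frequency <- function(mesh, cfg, f, compartments) {
  materials <- .materials_of(cfg)
  qs <- isTRUE(cfg$physics$qs_mode)
  order <- cfg$physics$order
  bc <- boundary_spec(mesh$contacts, floating_eps = cfg$physics$floating_eps)
  sol <- solve_eqs(mesh, materials, bc, f, order, qs)
  src <- mesh$contacts$id[mesh$contacts$role == "active"][1]
  J <- contact_current(sol, src)
  Z <- impedance(sol, J)
  if (cfg$signal$mode == "current") {
    sol <- scale_to_current(sol, J, mesh$contacts$value[
      mesh$contacts$role == "active"][1])
  } else if (isTRUE(cfg$physics$cpe) && f > 0) {
    act <- which(mesh$contacts$role == "active")
    gnd <- which(mesh$contacts$role == "ground")
    if (length(act) >= 1 && length(gnd) >= 1) {
      area <- .contact_area(mesh, mesh$contacts$id[act[1]])
      area2 <- .contact_area(mesh, mesh$contacts$id[gnd[1]])
      cpe1 <- cpe_from_area(cfg$physics$cpe_K_S_area, area,
                            cfg$physics$cpe_alpha)
      cpe2 <- cpe_from_area(cfg$physics$cpe_K_S_area, area2,
                            cfg$physics$cpe_alpha)
      Vsrc <- Re(sol$V_source)
      corr <- corrected_contact_voltages(Vsrc, Z, cpe1, cpe2, f,
                                         c(mesh$contacts$value[act[1]],
                                           mesh$contacts$value[gnd[1]]))
      vals <- as.complex(mesh$contacts$value)
      vals[act[1]] <- corr$contact_values[1]
      vals[gnd[1]] <- corr$contact_values[2]
      bc2 <- boundary_spec(mesh$contacts, vals,
                           floating_eps = cfg$physics$floating_eps)
      sol <- solve_eqs(mesh, materials, bc2, f, order, qs)
    }
  }
  probe <- if (!is.null(compartments)) probe_potential(sol, compartments)
           else NULL
  list(frequency = f, probe = probe, J = J$J, Z = Z, solution = sol)
}

# total area of a contact's facets (mm^2)
.contact_area <- function(mesh, contact_id) {
  fac <- contact_facets(mesh, contact_id)
  p1 <- mesh$nodes[fac$n1, , drop = FALSE]
  u <- mesh$nodes[fac$n2, , drop = FALSE] - p1
  v <- mesh$nodes[fac$n3, , drop = FALSE] - p1
  sum(sqrt((u[, 2] * v[, 3] - u[, 3] * v[, 2])^2 +
           (u[, 3] * v[, 1] - u[, 1] * v[, 3])^2 +
           (u[, 1] * v[, 2] - u[, 2] * v[, 1])^2) / 2)
}

#' Summarize a results bundle
#'
#' @param bundle a `simulation_bundle` from [run_simulation].
#' @return character vector (one line per item), printed invisibly.
#' @export
summarize_results <- function(bundle) {
  pop <- bundle$population
  lines <- c(sprintf("axons placed: %d", length(pop$axons)),
             sprintf("axons surviving: %d", sum(pop$survived)))
  if (any(!pop$survived)) {
    tab <- table(pop$reason[!pop$survived])
    lines <- c(lines, sprintf("excluded (%s): %d", names(tab), tab))
  }
  if (!is.null(bundle$activation) && nrow(bundle$activation))
    lines <- c(lines, sprintf("axons activated: %d",
                              sum(bundle$activation$activated)))
  for (i in seq_len(nrow(bundle$impedance)))
    lines <- c(lines, sprintf("impedance at %g Hz: %.4g Ohm (|Z|)",
                              bundle$impedance$frequency_hz[i],
                              Mod(bundle$impedance$Z[i])))
  lines <- c(lines, sprintf("mesh: %d cells", nrow(bundle$mesh$cells)))
  if (is.null(bundle$activation))
    lines <- c(lines, "warning: incomplete bundle (no activation step)")
  cat(lines, sep = "\n")
  invisible(lines)
}
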