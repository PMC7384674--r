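# Two-stage adaptive mesh refinement driven by pointwise solution
# convergence on neuron compartments: a CSF pass (highly conductive CSF
# must be resolved near the neurons before anything else) followed by a
# per-region adaptive pass. Four criteria control the loop: the CSF and
# potential deviations (max-norm of the potential-magnitude change on the
# compartments, relative to the voltage drop), the relative field change
# at cell midpoints (marks cells to bisect), and, in current mode, the
# per-cell current mismatch between a parent cell and its children.

#' Refinement configuration
#'
#' @param theta_csf CSF-pass deviation threshold (fraction of V_drop).
#' @param theta_phi adaptive-pass potential deviation threshold.
#' @param theta_E relative field-change threshold for cell marking.
#' @param theta_J relative current-deviation threshold (current mode).
#' @param skip_fraction cells carrying less than this fraction of the
#'   total current are never marked by the current criterion.
#' @param max_iterations cap on refinement iterations per region.
#' @param csf_max_edge target edge length of CSF cells near neurons, mm
#'   (`NULL`: the voxel size).
#' @return an object of class `refinement_config`.
#' @export
refinement_config <- function(theta_csf = 0.01, theta_phi = 0.01,
                              theta_E = 0.05, theta_J = 0.01,
                              skip_fraction = 1e-3, max_iterations = 8,
                              csf_max_edge = NULL) {
  if (any(c(theta_csf, theta_phi, theta_E, theta_J) <= 0))
    stop("all thresholds must be > 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(theta_csf = theta_csf, theta_phi = theta_phi,
                 theta_E = theta_E, theta_J = theta_J,
                 skip_fraction = skip_fraction,
                 max_iterations = max_iterations,
                 csf_max_edge = csf_max_edge),
            class = "refinement_config")
}

#' CSF-pass deviation between two compartment potential vectors
#'
#' Max-norm of the difference of potential magnitudes on the neuron
#' compartments, relative to the voltage drop across the tissue.
#'
#' @param phi_aim,phi_k complex potentials on the compartments (equal
#'   length).
#' @param V_drop voltage drop magnitude, V (> 0).
#' @return dimensionless deviation.
#' @export
csf_deviation <- function(phi_aim, phi_k, V_drop) {
  if (length(phi_aim) != length(phi_k))
    stop("compartment vectors differ in length")
  if (V_drop <= 0) stop("V_drop must be > 0")
  max(abs(Mod(phi_aim) - Mod(phi_k))) / V_drop
}

#' Adaptive-pass potential deviation
#'
#' Same functional form as [csf_deviation], applied to successive
#' refinement iterates.
#' @param phi_new,phi_old complex compartment potentials.
#' @param V_drop voltage drop magnitude, V.
#' @return dimensionless deviation.
#' @export
potential_deviation <- function(phi_new, phi_old, V_drop)
  csf_deviation(phi_new, phi_old, V_drop)

#' Mark cells by relative field change
#'
#' Marks the cells (midpoints of the coarser mesh) where
#' `||E_new - E_old||_2 / ||E_new||_2 > theta_E`. Cells with a vanishing
#' new field are never marked (the criterion divides by `||E_new||`).
#'
#' @param E_new,E_old complex n x 3 field matrices at cell midpoints.
#' @param theta_E relative threshold.
#' @return integer vector of marked cell indices.
#' @export
field_deviation_mark <- function(E_new, E_old, theta_E) {
  nn <- sqrt(rowSums(Mod(E_new)^2))
  nd <- sqrt(rowSums(Mod(E_new - E_old)^2))
  which(nn >= 1e-12 & nd / pmax(nn, 1e-300) > theta_E)
}

#' Mark cells by current deviation under refinement
#'
#' Marks parents where the relative mismatch between the summed child
#' currents and the parent current exceeds `theta_J`. Parents carrying
#' less than `skip_fraction` of the total current are skipped.
#'
#' @param parent_J numeric (or complex-magnitude) per-parent integrated
#'   current.
#' @param child_sum_J per-parent sum of child-cell currents.
#' @param theta_J relative threshold.
#' @param skip_fraction small-current gate.
#' @return integer vector of marked parent indices.
#' @export
current_deviation_mark <- function(parent_J, child_sum_J, theta_J,
                                   skip_fraction = 1e-3) {
  parent_J <- abs(parent_J); child_sum_J <- abs(child_sum_J)
  total <- sum(parent_J)
  dev <- abs(child_sum_J - parent_J) / pmax(child_sum_J, 1e-300)
  which(parent_J >= skip_fraction * total & child_sum_J > 0 & dev > theta_J)
}

# integrated |J| per cell: |kappa grad phi| * volume at the centroid
.cell_currents <- function(sol, cells = seq_len(nrow(sol$mesh$cells))) {
  E <- cell_field(sol, cells)
  KE <- .kappa_times(sol, cells, E)
  sqrt(rowSums(Mod(KE)^2)) * cell_volumes(sol$mesh)[cells]
}

#' Run the two-stage adaptive refinement
#'
#' Stage 1 resolves CSF near the neuron compartments: cells containing
#' CSF voxels within the compartment vicinity are bisected until none
#' exceeds the target edge; the solution on that maximally refined mesh
#' is the aim, and intermediate iterates stop as soon as their deviation
#' from the aim drops below `theta_csf`. Stage 2 sweeps the regions
#' (contact vicinity + encapsulation, then ROI, then ROT): each region is
#' uniformly bisected as a convergence probe; if the compartment
#' potentials move more than `theta_phi`, the cells with a large field
#' change (and, in current mode, a large current mismatch) are refined on
#' the coarser mesh and the probe repeats. A converged region is
#' re-probed once with another uniform bisection to guard against local
#' convergence.
#'
#' @param mesh a `domain_mesh` with tissue mapped.
#' @param materials a [tissue_table].
#' @param bc a [boundary_spec] (or `NULL` for the mesh's contact table).
#' @param f frequency to refine at, Hz (the adapted mesh is reused for
#'   the whole spectrum).
#' @param compartments n x 3 matrix of neuron compartment points (mm).
#' @param config a [refinement_config].
#' @param vol the `voxel_volume` used for tissue mapping (needed for the
#'   CSF pass and re-mapping of children; `NULL` skips the CSF pass).
#' @param current_mode evaluate the current criterion as well.
#' @param csf_radius vicinity radius around compartments for the CSF
#'   pass, mm.
#' @param order element order for the refinement solves.
#' @return list with `mesh` (adapted) and `report` (a data.frame of
#'   per-iteration records plus a `converged` flag and stage fields).
#' @export
run_refinement <- function(mesh, materials, bc, f, compartments, config,
                           vol = NULL, current_mode = FALSE,
                           csf_radius = 2, order = 2) {
  stopifnot(inherits(config, "refinement_config"))
  compartments <- matrix(compartments, ncol = 3)
  rows <- list()
  note <- function(stage, region, iter, n_refined, crit, conv)
    rows[[length(rows) + 1]] <<- data.frame(
      stage = stage, region = region, iteration = iter,
      cells_refined = n_refined, criterion = crit, converged = conv,
      n_cells = NA_integer_)
  solve_on <- function(m) solve_eqs(m, materials, bc, f, order = order)
  probe_on <- function(sol) probe_potential(sol, compartments)

  converged <- TRUE
  # --- stage 1: CSF pass
  if (!is.null(vol) && "csf" %in% vol$legend) {
    max_edge <- if (is.null(config$csf_max_edge)) abs(vol$affine[1, 1])
                else config$csf_max_edge
    aim_mesh <- mesh
    for (i in seq_len(config$max_iterations + 4)) {
      cs <- csf_cells_near_neurons(aim_mesh, vol, compartments, csf_radius,
                                   max_edge)
      if (!length(cs)) break
      aim_mesh <- refine_cells(aim_mesh, cs, volume = vol)
    }
    sol_aim <- solve_on(aim_mesh)
    phi_aim <- probe_on(sol_aim)
    Vd <- sol_aim$V_drop
    cur <- mesh
    sol_k <- solve_on(cur)
    dev <- csf_deviation(phi_aim, probe_on(sol_k), Vd)
    note("csf", "csf", 0L, 0L, dev, dev <= config$theta_csf)
    it <- 0L
    while (dev > config$theta_csf && it < config$max_iterations) {
      it <- it + 1L
      cs <- csf_cells_near_neurons(cur, vol, compartments, csf_radius,
                                   max_edge)
      if (!length(cs)) { cur <- aim_mesh; dev <- 0; note("csf", "csf", it, 0L, dev, TRUE); break }
      cur <- refine_cells(cur, cs, volume = vol)
      sol_k <- solve_on(cur)
      dev <- csf_deviation(phi_aim, probe_on(sol_k), Vd)
      note("csf", "csf", it, length(cs), dev, dev <= config$theta_csf)
    }
    if (dev > config$theta_csf) converged <- FALSE
    mesh <- cur
  }

  # --- stage 2: per-region adaptive pass
  groups <- list(vicinity = c("contact_vicinity", "encapsulation"),
                 ROI = "ROI", ROT = "ROT")
  for (gname in names(groups)) {
    regs <- groups[[gname]]
    if (!any(mesh$region %in% regs)) next
    sol_old <- solve_on(mesh)
    phi_old <- probe_on(sol_old)
    reg_conv <- FALSE
    for (it in seq_len(config$max_iterations)) {
      # every convergence test probes against a uniform bisection of the
      # region, so a passing test is already verified against uniform
      # refinement (no local-convergence blind spot)
      incells <- which(mesh$region %in% regs)
      probe_mesh <- refine_cells(mesh, incells,
                                 volume = if (is.null(vol)) NULL else vol)
      pm <- attr(probe_mesh, "parent_map")
      sol_new <- solve_on(probe_mesh)
      phi_new <- probe_on(sol_new)
      dev <- potential_deviation(phi_new, phi_old, sol_new$V_drop)
      if (dev <= config$theta_phi) {
        note("adaptive", gname, it, 0L, dev, TRUE)
        reg_conv <- TRUE
        break
      }
      # mark on the coarser mesh: field change at its cell midpoints
      E_old <- cell_field(sol_old, incells)
      mid <- cell_centroids(mesh)[incells, , drop = FALSE]
      loc <- .locate_points(probe_mesh, mid)
      E_new <- t(vapply(seq_along(incells), function(i)
        cell_field(sol_new, loc$cell[i])[1, ], complex(3)))
      marked <- incells[field_deviation_mark(E_new, E_old, config$theta_E)]
      if (current_mode) {
        pj <- .cell_currents(sol_old, incells)
        cj <- vapply(incells, function(cc)
          sum(.cell_currents(sol_new, pm[[as.character(cc)]])), numeric(1))
        marked <- union(marked,
                        incells[current_deviation_mark(
                          pj, cj, config$theta_J, config$skip_fraction)])
      }
      if (!length(marked)) marked <- incells  # fall back to uniform
      mesh <- refine_cells(mesh, marked,
                           volume = if (is.null(vol)) NULL else vol)
      sol_old <- solve_on(mesh)
      phi_old <- probe_on(sol_old)
      note("adaptive", gname, it, length(marked), dev, FALSE)
    }
    if (!reg_conv) converged <- FALSE
  }

  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0), region = character(0),
               iteration = integer(0), cells_refined = integer(0),
               criterion = numeric(0), converged = logical(0),
               n_cells = integer(0))
  list(mesh = mesh, report = report, converged = converged,
       n_cells = nrow(mesh$cells))
}

#' Write a refinement report as JSON
#' @param result value of [run_refinement].
#' @param path output path.
#' @export
write_refinement_report <- function(result, path) {
  jsonlite::write_json(list(converged = result$converged,
                            n_cells = result$n_cells,
                            iterations = result$report),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
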