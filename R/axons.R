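# Myelinated-axon compartment geometry (double-cable morphology: nodes of
# Ranvier separated by MYSA / FLUT / STIN internodal segments), ordered
# array construction, population filtering against the mesh and tissue
# map, time courses on compartments, and threshold-based activation
# estimates. Geometry only — no membrane dynamics.

# geometric morphology table of the double-cable axon model, keyed by
# fiber diameter (um): node-to-node spacing and per-type segment lengths.
# STIN length follows from the spacing identity
# deltax = node + 2 MYSA + 2 FLUT + 6 STIN.
.axon_morphology_table <- function() {
  d <- data.frame(
    diameter = c(5.7, 7.3, 8.7, 10.0, 11.5, 12.8, 14.0, 15.0, 16.0),
    node_spacing = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
    node_length = 1, mysa_length = 3,
    flut_length = c(35, 38, 40, 46, 50, 54, 56, 58, 60))
  d$stin_length <- (d$node_spacing - d$node_length - 2 * d$mysa_length -
                      2 * d$flut_length) / 6
  d
}

#' Axon morphology
#'
#' @param fiber_diameter fiber diameter, um; must be one of the tabulated
#'   diameters.
#' @param n_ranvier number of nodes of Ranvier (>= 2).
#' @return an object of class `axon_morphology` with the internodal
#'   pattern (MYSA, FLUT, 3x STIN mirrored) and per-type lengths in um.
#' @export
axon_morphology <- function(fiber_diameter = 5.7, n_ranvier = 21) {
  tab <- .axon_morphology_table()
  row <- tab[abs(tab$diameter - fiber_diameter) < 1e-9, ]
  if (!nrow(row))
    stop("fiber diameter ", fiber_diameter, " um not in the morphology ",
         "table; available: ", paste(tab$diameter, collapse = ", "))
  if (n_ranvier < 2) stop("n_ranvier must be >= 2")
  pattern <- c("mysa", "flut", rep("stin", 6), "flut", "mysa")
  len <- c(node = row$node_length, mysa = row$mysa_length,
           flut = row$flut_length, stin = row$stin_length)
  structure(list(fiber_diameter = fiber_diameter, n_ranvier = n_ranvier,
                 pattern = pattern, lengths_um = len,
                 node_spacing_um = row$node_spacing),
            class = "axon_morphology")
}

#' Build a straight axon
#'
#' Lays compartment centres along a direction: nodes of Ranvier separated
#' by the internodal pattern, with centre-to-centre steps of half the
#' adjacent segment lengths.
#'
#' @param morph an [axon_morphology].
#' @param start coordinate of the first node of Ranvier, mm.
#' @param direction direction vector (normalized internally).
#' @return list with `coords` (n x 3, mm), `types` (compartment type per
#'   row), `morph`.
#' @export
build_axon <- function(morph, start = c(0, 0, 0), direction = c(1, 0, 0)) {
  stopifnot(inherits(morph, "axon_morphology"))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  direction <- direction / nrm
  types <- c("node", rep(c(morph$pattern, "node"), morph$n_ranvier - 1))
  seglen <- morph$lengths_um[types] * 1e-3  # mm
  s <- cumsum(c(0, (seglen[-length(seglen)] + seglen[-1]) / 2))
  coords <- matrix(start, length(s), 3, byrow = TRUE) + outer(s, direction)
  list(coords = coords, types = types, morph = morph)
}

#' Build an ordered axon array
#'
#' One axon per grid point per orientation, each centred on its grid
#' point; deterministic ordering with x fastest, then y, z, then
#' orientation.
#'
#' @param morph an [axon_morphology].
#' @param center array centre, mm.
#' @param n integer(3): grid points per dimension.
#' @param spacing numeric(3) or scalar: grid spacing, mm.
#' @param orientations list of direction vectors.
#' @return an object of class `axon_population`.
#' @export
build_ordered_array <- function(morph, center = c(0, 0, 0), n = c(3, 3, 3),
                                spacing = 1,
                                orientations = list(c(1, 0, 0))) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(n < 1) || any(spacing <= 0)) stop("positive counts and spacings required")
  offs <- lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * spacing[a])
  grid <- as.matrix(expand.grid(x = offs[[1]], y = offs[[2]], z = offs[[3]]))
  axons <- list()
  for (o in seq_along(orientations)) {
    dirn <- orientations[[o]] / sqrt(sum(orientations[[o]]^2))
    span <- (morph$n_ranvier - 1) * morph$node_spacing_um * 1e-3
    for (gidx in seq_len(nrow(grid))) {
      start <- center + grid[gidx, ] - dirn * span / 2
      ax <- build_axon(morph, start, dirn)
      axons[[length(axons) + 1]] <- list(coords = ax$coords,
                                         types = ax$types,
                                         source = "generated_array")
    }
  }
  structure(list(axons = axons,
                 survived = rep(TRUE, length(axons)),
                 reason = rep(NA_character_, length(axons)),
                 morph = morph),
            class = "axon_population")
}

#' @export
print.axon_population <- function(x, ...) {
  cat("axon_population:", length(x$axons), "axons,",
      sum(x$survived), "surviving\n")
  invisible(x)
}

#' Filter an axon population against the domain
#'
#' An axon is excluded if any compartment lies outside the mesh, inside
#' an encapsulation or floating-conductor (electrode metal) cell, or in a
#' voxel whose tissue label is excluded (e.g. CSF). The exclusion reason
#' is recorded; surviving axons are untouched. Idempotent.
#'
#' @param pop an `axon_population`.
#' @param mesh a `domain_mesh`.
#' @param vol a `voxel_volume` (may be `NULL` to skip label exclusion).
#' @param excluded_labels character vector of excluded tissue labels.
#' @return the population with updated `survived` and `reason`.
#' @export
filter_population <- function(pop, mesh, vol = NULL,
                              excluded_labels = "csf") {
  stopifnot(inherits(pop, "axon_population"))
  bad_region <- c("encapsulation", "floating_conductor")
  for (a in seq_along(pop$axons)) {
    if (!is.na(pop$reason[a])) next
    pts <- pop$axons[[a]]$coords
    loc <- .locate_points(mesh, pts, error_outside = FALSE)
    if (anyNA(loc$cell)) {
      pop$survived[a] <- FALSE; pop$reason[a] <- "outside_domain"; next
    }
    reg <- mesh$region[loc$cell]
    metal <- !is.na(mesh$contact_cell[loc$cell])
    if (any(reg == "encapsulation")) {
      pop$survived[a] <- FALSE; pop$reason[a] <- "encapsulation"; next
    }
    if (any(reg == "floating_conductor" | metal)) {
      pop$survived[a] <- FALSE; pop$reason[a] <- "floating_conductor"; next
    }
    if (!is.null(vol) && length(excluded_labels)) {
      ci <- round(.world_to_voxel(vol, pts))
      dims <- dim(vol$labels)
      ci <- pmin(pmax(ci, 0), matrix(dims - 1, nrow(ci), 3, byrow = TRUE))
      codes <- vol$labels[ci + 1]
      labs <- vol$legend[as.character(codes)]
      hit <- labs %in% excluded_labels
      if (any(hit)) {
        pop$survived[a] <- FALSE
        pop$reason[a] <- labs[which(hit)[1]]
      }
    }
  }
  pop
}

#' Time courses of the potential on axon compartments
#'
#' For each surviving axon, probes the per-frequency field solutions at
#' every compartment and reconstructs the time-dependent potential via
#' the inverse Fourier transform of the stimulus spectrum.
#'
#' @param pop an `axon_population` (filtered).
#' @param solutions list of `field_solution`, one per solve frequency of
#'   `spec` (in the order of `solve_frequencies(spec)`).
#' @param spec the (possibly truncated) stimulus `spectrum`.
#' @param times numeric vector of times, seconds.
#' @param dc_solution optional `field_solution` for the DC component when
#'   the spectrum retains f = 0 (a purely conductive solve).
#' @return list per surviving axon of `n_times x n_compartments` matrices;
#'   names are the axon indices in the population.
#' @export
compartment_time_courses <- function(pop, solutions, spec, times,
                                     dc_solution = NULL) {
  reps <- solve_frequencies(spec)
  nonzero <- reps[reps > 0]
  sols <- solutions
  if (length(sols) == length(nonzero) && any(reps == 0)) {
    if (is.null(dc_solution)) stop("spectrum retains DC but no DC solution given")
    sols <- c(list(dc_solution), sols)
  }
  if (length(sols) != length(reps))
    stop("need one field solution per solve frequency (", length(reps), ")")
  out <- list()
  for (a in which(pop$survived)) {
    pts <- pop$axons[[a]]$coords
    H <- vapply(sols, function(s) probe_potential(s, pts),
                complex(nrow(pts)))
    H <- matrix(H, nrow = nrow(pts))
    tc <- vapply(seq_len(nrow(pts)), function(i)
      reconstruct_time_course(spec, H[i, ], times), numeric(length(times)))
    out[[as.character(a)]] <- matrix(tc, nrow = length(times))
  }
  out
}

#' Threshold-based activation estimate
#'
#' Two geometric activation approximations: `field_magnitude` flags an
#' axon when the peak electric-field magnitude over its compartments
#' reaches the threshold (V/mm); `activating_function` flags it when the
#' peak second spatial difference of the potential along the nodes of
#' Ranvier (actual inter-node spacing) reaches the threshold (V/mm^2).
#'
#' @param pop a filtered `axon_population`.
#' @param criterion `"field_magnitude"` or `"activating_function"`.
#' @param threshold positive threshold (V/mm or V/mm^2).
#' @param solution a `field_solution` used to evaluate fields/potentials.
#' @param courses optional output of [compartment_time_courses]; when
#'   given, the activating function is evaluated on the time courses and
#'   its peak over time is used.
#' @param nodes_only evaluate the activating function at nodes of Ranvier
#'   only (default) or at all compartments.
#' @return data.frame per surviving axon: `axon`, `peak_field`
#'   (V/mm, field criterion), `peak_af` (V/mm^2, activating function),
#'   `activated`.
#' @export
activation_by_threshold <- function(pop,
                                    criterion = c("field_magnitude",
                                                  "activating_function"),
                                    threshold, solution = NULL,
                                    courses = NULL, nodes_only = TRUE) {
  criterion <- match.arg(criterion)
  if (threshold <= 0) stop("threshold must be > 0")
  idx <- which(pop$survived)
  res <- data.frame(axon = idx, peak_field = NA_real_, peak_af = NA_real_,
                    activated = FALSE)
  for (r in seq_along(idx)) {
    a <- idx[r]
    pts <- pop$axons[[a]]$coords
    types <- pop$axons[[a]]$types
    if (criterion == "field_magnitude") {
      if (is.null(solution)) stop("field criterion needs a field solution")
      loc <- .locate_points(solution$mesh, pts)
      E <- .facet_gradients(solution, loc$cell, loc$bary)
      res$peak_field[r] <- max(sqrt(rowSums(Mod(E)^2)))
      res$activated[r] <- res$peak_field[r] >= threshold
    } else {
      sel <- if (nodes_only) which(types == "node") else seq_along(types)
      if (length(sel) < 3)
        stop("activating function needs >= 3 nodes (axon ", a, ")")
      s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))[sel]
      phi <- if (!is.null(courses)) courses[[as.character(a)]][, sel, drop = FALSE]
             else matrix(Mod(probe_potential(solution, pts[sel, , drop = FALSE])),
                         nrow = 1)
      af <- matrix(0, nrow(phi), length(sel))
      for (i in 2:(length(sel) - 1)) {
        h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
        af[, i] <- 2 * (phi[, i - 1] / (h1 * (h1 + h2)) -
                          phi[, i] / (h1 * h2) +
                          phi[, i + 1] / (h2 * (h1 + h2)))
      }
      res$peak_af[r] <- max(af)
      res$activated[r] <- res$peak_af[r] >= threshold
    }
  }
  res
}

#' Write an axon population as CSV
#' @param pop an `axon_population`.
#' @param path output CSV
#'   (`axon_id, compartment_index, x_mm, y_mm, z_mm, compartment_type`).
#' @export
write_population_csv <- function(pop, path) {
  rows <- lapply(seq_along(pop$axons), function(a) {
    ax <- pop$axons[[a]]
    data.frame(axon_id = a, compartment_index = seq_len(nrow(ax$coords)),
               x_mm = ax$coords[, 1], y_mm = ax$coords[, 2],
               z_mm = ax$coords[, 3], compartment_type = ax$types)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an axon population from CSV
#' @param path CSV in the format of [write_population_csv].
#' @return an `axon_population` with `source = "imported"`.
#' @export
read_population_csv <- function(path) {
  d <- utils::read.csv(path)
  axons <- lapply(split(d, d$axon_id), function(g) {
    g <- g[order(g$compartment_index), ]
    list(coords = as.matrix(g[, c("x_mm", "y_mm", "z_mm")]),
         types = as.character(g$compartment_type), source = "imported")
  })
  names(axons) <- NULL
  structure(list(axons = axons, survived = rep(TRUE, length(axons)),
                 reason = rep(NA_character_, length(axons)), morph = NULL),
            class = "axon_population")
}
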