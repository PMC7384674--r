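# Voxel tissue-label and diffusion-tensor volumes: synthetic phantoms,
# NIfTI / plain-text readers, and the voxel-to-mesh mapping operations.
# Voxel indices are 0-based; the affine maps (i, j, k, 1) to world mm
# (NIfTI convention); voxel centres sit at integer indices.

#' Construct a voxel label volume
#'
#' @param labels integer 3D array of tissue label codes.
#' @param affine 4x4 voxel-index-to-world transform (mm), invertible.
#' @param legend named character vector mapping label codes (names) to
#'   tissue labels, e.g. `c("1" = "grey_matter")`; must cover all codes
#'   present.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(labels, affine, legend) {
  stopifnot(length(dim(labels)) == 3, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-15) stop("affine must be invertible")
  present <- unique(as.vector(labels))
  if (!all(as.character(present) %in% names(legend)))
    stop("legend does not cover all labels present in the volume")
  structure(list(labels = labels, affine = affine, legend = legend),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(dim(x$labels), collapse = " x "),
      "voxels; labels:", paste(x$legend, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a voxel tensor volume
#'
#' @param comp 4D array `(nx, ny, nz, 6)` with components
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz per voxel.
#' @param affine 4x4 voxel-index-to-world transform (mm).
#' @return an object of class `tensor_volume`.
#' @export
tensor_volume <- function(comp, affine) {
  stopifnot(length(dim(comp)) == 4, dim(comp)[4] == 6)
  structure(list(comp = comp, affine = affine), class = "tensor_volume")
}

# world -> continuous voxel index (0-based)
.world_to_voxel <- function(vol, pts) {
  inv <- solve(vol$affine)
  p <- cbind(pts, 1) %*% t(inv)
  p[, 1:3, drop = FALSE]
}

.voxel_to_world <- function(vol, idx) {
  p <- cbind(idx, 1) %*% t(vol$affine)
  p[, 1:3, drop = FALSE]
}

#' Synthetic tissue phantoms
#'
#' Deterministic voxel phantoms used in place of segmented MRI data:
#' `uniform` (single label), `layered_sphere` (grey core, white shell, CSF
#' outer shell), `csf_pocket` (grey background with an ellipsoidal CSF
#' inclusion centred near `pocket_center`), `half_space` (grey for x < 0,
#' white for x >= 0).
#'
#' @param kind phantom type.
#' @param n integer(3) or scalar: voxels per dimension.
#' @param voxel_size voxel edge length, mm.
#' @param seed integer seed (phantoms are deterministic; the seed is kept
#'   in the interface for phantom kinds with stochastic options).
#' @param pocket_center centre of the CSF pocket, mm.
#' @param pocket_semiaxes semi-axes of the CSF pocket, mm.
#' @param radii for `layered_sphere`: outer radii of the grey core and
#'   white shell (mm); CSF fills the rest.
#' @return a `voxel_volume` centred on the origin.
#' @export
make_synthetic_tissue_volume <- function(kind = c("uniform", "layered_sphere",
                                                  "csf_pocket", "half_space"),
                                         n = 24, voxel_size = 0.5, seed = 1,
                                         pocket_center = c(1.5, 0, 0),
                                         pocket_semiaxes = c(1.2, 0.8, 0.8),
                                         radii = c(2.5, 4)) {
  kind <- match.arg(kind)
  if (length(n) == 1) n <- rep(n, 3)
  if (any(n < 1) || voxel_size <= 0) stop("positive shape and voxel size required")
  set.seed(seed)
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- -voxel_size * (n - 1) / 2
  idx <- as.matrix(expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1),
                               k = 0:(n[3] - 1)))
  xyz <- cbind(idx, 1) %*% t(affine)
  legend <- c("1" = "grey_matter", "2" = "white_matter", "3" = "csf")
  lab <- switch(kind,
    uniform = rep(1L, nrow(idx)),
    half_space = ifelse(xyz[, 1] < 0, 1L, 2L),
    layered_sphere = {
      r <- sqrt(rowSums(xyz[, 1:3]^2))
      ifelse(r <= radii[1], 1L, ifelse(r <= radii[2], 2L, 3L))
    },
    csf_pocket = {
      u <- sweep(xyz[, 1:3], 2, pocket_center) /
        matrix(pocket_semiaxes, nrow(xyz), 3, byrow = TRUE)
      ifelse(rowSums(u^2) <= 1, 3L, 1L)
    })
  voxel_volume(array(lab, dim = n), affine, legend)
}

#' Synthetic axis-aligned tensor volume
#'
#' Constant anisotropic weighting field aligned with a coordinate axis:
#' the weight along `axis` is `ratio` and the transverse weights are
#' chosen so the trace equals 3 (unit mean weight).
#'
#' @param n integer(3) or scalar voxels per dimension.
#' @param voxel_size voxel edge, mm.
#' @param axis 1, 2 or 3.
#' @param ratio longitudinal weight (> 0).
#' @return a `tensor_volume` with the same centred affine convention as
#'   [make_synthetic_tissue_volume].
#' @export
make_synthetic_tensor_volume <- function(n = 24, voxel_size = 0.5, axis = 1,
                                         ratio = 2) {
  if (length(n) == 1) n <- rep(n, 3)
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- -voxel_size * (n - 1) / 2
  trans <- (3 - ratio) / 2
  if (trans < 0) stop("ratio must be <= 3 for a trace-3 tensor")
  diagw <- c(trans, trans, trans); diagw[axis] <- ratio
  comp <- array(0, dim = c(n, 6))
  comp[, , , 1] <- diagw[1]; comp[, , , 4] <- diagw[2]; comp[, , , 6] <- diagw[3]
  tensor_volume(comp, affine)
}

# --- readers / writers -------------------------------------------------------

#' Read a voxel label volume
#'
#' Supports NIfTI (`.nii` / `.nii.gz`, via the RNifti package) and a
#' whitespace-delimited `.txt` grid with a JSON sidecar (`<path>.json`)
#' holding `dim`, `affine` (row-major 4x4) and `legend`.
#'
#' @param path volume path.
#' @param legend for NIfTI input: named character vector mapping label
#'   codes to tissue labels.
#' @return a `voxel_volume`.
#' @export
read_voxel_volume <- function(path, legend = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to read NIfTI volumes")
    img <- RNifti::readNifti(path)
    aff <- structure(RNifti::xform(img), class = NULL)
    if (is.null(legend)) stop("a label legend is required for NIfTI input")
    return(voxel_volume(array(as.integer(img), dim = dim(img)[1:3]),
                        matrix(aff, 4, 4), legend))
  }
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab <- as.integer(scan(path, quiet = TRUE))
  dims <- as.integer(side$dim)
  legend <- side$legend
  if (is.null(names(legend))) stop("sidecar legend must be named by label code")
  voxel_volume(array(lab, dim = dims),
               matrix(as.numeric(side$affine), 4, 4, byrow = TRUE), legend)
}

#' Write a voxel volume as a text grid with JSON sidecar
#' @param vol a `voxel_volume`.
#' @param path output `.txt` path; the sidecar is written to `<path>.json`.
#' @export
write_voxel_volume_txt <- function(vol, path) {
  writeLines(paste(as.vector(vol$labels), collapse = " "), path)
  jsonlite::write_json(list(dim = dim(vol$labels),
                            affine = as.vector(t(vol$affine)),
                            legend = as.list(vol$legend)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tensor volume from a text grid with JSON sidecar
#'
#' The text file holds one row of 6 components per voxel in column-major
#' voxel order; the sidecar holds `dim` and `affine`.
#' @param path `.txt` path.
#' @return a `tensor_volume`.
#' @export
read_tensor_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  comp <- as.matrix(utils::read.table(path))
  dims <- as.integer(side$dim)
  tensor_volume(array(comp, dim = c(dims, 6)),
                matrix(as.numeric(side$affine), 4, 4, byrow = TRUE))
}

# --- voxel -> mesh mapping ---------------------------------------------------

# label names of all voxel centres inside each listed cell, as a list of
# integer code vectors (possibly empty)
.voxels_in_cells <- function(mesh, vol, cells) {
  dims <- dim(vol$labels)
  out <- vector("list", length(cells))
  verts_idx <- .world_to_voxel(vol, mesh$nodes)
  for (ii in seq_along(cells)) {
    c4 <- mesh$cells[cells[ii], ]
    vi <- verts_idx[c4, , drop = FALSE]
    lo <- pmax(ceiling(apply(vi, 2, min) - 1e-9), 0)
    hi <- pmin(floor(apply(vi, 2, max) + 1e-9), dims - 1)
    if (any(lo > hi)) { out[[ii]] <- integer(0); next }
    cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                  k = lo[3]:hi[3]))
    P <- .voxel_to_world(vol, cand)
    A <- mesh$nodes[c4[1], ]
    Tm <- t(mesh$nodes[c4[2:4], , drop = FALSE]) - A
    bc <- solve(Tm, t(P) - A)
    inside <- bc[1, ] >= -1e-9 & bc[2, ] >= -1e-9 & bc[3, ] >= -1e-9 &
      colSums(bc) <= 1 + 1e-9
    out[[ii]] <- vol$labels[cand[inside, , drop = FALSE] + 1]
  }
  out
}

#' Map voxel tissue labels onto mesh cells
#'
#' Each cell receives the majority label among voxel centres falling
#' inside it (ties broken towards the smaller label code). Cells that
#' contain no voxel centre get the label of the voxel nearest to their
#' centroid; cells whose centroid lies outside the volume coverage get
#' `default_label` (local mapping). Encapsulation, floating-conductor and
#' electrode-metal cells are never overwritten.
#'
#' @param mesh a `domain_mesh`.
#' @param vol a `voxel_volume`.
#' @param default_label label for cells outside volume coverage; `NULL`
#'   keeps the cell's current label.
#' @param cells optional subset of cell indices to (re-)map.
#' @return the mesh with updated `tissue`.
#' @export
map_tissue_to_cells <- function(mesh, vol, default_label = "unknown",
                                cells = NULL) {
  stopifnot(inherits(mesh, "domain_mesh"), inherits(vol, "voxel_volume"))
  if (length(vol$labels) == 0) stop("empty volume")
  if (is.null(cells)) cells <- seq_len(nrow(mesh$cells))
  protected <- mesh$region %in% c("encapsulation", "floating_conductor") |
    !is.na(mesh$contact_cell)
  cells <- cells[!protected[cells]]
  if (!length(cells)) return(mesh)
  dims <- dim(vol$labels)
  inlab <- .voxels_in_cells(mesh, vol, cells)
  cent <- cell_centroids(mesh)[cells, , drop = FALSE]
  ci <- .world_to_voxel(vol, cent)
  for (ii in seq_along(cells)) {
    codes <- inlab[[ii]]
    if (length(codes)) {
      tab <- table(codes)
      code <- as.integer(names(tab)[which.max(tab)])  # ties -> smaller code
    } else {
      idx <- round(ci[ii, ])
      if (any(idx < -0.5 + 1e-9) || any(idx > dims - 0.5 - 1e-9)) {
        if (is.null(default_label)) next
        mesh$tissue[cells[ii]] <- default_label
        next
      }
      idx <- pmin(pmax(idx, 0), dims - 1)
      code <- vol$labels[matrix(idx + 1, 1)]
    }
    mesh$tissue[cells[ii]] <- vol$legend[[as.character(code)]]
  }
  mesh
}

#' Map voxel anisotropy tensors onto mesh cells
#'
#' Each cell receives the tensor of the voxel nearest to its centroid
#' (clamped to the volume). Tensors are validated symmetric positive
#' semi-definite; negative eigenvalues are clipped to zero with a warning.
#' `unit_trace` rescales each tensor so its trace equals 3 (weights
#' averaging to one). Encapsulation, floating-conductor and electrode
#' cells receive the identity weighting.
#'
#' @param mesh a `domain_mesh`.
#' @param tv a `tensor_volume`.
#' @param normalization `"none"` or `"unit_trace"`.
#' @return the mesh with per-cell `tensor` (n_cells x 6).
#' @export
map_tensors_to_cells <- function(mesh, tv,
                                 normalization = c("none", "unit_trace")) {
  stopifnot(inherits(mesh, "domain_mesh"), inherits(tv, "tensor_volume"))
  normalization <- match.arg(normalization)
  dims <- dim(tv$comp)[1:3]
  cent <- cell_centroids(mesh)
  ci <- round(.world_to_voxel(tv, cent))
  ci <- pmin(pmax(ci, 0), matrix(dims - 1, nrow(ci), 3, byrow = TRUE))
  M <- nrow(mesh$cells)
  tens <- matrix(0, M, 6)
  clipped <- FALSE
  for (m in seq_len(M)) {
    v <- tv$comp[ci[m, 1] + 1, ci[m, 2] + 1, ci[m, 3] + 1, ]
    D <- matrix(c(v[1], v[2], v[3],
                  v[2], v[4], v[5],
                  v[3], v[5], v[6]), 3, 3)
    ev <- eigen(D, symmetric = TRUE)
    if (any(ev$values < -1e-12)) {
      clipped <- TRUE
      vals <- pmax(ev$values, 0)
      D <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    }
    if (normalization == "unit_trace" && sum(diag(D)) > 0)
      D <- D * (3 / sum(diag(D)))
    tens[m, ] <- c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  }
  if (clipped) warning("negative tensor eigenvalues clipped to zero")
  protected <- mesh$region %in% c("encapsulation", "floating_conductor") |
    !is.na(mesh$contact_cell)
  tens[protected, ] <- rep(c(1, 0, 0, 1, 0, 1), each = sum(protected))
  mesh$tensor <- tens
  mesh
}

#' CSF cells near neuron compartments that are still too coarse
#'
#' Returns the cells that contain at least one CSF voxel centre, whose
#' centroid lies within `radius` of any neuron compartment point, and
#' whose longest edge exceeds `max_edge`. These are the cells the CSF
#' refinement pass bisects.
#'
#' @param mesh a `domain_mesh`.
#' @param vol a `voxel_volume` whose legend includes `csf`.
#' @param neuron_points n x 3 matrix of compartment coordinates (mm).
#' @param radius vicinity radius, mm.
#' @param max_edge target maximum edge length, mm (default: voxel size).
#' @return integer vector of cell indices.
#' @export
csf_cells_near_neurons <- function(mesh, vol, neuron_points, radius,
                                   max_edge = NULL) {
  stopifnot(inherits(mesh, "domain_mesh"), inherits(vol, "voxel_volume"))
  if (!"csf" %in% vol$legend) stop("volume legend has no csf label")
  if (is.null(max_edge)) max_edge <- abs(vol$affine[1, 1])
  neuron_points <- matrix(neuron_points, ncol = 3)
  edges <- cell_longest_edges(mesh)
  big <- which(edges > max_edge)
  if (!length(big)) return(integer(0))
  cent <- cell_centroids(mesh)[big, , drop = FALSE]
  mind <- rep(Inf, length(big))
  for (p in seq_len(nrow(neuron_points))) {
    d <- sqrt(rowSums(sweep(cent, 2, neuron_points[p, ])^2))
    mind <- pmin(mind, d)
  }
  big <- big[mind <= radius]
  if (!length(big)) return(integer(0))
  csf_code <- as.integer(names(vol$legend)[vol$legend == "csf"])
  inlab <- .voxels_in_cells(mesh, vol, big)
  hascsf <- vapply(inlab, function(x) any(x %in% csf_code), logical(1))
  sort(big[hascsf])
}
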