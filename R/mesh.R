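# Tetrahedral mesh container and constructors. Coordinates are world
# millimetres. Meshes are plain lists (class "domain_mesh") holding node
# coordinates, cell connectivity, per-cell region/tissue/contact tags,
# optional per-cell anisotropy tensors, and tagged boundary-node sets with
# the geometry needed to snap refined nodes back onto curved surfaces.

.new_mesh <- function(nodes, cells, region, tissue, contact_cell,
                      surf_nodes = list(), surface_geom = list(),
                      contacts = NULL, tensor = NULL, electrode = NULL) {
  m <- structure(list(
    nodes = nodes, cells = cells,
    region = region, tissue = tissue,
    contact_cell = contact_cell,
    tensor = tensor,
    surf_nodes = surf_nodes, surface_geom = surface_geom,
    contacts = contacts, electrode = electrode), class = "domain_mesh")
  .orient_cells(m)
}

#' @export
print.domain_mesh <- function(x, ...) {
  cat("domain_mesh:", nrow(x$nodes), "nodes,", nrow(x$cells), "tetrahedra\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  if (!is.null(x$contacts))
    cat("  contacts:", nrow(x$contacts), "(",
        paste(x$contacts$role, collapse = ", "), ")\n")
  invisible(x)
}

# signed volumes (mm^3); positive for correctly oriented tets
.signed_volumes <- function(nodes, cells) {
  a <- nodes[cells[, 1], , drop = FALSE]
  b <- nodes[cells[, 2], , drop = FALSE] - a
  c <- nodes[cells[, 3], , drop = FALSE] - a
  d <- nodes[cells[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

.orient_cells <- function(mesh) {
  v <- .signed_volumes(mesh$nodes, mesh$cells)
  neg <- v < 0
  if (any(neg))
    mesh$cells[neg, c(3, 4)] <- mesh$cells[neg, c(4, 3)]
  if (any(abs(.signed_volumes(mesh$nodes, mesh$cells)) < 1e-14))
    stop("degenerate (zero-volume) tetrahedra in mesh")
  mesh
}

#' Cell volumes
#' @param mesh a `domain_mesh`.
#' @return numeric vector of tetrahedron volumes (mm^3).
#' @export
cell_volumes <- function(mesh) abs(.signed_volumes(mesh$nodes, mesh$cells))

#' Cell centroids
#' @param mesh a `domain_mesh`.
#' @return n_cells x 3 matrix of centroids (mm).
#' @export
cell_centroids <- function(mesh) {
  (mesh$nodes[mesh$cells[, 1], ] + mesh$nodes[mesh$cells[, 2], ] +
   mesh$nodes[mesh$cells[, 3], ] + mesh$nodes[mesh$cells[, 4], ]) / 4
}

# local edge vertex pairs of a tetrahedron
.tet_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

#' Longest edge length per cell
#' @param mesh a `domain_mesh`.
#' @param cells cell indices (default all).
#' @return numeric vector of longest edge lengths (mm).
#' @export
cell_longest_edges <- function(mesh, cells = seq_len(nrow(mesh$cells))) {
  out <- numeric(length(cells))
  for (e in 1:6) {
    a <- mesh$nodes[mesh$cells[cells, .tet_edges[e, 1]], , drop = FALSE]
    b <- mesh$nodes[mesh$cells[cells, .tet_edges[e, 2]], , drop = FALSE]
    len <- sqrt(rowSums((a - b)^2))
    out <- pmax(out, len)
  }
  out
}

# --- boundary facets ---------------------------------------------------------

.tet_faces <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
# face vertex orders chosen so the outward normal of face i (opposite
# vertex i) points away from the cell for a positively oriented tet

#' Boundary facets of a mesh
#'
#' @param mesh a `domain_mesh`.
#' @return data.frame with columns `cell`, `n1`, `n2`, `n3` (outward
#'   vertex order) for every facet that belongs to exactly one cell.
#' @export
boundary_facets <- function(mesh) {
  M <- nrow(mesh$cells)
  cells <- rep(seq_len(M), each = 4)
  faceno <- rep(1:4, times = M)
  f1 <- mesh$cells[cbind(cells, .tet_faces[faceno, 1])]
  f2 <- mesh$cells[cbind(cells, .tet_faces[faceno, 2])]
  f3 <- mesh$cells[cbind(cells, .tet_faces[faceno, 3])]
  key3 <- cbind(f1, f2, f3)
  skey <- apply(key3, 1, function(r) paste(sort(r), collapse = "_"))
  cnt <- table(skey)
  keep <- cnt[skey] == 1
  data.frame(cell = cells[keep], n1 = f1[keep], n2 = f2[keep], n3 = f3[keep])
}

# resolve a tag for each boundary facet from tagged node sets; contacts
# take priority over the lead shaft, which takes priority over the outer
# boundary. Returns a character vector (NA where untagged).
.facet_tags <- function(mesh, facets) {
  tags <- rep(NA_character_, nrow(facets))
  prio <- names(mesh$surf_nodes)
  prio <- prio[order(!startsWith(prio, "contact_"), prio != "lead")]
  for (tag in prio) {
    set <- mesh$surf_nodes[[tag]]
    inset <- facets$n1 %in% set & facets$n2 %in% set & facets$n3 %in% set
    tags[is.na(tags) & inset] <- tag
  }
  tags
}

#' Facets of one contact
#'
#' For facet-realized contacts, returns the boundary facets whose vertices
#' all lie on the tagged contact surface. For region-realized contacts
#' (electrode metal kept as cells), returns the interface facets between
#' the contact's cell region and the surrounding tissue, oriented outward
#' from the tissue side.
#'
#' @param mesh a `domain_mesh`.
#' @param contact_id integer contact id.
#' @return data.frame `cell`, `n1`, `n2`, `n3`; `cell` is always a tissue
#'   cell and the facet normal implied by the vertex order points from the
#'   tissue into the contact.
#' @export
contact_facets <- function(mesh, contact_id) {
  tag <- paste0("contact_", contact_id)
  if (tag %in% names(mesh$surf_nodes)) {
    bf <- boundary_facets(mesh)
    tg <- .facet_tags(mesh, bf)
    out <- bf[!is.na(tg) & tg == tag, , drop = FALSE]
    if (nrow(out)) return(out)
  }
  # region-realized: faces shared by a contact cell and a tissue cell
  inreg <- which(!is.na(mesh$contact_cell) & mesh$contact_cell == contact_id)
  if (!length(inreg)) stop("unknown contact or contact without facets: ",
                           contact_id)
  M <- nrow(mesh$cells)
  cells <- rep(seq_len(M), each = 4)
  faceno <- rep(1:4, times = M)
  f1 <- mesh$cells[cbind(cells, .tet_faces[faceno, 1])]
  f2 <- mesh$cells[cbind(cells, .tet_faces[faceno, 2])]
  f3 <- mesh$cells[cbind(cells, .tet_faces[faceno, 3])]
  skey <- apply(cbind(f1, f2, f3), 1, function(r) paste(sort(r), collapse = "_"))
  iscontact <- cells %in% inreg
  # faces listed once from a contact cell and once from a non-contact cell
  tab <- split(seq_along(skey), skey)
  rows <- integer(0)
  for (idx in tab) {
    if (length(idx) == 2 && xor(iscontact[idx[1]], iscontact[idx[2]]))
      rows <- c(rows, idx[[which(!iscontact[idx])]])
  }
  if (!length(rows)) stop("contact ", contact_id, " has no interface facets")
  # tissue-side face with outward order: outward from the tissue cell
  # points into the contact region, as required
  data.frame(cell = cells[rows], n1 = f1[rows], n2 = f2[rows], n3 = f3[rows])
}

# --- structured box / sphere meshes ------------------------------------------

# Kuhn triangulation: 6 tetrahedra per grid cube, conforming across cubes
.kuhn_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

.structured_tets <- function(origin, h, n) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  vid <- function(i, j, k) i + (nx + 1) * (j + (ny + 1) * k) + 1L
  gx <- origin[1] + h * (0:nx)
  gy <- origin[2] + h * (0:ny)
  gz <- origin[3] + h * (0:nz)
  nodes <- cbind(rep(gx, times = (ny + 1) * (nz + 1)),
                 rep(rep(gy, each = nx + 1), times = nz + 1),
                 rep(gz, each = (nx + 1) * (ny + 1)))
  ijk <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  ncube <- nrow(ijk)
  cells <- matrix(0L, 6 * ncube, 4)
  base <- cbind(ijk$i, ijk$j, ijk$k)
  for (p in 1:6) {
    perm <- .kuhn_perms[p, ]
    v0 <- base
    v1 <- v0; v1[, perm[1]] <- v1[, perm[1]] + 1
    v2 <- v1; v2[, perm[2]] <- v2[, perm[2]] + 1
    v3 <- v2; v3[, perm[3]] <- v3[, perm[3]] + 1
    cells[seq(p, by = 6, length.out = ncube), ] <-
      cbind(vid(v0[, 1], v0[, 2], v0[, 3]), vid(v1[, 1], v1[, 2], v1[, 3]),
            vid(v2[, 1], v2[, 2], v2[, 3]), vid(v3[, 1], v3[, 2], v3[, 3]))
  }
  list(nodes = nodes, cells = cells)
}

# drop unused nodes and renumber connectivity
.compact_nodes <- function(nodes, cells) {
  used <- sort(unique(as.vector(cells)))
  map <- integer(nrow(nodes)); map[used] <- seq_along(used)
  list(nodes = nodes[used, , drop = FALSE],
       cells = matrix(map[cells], ncol = 4), keep = used)
}

#' Box mesh with two opposite plate contacts
#'
#' A Kuhn-triangulated box on `[0,Lx] x [0,Ly] x [0,Lz]`. The faces
#' `x = 0` and `x = Lx` are tagged as contacts 1 and 2 (facet-realized
#' Dirichlet plates); the remaining boundary is the insulated outer
#' surface. Used for slab verification problems.
#'
#' @param lengths numeric(3), box edge lengths (mm).
#' @param n integer(3), cubes per direction.
#' @param tissue tissue label for all cells.
#' @return a `domain_mesh`.
#' @export
mesh_box <- function(lengths = c(4, 2, 2), n = c(8, 4, 4),
                     tissue = "grey_matter") {
  h <- lengths[1] / n[1]
  if (abs(lengths[2] / n[2] - h) > 1e-12 || abs(lengths[3] / n[3] - h) > 1e-12)
    stop("mesh_box requires cubic grid cells: lengths/n equal per direction")
  g <- .structured_tets(c(0, 0, 0), h, n)
  tol <- 1e-9
  surf <- list(
    contact_1 = which(abs(g$nodes[, 1]) < tol),
    contact_2 = which(abs(g$nodes[, 1] - lengths[1]) < tol),
    outer = which(abs(g$nodes[, 2]) < tol |
                  abs(g$nodes[, 2] - lengths[2]) < tol |
                  abs(g$nodes[, 3]) < tol |
                  abs(g$nodes[, 3] - lengths[3]) < tol))
  M <- nrow(g$cells)
  .new_mesh(g$nodes, g$cells,
            region = rep("ROI", M), tissue = rep(tissue, M),
            contact_cell = rep(NA_integer_, M),
            surf_nodes = surf,
            surface_geom = list(),
            contacts = data.frame(id = 1:2, role = c("active", "ground"),
                                  value = c(1, 0)))
}

# --- icosphere-based spherical shell -----------------------------------------

.icosphere <- function(subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    env <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- env[[key]]
      if (!is.null(id)) return(id)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      id <- nrow(verts)
      env[[key]] <- id
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts; f <- nf
  }
  list(vertices = v, faces = f)
}

#' Spherical-shell mesh between two concentric spherical contacts
#'
#' Radially extruded icosphere: the inner sphere (radius `r_inner`) is
#' contact 1 and the outer sphere (radius `r_outer`) contact 2 (ground).
#' Layer radii are geometrically graded so the mesh is finest near the
#' inner contact, where the field concentrates. All boundary nodes lie
#' exactly on the two spheres, and refined nodes are snapped back onto
#' them, making the mesh suitable for comparison with the closed-form
#' concentric-spheres solution.
#'
#' @param r_inner,r_outer sphere radii, mm.
#' @param subdiv icosphere subdivision level (2 -> 162 surface vertices).
#' @param n_layers number of radial layers.
#' @param center sphere centre (mm).
#' @param tissue tissue label.
#' @return a `domain_mesh` with facet-realized contacts 1 (inner, active)
#'   and 2 (outer, ground).
#' @export
mesh_spherical_shell <- function(r_inner = 0.5, r_outer = 5, subdiv = 2,
                                 n_layers = 8, center = c(0, 0, 0),
                                 tissue = "grey_matter") {
  if (r_inner <= 0 || r_outer <= r_inner) stop("need 0 < r_inner < r_outer")
  ico <- .icosphere(subdiv)
  ns <- nrow(ico$vertices)
  radii <- r_inner * (r_outer / r_inner)^(seq(0, 1, length.out = n_layers + 1))
  nodes <- do.call(rbind, lapply(radii, function(r)
    sweep(ico$vertices * r, 2, center, "+")))
  # split each radial prism into three tetrahedra with the global-index
  # diagonal rule (conforming across neighbouring prisms)
  cells <- matrix(0L, 0, 4)
  cell_list <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lo <- (l - 1) * ns
    hi <- l * ns
    f <- t(apply(ico$faces, 1, sort))  # v0 < v1 < v2 by surface id
    c1 <- cbind(lo + f[, 1], lo + f[, 2], lo + f[, 3], hi + f[, 1])
    c2 <- cbind(lo + f[, 2], lo + f[, 3], hi + f[, 1], hi + f[, 2])
    c3 <- cbind(lo + f[, 3], hi + f[, 1], hi + f[, 2], hi + f[, 3])
    cell_list[[l]] <- rbind(c1, c2, c3)
  }
  cells <- do.call(rbind, cell_list)
  M <- nrow(cells)
  surf <- list(contact_1 = 1:ns,
               contact_2 = (n_layers * ns + 1):((n_layers + 1) * ns))
  geom <- list(contact_1 = list(kind = "sphere", center = center,
                                radius = r_inner, snap = TRUE),
               contact_2 = list(kind = "sphere", center = center,
                                radius = r_outer, snap = TRUE))
  .new_mesh(nodes, cells,
            region = rep("ROI", M), tissue = rep(tissue, M),
            contact_cell = rep(NA_integer_, M),
            surf_nodes = surf, surface_geom = geom,
            contacts = data.frame(id = 1:2, role = c("active", "ground"),
                                  value = c(1, 0)))
}

# --- VTK export --------------------------------------------------------------

#' Write a mesh (with optional fields) as a legacy VTK unstructured grid
#'
#' @param mesh a `domain_mesh`.
#' @param path output `.vtk` path (ASCII legacy format).
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-cell numeric vectors; region and
#'   tissue tags are always written as integer codes.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- nrow(mesh$nodes); M <- nrow(mesh$cells)
  writeLines(c("# vtk DataFile Version 3.0", "dbsvcm mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", N, "double")), con)
  utils::write.table(format(mesh$nodes, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("CELLS", M, 5 * M), con)
  utils::write.table(cbind(4L, mesh$cells - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", M), con)
  writeLines(as.character(rep(10L, M)), con)
  cell_data$region_code <- as.integer(factor(mesh$region))
  cell_data$tissue_code <- as.integer(factor(mesh$tissue))
  writeLines(paste("CELL_DATA", M), con)
  for (nm in names(cell_data)) {
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], digits = 10), con)
  }
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", N), con)
    for (nm in names(point_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"),
                 con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}
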