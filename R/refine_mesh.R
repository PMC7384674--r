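# Conforming longest-edge bisection (Rivara-style) of marked tetrahedra.
# Children inherit region / tissue / contact tags; newly created boundary
# nodes inherit surface membership from their edge endpoints and are
# snapped back onto curved tagged surfaces. A parent -> children map over
# the originally active cells is returned for the current-convergence
# criterion.

# deterministic longest edge of one cell: ties broken by the smallest
# sorted global node pair, so every cell sharing the edge agrees on it
.longest_edge_of <- function(nodes, cell) {
  a <- cell[.tet_edges[, 1]]
  b <- cell[.tet_edges[, 2]]
  len <- sqrt(rowSums((nodes[a, , drop = FALSE] - nodes[b, , drop = FALSE])^2))
  cand <- which(len >= max(len) * (1 - 1e-9))
  lo <- pmin(a[cand], b[cand]); hi <- pmax(a[cand], b[cand])
  pick <- cand[order(lo, hi)[1]]
  c(min(a[pick], b[pick]), max(a[pick], b[pick]))
}

.snap_node <- function(x, geom) {
  if (is.null(geom) || !isTRUE(geom$snap)) return(x)
  if (geom$kind == "sphere") {
    d <- x - geom$center
    geom$center + d * (geom$radius / sqrt(sum(d^2)))
  } else if (geom$kind == "cylinder") {
    # axis through geom$point along unit geom$dir, radius geom$radius
    d <- x - geom$point
    ax <- sum(d * geom$dir)
    radial <- d - ax * geom$dir
    rl <- sqrt(sum(radial^2))
    if (rl < 1e-12) return(x)
    geom$point + ax * geom$dir + radial * (geom$radius / rl)
  } else x
}

#' Refine marked cells by conforming longest-edge bisection
#'
#' Marked cells are bisected at their longest edge; conformity is restored
#' by propagating bisections to neighbours (longest-edge propagation), so
#' the result contains no hanging nodes. Children inherit the parent's
#' region, tissue label, contact assignment and anisotropy tensor; tissue
#' labels can be re-mapped afterwards by passing the voxel volume.
#'
#' @param mesh a `domain_mesh`.
#' @param marked integer vector of cell indices to refine; empty -> the
#'   mesh is returned unchanged.
#' @param volume optional `voxel_volume`; when given, tissue labels of all
#'   child cells are re-mapped from the volume.
#' @return the refined `domain_mesh` with attribute `parent_map`: a list
#'   mapping each input cell index (as character) to the indices of the
#'   active cells it became (identity for unsplit cells).
#' @export
refine_cells <- function(mesh, marked, volume = NULL) {
  stopifnot(inherits(mesh, "domain_mesh"))
  marked <- unique(as.integer(marked))
  M0 <- nrow(mesh$cells)
  if (!length(marked)) {
    attr(mesh, "parent_map") <- stats::setNames(
      as.list(seq_len(M0)), as.character(seq_len(M0)))
    return(mesh)
  }
  if (any(marked < 1 | marked > M0)) stop("marked cell index out of range")

  nodes <- mesh$nodes
  nN <- nrow(nodes)
  cap <- max(64L, 4L * M0)
  cells <- rbind(mesh$cells, matrix(0L, cap - M0, 4))
  region <- c(mesh$region, character(cap - M0))
  tissue <- c(mesh$tissue, character(cap - M0))
  contact_cell <- c(mesh$contact_cell, rep(NA_integer_, cap - M0))
  tensor <- if (!is.null(mesh$tensor))
    rbind(mesh$tensor, matrix(0, cap - M0, 6)) else NULL
  active <- c(rep(TRUE, M0), rep(FALSE, cap - M0))
  nM <- M0
  parent <- rep(NA_integer_, cap)  # immediate parent of each cell

  # node -> incident active cells
  inc <- vector("list", max(4 * nN, 2 * nN))
  for (v in 1:4) {
    byn <- split(seq_len(M0), mesh$cells[, v])
    for (nm in names(byn))
      inc[[as.integer(nm)]] <- c(inc[[as.integer(nm)]], byn[[nm]])
  }
  grow_cells <- function(extra) {
    newcap <- max(2 * length(active), length(active) + extra)
    cells <<- rbind(cells, matrix(0L, newcap - nrow(cells), 4))
    add <- newcap - length(active)
    region <<- c(region, character(add))
    tissue <<- c(tissue, character(add))
    contact_cell <<- c(contact_cell, rep(NA_integer_, add))
    if (!is.null(tensor)) tensor <<- rbind(tensor, matrix(0, add, 6))
    parent <<- c(parent, rep(NA_integer_, add))
    active <<- c(active, rep(FALSE, add))
  }
  surf_nodes <- mesh$surf_nodes
  surf_member <- lapply(surf_nodes, function(s) {
    v <- logical(nN); v[s] <- TRUE; v
  })

  cells_with_edge <- function(a, b) {
    ca <- inc[[a]]
    ca <- ca[active[ca]]
    if (!length(ca)) return(integer(0))
    hasb <- cells[ca, 1] == b | cells[ca, 2] == b |
            cells[ca, 3] == b | cells[ca, 4] == b
    ca[hasb]
  }

  split_done <- new.env(hash = TRUE)   # "a_b" -> midpoint id

  do_split <- function(a, b) {
    key <- paste0(a, "_", b)
    C <- cells_with_edge(a, b)
    mid <- (nodes[a, ] + nodes[b, ]) / 2
    # surface membership and snapping for the new node
    memb <- character(0)
    for (tag in names(surf_member)) {
      sm <- surf_member[[tag]]
      if (a <= length(sm) && b <= length(sm) && sm[a] && sm[b]) {
        memb <- c(memb, tag)
        mid <- .snap_node(mid, mesh$surface_geom[[tag]])
      }
    }
    nodes <<- rbind(nodes, mid)
    m <- nrow(nodes)
    for (tag in memb) {
      sm <- surf_member[[tag]]
      sm[m] <- TRUE
      surf_member[[tag]] <<- sm
    }
    if (length(inc) < m) length(inc) <<- 2L * m
    assign(key, m, envir = split_done)
    for (cc in C) {
      cv <- cells[cc, ]
      active[cc] <<- FALSE
      for (repl in c(a, b)) {
        child <- cv
        child[child == repl] <- m
        if (nM + 1 > nrow(cells)) grow_cells(64L)
        nM <<- nM + 1L
        cells[nM, ] <<- child
        region[nM] <<- region[cc]
        tissue[nM] <<- tissue[cc]
        contact_cell[nM] <<- contact_cell[cc]
        if (!is.null(tensor)) tensor[nM, ] <<- tensor[cc, ]
        parent[nM] <<- cc
        active[nM] <<- TRUE
        for (v in child) inc[[v]] <<- c(inc[[v]], nM)
      }
    }
    m
  }

  split_edge <- function(a0, b0) {
    stack <- list(c(a0, b0))
    guard <- 0L
    while (length(stack)) {
      guard <- guard + 1L
      if (guard > 200000L) stop("bisection propagation did not terminate")
      e <- stack[[length(stack)]]
      if (!is.null(split_done[[paste0(e[1], "_", e[2])]])) {
        stack[[length(stack)]] <- NULL; next
      }
      C <- cells_with_edge(e[1], e[2])
      if (!length(C)) { stack[[length(stack)]] <- NULL; next }
      bad <- NULL
      for (cc in C) {
        le <- .longest_edge_of(nodes, cells[cc, ])
        if (!(le[1] == e[1] && le[2] == e[2])) { bad <- le; break }
      }
      if (is.null(bad)) {
        do_split(e[1], e[2])
        stack[[length(stack)]] <- NULL
      } else {
        stack[[length(stack) + 1]] <- bad
      }
    }
  }

  for (t in marked) {
    if (!active[t]) next  # already split through propagation
    le <- .longest_edge_of(nodes, cells[t, ])
    split_edge(le[1], le[2])
  }

  keep <- which(active[seq_len(nM)])
  newid <- integer(nM); newid[keep] <- seq_along(keep)
  out <- mesh
  out$nodes <- nodes
  out$cells <- cells[keep, , drop = FALSE]
  out$region <- region[keep]
  out$tissue <- tissue[keep]
  out$contact_cell <- contact_cell[keep]
  out$tensor <- if (!is.null(tensor)) tensor[keep, , drop = FALSE] else NULL
  out$surf_nodes <- lapply(surf_member, which)

  # descendants of each originally active cell
  root <- integer(nM)
  root[seq_len(M0)] <- seq_len(M0)
  if (nM > M0)
    for (i in (M0 + 1):nM) root[i] <- root[parent[i]]
  pm <- split(newid[keep], root[keep])
  parent_map <- stats::setNames(as.list(seq_len(M0)), as.character(seq_len(M0)))
  for (nm in names(pm)) parent_map[[nm]] <- as.integer(pm[[nm]])

  if (!is.null(volume)) {
    changed <- unlist(parent_map[vapply(parent_map, length, 1L) > 1])
    if (length(changed))
      out <- map_tissue_to_cells(out, volume,
                                 default_label = NULL, cells = changed)
  }
  attr(out, "parent_map") <- parent_map
  out
}
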