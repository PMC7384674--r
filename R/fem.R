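# Complex-valued electro-quasistatic finite elements on tetrahedra.
# P1 / P2 Lagrange spaces; the complex problem
#   div( (sigma D + j w eps0 eps_r I) grad phi ) = 0
# is assembled as two real stiffness matrices (conductive part, possibly
# tensor-weighted; capacitive part, always isotropic) and solved as a
# 2x2 real block system over (Re phi, Im phi). Dirichlet data are applied
# on contact surfaces or contact cell regions; floating conductors enter
# through a large virtual permittivity instead of a constraint.

# --- finite-element space ----------------------------------------------------

#' Build a P1 or P2 Lagrange space on a mesh
#'
#' @param mesh a `domain_mesh`.
#' @param order 1 or 2.
#' @return a list with `order`, `ndof`, `cell_dofs` (n_cells x 4 or x 10),
#'   `edge_nodes` (edge endpoint pairs for the P2 edge dofs), `nvert`.
#' @export
fem_space <- function(mesh, order = 2) {
  stopifnot(order %in% c(1, 2))
  N <- nrow(mesh$nodes)
  M <- nrow(mesh$cells)
  if (order == 1)
    return(list(order = 1, ndof = N, cell_dofs = mesh$cells,
                edge_nodes = NULL, nvert = N))
  ea <- mesh$cells[, .tet_edges[, 1]]
  eb <- mesh$cells[, .tet_edges[, 2]]
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- (lo - 1) * N + hi
  ukey <- sort(unique(as.vector(key)))
  eid <- matrix(match(key, ukey), M, 6)
  edge_nodes <- cbind((ukey - 1) %/% N + 1, (ukey - 1) %% N + 1)
  list(order = 2, ndof = N + length(ukey),
       cell_dofs = cbind(mesh$cells, N + eid),
       edge_nodes = edge_nodes, nvert = N)
}

# barycentric gradients g[cell, vertex, xyz] and signed volumes
.cell_geometry <- function(mesh) {
  a <- mesh$nodes[mesh$cells[, 1], , drop = FALSE]
  b <- mesh$nodes[mesh$cells[, 2], , drop = FALSE] - a
  c <- mesh$nodes[mesh$cells[, 3], , drop = FALSE] - a
  d <- mesh$nodes[mesh$cells[, 4], , drop = FALSE] - a
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  vol6 <- rowSums(b * cr(c, d))
  g2 <- cr(c, d) / vol6
  g3 <- cr(d, b) / vol6
  g4 <- cr(b, c) / vol6
  g1 <- -(g2 + g3 + g4)
  M <- nrow(mesh$cells)
  g <- array(0, c(M, 4, 3))
  g[, 1, ] <- g1; g[, 2, ] <- g2; g[, 3, ] <- g3; g[, 4, ] <- g4
  list(g = g, vol = abs(vol6) / 6)
}

# 4-point tetrahedral quadrature (degree-2 exact), barycentric coordinates
.tet_qp <- local({
  aa <- 0.5854101966249685; bb <- 0.1381966011250105
  rbind(c(aa, bb, bb, bb), c(bb, aa, bb, bb),
        c(bb, bb, aa, bb), c(bb, bb, bb, aa))
})

# per-cell gradients of all basis functions at one quadrature point:
# returns array [cell, dof, xyz]
.basis_gradients <- function(geom, order, L) {
  g <- geom$g
  M <- dim(g)[1]
  if (order == 1) return(g)
  nd <- 10
  G <- array(0, c(M, nd, 3))
  for (i in 1:4) G[, i, ] <- (4 * L[i] - 1) * g[, i, ]
  for (e in 1:6) {
    i <- .tet_edges[e, 1]; j <- .tet_edges[e, 2]
    G[, 4 + e, ] <- 4 * (L[j] * g[, i, ] + L[i] * g[, j, ])
  }
  G
}

# assemble a stiffness matrix with per-cell coefficient: either a scalar
# coefficient `coef` (isotropic) or additionally a per-cell symmetric
# tensor weighting `tensor` (n x 6: Dxx Dxy Dxz Dyy Dyz Dzz) on top of it
.assemble_stiffness <- function(mesh, space, geom, coef, tensor = NULL) {
  M <- nrow(mesh$cells)
  nd <- if (space$order == 1) 4 else 10
  npair <- nd * (nd + 1) / 2
  nqp <- nrow(.tet_qp)
  acc <- vector("list", nqp)
  for (q in seq_len(nqp)) {
    G <- .basis_gradients(geom, space$order, .tet_qp[q, ])
    if (is.null(tensor)) {
      KG <- G * as.vector(coef)
    } else {
      KG <- array(0, dim(G))
      cxx <- coef * tensor[, 1]; cxy <- coef * tensor[, 2]
      cxz <- coef * tensor[, 3]; cyy <- coef * tensor[, 4]
      cyz <- coef * tensor[, 5]; czz <- coef * tensor[, 6]
      KG[, , 1] <- G[, , 1] * cxx + G[, , 2] * cxy + G[, , 3] * cxz
      KG[, , 2] <- G[, , 1] * cxy + G[, , 2] * cyy + G[, , 3] * cyz
      KG[, , 3] <- G[, , 1] * cxz + G[, , 2] * cyz + G[, , 3] * czz
    }
    vals <- matrix(0, M, npair)
    p <- 0
    for (i in seq_len(nd)) for (j in i:nd) {
      p <- p + 1
      vals[, p] <- G[, i, 1] * KG[, j, 1] + G[, i, 2] * KG[, j, 2] +
        G[, i, 3] * KG[, j, 3]
    }
    acc[[q]] <- vals
  }
  vals <- Reduce(`+`, acc) * (geom$vol / nqp)
  ii <- jj <- matrix(0L, M, npair)
  p <- 0
  for (i in seq_len(nd)) for (j in i:nd) {
    p <- p + 1
    ii[, p] <- space$cell_dofs[, i]
    jj[, p] <- space$cell_dofs[, j]
  }
  offdiag <- as.vector(ii) != as.vector(jj)
  Matrix::sparseMatrix(
    i = c(as.vector(ii), as.vector(jj)[offdiag]),
    j = c(as.vector(jj), as.vector(ii)[offdiag]),
    x = c(as.vector(vals), as.vector(vals)[offdiag]),
    dims = c(space$ndof, space$ndof))
}

# Preconditioned conjugate-orthogonal CG (COCG) for the complex symmetric
# system (Kr + j Ki) z = b, with the real SPD preconditioner M = Kr + Ki
# (both parts are PSD and their sum is definite on the free dofs, covering
# purely capacitive floating regions as well as purely conductive tissue).
# Equivalent to the 2x2 real block formulation over (Re phi, Im phi).
.solve_complex <- function(Kr, Ki, b, tol = 1e-10, maxit = 1000L) {
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kr + Ki), super = TRUE)
  prec <- function(v)
    as.vector(Matrix::solve(Ch, Re(v))) +
      1i * as.vector(Matrix::solve(Ch, Im(v)))
  amul <- function(v)
    as.vector(Kr %*% Re(v)) - as.vector(Ki %*% Im(v)) +
      1i * (as.vector(Kr %*% Im(v)) + as.vector(Ki %*% Re(v)))
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) return(complex(length.out = length(b)))
  x <- complex(length.out = length(b))
  r <- b
  z <- prec(r)
  p <- z
  rho <- sum(r * z)                       # unconjugated inner product
  for (it in seq_len(maxit)) {
    q <- amul(p)
    alpha <- rho / sum(p * q)
    x <- x + alpha * p
    r <- r - alpha * q
    if (sqrt(sum(Mod(r)^2)) / nb < tol) return(x)
    z <- prec(r)
    rho_new <- sum(r * z)
    p <- z + (rho_new / rho) * p
    rho <- rho_new
  }
  stop("complex EQS solve did not converge: relative residual ",
       signif(sqrt(sum(Mod(r)^2)) / nb, 3), " after ", maxit, " iterations")
}

# --- boundary specification --------------------------------------------------

#' Boundary specification for an EQS solve
#'
#' @param contacts data.frame with columns `id`, `role` (`active`,
#'   `ground`, `floating`, `inactive`) — defaults to the mesh's own
#'   contact table when `NULL` in [solve_eqs].
#' @param values complex or numeric vector of Dirichlet values, aligned
#'   with `contacts` rows (ignored for floating/inactive contacts).
#' @param outer `"grounded"` or `"insulated"` outer boundary.
#' @param floating_eps virtual relative permittivity of floating and
#'   inactive conductors.
#' @param floating_dc_sigma virtual conductivity used for floating
#'   conductors in a DC solve, where the permittivity path vanishes;
#'   default matches the magnitude of the virtual permittivity path at
#'   130 Hz.
#' @return an object of class `boundary_spec`.
#' @export
boundary_spec <- function(contacts, values = NULL,
                          outer = c("insulated", "grounded"),
                          floating_eps = 1e9,
                          floating_dc_sigma = NULL) {
  outer <- match.arg(outer)
  if (floating_eps <= 0) stop("floating permittivity must be > 0")
  if (is.null(values)) values <- contacts$value
  if (is.null(floating_dc_sigma))
    floating_dc_sigma <- EPS0 * floating_eps * 2 * pi * 130
  dir_roles <- contacts$role %in% c("active", "ground")
  if (outer == "insulated" && !any(dir_roles))
    stop("no Dirichlet surface: insulated outer boundary needs an active or ground contact")
  structure(list(contacts = contacts, values = as.complex(values),
                 outer = outer, floating_eps = floating_eps,
                 floating_dc_sigma = floating_dc_sigma),
            class = "boundary_spec")
}

# Dirichlet dofs and values for a space; returns list(dofs, values)
.dirichlet_dofs <- function(mesh, space, bc) {
  dofs <- integer(0); vals <- complex(0)
  add <- function(nodeset, value) {
    if (!length(nodeset)) return()
    dd <- nodeset
    if (space$order == 2) {
      inset <- logical(space$nvert); inset[nodeset] <- TRUE
      eon <- which(inset[space$edge_nodes[, 1]] & inset[space$edge_nodes[, 2]])
      dd <- c(dd, space$nvert + eon)
    }
    dofs <<- c(dofs, dd)
    vals <<- c(vals, rep(as.complex(value), length(dd)))
  }
  for (r in seq_len(nrow(bc$contacts))) {
    id <- bc$contacts$id[r]
    if (!bc$contacts$role[r] %in% c("active", "ground")) next
    value <- bc$values[r]
    tag <- paste0("contact_", id)
    if (tag %in% names(mesh$surf_nodes) &&
        length(mesh$surf_nodes[[tag]])) {
      add(mesh$surf_nodes[[tag]], value)
    } else {
      incells <- which(!is.na(mesh$contact_cell) & mesh$contact_cell == id)
      if (!length(incells)) stop("contact ", id, " not present in mesh")
      add(unique(as.vector(mesh$cells[incells, ])), value)
      if (space$order == 2) {
        # edge dofs internal to the contact region
        ed <- unique(as.vector(space$cell_dofs[incells, 5:10]))
        dofs <<- c(dofs, ed)
        vals <<- c(vals, rep(as.complex(value), length(ed)))
      }
    }
  }
  if (bc$outer == "grounded" && "outer" %in% names(mesh$surf_nodes))
    add(mesh$surf_nodes$outer, 0)
  keep <- !duplicated(dofs)
  list(dofs = dofs[keep], values = vals[keep])
}

# --- the solver --------------------------------------------------------------

#' Solve the electro-quasistatic problem at one frequency
#'
#' Assembles and solves the weak form of
#' `div((sigma D + j w eps0 eps_r I) grad phi) = 0` on the mesh, with
#' Dirichlet data on active/ground contacts, a grounded or insulated outer
#' boundary, and floating conductors realized through the virtual
#' permittivity. At `f = 0` (or in quasistatic mode) the capacitive term
#' vanishes and a purely conductive real system is solved.
#'
#' @param mesh a `domain_mesh` with tissue labels assigned.
#' @param materials a [tissue_table].
#' @param bc a [boundary_spec]; `NULL` uses the mesh's own contact table
#'   with an insulated outer boundary.
#' @param f frequency, Hz (>= 0).
#' @param order element order, 1 or 2.
#' @param qs_mode quasistatic flag: permittivity ignored everywhere except
#'   in floating conductors.
#' @return an object of class `field_solution` with the complex nodal
#'   potential `phi`, the space, `V_drop`, and the inputs needed for
#'   post-processing.
#' @export
solve_eqs <- function(mesh, materials, bc = NULL, f = 130, order = 2,
                      qs_mode = FALSE) {
  stopifnot(inherits(mesh, "domain_mesh"), inherits(materials, "tissue_table"))
  if (is.null(bc)) bc <- boundary_spec(mesh$contacts)
  space <- fem_space(mesh, order)
  geom <- .cell_geometry(mesh)
  M <- nrow(mesh$cells)

  # per-cell conductivity / permittivity
  lab <- ifelse(mesh$region == "encapsulation", "encapsulation", mesh$tissue)
  sig <- numeric(M); epsr <- numeric(M)
  for (l in unique(lab)) {
    se <- sigma_eps_at(materials, l, f, qs_mode)
    sel <- lab == l
    sig[sel] <- se$sigma
    epsr[sel] <- se$eps_r
  }
  # floating / inactive conductors: virtual permittivity (or virtual
  # conductivity at DC); Dirichlet-constrained contact regions keep it too
  # (their dofs are eliminated anyway)
  float_ids <- bc$contacts$id[bc$contacts$role %in% c("floating", "inactive")]
  metal <- !is.na(mesh$contact_cell) | mesh$region == "floating_conductor"
  isfloat <- (!is.na(mesh$contact_cell) & mesh$contact_cell %in% float_ids) |
    (mesh$region == "floating_conductor" & is.na(mesh$contact_cell))
  if (any(isfloat)) {
    if (f > 0) { sig[isfloat] <- 0; epsr[isfloat] <- bc$floating_eps }
    else { sig[isfloat] <- bc$floating_dc_sigma; epsr[isfloat] <- 0 }
  }

  # anisotropy applies to the conductive part of plain tissue cells only
  tensor <- mesh$tensor
  if (!is.null(tensor)) {
    tensor <- tensor
    off <- mesh$region %in% c("encapsulation", "floating_conductor") | metal
    tensor[off, ] <- rep(c(1, 0, 0, 1, 0, 1), each = sum(off))
  }

  Ks <- .assemble_stiffness(mesh, space, geom, sig, tensor)
  w <- 2 * pi * f
  has_imag <- f > 0 && any(epsr != 0)
  dir <- .dirichlet_dofs(mesh, space, bc)
  if (!length(dir$dofs)) stop("singular system: no Dirichlet constraint anywhere")
  free <- setdiff(seq_len(space$ndof), dir$dofs)
  phi <- complex(length.out = space$ndof)
  phi[dir$dofs] <- dir$values

  if (!has_imag && all(Im(dir$values) == 0)) {
    rhs <- -Ks[free, dir$dofs, drop = FALSE] %*% Re(dir$values)
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ks[free, free]),
                           super = TRUE)
    phi[free] <- as.vector(Matrix::solve(Ch, rhs))
  } else {
    Ke <- if (has_imag)
      .assemble_stiffness(mesh, space, geom, w * EPS0 * epsr, NULL)
    else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = dim(Ks))
    Ksc <- Ks[free, dir$dofs, drop = FALSE]
    Kec <- Ke[free, dir$dofs, drop = FALSE]
    rhs <- complex(
      real = -as.vector(Ksc %*% Re(dir$values)) +
        as.vector(Kec %*% Im(dir$values)),
      imaginary = -as.vector(Ksc %*% Im(dir$values)) -
        as.vector(Kec %*% Re(dir$values)))
    phi[free] <- .solve_complex(Ks[free, free], Ke[free, free], rhs)
  }

  dv <- dir$values
  if (bc$outer == "grounded") dv <- c(dv, 0 + 0i)
  V_source <- dv[which.max(Mod(dv))] - dv[which.min(Mod(dv))]
  if (!exists("Ke", inherits = FALSE)) Ke <- NULL
  structure(list(frequency = f, phi = phi, space = space, order = order,
                 qs_mode = qs_mode, mesh = mesh, bc = bc,
                 sigma_cells = sig, epsr_cells = epsr, tensor_cells = tensor,
                 Ks = Ks, Ke = Ke,
                 V_drop = Mod(V_source), V_source = V_source),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution: f = %g Hz, %d dofs (P%d)%s, V_drop = %g V\n",
              x$frequency, x$space$ndof, x$order,
              if (x$qs_mode) " [QS]" else "", x$V_drop))
  invisible(x)
}

# --- post-processing ---------------------------------------------------------

# locate points in cells; returns list(cell, bary 4 columns); with
# error_outside = FALSE, outside points get cell = NA instead of an error
.locate_points <- function(mesh, points, error_outside = TRUE) {
  points <- matrix(points, ncol = 3)
  M <- nrow(mesh$cells)
  lo <- hi <- vector("list", 3)
  v1 <- mesh$nodes[mesh$cells[, 1], , drop = FALSE]
  v2 <- mesh$nodes[mesh$cells[, 2], , drop = FALSE]
  v3 <- mesh$nodes[mesh$cells[, 3], , drop = FALSE]
  v4 <- mesh$nodes[mesh$cells[, 4], , drop = FALSE]
  blo <- pmin(v1, pmin(v2, pmin(v3, v4))) - 1e-9
  bhi <- pmax(v1, pmax(v2, pmax(v3, v4))) + 1e-9
  cellof <- integer(nrow(points))
  bary <- matrix(0, nrow(points), 4)
  for (p in seq_len(nrow(points))) {
    x <- points[p, ]
    cand <- which(blo[, 1] <= x[1] & bhi[, 1] >= x[1] &
                  blo[, 2] <= x[2] & bhi[, 2] >= x[2] &
                  blo[, 3] <= x[3] & bhi[, 3] >= x[3])
    found <- 0L
    best <- -Inf; bestc <- 0L; bestb <- NULL
    for (cc in cand) {
      A <- v1[cc, ]
      Tm <- cbind(v2[cc, ] - A, v3[cc, ] - A, v4[cc, ] - A)
      b3 <- solve(Tm, x - A)
      b <- c(1 - sum(b3), b3)
      mn <- min(b)
      if (mn > best) { best <- mn; bestc <- cc; bestb <- b }
      if (mn >= -1e-8) { found <- cc; break }
    }
    if (!found) {
      if (best > -1e-6) { found <- bestc }  # boundary round-off
      else if (!error_outside) { cellof[p] <- NA_integer_; next }
      else stop("point outside mesh: (", paste(signif(x, 6), collapse = ", "), ")")
    }
    cellof[p] <- found
    bary[p, ] <- if (found == bestc) bestb else bary[p, ]
    if (found != bestc) {
      A <- v1[found, ]
      Tm <- cbind(v2[found, ] - A, v3[found, ] - A, v4[found, ] - A)
      b3 <- solve(Tm, x - A)
      bary[p, ] <- c(1 - sum(b3), b3)
    }
  }
  list(cell = cellof, bary = bary)
}

# P1/P2 basis values at barycentric coordinates
.basis_values <- function(order, bary) {
  if (order == 1) return(bary)
  n <- nrow(bary)
  out <- matrix(0, n, 10)
  out[, 1:4] <- bary * (2 * bary - 1)
  for (e in 1:6)
    out[, 4 + e] <- 4 * bary[, .tet_edges[e, 1]] * bary[, .tet_edges[e, 2]]
  out
}

#' Probe the complex potential at points
#'
#' Element-order-consistent interpolation of the solution at arbitrary
#' interior points.
#'
#' @param sol a `field_solution`.
#' @param points n x 3 matrix of coordinates (mm).
#' @return complex vector of potentials (V).
#' @export
probe_potential <- function(sol, points) {
  stopifnot(inherits(sol, "field_solution"))
  points <- matrix(points, ncol = 3)
  loc <- .locate_points(sol$mesh, points)
  bv <- .basis_values(sol$order, loc$bary)
  dofs <- sol$space$cell_dofs[loc$cell, , drop = FALSE]
  vals <- matrix(sol$phi[dofs], nrow(points))
  rowSums(bv * vals)
}

#' Complex electric field at cell midpoints
#'
#' Evaluates `E = -grad phi` at the centroid of the given cells.
#'
#' @param sol a `field_solution`.
#' @param cells cell indices (default all).
#' @return complex n x 3 matrix (V/mm).
#' @export
cell_field <- function(sol, cells = seq_len(nrow(sol$mesh$cells))) {
  geom <- .cell_geometry(sol$mesh)
  L <- c(0.25, 0.25, 0.25, 0.25)
  G <- .basis_gradients(list(g = geom$g[cells, , , drop = FALSE]),
                        sol$order, L)
  dofs <- sol$space$cell_dofs[cells, , drop = FALSE]
  vals <- matrix(sol$phi[dofs], length(cells))
  E <- matrix(0 + 0i, length(cells), 3)
  for (a in 1:3) E[, a] <- -rowSums(vals * G[, , a])
  E
}

# complex admittivity tensor applied to a complex vector field, per cell
.kappa_times <- function(sol, cells, V) {
  sig <- sol$sigma_cells[cells]
  ew <- 2 * pi * sol$frequency * EPS0 * sol$epsr_cells[cells]
  if (is.null(sol$tensor_cells)) {
    sweep(V, 1, sig + 1i * ew, "*")
  } else {
    D <- sol$tensor_cells[cells, , drop = FALSE]
    out <- V
    out[, 1] <- sig * (D[, 1] * V[, 1] + D[, 2] * V[, 2] + D[, 3] * V[, 3])
    out[, 2] <- sig * (D[, 2] * V[, 1] + D[, 4] * V[, 2] + D[, 5] * V[, 3])
    out[, 3] <- sig * (D[, 3] * V[, 1] + D[, 5] * V[, 2] + D[, 6] * V[, 3])
    out + 1i * sweep(V, 1, ew, "*")
  }
}

#' Complex current through a contact
#'
#' Surface integral of the normal admittivity flux
#' `J_n = oint (sigma + j w eps) E . n dS` over the contact's facets,
#' oriented so that a positive real part is current delivered from the
#' contact into the tissue.
#'
#' @param sol a `field_solution`.
#' @param contact_id contact id.
#' @return list with `contact`, `J` (complex A).
#' @export
contact_current <- function(sol, contact_id) {
  mesh <- sol$mesh
  fac <- contact_facets(mesh, contact_id)
  # facet normal (vertex order points from tissue into the contact),
  # area-weighted; gradient of phi at the facet centroid of the owning
  # tissue cell (exact for the linear P2 gradient)
  p1 <- mesh$nodes[fac$n1, , drop = FALSE]
  p2 <- mesh$nodes[fac$n2, , drop = FALSE]
  p3 <- mesh$nodes[fac$n3, , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nvec <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1]) / 2  # area-weighted
  centr <- (p1 + p2 + p3) / 3
  loc <- .locate_in_given_cells(mesh, centr, fac$cell)
  G <- .facet_gradients(sol, fac$cell, loc)
  # J . n with J = kappa * E = -kappa * grad(phi); outward-from-tissue
  # normal points into the contact, so delivered current is
  # +int kappa grad(phi) . n dS
  KG <- .kappa_times(sol, fac$cell, G)
  J <- sum(KG[, 1] * nvec[, 1] + KG[, 2] * nvec[, 2] + KG[, 3] * nvec[, 3])
  # scale: coordinates in mm -> gradient in V/mm, area in mm^2; sigma is
  # S/m, so convert mm to m once (1/mm * mm^2 = mm = 1e-3 m)
  list(contact = contact_id, J = J * 1e-3)
}

# barycentric coordinates of points within prescribed cells
.locate_in_given_cells <- function(mesh, points, cells) {
  n <- nrow(points)
  bary <- matrix(0, n, 4)
  for (p in seq_len(n)) {
    c4 <- mesh$cells[cells[p], ]
    A <- mesh$nodes[c4[1], ]
    Tm <- cbind(mesh$nodes[c4[2], ] - A, mesh$nodes[c4[3], ] - A,
                mesh$nodes[c4[4], ] - A)
    b3 <- solve(Tm, points[p, ] - A)
    bary[p, ] <- c(1 - sum(b3), b3)
  }
  bary
}

# gradient of phi at given barycentric points of given cells
.facet_gradients <- function(sol, cells, bary) {
  mesh <- sol$mesh
  geomg <- .cell_geometry(mesh)$g[cells, , , drop = FALSE]
  n <- length(cells)
  dofs <- sol$space$cell_dofs[cells, , drop = FALSE]
  vals <- matrix(sol$phi[dofs], n)
  G <- matrix(0 + 0i, n, 3)
  if (sol$order == 1) {
    for (a in 1:3) G[, a] <- rowSums(vals * geomg[, , a])
    return(G)
  }
  for (p in seq_len(n)) {
    B <- .basis_gradients(list(g = geomg[p, , , drop = FALSE]), 2, bary[p, ])
    for (a in 1:3) G[p, a] <- sum(vals[p, ] * B[1, , a])
  }
  G
}

#' Volume-consistent (residual-based) contact current
#'
#' Discretely conservative flux through a Dirichlet-constrained contact:
#' the sum of the weak residual `K phi` over the contact's constrained
#' dofs equals the admittivity flux through the contact surface, with the
#' natural boundary condition absorbing the insulating surfaces. More
#' accurate than facet integration on coarse meshes; used as the
#' independent cross-check of [contact_current].
#'
#' @param sol a `field_solution`.
#' @param contact_id contact id (must be Dirichlet-constrained).
#' @return list with `contact`, `J` (complex A).
#' @export
contact_current_residual <- function(sol, contact_id) {
  mesh <- sol$mesh
  space <- sol$space
  Ks <- sol$Ks
  if (is.null(Ks)) {
    geom <- .cell_geometry(mesh)
    Ks <- .assemble_stiffness(mesh, space, geom, sol$sigma_cells,
                              sol$tensor_cells)
  }
  w <- 2 * pi * sol$frequency
  dofs <- integer(0)
  tag <- paste0("contact_", contact_id)
  if (tag %in% names(mesh$surf_nodes) && length(mesh$surf_nodes[[tag]])) {
    nodeset <- mesh$surf_nodes[[tag]]
    dofs <- nodeset
    if (space$order == 2) {
      inset <- logical(space$nvert); inset[nodeset] <- TRUE
      dofs <- c(dofs, space$nvert +
                  which(inset[space$edge_nodes[, 1]] &
                        inset[space$edge_nodes[, 2]]))
    }
  } else {
    incells <- which(!is.na(mesh$contact_cell) &
                       mesh$contact_cell == contact_id)
    if (!length(incells)) stop("unknown contact: ", contact_id)
    dofs <- unique(as.vector(space$cell_dofs[incells, ]))
  }
  r <- as.vector(Ks %*% Re(sol$phi)) + 1i * as.vector(Ks %*% Im(sol$phi))
  if (sol$frequency > 0 && any(sol$epsr_cells != 0)) {
    Ke <- sol$Ke
    if (is.null(Ke))
      Ke <- .assemble_stiffness(mesh, space, .cell_geometry(mesh),
                                w * EPS0 * sol$epsr_cells, NULL)
    r <- r + 1i * (as.vector(Ke %*% Re(sol$phi)) +
                     1i * as.vector(Ke %*% Im(sol$phi)))
  }
  list(contact = contact_id, J = sum(r[dofs]) * 1e-3)
}

#' Rescale a solution to a target contact current
#'
#' Uses linearity of the field problem: multiplies the potential by
#' `target / J` so the re-evaluated contact current equals the target.
#'
#' @param sol a `field_solution`.
#' @param reading a [contact_current] reading of the driving contact.
#' @param target target complex current, A.
#' @return the rescaled `field_solution`.
#' @export
scale_to_current <- function(sol, reading, target) {
  if (Mod(reading$J) == 0) stop("zero contact current: degenerate boundary conditions")
  s <- target / reading$J
  sol$phi <- sol$phi * s
  sol$V_source <- sol$V_source * s
  sol$V_drop <- Mod(sol$V_source)
  sol$scaled_by <- s
  sol
}

#' Tissue impedance seen by the source
#'
#' @param sol a `field_solution`.
#' @param reading a [contact_current] reading of the source contact.
#' @return complex impedance `V_source / J`, Ohm.
#' @export
impedance <- function(sol, reading) {
  if (Mod(reading$J) == 0) stop("zero current: impedance undefined")
  sol$V_source / reading$J
}

#' Multicontact current-controlled boundary values
#'
#' For each contact with a prescribed current, solves once with that
#' contact driven (Dirichlet value numerically equal to the prescribed
#' current), the ground contact at zero, and all other contacts floating.
#' The per-contact Dirichlet value is then assembled as the Ohm's-law
#' rescaling of its own solve plus the superposed floating potentials of
#' the other solves, and the combined problem is re-solved.
#'
#' @param mesh a `domain_mesh` with region-realized contacts.
#' @param materials a [tissue_table].
#' @param currents named numeric vector: prescribed currents (A) keyed by
#'   contact id.
#' @param ground_id id of the ground (return) contact.
#' @param f frequency, Hz.
#' @param order element order (>= 2 recommended for current evaluation).
#' @param qs_mode quasistatic flag.
#' @param tol_J relative tolerance on the achieved currents.
#' @param flux flux evaluator used for the Ohm's-law rescaling and the
#'   achieved-current check: `"residual"` (volume-consistent, discretely
#'   conservative; default) or `"facet"` (surface integration per
#'   [contact_current]).
#' @return list with `values` (complex Dirichlet value per driven
#'   contact), `solution` (the combined `field_solution`), `achieved`
#'   (complex currents re-evaluated from the combined solve).
#' @export
multicontact_current_mode <- function(mesh, materials, currents, ground_id,
                                      f = 130, order = 2, qs_mode = FALSE,
                                      tol_J = 0.02,
                                      flux = c("residual", "facet")) {
  flux <- match.arg(flux)
  readJ <- if (flux == "residual") contact_current_residual else contact_current
  ids <- as.integer(names(currents))
  all_ids <- mesh$contacts$id
  sols <- list(); Jn <- complex(length(ids)); floatV <- matrix(
    0 + 0i, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in seq_along(ids)) {
    k <- ids[s]
    roles <- ifelse(all_ids == k, "active",
                    ifelse(all_ids == ground_id, "ground", "floating"))
    vals <- ifelse(all_ids == k, currents[[s]], 0)
    bc <- boundary_spec(data.frame(id = all_ids, role = roles), vals)
    sol <- solve_eqs(mesh, materials, bc, f, order, qs_mode)
    Jn[s] <- readJ(sol, k)$J
    for (s2 in seq_along(ids)) {
      if (s2 == s) next
      floatV[s2, s] <- .contact_mean_potential(sol, ids[s2])
    }
    sols[[s]] <- sol
  }
  scale <- currents / Jn
  values <- complex(length(ids))
  for (s in seq_along(ids)) {
    values[s] <- currents[[s]] * scale[s] +
      sum(floatV[s, -s] * scale[-s])
  }
  roles <- ifelse(all_ids %in% ids, "active",
                  ifelse(all_ids == ground_id, "ground", "floating"))
  vals <- complex(length(all_ids))
  vals[match(ids, all_ids)] <- values
  bc <- boundary_spec(data.frame(id = all_ids, role = roles), vals)
  combined <- solve_eqs(mesh, materials, bc, f, order, qs_mode)
  achieved <- vapply(ids, function(k) readJ(combined, k)$J,
                     complex(1))
  rel <- Mod(achieved - currents) / Mod(currents)
  if (any(rel > tol_J))
    warning("achieved currents deviate from prescribed by up to ",
            signif(max(rel) * 100, 3), "%")
  list(values = stats::setNames(values, ids), solution = combined,
       achieved = stats::setNames(achieved, ids))
}

#' Export a field solution as VTK point data
#'
#' Writes the mesh with `phi_re`, `phi_im` and the field magnitude
#' `E_mag` (cell data, V/mm) to a legacy VTK file.
#'
#' @param sol a `field_solution`.
#' @param path output `.vtk` path.
#' @export
write_solution_vtk <- function(sol, path) {
  nv <- sol$space$nvert
  E <- cell_field(sol)
  write_mesh_vtk(sol$mesh, path,
                 point_data = list(phi_re = Re(sol$phi[seq_len(nv)]),
                                   phi_im = Im(sol$phi[seq_len(nv)])),
                 cell_data = list(E_mag = sqrt(rowSums(Mod(E)^2))))
}

#' Write a time course as CSV
#' @param times numeric vector, seconds.
#' @param values numeric vector of the same length.
#' @param path output CSV (`time_s, value`).
#' @export
write_time_course_csv <- function(times, values, path) {
  utils::write.csv(data.frame(time_s = times, value = values), path,
                   row.names = FALSE)
  invisible(path)
}

# mean potential over the dofs of a contact (floating contacts are
# near-equipotential, so the mean is a faithful single value)
.contact_mean_potential <- function(sol, contact_id) {
  mesh <- sol$mesh
  tag <- paste0("contact_", contact_id)
  if (tag %in% names(mesh$surf_nodes) && length(mesh$surf_nodes[[tag]])) {
    return(mean(sol$phi[mesh$surf_nodes[[tag]]]))
  }
  incells <- which(!is.na(mesh$contact_cell) & mesh$contact_cell == contact_id)
  mean(sol$phi[unique(as.vector(mesh$cells[incells, ]))])
}
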