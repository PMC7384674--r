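# Computational-domain construction: a sphere or ellipsoid of tissue with
# a parametric cylindrical lead carved out. Ring contacts are kept in the
# mesh as metal cell regions (so they can be driven or left floating); the
# insulating shaft becomes a hole with a homogeneous Neumann boundary. The
# mesh is partitioned into encapsulation, contact vicinity, ROI and ROT,
# and graded towards per-region target edge lengths by conforming
# bisection.

#' Parametric electrode specification
#'
#' A cylindrical lead entering the domain along `direction` from
#' `tip_position`, carrying ring contacts over given axial spans. A
#' `snex_like` preset builds a coaxial two-contact (tip + ring) rodent
#' electrode.
#'
#' @param tip_position lead tip, mm.
#' @param direction lead axis direction (need not be normalized).
#' @param lead_radius lead radius, mm.
#' @param contacts data.frame with `id`, `z_start`, `z_end` (axial span
#'   from the tip, mm), `role` (`active`, `ground`, `floating`,
#'   `inactive`), `value` (assigned V or A).
#' @param encapsulation_thickness thickness of the fibrotic sheath, mm.
#' @param lead_length carved shaft length from the tip, mm (default: past
#'   the last contact and out of the domain).
#' @return an object of class `electrode_spec`.
#' @export
electrode_spec <- function(tip_position = c(0, 0, 0),
                           direction = c(0, 0, 1),
                           lead_radius = 0.6,
                           contacts = data.frame(
                             id = 1:2,
                             z_start = c(0.5, 2.5), z_end = c(1.5, 3.5),
                             role = c("active", "ground"),
                             value = c(1, 0)),
                           encapsulation_thickness = 0.1,
                           lead_length = NULL) {
  direction <- direction / sqrt(sum(direction^2))
  if (encapsulation_thickness <= 0) stop("encapsulation thickness must be > 0")
  o <- order(contacts$z_start)
  contacts <- contacts[o, , drop = FALSE]
  if (any(contacts$z_end <= contacts$z_start))
    stop("contact spans must have z_end > z_start")
  if (nrow(contacts) > 1 &&
      any(contacts$z_start[-1] < contacts$z_end[-nrow(contacts)]))
    stop("contacts overlap along the lead axis")
  structure(list(tip_position = tip_position, direction = direction,
                 lead_radius = lead_radius, contacts = contacts,
                 encapsulation_thickness = encapsulation_thickness,
                 lead_length = lead_length),
            class = "electrode_spec")
}

#' Coaxial SNEX-like two-contact electrode preset
#' @param tip_position,direction lead placement (mm / unit vector).
#' @param value assigned value of the core (tip) contact.
#' @return an [electrode_spec] with a tip core contact and a ring ground.
#' @export
electrode_snex_like <- function(tip_position = c(0, 0, 0),
                                direction = c(0, 0, 1), value = 1) {
  electrode_spec(tip_position, direction, lead_radius = 0.25,
                 contacts = data.frame(id = 1:2,
                                       z_start = c(0, 1.0),
                                       z_end = c(0.5, 1.5),
                                       role = c("active", "ground"),
                                       value = c(value, 0)),
                 encapsulation_thickness = 0.1)
}

#' Build the computational domain mesh around an electrode
#'
#' Generates a Kuhn-triangulated background grid over the domain, removes
#' the insulating lead shaft (leaving a Neumann hole), keeps the ring
#' contacts as metal cell regions, tags the encapsulation shell, the
#' contact vicinity, ROI and ROT, and bisects cells until each region
#' meets its target edge length.
#'
#' @param domain list with `shape` (`"sphere"` or `"ellipsoid"`),
#'   `diameter` (sphere) or `semiaxes` (ellipsoid, mm) and optional
#'   `center` (mm).
#' @param electrode an [electrode_spec]; must lie inside the domain.
#' @param target_edges named list of per-region target longest-edge
#'   lengths (mm): `roi`, `vicinity`, `rot` (encapsulation and contact
#'   metal share the vicinity target).
#' @param base_edge background grid edge (mm); default
#'   `min(lead_radius, rot target)`.
#' @param roi_center,roi_radius ROI bounding sphere (mm); default a 1 mm
#'   ball past the first contact.
#' @param max_refine_rounds cap on bisection rounds per call.
#' @return a `domain_mesh` with `tissue = "unknown"` (map a voxel volume
#'   afterwards), regions tagged, contacts attached.
#' @export
build_domain_mesh <- function(domain = list(shape = "sphere", diameter = 10),
                              electrode = electrode_spec(),
                              target_edges = list(roi = 0.5, vicinity = 0.1,
                                                  rot = 2.0),
                              base_edge = NULL,
                              roi_center = NULL, roi_radius = NULL,
                              max_refine_rounds = 12) {
  stopifnot(inherits(electrode, "electrode_spec"))
  center <- if (is.null(domain$center)) c(0, 0, 0) else domain$center
  semi <- switch(domain$shape,
                 sphere = rep(domain$diameter / 2, 3),
                 ellipsoid = domain$semiaxes,
                 stop("unknown domain shape: ", domain$shape))
  if (any(unlist(target_edges) <= 0)) stop("target edge lengths must be > 0")
  if (is.null(base_edge))
    base_edge <- min(electrode$lead_radius, target_edges$rot)
  ax <- electrode$direction
  tip <- electrode$tip_position
  th <- electrode$encapsulation_thickness
  Llead <- if (is.null(electrode$lead_length))
    max(electrode$contacts$z_end) + 2 * max(semi) else electrode$lead_length
  # electrode inside the domain: every contact span centre within
  in_dom <- function(p) sum(((p - center) / semi)^2) <= 1
  for (r in seq_len(nrow(electrode$contacts))) {
    zm <- (electrode$contacts$z_start[r] + electrode$contacts$z_end[r]) / 2
    if (!in_dom(tip + zm * ax)) stop("electrode contact outside the domain")
  }

  n <- ceiling(2 * semi / base_edge)
  g <- .structured_tets(center - semi, base_edge, n)
  cent <- (g$nodes[g$cells[, 1], ] + g$nodes[g$cells[, 2], ] +
           g$nodes[g$cells[, 3], ] + g$nodes[g$cells[, 4], ]) / 4
  u <- sweep(cent, 2, center)
  inside <- rowSums(sweep(u, 2, semi, "/")^2) <= 1
  rel <- sweep(cent, 2, tip)
  z <- rel %*% ax
  rho <- sqrt(pmax(rowSums(rel^2) - z^2, 0))
  in_lead <- rho <= electrode$lead_radius & z >= 0 & z <= Llead
  contact_of <- rep(NA_integer_, nrow(cent))
  for (r in seq_len(nrow(electrode$contacts))) {
    sel <- in_lead & z >= electrode$contacts$z_start[r] &
      z <= electrode$contacts$z_end[r]
    contact_of[sel] <- electrode$contacts$id[r]
  }
  keep <- inside & (!in_lead | !is.na(contact_of))
  if (!any(keep)) stop("empty mesh: electrode removes the whole domain")
  cells <- g$cells[keep, , drop = FALSE]
  contact_of <- contact_of[keep]
  z <- z[keep]; rho <- rho[keep]
  cmp <- .compact_nodes(g$nodes, cells)

  # region partition by distance from the lead / contacts
  region <- rep("ROT", nrow(cells))
  near_contact_z <- rep(FALSE, nrow(cells))
  for (r in seq_len(nrow(electrode$contacts)))
    near_contact_z <- near_contact_z |
      (z >= electrode$contacts$z_start[r] - 2 * th &
       z <= electrode$contacts$z_end[r] + 2 * th)
  in_shell <- rho <= electrode$lead_radius + th &
    z >= -th & z <= Llead + th & is.na(contact_of)
  in_vic <- rho <= electrode$lead_radius + 2 * th & near_contact_z &
    is.na(contact_of) & !in_shell
  if (is.null(roi_center))
    roi_center <- tip + (max(electrode$contacts$z_end) / 2) * ax +
      c(1, 0, 0) * (electrode$lead_radius + 1)
  if (is.null(roi_radius)) roi_radius <- 1 + electrode$lead_radius
  d_roi <- sqrt(rowSums(sweep(cent[keep, , drop = FALSE], 2, roi_center)^2))
  region[d_roi <= roi_radius] <- "ROI"
  region[in_vic] <- "contact_vicinity"
  region[in_shell] <- "encapsulation"
  region[!is.na(contact_of)] <- "floating_conductor"

  # neighbouring contact regions must not share mesh nodes (a shared node
  # would tie a floating contact to its neighbour's Dirichlet data)
  cids <- sort(unique(contact_of[!is.na(contact_of)]))
  nodesets <- lapply(cids, function(k)
    unique(as.vector(cmp$cells[which(contact_of == k), ])))
  for (a in seq_along(cids)) for (b in seq_len(a - 1)) {
    if (length(intersect(nodesets[[a]], nodesets[[b]])))
      warning("contacts ", cids[b], " and ", cids[a], " share mesh nodes; ",
              "increase the inter-contact gap or reduce base_edge")
  }

  # boundary node tagging: hole (lead) surface vs outer surface
  mesh <- .new_mesh(cmp$nodes, cmp$cells, region = region,
                    tissue = rep("unknown", nrow(cells)),
                    contact_cell = contact_of,
                    contacts = data.frame(id = electrode$contacts$id,
                                          role = electrode$contacts$role,
                                          value = electrode$contacts$value),
                    electrode = electrode)
  mesh <- .tag_domain_boundary(mesh, center, semi, electrode, Llead, base_edge)

  # grade towards per-region targets
  tgt <- c(ROI = target_edges$roi, contact_vicinity = target_edges$vicinity,
           ROT = target_edges$rot, encapsulation = target_edges$vicinity,
           floating_conductor = target_edges$vicinity)
  for (round in seq_len(max_refine_rounds)) {
    edges <- cell_longest_edges(mesh)
    marked <- which(edges > tgt[mesh$region] * (1 + 1e-9))
    if (!length(marked)) break
    mesh <- refine_cells(mesh, marked)
  }
  mesh
}

.tag_domain_boundary <- function(mesh, center, semi, electrode, Llead,
                                 base_edge) {
  bf <- boundary_facets(mesh)
  bn <- unique(c(bf$n1, bf$n2, bf$n3))
  rel <- sweep(mesh$nodes[bn, , drop = FALSE], 2, electrode$tip_position)
  z <- rel %*% electrode$direction
  rho <- sqrt(pmax(rowSums(rel^2) - z^2, 0))
  on_lead <- rho <= electrode$lead_radius + 0.75 * base_edge &
    z >= -0.75 * base_edge & z <= Llead + 0.75 * base_edge
  mesh$surf_nodes <- list(lead = bn[on_lead], outer = bn[!on_lead])
  mesh$surface_geom <- list()
  mesh
}
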