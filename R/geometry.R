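# Resolve an atom selection to a coordinate matrix. `labels` selects by
# atom label; `group` restricts disordered atoms to one disorder group
# (group-0 atoms, i.e. ordered host atoms, always match).
.select_coords <- function(struct, labels, group = NULL) {
  a <- struct$atoms
  keep <- a$label %in% labels
  if (!is.null(group)) keep <- keep & a$disorder_group %in% c(0L, group)
  missing <- setdiff(labels, a$label[keep])
  if (length(missing))
    stop("unresolvable atom label(s): ", paste(missing, collapse = ", "))
  as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
}

#' Centroid of an atom selection
#'
#' Unweighted mean position of the selected atoms (the convention for
#' portal and equatorial centroids of a macrocyclic host; occupancy
#' weighting is deliberately not applied).
#'
#' @param x a \code{\link{structure_model}} or a numeric matrix of
#'   coordinates (rows = atoms).
#' @param labels atom labels to select (when \code{x} is a structure).
#' @param group optional disorder group to restrict to.
#' @return numeric length-3 point.
#' @export
centroid <- function(x, labels = NULL, group = NULL) {
  coords <- if (inherits(x, "structure_model"))
    .select_coords(x, labels, group) else as.matrix(x)
  if (nrow(coords) < 1) stop("empty selection")
  colMeans(coords)
}

#' Least-squares plane through an atom selection
#'
#' Total-least-squares plane: the plane through the selection centroid
#' whose normal is the smallest principal direction of the centered
#' coordinates, minimising the sum of squared perpendicular distances.
#' The rms residual is 0 for coplanar input. If a reference point is
#' supplied the normal is oriented towards it, fixing the sign convention
#' (e.g. towards the host cavity interior).
#'
#' @param x structure model or coordinate matrix.
#' @param labels,group selection (see \code{\link{centroid}}).
#' @param orient_towards optional point the normal should point at.
#' @return object of class \code{hg_plane}: \code{normal} (unit),
#'   \code{point} (selection centroid), \code{rms} residual.
#' @export
fit_plane <- function(x, labels = NULL, group = NULL, orient_towards = NULL) {
  coords <- if (inherits(x, "structure_model"))
    .select_coords(x, labels, group) else as.matrix(x)
  if (nrow(coords) < 3) stop("plane fitting needs at least 3 atoms")
  ctr <- colMeans(coords)
  centered <- sweep(coords, 2, ctr)
  sv <- svd(centered)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) selection: plane undefined")
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  if (!is.null(orient_towards)) {
    if (sum((orient_towards - ctr) * normal) < 0) normal <- -normal
  }
  rms <- sqrt(mean((centered %*% normal)^2))
  structure(list(normal = normal, point = ctr, rms = rms),
            class = "hg_plane")
}

#' Distance from a point to a plane
#'
#' Perpendicular distance; unsigned by default, signed (positive on the
#' side the normal points to) with \code{signed = TRUE}.
#'
#' @param point numeric length-3 point.
#' @param plane an \code{hg_plane} from \code{\link{fit_plane}}.
#' @param signed return the signed distance.
#' @return distance in the coordinate unit (Angstrom).
#' @export
point_plane_distance <- function(point, plane, signed = FALSE) {
  stopifnot(inherits(plane, "hg_plane"))
  d <- sum((point - plane$point) * plane$normal)
  if (signed) d else abs(d)
}

#' Angle at the vertex of three points
#'
#' Angle a-b-c measured at \code{b}, in degrees within [0, 180].
#'
#' @param a,b,c numeric length-3 points; \code{b} is the vertex.
#' @return angle in degrees.
#' @export
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length arm: vertex coincides with an endpoint")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Acute angle between two planes
#'
#' Angle between the plane normals, folded into [0, 90] degrees (the
#' dihedral convention used for ring-tilt descriptors).
#'
#' @param p1,p2 \code{hg_plane} objects.
#' @return angle in degrees in [0, 90].
#' @export
plane_plane_angle <- function(p1, p2) {
  stopifnot(inherits(p1, "hg_plane"), inherits(p2, "hg_plane"))
  cosang <- abs(sum(p1$normal * p2$normal))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Binding-pose descriptors of a guest in a macrocyclic host
#'
#' Computes, per guest disorder group, the descriptors used to
#' characterise how a piperazinium guest sits in the CB[7] cavity:
#' \itemize{
#'   \item \code{d_N29_plane1}: distance of the charged piperazinium
#'     nitrogen (N29) from the portal-oxygen plane (Plane1);
#'   \item \code{angle_cen1_cen2_N29}: angle at the equatorial centroid
#'     (Cen2) between the portal centroid (Cen1) and N29 - small values
#'     mean the nitrogen sits on the portal axis;
#'   \item \code{angle_phenyl_plane2}: tilt of the phenyl ring plane
#'     against the equatorial plane (Plane2), folded to [0, 90];
#'   \item optionally \code{d_cen1prime_halogen}: distance from the
#'     centroid of the far portal (Cen1') to a para-halogen atom.
#' }
#'
#' Host planes and centroids use all (ordered) host atoms unweighted;
#' guest descriptors are computed separately for each disorder group with
#' its occupancy carried through - conformers are never occupancy-mixed.
#'
#' @param struct a \code{\link{structure_model}}.
#' @param selections list with character vectors \code{portal_O},
#'   \code{equatorial_C}, \code{phenyl}, single labels \code{n29} and
#'   optionally \code{halogen}, and optionally \code{portal_O_prime} (the
#'   far portal oxygens, required for the halogen distance).
#' @return data frame with one row per disorder group: \code{group},
#'   \code{occupancy}, the three descriptors and (when requested)
#'   \code{d_cen1prime_halogen}.
#' @export
pose_descriptors <- function(struct, selections) {
  stopifnot(inherits(struct, "structure_model"))
  need <- c("portal_O", "equatorial_C", "n29", "phenyl")
  missing <- setdiff(need, names(selections))
  if (length(missing))
    stop("missing selection(s): ", paste(missing, collapse = ", "))
  if (length(selections$portal_O) < 3 || length(selections$equatorial_C) < 3 ||
      length(selections$phenyl) < 3)
    stop("plane-defining selections need at least 3 atoms")

  cen2 <- centroid(struct, selections$equatorial_C)
  plane1 <- fit_plane(struct, selections$portal_O, orient_towards = cen2)
  cen1 <- plane1$point
  plane2 <- fit_plane(struct, selections$equatorial_C)

  a <- struct$atoms
  n29_rows <- a[a$label == selections$n29, , drop = FALSE]
  if (!nrow(n29_rows)) stop("unresolvable atom label: ", selections$n29)
  groups <- sort(unique(n29_rows$disorder_group))

  out <- lapply(groups, function(g) {
    n29 <- as.numeric(n29_rows[n29_rows$disorder_group == g,
                               c("x", "y", "z")][1, ])
    occ <- n29_rows$occupancy[n29_rows$disorder_group == g][1]
    phen_plane <- fit_plane(struct, selections$phenyl,
                            group = if (g == 0) NULL else g)
    row <- data.frame(
      group = g, occupancy = occ,
      d_N29_plane1 = point_plane_distance(n29, plane1),
      angle_cen1_cen2_N29 = vertex_angle(cen1, cen2, n29),
      angle_phenyl_plane2 = plane_plane_angle(phen_plane, plane2))
    if (!is.null(selections$halogen)) {
      if (is.null(selections$portal_O_prime))
        stop("halogen distance requested but portal_O_prime not supplied")
      cen1p <- centroid(struct, selections$portal_O_prime)
      hal <- .select_coords(struct, selections$halogen,
                            group = if (g == 0) NULL else g)
      row$d_cen1prime_halogen <- sqrt(sum((hal[1, ] - cen1p)^2))
    }
    row
  })
  do.call(rbind, out)
}

#' Hydrogen-bond geometry between three labelled atoms
#'
#' Donor-acceptor distance and donor-hydrogen-acceptor angle (vertex at
#' the hydrogen), the two quantities tabulated for crystallographic
#' hydrogen bonds.
#'
#' @param struct a \code{\link{structure_model}}.
#' @param donor,hydrogen,acceptor atom labels.
#' @param group optional disorder group.
#' @return data frame with \code{donor}, \code{hydrogen}, \code{acceptor},
#'   \code{d_DA} (Angstrom), \code{angle_DHA} (degrees).
#' @export
hbond_geometry <- function(struct, donor, hydrogen, acceptor, group = NULL) {
  d <- .select_coords(struct, donor, group)[1, ]
  h <- .select_coords(struct, hydrogen, group)[1, ]
  a <- .select_coords(struct, acceptor, group)[1, ]
  data.frame(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
             d_DA = sqrt(sum((d - a)^2)),
             angle_DHA = vertex_angle(d, h, a),
             stringsAsFactors = FALSE)
}

# Apply a rigid-body transform (rotation matrix R then translation t) to
# all atoms of a structure. Used by the generators and invariance tests.
#' Rigid-body transform of a structure
#'
#' Rotates and translates every atom site. Pose descriptors are invariant
#' under such isometries.
#'
#' @param struct a \code{\link{structure_model}}.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector.
#' @return transformed \code{structure_model}.
#' @export
transform_structure <- function(struct, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(struct, "structure_model"))
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  struct$atoms$x <- xyz[, 1]
  struct$atoms$y <- xyz[, 2]
  struct$atoms$z <- xyz[, 3]
  struct$cell <- NULL   # cell no longer meaningful after a Cartesian move
  struct
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
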