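# Eversion-angle reaction coordinate and per-frame structural observables.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.group_xyz <- function(frame, sel) {
  idx <- if (is.numeric(sel)) as.integer(sel) else resolve_selection(frame, sel)
  list(xyz = frame$xyz[idx, , drop = FALSE], mass = frame$atoms$mass[idx])
}

#' Mass-weighted center of mass
#'
#' @param frame a `flip_frame`.
#' @param sel a `group_selection` or integer atom indices.
#' @return length-3 numeric vector (angstrom).
#' @export
center_of_mass <- function(frame, sel) {
  g <- .group_xyz(frame, sel)
  if (nrow(g$xyz) == 0L) .validation_error("empty atom group")
  m <- sum(g$mass)
  if (!is.finite(m) || m <= 0) .validation_error("non-positive total mass")
  as.numeric(colSums(g$xyz * g$mass) / m)
}

#' Signed pseudodihedral angle of four points
#'
#' Standard IUPAC convention: right-handed rotation of the a-b bond onto
#' the c-d bond viewed along b-c is positive; the result lies in
#' (-180, 180] degrees.
#'
#' @param a,b,c,d length-3 numeric points (angstrom).
#' @return angle in degrees.
#' @export
pseudodihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  if (any(vapply(list(b1, b2, b3), function(v) sqrt(sum(v^2)), 1) < 1e-9)) {
    .validation_error("degenerate geometry: coincident consecutive points")
  }
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    .validation_error("degenerate geometry: collinear bond vectors")
  }
  b2h <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2h)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Define the eversion-angle coordinate
#'
#' Four center-of-mass points form a pseudodihedral: P1, the flanking
#' bases of the target pair; P2, the 5' phosphate group; P3, the 3'
#' phosphate group; P4, the Watson-Crick edge of the everting base. The
#' raw dihedral is unwrapped onto a continuous axis on which the
#' intrahelical reference sits near `reference_angle` and eversion
#' proceeds toward larger positive angles.
#'
#' @param p1,p2,p3,p4 `group_selection`s for the four COM groups.
#' @param reference_angle intrahelical anchor, degrees in \[-180, 180).
#' @return an `eversion_definition`.
#' @export
eversion_definition <- function(p1, p2, p3, p4, reference_angle = 0) {
  for (s in list(p1, p2, p3, p4)) stopifnot(inherits(s, "group_selection"))
  if (reference_angle < -180 || reference_angle >= 180) {
    .validation_error("reference_angle must lie in [-180, 180)")
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 reference_angle = reference_angle),
            class = "eversion_definition")
}

#' Unwrap a raw dihedral onto the continuous eversion axis
#'
#' Adds 360 degrees whenever the raw value falls below
#' `reference_angle - 90`, so the sampled 0 to ~280 degree range is
#' continuous with no wrap.
#'
#' @param raw raw dihedral(s), degrees in (-180, 180].
#' @param reference_angle anchor angle, degrees.
#' @return unwrapped angle(s), degrees.
#' @export
unwrap_eversion <- function(raw, reference_angle = 0) {
  raw + 360 * (raw < reference_angle - 90)
}

#' Eversion angle of one frame
#'
#' @param frame a `flip_frame`.
#' @param defn an `eversion_definition`.
#' @return unwrapped eversion angle, degrees.
#' @export
eversion_angle <- function(frame, defn) {
  stopifnot(inherits(defn, "eversion_definition"))
  raw <- pseudodihedral(center_of_mass(frame, defn$p1),
                        center_of_mass(frame, defn$p2),
                        center_of_mass(frame, defn$p3),
                        center_of_mass(frame, defn$p4))
  unwrap_eversion(raw, defn$reference_angle)
}

#' Eversion-angle series over a trajectory
#'
#' @param traj a `flip_traj`.
#' @param defn an `eversion_definition`.
#' @return data frame with columns `frame` and `angle` (degrees).
#' @export
eversion_series <- function(traj, defn) {
  nf <- n_frames(traj)
  ang <- vapply(seq_len(nf), function(i) eversion_angle(get_frame(traj, i), defn),
                numeric(1))
  data.frame(frame = seq_len(nf), angle = ang)
}

#' Distance between two atoms or group centers of mass
#'
#' Single-atom selections give the atom-atom distance; multi-atom
#' selections are reduced to their COMs first.
#'
#' @param frame a `flip_frame`.
#' @param selA,selB `group_selection`s.
#' @return distance in angstrom.
#' @export
atom_distance <- function(frame, selA, selB) {
  pa <- center_of_mass(frame, selA)
  pb <- center_of_mass(frame, selB)
  sqrt(sum((pa - pb)^2))
}

#' DNA-to-hairpin gap distance
#'
#' Convenience wrapper around [atom_distance()] for the gap estimate used
#' to compare lesion and normal-base eversion: the distance between the
#' C3' of the nucleotide 5' of the target and a reference C-alpha on the
#' zinc-finger hairpin.
#'
#' @param frame a `flip_frame`.
#' @param c3prime_sel,calpha_sel single-atom `group_selection`s.
#' @return distance in angstrom.
#' @export
gap_distance <- function(frame, c3prime_sel, calpha_sel) {
  atom_distance(frame, c3prime_sel, calpha_sel)
}

#' Hydrogen-bond geometric criterion
#'
#' @param dist_cutoff donor-acceptor distance cutoff (angstrom).
#' @param angle_cutoff donor-H-acceptor angle cutoff (degrees, <= 180);
#'   the bond is present when the angle is at least this large.
#' @return an `hbond_criterion`.
#' @export
hbond_criterion <- function(dist_cutoff = 3.5, angle_cutoff = 135) {
  if (dist_cutoff <= 0 || angle_cutoff <= 0 || angle_cutoff > 180) {
    .validation_error("hbond cutoffs must be positive and angle <= 180")
  }
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

.single_atom_xyz <- function(frame, sel, what) {
  idx <- resolve_selection(frame, sel)
  if (length(idx) != 1L) .validation_error(what, " selection must resolve to one atom")
  frame$xyz[idx, ]
}

#' Is a hydrogen bond present?
#'
#' Present iff the donor-acceptor distance is at most the distance cutoff
#' AND the donor-H-acceptor angle is at least the angle cutoff.
#'
#' @param frame a `flip_frame`.
#' @param donor,hydrogen,acceptor single-atom `group_selection`s.
#' @param crit an `hbond_criterion`.
#' @return logical.
#' @export
hbond_present <- function(frame, donor, hydrogen, acceptor,
                          crit = hbond_criterion()) {
  d <- .single_atom_xyz(frame, donor, "donor")
  h <- .single_atom_xyz(frame, hydrogen, "hydrogen")
  a <- .single_atom_xyz(frame, acceptor, "acceptor")
  dist_da <- sqrt(sum((d - a)^2))
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  dist_da <= crit$dist_cutoff && ang >= crit$angle_cutoff
}

#' Base-pair step twist angle
#'
#' Simplified C1'-vector convention: the inter-strand C1'-C1' vector of
#' pair i and of pair i+1 are each projected onto the plane perpendicular
#' to the local step axis (midpoint(i) to midpoint(i+1)); the signed angle
#' between the projections is the twist, positive for a right-handed
#' step.
#'
#' @param frame a `flip_frame`.
#' @param c1_i_s1,c1_i_s2 single-atom selections: C1' of pair i on each strand.
#' @param c1_j_s1,c1_j_s2 single-atom selections: C1' of pair i+1 on each strand.
#' @return twist angle in degrees.
#' @export
twist_angle <- function(frame, c1_i_s1, c1_i_s2, c1_j_s1, c1_j_s2) {
  a1 <- .single_atom_xyz(frame, c1_i_s1, "C1' (i, strand 1)")
  a2 <- .single_atom_xyz(frame, c1_i_s2, "C1' (i, strand 2)")
  b1 <- .single_atom_xyz(frame, c1_j_s1, "C1' (i+1, strand 1)")
  b2 <- .single_atom_xyz(frame, c1_j_s2, "C1' (i+1, strand 2)")
  axis <- (b1 + b2) / 2 - (a1 + a2) / 2
  nax <- sqrt(sum(axis^2))
  if (nax < 1e-9) .validation_error("degenerate step axis")
  ax <- axis / nax
  proj <- function(v) v - sum(v * ax) * ax
  v1 <- proj(a2 - a1)
  v2 <- proj(b2 - b1)
  if (sqrt(sum(v1^2)) < 1e-9 || sqrt(sum(v2^2)) < 1e-9) {
    .validation_error("inter-strand vector parallel to step axis")
  }
  atan2(sum(.cross3(v1, v2) * ax), sum(v1 * v2)) * 180 / pi
}

#' Default Watson-Crick edge atom names for G-like bases
#'
#' Heavy atoms of the pairing edge of guanine / 8-oxoguanine: O6, N1, N2.
#'
#' @return character vector of atom names.
#' @export
wc_edge_atoms <- function() c("O6", "N1", "N2")

#' Default phosphate-group atom names
#'
#' @return character vector of atom names: P, OP1, OP2, O5'.
#' @export
phosphate_atoms <- function() c("P", "OP1", "OP2", "O5'")
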