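#' Inter-residue geometry bin specification
#'
#' The four geometry descriptors are discretised as in the trRosetta
#' convention: bin 0 of every descriptor is the shared *no-contact* bin
#' (CB-CB distance >= 20 A, or geometry undefined); distance then has
#' 36 bins of 0.5 A over \[2, 20) A; the dihedrals omega and theta have
#' 24 bins of 15 degrees over \[-180, 180); the planar angle phi has 12
#' bins of 15 degrees over \[0, 180\] with 180 assigned to the top bin.
#' Totals: 37 / 25 / 25 / 13.
#'
#' @return A list with per-descriptor bin counts and edges.
#' @export
geometry_spec <- function() {
  list(
    dist = list(n = 37L, first = 2, width = 0.5, no_contact = 20),
    omega = list(n = 25L, first = -180, width = 15),
    theta = list(n = 25L, first = -180, width = 15),
    phi = list(n = 13L, first = 0, width = 15)
  )
}

#' Midpoints of the 36 contact distance bins (Angstrom)
#' @return Numeric vector of length 36: 2.25, 2.75, ..., 19.75.
#' @export
distance_bin_midpoints <- function() {
  2 + 0.5 * (seq_len(36) - 1) + 0.25
}

vcross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

as_row_matrix <- function(p) {
  if (is.null(dim(p))) matrix(p, nrow = 1) else p
}

#' Dihedral and planar angles from point coordinates
#'
#' `dihedral_angle()` returns the torsion p1-p2-p3-p4 in degrees in
#' \[-180, 180); `planar_angle()` returns the angle at p2 of the
#' triangle p1-p2-p3 in degrees in \[0, 180\].  Arguments are length-3
#' vectors or row-wise matrices of points.
#'
#' @param p1,p2,p3,p4 Points (length-3 vectors or n x 3 matrices).
#' @return Numeric vector of angles in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- as_row_matrix(p1); p2 <- as_row_matrix(p2)
  p3 <- as_row_matrix(p3); p4 <- as_row_matrix(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- vcross(n1, b2n)
  ang <- -atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang >= 180] <- -180
  ang
}

#' @rdname dihedral_angle
#' @export
planar_angle <- function(p1, p2, p3) {
  p1 <- as_row_matrix(p1); p2 <- as_row_matrix(p2); p3 <- as_row_matrix(p3)
  u <- p1 - p2; v <- p3 - p2
  cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Place a virtual CB atom from backbone N, CA, C
#'
#' Uses the fixed ideal-geometry linear combination of
#' `b = CA - N`, `c = C - CA` and `a = b x c`:
#' `CB = -0.58273431 a + 0.56802827 b - 0.54067466 c + CA`.
#' Required for glycine and any residue whose CB is missing.
#'
#' @param n,ca,c Backbone coordinates (length-3 vectors or row-wise
#'   matrices).
#' @return CB coordinates with the same shape as `ca`.
#' @export
virtual_cbeta <- function(n, ca, c) {
  vec_in <- is.null(dim(ca))
  n <- as_row_matrix(n); ca <- as_row_matrix(ca); c <- as_row_matrix(c)
  b <- ca - n
  cc <- c - ca
  a <- vcross(b, cc)
  if (any(sqrt(rowSums(a^2)) < 1e-8)) {
    stop_protgeom("collinear N, CA, C: virtual CB undefined")
  }
  cb <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
  if (vec_in) drop(cb) else cb
}

#' Compute real-valued inter-residue geometry maps
#'
#' For every residue pair (i, j): the CB-CB distance `d`, the
#' CA_i-CB_i-CB_j-CA_j dihedral `omega` (symmetric), the
#' N_i-CA_i-CB_i-CB_j dihedral `theta` and the CA_i-CB_i-CB_j planar
#' angle `phi` (both asymmetric).  Virtual CBs are built with
#' [virtual_cbeta()] wherever the real CB is absent.  The validity
#' mask is false on the diagonal and wherever a needed backbone atom
#' is missing.
#'
#' @param struct A [new_backbone()] object.
#' @return A list of class `geometry_maps` with elements `d`, `omega`,
#'   `theta`, `phi` (L x L numeric) and `mask` (L x L logical).
#' @export
compute_geometries <- function(struct) {
  L <- length(struct)
  if (L < 2L) stop_protgeom("need at least two residues")
  valid <- stats::complete.cases(struct$n) &
    stats::complete.cases(struct$ca) &
    stats::complete.cases(struct$c)
  cb <- struct$cb
  need_virtual <- !stats::complete.cases(cb) & valid
  if (any(need_virtual)) {
    cb[need_virtual, ] <- virtual_cbeta(
      struct$n[need_virtual, , drop = FALSE],
      struct$ca[need_virtual, , drop = FALSE],
      struct$c[need_virtual, , drop = FALSE]
    )
  }
  ii <- rep(seq_len(L), times = L)
  jj <- rep(seq_len(L), each = L)
  off <- ii != jj & valid[ii] & valid[jj]
  d <- om <- th <- ph <- rep(0, L * L)
  i <- ii[off]; j <- jj[off]
  d[off] <- sqrt(rowSums((cb[i, , drop = FALSE] - cb[j, , drop = FALSE])^2))
  om[off] <- dihedral_angle(struct$ca[i, ], cb[i, ], cb[j, ], struct$ca[j, ])
  th[off] <- dihedral_angle(struct$n[i, ], struct$ca[i, ], cb[i, ], cb[j, ])
  ph[off] <- planar_angle(struct$ca[i, ], cb[i, ], cb[j, ])
  structure(
    list(
      d = matrix(d, L, L), omega = matrix(om, L, L),
      theta = matrix(th, L, L), phi = matrix(ph, L, L),
      mask = matrix(off, L, L), cb = cb
    ),
    class = "geometry_maps"
  )
}

#' Discretise geometry maps into bin labels
#'
#' Pairs with `d >= 20` A or an invalid mask get label 0 (the shared
#' no-contact bin) in all four label maps; otherwise the distance label
#' is `floor((d - 2)/0.5) + 1` clipped to \[1, 36\] and the angular
#' labels fall on their 15-degree grids.
#'
#' @param maps A [compute_geometries()] result.
#' @param spec Bin specification (defaults to [geometry_spec()]).
#' @return A list of class `geometry_labels` with integer L x L label
#'   maps `dist`, `omega`, `theta`, `phi` and the logical `mask` of
#'   pairs that carry geometry (label > 0).
#' @export
bin_geometries <- function(maps, spec = geometry_spec()) {
  contact <- maps$mask & maps$d < spec$dist$no_contact
  lab <- function(x, first, width, top) {
    l <- floor((x - first) / width) + 1
    pmin(top, pmax(1, l))
  }
  dl <- ifelse(contact, lab(maps$d, 2, 0.5, 36), 0)
  ol <- ifelse(contact, lab(maps$omega, -180, 15, 24), 0)
  tl <- ifelse(contact, lab(maps$theta, -180, 15, 24), 0)
  pl <- ifelse(contact, lab(maps$phi, 0, 15, 12), 0)
  structure(
    list(
      dist = matrix(as.integer(dl), nrow(dl)),
      omega = matrix(as.integer(ol), nrow(ol)),
      theta = matrix(as.integer(tl), nrow(tl)),
      phi = matrix(as.integer(pl), nrow(pl)),
      mask = contact
    ),
    class = "geometry_labels"
  )
}

#' Build a smoothed one-hot posterior from label maps
#'
#' Places `1 - smoothing` on the labelled bin and spreads `smoothing`
#' uniformly over the remaining bins of each head.  Label 0 maps to the
#' no-contact bin (array index 1).  Used to turn template geometry into
#' a posterior for oracle checks and template-only predictions.
#'
#' @param labels A [bin_geometries()] result.
#' @param smoothing Probability mass spread off the labelled bin.
#' @return A [new_geometry_posterior()].
#' @export
posterior_from_labels <- function(labels, smoothing = 0.1) {
  L <- nrow(labels$dist)
  mk <- function(lab, nb) {
    a <- array(smoothing / (nb - 1), c(L, L, nb))
    ii <- rep(seq_len(L), L); jj <- rep(seq_len(L), each = L)
    a[cbind(ii, jj, as.vector(lab) + 1L)] <- 1 - smoothing
    a
  }
  new_geometry_posterior(
    mk(labels$dist, 37L), mk(labels$omega, 25L),
    mk(labels$theta, 25L), mk(labels$phi, 13L)
  )
}
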