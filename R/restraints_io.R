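#' Geometry posteriors
#'
#' A `geometry_posterior` holds, for every residue pair (i, j), four
#' categorical distributions over binned inter-residue geometry: the
#' CB-CB distance (37 bins), the CA-CB-CB-CA dihedral omega (25 bins),
#' the N-CA-CB-CB dihedral theta (25 bins) and the CA-CB-CB planar
#' angle phi (13 bins).  Bin 1 of every head is the shared no-contact
#' bin (d >= 20 A or geometry undefined).
#'
#' @param dist,omega,theta,phi Arrays of shape L x L x (37/25/25/13);
#'   each last-axis slice must be a probability distribution.
#' @return An object of class `geometry_posterior`.
#' @export
new_geometry_posterior <- function(dist, omega, theta, phi) {
  p <- list(dist = dist, omega = omega, theta = theta, phi = phi)
  for (h in names(p)) {
    d <- dim(p[[h]])
    if (length(d) != 3L || d[3] != HEAD_BINS[[h]] || d[1] != d[2]) {
      stop_protgeom(sprintf(
        "head '%s' must be an L x L x %d array", h, HEAD_BINS[[h]]
      ))
    }
  }
  structure(p, class = "geometry_posterior")
}

#' @export
print.geometry_posterior <- function(x, ...) {
  cat(sprintf(
    "<geometry_posterior> L = %d, heads d/omega/theta/phi (%s bins)\n",
    dim(x$dist)[1], paste(HEAD_BINS, collapse = "/")
  ))
  invisible(x)
}

check_posterior_normalized <- function(posterior, tol = 1e-4) {
  for (h in names(HEAD_BINS)) {
    a <- posterior[[h]]
    if (anyNA(a) || !all(is.finite(a))) {
      stop_protgeom("posterior head '", h, "' contains non-finite values")
    }
    if (any(a < 0)) {
      stop_protgeom("posterior head '", h, "' has negative entries")
    }
    s <- rowSums(matrix(a, ncol = dim(a)[3]))
    if (any(abs(s - 1) > tol)) {
      stop_protgeom(sprintf(
        "posterior head '%s' is not normalized (max |sum - 1| = %.3g)",
        h, max(abs(s - 1))
      ))
    }
  }
  invisible(TRUE)
}

#' Write and read geometry restraint archives
#'
#' The archive is a compressed named-array container with the four keys
#' `dist`, `omega`, `theta` and `phi` (the restraint convention used by
#' trRosetta-style structure servers).  Round-trips are bit-exact.
#' Writing an unnormalised posterior (any pixel sum off by more than
#' 1e-4) is an error.
#'
#' @param posterior A [new_geometry_posterior()].
#' @param path Archive path.
#' @return `write_restraints()`: `path`, invisibly.
#'   `read_restraints()`: the `geometry_posterior`.
#' @export
write_restraints <- function(posterior, path) {
  check_posterior_normalized(posterior)
  saveRDS(
    list(dist = posterior$dist, omega = posterior$omega,
         theta = posterior$theta, phi = posterior$phi),
    path, compress = "gzip"
  )
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  x <- readRDS(path)
  if (!setequal(names(x), c("dist", "omega", "theta", "phi"))) {
    stop_protgeom("restraint archive must hold keys dist/omega/theta/phi")
  }
  new_geometry_posterior(x$dist, x$omega, x$theta, x$phi)
}
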