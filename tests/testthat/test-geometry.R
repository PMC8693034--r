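# Build an atom at distance/angle/torsion from three reference points
# (standard internal-coordinate construction, used as an independent
# ideal-geometry oracle).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
         bond * sin(tor) * sin(ang))
  c + d[1] * bc + d[2] * m + d[3] * n
}

random_rigid <- function() {
  q <- matrix(rnorm(9), 3)
  r <- qr.Q(qr(q))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  list(rot = r, shift = rnorm(3, sd = 5))
}

test_that("virtual CB lands near the real CB of an ideal residue", {
  # ideal alanine-like residue from standard bond lengths/angles
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  c_at <- place_atom(c(0, 1, 0), n, ca, 1.525, 111.0, 120)
  cb_real <- place_atom(c_at, n, ca, 1.53, 110.5, -122.6)
  cb_virt <- virtual_cbeta(n, ca, c_at)
  expect_lt(sqrt(sum((cb_virt - cb_real)^2)), 0.3)
})

test_that("virtual CB is equivariant under rigid motion and rejects collinear input", {
  set.seed(12)
  n <- rnorm(3); ca <- rnorm(3) + 1.4; c_at <- rnorm(3) - 1
  base <- virtual_cbeta(n, ca, c_at)
  tr <- random_rigid()
  moved <- virtual_cbeta(
    drop(tr$rot %*% n) + tr$shift, drop(tr$rot %*% ca) + tr$shift,
    drop(tr$rot %*% c_at) + tr$shift
  )
  expect_equal(as.vector(moved), as.vector(tr$rot %*% base + tr$shift),
               tolerance = 1e-9)
  expect_error(virtual_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("dihedrals and angles match an independent vector-algebra oracle", {
  # planar cis arrangement -> 0; trans -> +/-180
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                              c(1, 1, 0)), 0)
  expect_equal(abs(oracle_dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                   c(-1, 1, 0))), 180)
  expect_equal(abs(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                                  c(-1, 1, 0))), 180)

  set.seed(77)
  for (i in 1:100) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    got <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    want <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(planar_angle(p[1, ], p[2, ], p[3, ]),
                 oracle_planar(p[1, ], p[2, ], p[3, ]),
                 tolerance = 1e-9)
  }
})

test_that("geometry maps are symmetric where they must be", {
  for (seed in c(1, 2, 3)) {
    bb <- gen_backbone(12, seed = seed)
    gm <- compute_geometries(bb)
    expect_equal(gm$d, t(gm$d), tolerance = 1e-9)
    expect_equal(gm$omega, t(gm$omega), tolerance = 1e-6)
    expect_true(all(diag(gm$d) == 0))
    expect_false(any(diag(gm$mask)))
  }
  expect_error(
    compute_geometries(new_backbone(
      1L, "A", matrix(0, 1, 3), matrix(1, 1, 3),
      matrix(2, 1, 3), matrix(NA_real_, 1, 3)
    )),
    "two residues"
  )
})

test_that("binning respects the stated edges and the shared no-contact bin", {
  mk_maps <- function(d) {
    m2 <- matrix(c(0, d, d, 0), 2)
    list(d = m2, omega = m2 * 0, theta = m2 * 0, phi = m2 * 0,
         mask = matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
  }
  lab <- bin_geometries(mk_maps(25))
  expect_equal(lab$dist[1, 2], 0L)
  expect_equal(lab$omega[1, 2], 0L)
  expect_equal(lab$theta[1, 2], 0L)
  expect_equal(lab$phi[1, 2], 0L)

  expect_equal(bin_geometries(mk_maps(2.0))$dist[1, 2], 1L)
  expect_equal(bin_geometries(mk_maps(7.99))$dist[1, 2], 12L)
  expect_equal(bin_geometries(mk_maps(19.99))$dist[1, 2], 36L)

  # angular edges: -180 inclusive at bin 1; phi 180 in top bin
  maps <- mk_maps(5)
  maps$omega[1, 2] <- -180; maps$omega[2, 1] <- 179.9
  maps$phi[1, 2] <- 180
  lab <- bin_geometries(maps)
  expect_equal(lab$omega[1, 2], 1L)
  expect_equal(lab$omega[2, 1], 24L)
  expect_equal(lab$phi[1, 2], 12L)
})

test_that("binned geometry is invariant under rigid transforms", {
  bb <- toy_backbone(16)
  lab1 <- bin_geometries(compute_geometries(bb))
  set.seed(5)
  tr <- random_rigid()
  mv <- function(m) t(tr$rot %*% t(m) + tr$shift)
  bb2 <- new_backbone(bb$residue_index, bb$aa, mv(bb$n), mv(bb$ca),
                      mv(bb$c), mv(bb$cb))
  lab2 <- bin_geometries(compute_geometries(bb2))
  expect_identical(lab1$dist, lab2$dist)
  expect_identical(lab1$omega, lab2$omega)
  expect_identical(lab1$theta, lab2$theta)
  expect_identical(lab1$phi, lab2$phi)
})
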