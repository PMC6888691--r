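test_that("procedural B-DNA helix has the canonical geometry", {
  d1 <- build_bdna(1)
  expect_equal(nrow(d1$sites), 2)
  expect_equal(d1$sites$z, c(0, 0))
  sep <- sqrt(diff(d1$sites$x)^2 + diff(d1$sites$y)^2)
  expect_equal(sep, 2 * 0.94)  # antipodal strands: 2 r sin(90 deg)

  d11 <- build_bdna(11, twist = 36)
  s0 <- d11$sites[d11$sites$strand == 0, ]
  expect_equal(s0$x[11], s0$x[1], tolerance = 1e-12)
  expect_equal(s0$y[11], s0$y[1], tolerance = 1e-12)
  expect_equal(s0$z[11], 10 * 0.34)

  for (n in c(2, 7, 50)) expect_equal(nrow(build_bdna(n)$sites), 2 * n)
  expect_error(build_bdna(0), ">= 1")
})

test_that("successive same-strand site distances are constant (helix symmetry)", {
  d <- build_bdna(50, strand_offset = -35)
  for (s in 0:1) {
    sites <- d$sites[d$sites$strand == s, ]
    sites <- sites[order(sites$bp_index), ]
    step <- sqrt(diff(sites$x)^2 + diff(sites$y)^2 + diff(sites$z)^2)
    expect_lt(max(step) - min(step), 1e-12)
  }
})

test_that("rigid-body transforms move all site centres equivariantly", {
  d <- build_bdna(20)
  set.seed(1)
  qr_dec <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- c(5, -3, 12)
  d2 <- transform_duplex(d, R, tr)
  xyz <- as.matrix(d$sites[, c("x", "y", "z")])
  expected <- sweep(xyz %*% t(R), 2, tr, `+`)
  expect_equal(as.matrix(d2$sites[, c("x", "y", "z")]), expected,
               ignore_attr = TRUE)
  # pairwise distances are invariant
  expect_equal(as.numeric(dist(expected)), as.numeric(dist(xyz)))
})

test_that("PDB loading collapses residues to backbone centroids", {
  f <- system.file("extdata", "duplex_fixture_synthetic.pdb",
                   package = "npdamage")
  d <- load_pdb(f)
  expect_equal(nrow(d$sites), 4)
  expect_equal(d$n_bp, 2L)
  # hand-computed backbone-atom centroids (Angstrom -> nm); the base atom
  # N9 of chain A residue 1 must not enter the centroid
  a <- d$sites[d$sites$strand == 0, ]
  b <- d$sites[d$sites$strand == 1, ]
  expect_equal(unlist(a[1, c("x", "y", "z")]), c(x = 0.1, y = 0.94, z = 0.1))
  expect_equal(unlist(a[2, c("x", "y", "z")]),
               c(x = 0.6027, y = 0.7606, z = 0.39))
  expect_equal(unlist(b[1, c("x", "y", "z")]),
               c(x = -0.05, y = -0.94, z = 0.05))
  expect_equal(unlist(b[2, c("x", "y", "z")]),
               c(x = -0.6527, y = -0.7606, z = 0.44))
})

test_that("PDB files without two usable chains are rejected", {
  one_chain <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P    DA A   1       0.000   1.000   2.000  1.00  0.00           P",
    "ATOM      2  O5'  DA A   2       1.000   1.000   2.000  1.00  0.00           O",
    "END"), one_chain)
  expect_error(load_pdb(one_chain), "1 chain")

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(load_pdb(empty))
})
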