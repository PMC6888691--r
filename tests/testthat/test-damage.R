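test_that("deposits accumulate onto the nearest site within its capture radius", {
  d <- build_bdna(5)
  s1 <- d$sites[1, ]
  ps <- make_phase_space(s1$x, s1$y, s1$z, 10)
  e <- accumulate(ps, d)
  expect_equal(e[1], 10)
  expect_equal(sum(e), 10)

  # two deposits inside the same capture radius add up
  ps2 <- make_phase_space(c(s1$x, s1$x + 0.1), c(s1$y, s1$y), c(s1$z, s1$z),
                          c(5, 5))
  expect_equal(accumulate(ps2, d)[1], 10)

  # a deposit beyond every capture radius is discarded
  ps3 <- make_phase_space(s1$x + 50, s1$y, s1$z, 100)
  expect_equal(sum(accumulate(ps3, d)), 0)
})

test_that("SSB calling is strict in the energy threshold and monotone in it", {
  d <- build_bdna(3)
  e <- c(8.22, 8.23, 5, 0, 0, 0)
  cfg <- damage_config()
  ssbs <- call_ssb(e, d, cfg)
  expect_equal(nrow(ssbs), 1)  # exactly 8.22 eV is NOT a break
  expect_equal(ssbs$bp_index, d$sites$bp_index[2])
  expect_equal(nrow(call_ssb(numeric(6), d, cfg)), 0)

  ph <- build_phantom(1, 0.01, 3, 2, "Au", seed = 3)
  dup <- build_bdna(100, capture_radius = 2)
  ps <- sample_events(ph, 5000, track_config(), seed = 9)
  se <- accumulate(ps, dup)
  counts <- sapply(c(5, 8.22, 15), function(th)
    nrow(call_ssb(se, dup, damage_config(ssb_energy_threshold = th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("DSB sweep clustering applies the opposite-strand 10 bp rule", {
  cfg <- damage_config()
  mk <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(strand = m[, 1], bp_index = m[, 2])
  }
  expect_equal(call_dsb(mk(0, 5, 1, 12), cfg)$n_dsb, 1)   # gap 7 <= 10
  expect_equal(call_dsb(mk(0, 5, 0, 12), cfg)$n_dsb, 0)   # same strand
  expect_equal(call_dsb(mk(0, 0, 1, 11), cfg)$n_dsb, 0)   # gap 11 > 10
  expect_equal(call_dsb(mk(0, 0, 1, 10), cfg)$n_dsb, 1)   # gap 10 inclusive
  expect_equal(call_dsb(mk(0, 4, 1, 4), cfg)$n_dsb, 1)    # same bp, gap 0
  # one chain-linked cluster is a single DSB however many SSBs it holds
  expect_equal(call_dsb(mk(0, 0, 1, 8, 0, 16, 1, 24), cfg)$n_dsb, 1)
  expect_equal(call_dsb(data.frame(strand = integer(0), bp_index = integer(0)),
                        cfg)$n_dsb, 0)
})

test_that("sweep clustering matches the brute-force component oracle", {
  skip_if_not_installed("igraph")
  cfg <- damage_config()
  set.seed(20)
  for (i in 1:1000) {
    n <- sample(0:12, 1)
    ssbs <- random_ssbs(n, n_bp = sample(5:30, 1))
    ssbs <- unique(ssbs)
    expect_equal(call_dsb(ssbs, cfg)$n_dsb,
                 oracle_dsb_count(ssbs, cfg$dsb_bp_threshold))
  }
})

test_that("DSB counts are bounded by SSB structure", {
  cfg <- damage_config()
  set.seed(33)
  for (i in 1:200) {
    ssbs <- unique(random_ssbs(sample(1:12, 1), 30))
    res <- call_dsb(ssbs, cfg)
    expect_lte(res$n_dsb, length(res$clusters))
    expect_lte(res$n_dsb, max(0, nrow(ssbs) - 1))
    expect_equal(sum(vapply(res$clusters, nrow, integer(1))), nrow(ssbs))
    # every DSB cluster holds >= 2 SSBs on both strands
    for (cl in res$dsb_clusters) {
      expect_gte(nrow(cl), 2)
      expect_equal(sort(unique(cl$strand)), c(0, 1))
    }
  }
})

test_that("rates and amplification factors follow their defining formulas", {
  expect_equal(dsb_rate(1, 1, 1e9), 1)
  expect_equal(dsb_rate(0, 10, 1e6), 0)
  expect_equal(dsb_rate(5, 2, 1e9), dsb_rate(5, 1, 1e9) / 2)
  expect_error(dsb_rate(1, 0, 1e9), "positive")
  expect_error(dsb_rate(1, 1, 0), "positive")

  expect_equal(amplification_factor(13.10, 9.32), 100 * 3.78 / 9.32)
  expect_equal(amplification_factor(13.53, 9.32), 45.17, tolerance = 1e-3)
  expect_equal(amplification_factor(7, 7), 0)
  expect_error(amplification_factor(1, 0), "positive")
})

test_that("sub-threshold phase spaces yield no damage", {
  dup <- build_bdna(50, capture_radius = 2)
  xyz <- dup$sites[, c("x", "y", "z")]
  ps <- make_phase_space(xyz$x, xyz$y, xyz$z, rep(8.0, nrow(xyz)))
  rec <- score_damage(ps, dup, damage_config(), dose = 1)
  expect_equal(rec$n_ssb, 0)
  expect_equal(rec$n_dsb, 0)
  expect_equal(rec$rate, 0)
})
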