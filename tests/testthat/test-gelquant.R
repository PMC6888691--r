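test_that("lane normalization applies the staining correction and Poisson inversion", {
  n1 <- normalize_lane(data.frame(S = 0.95, R = 0.05, L = 0))
  expect_equal(n1$total, 1.47 * 0.95 + 0.05)
  expect_equal(n1$l_prime, 0)
  expect_equal(n1$dsb_per_plasmid, 0)

  n2 <- normalize_lane(data.frame(S = 0, R = 0.5, L = 0.5))
  expect_equal(n2$l_prime, 0.5)
  expect_equal(n2$dsb_per_plasmid, 1)

  n3 <- normalize_lane(data.frame(S = 1, R = 0, L = 0.47))
  expect_equal(n3$total, 1.94)
  lp <- 0.47 / 1.94
  expect_equal(n3$l_prime, lp)
  expect_equal(n3$dsb_per_plasmid, lp / (1 - lp))

  expect_error(normalize_lane(data.frame(S = 0, R = 0, L = 1)), "all-linear")
  expect_error(normalize_lane(data.frame(S = 0, R = 0, L = 0)), "all-zero")
  expect_error(normalize_lane(data.frame(S = -1, R = 1, L = 0)), "non-negative")
})

test_that("dose-response fit recovers an exact generating line", {
  lanes <- noiseless_lanes(table2_slopes[["control"]])
  dr <- fit_dose_response(lanes)
  expect_equal(dr$slope, 17.47e-5, tolerance = 1e-10)
  expect_lt(dr$slope_se, 1e-12)
  expect_equal(dr$intercept, 0, tolerance = 1e-12)

  flat <- synth_gel(gel_doses, 0, m_ssb_true = 1e-4, noise_sd = 0, seed = 1)
  expect_equal(fit_dose_response(flat)$slope, 0, tolerance = 1e-15)
  expect_true(all(flat$L == 0))

  expect_error(fit_dose_response(lanes[lanes$dose < 150, ]), "3 distinct doses")
})

test_that("gel forward model inverts exactly without noise", {
  # round trip across the yield range, relative 1e-10
  set.seed(7)
  for (i in 1:20) {
    m <- runif(1, 1e-6, 5e-4)
    dr <- fit_dose_response(synth_gel(gel_doses, m, noise_sd = 0, seed = i))
    expect_equal(dr$slope, m, tolerance = 1e-10)
  }
  # Poisson inversion is the exact inverse of the forward l-map
  l <- seq(0, 0.99, by = 0.01)
  mu <- l / (1 - l)
  expect_equal(mu / (1 + mu), l, tolerance = 1e-12)

  # noiseless single-dose check: l = 0.05/1.05 at m = 1e-4, D = 500
  lane <- synth_gel(500, 1e-4, m_ssb_true = 0, noise_sd = 0, replicates = 1,
                    seed = 1)
  expect_equal(lane$L, 0.05 / 1.05)
  expect_equal(normalize_lane(lane)$dsb_per_plasmid, 0.05, tolerance = 1e-12)
})

test_that("the staining factor cancels when generation and analysis agree", {
  m <- 2.3e-4
  slopes <- sapply(c(1.0, 1.47, 2.0), function(sf)
    fit_dose_response(synth_gel(gel_doses, m, noise_sd = 0, seed = 1,
                                staining_factor = sf),
                      staining_factor = sf)$slope)
  expect_equal(slopes, rep(m, 3), tolerance = 1e-10)
})

test_that("amplification and scavenger decomposition are recovered from noiseless arms", {
  drs <- lapply(table2_slopes, function(m) fit_dose_response(noiseless_lanes(m)))
  af_au <- amplification(drs$au, drs$control)
  af_aupt <- amplification(drs$aupt, drs$control)
  af_au_dmso <- amplification(drs$au_dmso, drs$control_dmso)
  expect_equal(af_au$af, 100 * (23.49 - 17.47) / 17.47, tolerance = 1e-6)
  expect_equal(af_aupt$af, 89.9256, tolerance = 1e-4)
  expect_equal(af_au_dmso$af, 22.3368, tolerance = 1e-4)

  oh_c <- oh_effect(drs$control, drs$control_dmso)
  expect_equal(oh_c$effect, 100 * (17.47 - 2.91) / 17.47, tolerance = 1e-6)
  expect_equal(oh_effect(drs$control, drs$control)$effect, 0)

  # AF and OH effect are invariant under a common rescaling of all yields
  drs2 <- lapply(table2_slopes * 3.7, function(m)
    fit_dose_response(noiseless_lanes(m)))
  expect_equal(amplification(drs2$au, drs2$control)$af, af_au$af,
               tolerance = 1e-8)
  expect_equal(oh_effect(drs2$control, drs2$control_dmso)$effect, oh_c$effect,
               tolerance = 1e-8)
})

test_that("noisy synthetic gels give slope estimates consistent with the truth", {
  m <- table2_slopes[["control"]]
  hits <- 0
  for (s in 1:50) {
    dr <- fit_dose_response(synth_gel(gel_doses, m, noise_sd = 0.01,
                                      replicates = 3, seed = s))
    if (abs(dr$slope - m) <= 3 * dr$slope_se) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("gel lane CSV round-trips", {
  lanes <- synth_gel(gel_doses, 2e-4, noise_sd = 0.01, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_gel_lanes(lanes, f)
  back <- read_gel_lanes(f)
  expect_equal(back$dose, lanes$dose)
  expect_equal(back$S, lanes$S, tolerance = 1e-12)
  writeLines("a,b\n1,2", f)
  expect_error(read_gel_lanes(f), "columns")
})
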