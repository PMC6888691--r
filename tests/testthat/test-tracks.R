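test_that("realized water dose matches the prescription and conserves energy", {
  ph0 <- build_phantom(0, 50, seed = 0)
  ps <- sample_events(ph0, 1, track_config(), seed = 3)
  rd <- dose_in_region(ps, ph0, "water_sphere")
  expect_equal(rd$dose, 1, tolerance = 0.01)
  # with every deposit in water, dose x mass equals total energy in joules
  expect_equal(rd$dose * rd$mass,
               sum(ps$deposits$energy) * 1.602176634e-19,
               tolerance = 1e-9)
  expect_error(sample_events(ph0, -1, track_config()), "positive")
})

test_that("identical seed and config give an identical phase space", {
  ph <- build_phantom(3, 0.05, 3, 2, "Pt", seed = 5)
  cfg <- track_config()
  ps1 <- sample_events(ph, 100, cfg, seed = 11)
  ps2 <- sample_events(ph, 100, cfg, seed = 11)
  expect_identical(ps1$deposits, ps2$deposits)
  expect_identical(ps1$config_digest, ps2$config_digest)
  ps3 <- sample_events(ph, 100, cfg, seed = 12)
  expect_false(identical(ps1$deposits, ps3$deposits))
})

test_that("phase-space text round trip is lossless and malformed files are rejected", {
  ph <- build_phantom(2, 0.05, 3, 2, "Au", seed = 2)
  ps <- sample_events(ph, 50, track_config(), seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phase_space(ps, f)
  ps2 <- read_phase_space(f)
  expect_equal(ps2$deposits, ps$deposits)
  expect_equal(ps2$seed, ps$seed)
  expect_equal(ps2$config_digest, ps$config_digest)
  expect_equal(ps2$target_dose, ps$target_dose)

  # empty body with a valid header is an empty phase space
  writeLines(c("# seed: 7", "# config_digest: abc", "# target_dose_Gy: 2"), f)
  expect_equal(nrow(read_phase_space(f)$deposits), 0)

  writeLines(c("# seed: 7", "# config_digest: abc", "# target_dose_Gy: 2",
               "0\t0\t0\t-5\tionization\t1"), f)
  expect_error(read_phase_space(f), "line 4")
  writeLines(c("# config_digest: abc", "# target_dose_Gy: 2"), f)
  expect_error(read_phase_space(f), "seed")
})

test_that("process label frequencies follow the configured weights", {
  w <- c(elastic = 2.3e5, electronic_excitation = 2.4e4,
         vibrational_excitation = 1.61e5, ionization = 5.37e4,
         attachment = 467)
  cfg <- track_config(process_frequencies = w,
                      background_event_density = 1e5)
  ph0 <- build_phantom(0, 1, seed = 0)
  ps <- sample_events(ph0, 1, cfg, seed = 8)
  expect_equal(nrow(ps$deposits), 1e5, tolerance = 0.01)
  cens <- process_census(ps)
  expect_equal(sum(cens), nrow(ps$deposits))
  freq <- cens / sum(cens)
  expect_true(all(abs(freq - w / sum(w)) < 0.02))
  chi <- suppressWarnings(stats::chisq.test(cens, p = w / sum(w)))
  expect_gt(chi$p.value, 0.001)
})

test_that("near-particle event density rises monotonically with the enhancement factor", {
  ph <- build_phantom(1, 0.01, 3, 2, "Pt", seed = 6)
  p1 <- ph$particles[1, ]
  annulus_count <- function(ps, r_in = 3.5, r_out = 23.5) {
    d2 <- (ps$deposits$x - p1$cx)^2 + (ps$deposits$y - p1$cy)^2 +
      (ps$deposits$z - p1$cz)^2
    sum(d2 > r_in^2 & d2 <= r_out^2)
  }
  counts <- sapply(c(0, 1, 5), function(f) {
    cfg <- track_config(enhancement_factor = c(Au = f, Pt = f),
                        enhancement_radius = 20)
    mean(sapply(1:3, function(s)
      annulus_count(sample_events(ph, 200, cfg, seed = s))))
  })
  expect_true(counts[1] < counts[2] && counts[2] < counts[3])

  # with zero enhancement the annulus density equals the background density
  cfg0 <- track_config(enhancement_factor = c(Au = 0, Pt = 0),
                       enhancement_radius = 20)
  ps0 <- sample_events(ph, 200, cfg0, seed = 1)
  v_ann <- 4 / 3 * pi * (23.5^3 - 3.5^3)
  v_sph <- 4 / 3 * pi * ph$sphere_radius_nm^3
  expected <- nrow(ps0$deposits) * v_ann / v_sph
  expect_lt(abs(annulus_count(ps0) - expected), 4 * sqrt(expected) + 1)
})

test_that("region dose accounting assigns deposits geometrically and conserves energy", {
  ph <- build_phantom(3, 0.05, 3, 2, "Pt", seed = 5)
  p1 <- ph$particles[1, ]
  ps <- make_phase_space(
    x = c(p1$cx, p1$cx + 2.5, p1$cx + 100),
    y = c(p1$cy, p1$cy, p1$cy),
    z = c(p1$cz, p1$cz, p1$cz),
    energy = c(10, 20, 30)
  )
  core <- dose_in_region(ps, ph, "cores")
  shell <- dose_in_region(ps, ph, "shells")
  water <- dose_in_region(ps, ph, "water_sphere")
  expect_equal(core$deposited_energy, 10)
  expect_equal(shell$deposited_energy, 20)
  expect_equal(water$deposited_energy, 30)
  expect_equal(water$dose, 30 * 1.602176634e-19 / water$mass)
  expect_equal(core$dose * core$mass + shell$dose * shell$mass +
                 water$dose * water$mass,
               60 * 1.602176634e-19, tolerance = 1e-12)

  empty <- make_phase_space(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(dose_in_region(empty, ph, "water_sphere")$dose, 0)
  expect_error(dose_in_region(ps, ph, "cytoplasm"))

  cens <- process_census(make_phase_space(1:5, 1:5, 1:5, rep(1, 5),
    process = c("ionization", "ionization", "ionization", "elastic", "elastic")))
  expect_equal(unname(cens[c("ionization", "elastic", "attachment")]),
               c(3L, 2L, 0L))
})
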