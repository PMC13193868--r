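test_that("cohort sampling enforces the exact early/late split", {
  for (sd in c(42L, 7L)) {
    co <- sample_cohort(simulator_config(seed = sd))
    expect_equal(nrow(co), 39)
    expect_equal(sum(co$tto_hours < 4.5), 12)
    expect_equal(sum(co$group == "late"), 27)
    expect_true(all(co$tto_hours > 0 & co$tto_hours <= 48))
  }
  expect_equal(nrow(sample_cohort(simulator_config(n_patients = 0))), 0)
})

test_that("incompatible rebalancing targets are rejected", {
  expect_error(sample_cohort(simulator_config(tto_max = 4, seed = 1L)),
               "incompatible")
  expect_error(sample_cohort(simulator_config(tto_min = 5, tto_max = 48,
                                              frac_late = 0.5, seed = 1L)),
               "incompatible")
})

test_that("unrebalanced TTO matches the closed-form truncated log-normal mean", {
  cfg <- simulator_config(n_patients = 5000, frac_late = NULL, seed = 23L)
  co <- sample_cohort(cfg)
  # independent closed form: E[T | lo < T < hi] for T ~ lognormal(mu, sigma)
  mu <- cfg$tto_meanlog; s <- cfg$tto_sdlog
  a <- (log(cfg$tto_min) - mu) / s
  b <- (log(cfg$tto_max) - mu) / s
  m_closed <- exp(mu + s^2 / 2) * (pnorm(b - s) - pnorm(a - s)) /
    (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(co$tto_hours) - m_closed), 1.0)
})

test_that("cohort draws are reproducible and per-patient deterministic", {
  cfg <- simulator_config(seed = 5L)
  co1 <- sample_cohort(cfg)
  co2 <- sample_cohort(cfg)
  expect_identical(co1, co2)
  tr1 <- simulate_truth(co1[4, ], cfg)
  tr2 <- simulate_truth(co1[4, ], cfg)
  expect_identical(tr1, tr2)
  expect_false(identical(sample_cohort(simulator_config(seed = 6L))$tto_hours,
                         co1$tto_hours))
})

test_that("latent model limits: no change at t -> 0+, saturation at t -> Inf", {
  cfg <- simulator_config(seed = 2L)
  rec <- list(patient_id = "P001", tto_hours = 1e-9, laterality = "OD")
  tr0 <- simulate_truth(rec, cfg)
  expect_equal(tr0$h, 1, tolerance = 1e-8)
  expect_equal(unname(tr0$g), rep(1, 5), tolerance = 1e-8)
  # rho_crao collapses to rho0 * compartment offsets, i.e. ~ rho_fellow
  expect_lt(abs(median(tr0$rho_crao) - tr0$rho0), 0.3 * tr0$rho0)
  rec$tto_hours <- 1e6
  trI <- simulate_truth(rec, cfg)
  expect_equal(trI$h, 1 + cfg$A_irl, tolerance = 1e-12)   # 1.35 exactly
})

test_that("latent trajectories satisfy the mechanistic invariants", {
  cfg <- simulator_config(seed = 8L)
  ts <- c(2, 6, 12, 24, 48)
  for (pid in c("P001", "P017")) {
    trs <- lapply(ts, function(t) {
      simulate_truth(list(patient_id = pid, tto_hours = t, laterality = "OD"), cfg)
    })
    h <- vapply(trs, `[[`, 0, "h")
    expect_true(all(h >= 1) && all(diff(h) >= 0))
    g <- t(vapply(trs, `[[`, numeric(5), "g"))
    expect_true(all(g > 0 & g <= 1))
    expect_true(all(diff(g) <= 1e-12))
    rho <- t(vapply(trs, `[[`, numeric(5), "rho_crao"))
    expect_true(all(diff(rho) >= -1e-12))        # non-decreasing in t
    orl <- t(vapply(trs, `[[`, numeric(5), "orl_ratio"))
    expect_true(all(diff(orl) <= 1e-12))         # non-increasing in t
    tc <- t(vapply(trs, function(x) unname(x$t_crao_um), numeric(9)))
    tf <- t(vapply(trs, function(x) unname(x$t_fellow_um), numeric(9)))
    expect_true(all(tc >= tf))
    expect_equal(length(unique(tf[, 1])), 1)     # fellow independent of t
    rf <- t(vapply(trs, `[[`, numeric(5), "rho_fellow"))
    expect_equal(unname(apply(rf, 2, sd)), rep(0, 5), tolerance = 1e-14)
  }
})

test_that("pixel-extracted rho is monotone in time for a fixed patient", {
  cfg <- simulator_config(seed = 3L)
  rho <- t(vapply(c(2, 6, 12, 24, 48), function(t) {
    tr <- simulate_truth(list(patient_id = "P005", tto_hours = t,
                              laterality = "OD"), cfg)
    vol <- render_volume_pair(tr, light_geometry(), cfg)$crao
    refl <- volume_reflectivity(vol)
    setNames(refl$rho, refl$location)
  }, numeric(5)))
  expect_true(all(diff(rho) > -0.01))
})

test_that("IRL hyperreflectivity plateaus early (6 h vs 24 h within 5%)", {
  cfg <- simulator_config(seed = 12L)
  r6 <- simulate_truth(list(patient_id = "P003", tto_hours = 6,
                            laterality = "OD"), cfg)$irl_ratio
  r24 <- simulate_truth(list(patient_id = "P003", tto_hours = 24,
                             laterality = "OD"), cfg)$irl_ratio
  expect_true(all(abs(r24 / r6 - 1) < 0.05))
})

test_that("fellow-eye ratio carries no time information", {
  cfg <- simulator_config(n_patients = 200, frac_late = NULL, seed = 31L)
  co <- sample_cohort(cfg)
  rho_f <- vapply(seq_len(200), function(i) {
    simulate_truth(co[i, ], cfg)$rho_fellow[["c"]]
  }, numeric(1))
  expect_lt(tto_trend(rho_f, co$tto_hours)$r2, 0.05)
})

test_that("the foveal sector swells least in every patient", {
  cfg <- simulator_config(seed = 4L)
  co <- sample_cohort(cfg)
  for (i in seq_len(nrow(co))) {
    tr <- simulate_truth(co[i, ], cfg)
    expect_true(tr$rrti[["S1"]] < tr$rrti[["S8"]])
    expect_equal(unname(which.min(tr$rrti)), 1)
  }
})

test_that("noise-free rendering round-trips the configured band intensities", {
  cfg <- simulator_config(seed = 17L)
  co <- sample_cohort(cfg)
  tr <- simulate_truth(co[2, ], cfg)
  pair <- render_volume_pair(tr, light_geometry(), cfg, speckle_sd = 0)
  for (eye in c("crao", "fellow")) {
    vol <- pair[[eye]]
    refl <- volume_reflectivity(vol)
    i_irl <- if (eye == "crao") tr$i_irl_crao else tr$i_irl_fel
    i_orl <- if (eye == "crao") tr$i_orl_crao else tr$i_orl_fel
    expect_true(all(abs(refl$r_irl - i_irl[refl$location]) <= 0.5))
    expect_true(all(abs(refl$r_orl - i_orl[refl$location]) <= 0.5))
  }
})

test_that("at t -> 0+ the rendered eye pair is statistically identical", {
  cfg <- simulator_config(seed = 19L)
  per_patient <- vapply(sprintf("P%03d", 1:8), function(pid) {
    tr <- simulate_truth(list(patient_id = pid, tto_hours = 1e-6,
                              laterality = "OD"), cfg)
    pair <- render_volume_pair(tr, light_geometry(), cfg)
    mean(volume_reflectivity(pair$crao)$rho -
           volume_reflectivity(pair$fellow)$rho)
  }, numeric(1))
  expect_gt(t.test(per_patient)$p.value, 0.005)
})

test_that("extracted ratios track latent truth under default speckle", {
  cfg <- simulator_config(seed = 21L)
  tr <- simulate_truth(list(patient_id = "P009", tto_hours = 24,
                            laterality = "OS"), cfg)
  vol <- render_volume_pair(tr, render_geometry(), cfg)$crao
  refl <- volume_reflectivity(vol)
  expect_true(all(abs(refl$rho / tr$rho_crao[refl$location] - 1) < 0.10))
})

test_that("a raster too small for the simulated retina is refused", {
  cfg <- simulator_config(seed = 1L)
  tr <- simulate_truth(list(patient_id = "P001", tto_hours = 24,
                            laterality = "OD"), cfg)
  g <- render_geometry(n_rows = 64)
  expect_error(render_volume_pair(tr, g, cfg), "raster too small")
})

test_that("configuration invariants are enforced", {
  expect_error(simulator_config(A_irl = -1))
  expect_error(simulator_config(tau_edema = 0))
  expect_error(simulator_config(tto_min = 0))
  amp <- c(S1 = 0.5, S2 = 0.3, S3 = 0.3, S4 = 0.3, S5 = 0.3, S6 = 0.3,
           S7 = 0.3, S8 = 0.3, S9 = 0.3)
  expect_error(simulator_config(sector_amplitude = amp), "foveal")
})
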