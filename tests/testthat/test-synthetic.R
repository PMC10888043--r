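test_that("phantom pairs are deterministic with an exact hotspot peak", {
  p <- phantom_params(noise_sd = 0)
  a <- simulate_phantom_pair(p, latent_risk = 0, seed = 11)
  b <- simulate_phantom_pair(p, latent_risk = 0, seed = 11)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$pet$voxels, b$pet$voxels)
  # sigmoid(0) = 0.5 so the clean hotspot peak is exactly gain * 0.5
  expect_equal(max(a$pet$voxels), p$pet_hotspot_gain * 0.5)
  # higher latent risk -> strictly hotter tumor on PET (direct pixel average)
  lo <- simulate_phantom_pair(p, -3, seed = 4)
  hi <- simulate_phantom_pair(p, +3, seed = 4)
  expect_gt(mean(hi$pet$voxels[hi$mask$voxels == 1]),
            mean(lo$pet$voxels[lo$mask$voxels == 1]))
  # larger latent risk -> larger tumor
  expect_gt(sum(hi$mask$voxels), sum(lo$mask$voxels))
  expect_error(phantom_params(tumor_radius_range = c(4, 40)), "exceeds")
})

test_that("clinical simulator reproduces the cohort margins", {
  recs <- lapply(1:4000, function(i) simulate_clinical(0, seed = i))
  ages <- vapply(recs, `[[`, 0, "age")
  expect_true(all(ages >= 18 & ages <= 90))
  male <- mean(vapply(recs, `[[`, "", "sex") == "male")
  expect_lt(abs(male - 0.79), 0.02)
  # strongly positive latent risk saturates the stage distribution at IV
  high <- vapply(1:200, function(i)
    simulate_clinical(30, seed = i)$overall_stage, "")
  expect_true(all(high == "IV"))
  # internal consistency of the monotone stage map
  for (r in recs[1:50]) {
    tt <- as.integer(substring(r$t_stage, 2))
    nn <- as.integer(substring(r$n_stage, 2))
    expect_equal(match(r$overall_stage, c("I", "II", "III", "IV")),
                 overall_stage(tt, nn))
  }
  expect_true(all(vapply(recs, `[[`, "", "m_stage") == "M0"))
})

test_that("Weibull sampler matches exponential closed forms", {
  # kappa = 1, rho = 0.01/day, no censoring: mean event time = 100 days
  m <- hazard_model(shape = 1, rate = 0.01, beta = c(x = 0),
                    censor_rate = 1e-12)
  tt <- vapply(1:20000, function(i)
    simulate_survival(m, 0, "OS", seed = i)$time, 0)
  expect_lt(abs(mean(tt) - 100) / 100, 0.02)
  # beta'x = ln 2 halves the mean under the exponential baseline
  tb <- vapply(1:20000, function(i)
    simulate_survival(hazard_model(shape = 1, rate = 0.01, beta = c(x = log(2)),
                                   censor_rate = 1e-12),
                      1, "OS", seed = i)$time, 0)
  expect_lt(abs(mean(tt) / mean(tb) - 2), 0.08)
  expect_error(hazard_model(shape = -1), "positive")
  expect_error(simulate_survival(m, c(1, 2), "OS", 1), "length")
})

test_that("inverse-transform sampler matches S(t) at deciles", {
  m <- hazard_model(shape = 1.3, rate = 1 / 1200, beta = c(x = 0.7),
                    censor_rate = 1e-12)
  x <- 0.4
  tt <- vapply(1:20000, function(i) simulate_survival(m, x, "OS", seed = i)$time, 0)
  S <- function(t) exp(-(m$rate * t)^m$shape * exp(m$beta * x))
  qs <- stats::quantile(tt, seq(0.1, 0.9, 0.1))
  expect_lt(max(abs(S(qs) - seq(0.9, 0.1, -0.1))), 0.01)
})

test_that("no covariate signal gives chance-level concordance", {
  m <- hazard_model(beta = c(latent = 0, age_z = 0, stage_z = 0))
  co <- simulate_cohort(3000, model = m, seed = 5, endpoints = "OS",
                        images = FALSE)
  os <- co$survival
  expect_lt(abs(harrell_c(os$time_days, os$event, co$latent) - 0.5), 0.02)
})

test_that("latent signal drives concordance monotonically", {
  cs <- vapply(c(0.3, 1.1, 3), function(b) {
    co <- simulate_cohort(1500, model = hazard_model(beta = c(latent = b,
                                                              age_z = 0,
                                                              stage_z = 0)),
                          seed = 7, endpoints = "OS", images = FALSE)
    harrell_c(co$survival$time_days, co$survival$event, co$latent)
  }, 0)
  expect_true(all(diff(cs) > 0))
  expect_gt(cs[3], 0.8)
})

test_that("cohorts are pure functions of their seed and hit the event target", {
  co1 <- simulate_cohort(30, seed = 9, images = FALSE)
  co2 <- simulate_cohort(30, seed = 9, images = FALSE)
  expect_identical(co1$survival, co2$survival)
  expect_identical(co1$clinical, co2$clinical)
  big <- simulate_cohort(500, seed = 10, endpoints = "OS", images = FALSE)
  target <- big$model$target_event_fraction
  expect_lt(abs(mean(big$survival$event) - target), 0.05)
})

test_that("write_cohort writes a complete, reproducible cohort", {
  dir1 <- file.path(tempdir(), "coh1")
  unlink(dir1, recursive = TRUE)
  write_cohort(6, phantom_params(image_side = 24L, tumor_radius_range = c(2, 6)),
               hazard_model(), dir1, seed = 3, endpoints = c("OS", "RFS"))
  expect_length(list.files(file.path(dir1, "images"), pattern = "_PET"), 6)
  expect_length(list.files(file.path(dir1, "images"), pattern = "_CT"), 6)
  clin <- utils::read.csv(file.path(dir1, "clinical.csv"))
  expect_equal(nrow(clin), 6)
  expect_equal(names(clin), c("subject_id", "age", "sex", "t_stage", "n_stage",
                              "m_stage", "overall_stage"))
  # regenerating with the same seed gives byte-identical tables
  dir2 <- file.path(tempdir(), "coh2")
  unlink(dir2, recursive = TRUE)
  write_cohort(6, phantom_params(image_side = 24L, tumor_radius_range = c(2, 6)),
               hazard_model(), dir2, seed = 3, endpoints = c("OS", "RFS"))
  expect_identical(readLines(file.path(dir1, "clinical.csv")),
                   readLines(file.path(dir2, "clinical.csv")))
  expect_identical(readLines(file.path(dir1, "survival_OS.csv")),
                   readLines(file.path(dir2, "survival_OS.csv")))
  # manifest collision is refused without overwrite
  expect_error(write_cohort(6, phantom_params(image_side = 24L,
                                              tumor_radius_range = c(2, 6)),
                            hazard_model(), dir1, seed = 3), "overwrite")
  # volumes round-trip bit-for-bit through NIfTI
  back <- read_cohort(dir1)
  co <- simulate_cohort(6, phantom_params(image_side = 24L,
                                          tumor_radius_range = c(2, 6)),
                        hazard_model(), seed = 3, endpoints = c("OS", "RFS"))
  expect_equal(back$images[["S0001"]]$pet$voxels, co$images[["S0001"]]$pet$voxels)
})
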