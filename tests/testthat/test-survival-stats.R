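test_that("risk sets follow the at-risk definition with Breslow ties", {
  time <- c(5, 3, 8)
  event <- c(1, 1, 0)
  expect_setequal(risk_set(time, event, 1), c(1, 3))
  expect_setequal(risk_set(time, event, 2), 1:3)  # earliest event: everyone
  expect_error(risk_set(time, event, 3), "censored")
  # all times tied: full risk set for every event
  expect_setequal(risk_set(c(2, 2, 2), c(1, 1, 1), 2), 1:3)
})

test_that("sigmoid partial likelihood matches hand evaluation", {
  # two subjects, T = (1, 2), both events, all scores 0 (sigma = 0.5):
  # event 1 contributes ln(0.5/1.0) = -ln 2, event 2 contributes 0
  expect_equal(proposed_loss(c(0, 0), c(1, 2), c(1, 1)), log(2) / 2,
               tolerance = 1e-12)
  # a single event whose risk set is itself scores a perfect 0
  expect_equal(proposed_loss(0, 5, 1), 0, tolerance = 1e-12)
  expect_error(proposed_loss(c(0, 0), c(1, 2), c(0, 0)), "zero events")
  expect_error(proposed_loss(c(NaN, 0), c(1, 2), c(1, 1)), "NaN")
  # nonnegative on random fixtures, and zero only for singleton risk sets
  for (s in 1:20) {
    f <- make_surv_fixture(8, s)
    expect_gte(proposed_loss(f$risk, f$time, f$event), 0)
  }
})

test_that("sigmoid link is not shift-invariant but exp link is", {
  f <- make_surv_fixture(10, 42)
  base <- proposed_loss(f$risk, f$time, f$event)
  shifted <- proposed_loss(f$risk + 1.3, f$time, f$event)
  expect_gt(abs(base - shifted), 1e-6)
  # the exponential link restores the Cox shift invariance
  expect_equal(proposed_loss(f$risk + 1.3, f$time, f$event, link = "exp"),
               proposed_loss(f$risk, f$time, f$event, link = "exp"),
               tolerance = 1e-10)
  expect_equal(cox_loss(f$risk + 5, f$time, f$event),
               cox_loss(f$risk, f$time, f$event), tolerance = 1e-10)
})

test_that("increasing an event subject's own score decreases the loss", {
  f <- make_surv_fixture(12, 7)
  i <- which(f$event == 1)[1]
  ev_times <- sort(unique(f$time[f$event == 1]))
  S <- matrix(f$risk, 12, length(ev_times))
  k <- match(f$time[i], ev_times)
  g <- proposed_loss(S, f$time, f$event, return_grad = TRUE)$grad
  expect_lt(g[i, k], 0)
})

test_that("cox_loss matches survival::coxph partial likelihood", {
  f <- make_surv_fixture(30, 13, tie_prob = 0.4)
  fit <- survival::coxph(survival::Surv(f$time, f$event) ~ offset(f$risk),
                         ties = "breslow")
  expect_equal(cox_loss(f$risk, f$time, f$event),
               -fit$loglik[1] / sum(f$event), tolerance = 1e-8)
})

test_that("focal loss limits and closed forms", {
  p <- c(0.2, 0.7, 0.9)
  ev <- c(0, 1, 1)
  # gamma = 0 reduces to binary cross-entropy
  bce <- -mean(ifelse(ev == 1, log(p), log(1 - p)))
  expect_equal(focal_loss(p, ev, gamma = 0), bce, tolerance = 1e-12)
  # single case p = 0.5, event, gamma = 2 -> 0.25 ln 2
  expect_equal(focal_loss(0.5, 1, 2), 0.25 * log(2), tolerance = 1e-12)
  # perfect predictions drive the loss to 0
  expect_lt(focal_loss(c(1 - 1e-9, 1e-9), c(1, 0), 2), 1e-15)
  expect_error(focal_loss(c(0, 0.5), c(1, 0)), "probabilities")
})

test_that("combined loss is linear in its components", {
  f <- make_surv_fixture(9, 21)
  S <- matrix(f$risk, 9, length(unique(f$time[f$event == 1])))
  prop <- proposed_loss(S, f$time, f$event)
  expect_equal(combined_loss(S, f$risk, f$time, f$event,
                             weights = c(proposed = 1)), prop)
  foc <- focal_loss(stats::plogis(f$risk), f$event)
  expect_equal(combined_loss(S, f$risk, f$time, f$event,
                             weights = c(proposed = 1, focal = 1)),
               prop + foc, tolerance = 1e-12)
  # cox + focal on the two-subject fixture, summed by hand
  expect_equal(combined_loss(c(0, 0), c(0, 0), c(1, 2), c(1, 1),
                             weights = c(cox = 1, focal = 1)),
               log(2) / 2 + 0.25 * log(2), tolerance = 1e-12)
  expect_error(combined_loss(S, f$risk, f$time, f$event,
                             weights = c(cox = 0)), "disabled")
})

test_that("harrell_c recovers perfect, reversed and tied orderings", {
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 0)
  expect_equal(harrell_c(c(1, 2), c(1, 1), c(1, 1)), 0.5)  # risk tie -> 1/2
  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)), "comparable")
  # complement under risk negation on tie-free data
  f <- make_surv_fixture(15, 3, tie_prob = 0)
  expect_equal(harrell_c(f$time, f$event, f$risk) +
                 harrell_c(f$time, f$event, -f$risk), 1)
})

test_that("harrell_c agrees with survival::concordance on tie-free data", {
  for (s in 1:5) {
    f <- make_surv_fixture(40, s, tie_prob = 0)
    f$time <- f$time + stats::runif(40)  # break residual time ties
    ref <- survival::concordance(survival::Surv(f$time, f$event) ~ f$risk,
                                 reverse = TRUE)$concordance
    expect_equal(harrell_c(f$time, f$event, f$risk), unname(ref),
                 tolerance = 1e-12)
  }
})

test_that("statistics are invariant to subject reordering", {
  f <- make_surv_fixture(25, 17)
  perm <- sample(25)
  expect_equal(harrell_c(f$time, f$event, f$risk),
               harrell_c(f$time[perm], f$event[perm], f$risk[perm]))
  expect_equal(proposed_loss(f$risk, f$time, f$event),
               proposed_loss(f$risk[perm], f$time[perm], f$event[perm]),
               tolerance = 1e-12)
  expect_equal(cox_loss(f$risk, f$time, f$event),
               cox_loss(f$risk[perm], f$time[perm], f$event[perm]),
               tolerance = 1e-12)
})

test_that("bootstrap CI is deterministic, ordered and degenerate-safe", {
  f <- make_surv_fixture(60, 31, tie_prob = 0)
  a <- bootstrap_ci(f$time, f$event, f$risk, B = 200, seed = 5)
  b <- bootstrap_ci(f$time, f$event, f$risk, B = 200, seed = 5)
  expect_identical(a, b)
  expect_lte(a$ci_lower, a$ci_upper)
  # perfectly concordant data: every resample scores 1 -> zero-width CI
  d <- bootstrap_ci(1:10, rep(1, 10), 10:1, B = 100, seed = 2)
  expect_equal(d$ci_lower, 1)
  expect_equal(d$ci_upper, 1)
  expect_equal(d$estimate, 1)
})

test_that("Kaplan-Meier estimator matches the hand product-limit", {
  k <- km_curve(c(1, 2, 3), c(1, 1, 0))
  expect_equal(k$surv[k$time == 1], 2 / 3)
  expect_equal(k$surv[k$time == 2], 1 / 3)
  expect_equal(k$surv[k$time == 3], 1 / 3)  # censoring leaves S unchanged
  # no events: S identically 1
  k0 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(k0$surv == 1))
  # no censoring: S is the empirical survivor fraction
  k1 <- km_curve(1:4, rep(1, 4))
  expect_equal(k1$surv, c(3, 2, 1, 0) / 4)
  expect_true(all(diff(k1$surv) <= 0))
})

test_that("log-rank test matches the hand O-E computation", {
  lr0 <- log_rank(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # 4-subject textbook case: one 2x2 table per event time
  ta <- c(1, 3); ea <- c(1, 0)
  tb <- c(2, 4); eb <- c(1, 1)
  # event t=1: n=4, nA=2, d=1 -> E_A = 0.5, V = 4*2*2*3/(16*3)... use survdiff
  sd <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~
                             rep(c("A", "B"), each = 2))
  lr <- log_rank(ta, ea, tb, eb)
  expect_equal(lr$statistic, sd$chisq)
  O <- sd$obs[1]; E <- sd$exp[1]
  expect_equal(lr$statistic, (O - E)^2 / sd$var[1, 1], tolerance = 1e-10)
  expect_error(log_rank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "zero events")
  expect_error(log_rank(numeric(0), numeric(0), 1, 1), "nonempty")
})

test_that("log-rank separates strongly different exponential groups", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    ta <- stats::rexp(100, 1); tb <- stats::rexp(100, 4)
    p <- log_rank(ta, rep(1, 100), tb, rep(1, 100))$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("median-split stratification follows the stated tie rule", {
  g <- stratify(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "cutoff"), 2.5)
  # ties at the median go to the low group, by enumeration
  g5 <- stratify(c(1, 2, 2, 2, 3))
  expect_equal(as.character(g5), c("low", "low", "low", "low", "high"))
  # rank-invariance under monotone transforms
  r <- c(0.2, 1.5, 0.9, 3.1, 2.2, 0.1)
  expect_equal(as.character(stratify(r)), as.character(stratify(exp(r))))
  expect_error(stratify(rep(1, 5)), "cannot stratify")
  expect_error(stratify(1), "at least 2")
})

test_that("L2-to-event distances follow the closed forms", {
  # constant sigma = 0.5 -> every distance 0.5
  l <- l2_event_distance(rep(0.5, 4), c(1, 0, 1, 0))
  expect_true(all(l$distances == 0.5))
  expect_equal(l$mean, 0.5)
  # near-perfect predictor -> distances near 0
  lp <- l2_event_distance(c(0.999, 0.001), c(1, 0))
  expect_lt(lp$mean, 0.01)
  mixed <- l2_event_distance(c(0.8, 0.3, 0.6), c(1, 0, 0))
  expect_equal(mixed$distances, c(0.2, 0.3, 0.6))
  expect_error(l2_event_distance(c(0.5, NA), c(1, 0)), "missing score")
  expect_error(l2_event_distance(0.5, c(1, 0)), "missing score")
})

test_that("survival_table validates its contract", {
  expect_error(survival_table("a", 0, 1), "positive")
  expect_error(survival_table("a", 1, 2), "0/1")
  tb <- survival_table(c("a", "b"), c(10, 20), c(1, 0), "RFS")
  expect_s3_class(tb, "survival_table")
  expect_equal(tb$endpoint, c("RFS", "RFS"))
})
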