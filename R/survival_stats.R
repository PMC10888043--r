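# Survival losses and evaluation statistics.
#
# The central objective is a time-indexed partial likelihood with a sigmoid
# link: the baseline hazard cancels between numerator and denominator exactly
# as in the Cox partial likelihood, but the per-subject relative risk is
# sigmoid(N(y, t)) with the network score N evaluated at the event time of the
# risk set being scored. Unlike the exponential link, the sigmoid link is not
# shift-invariant, so absolute score levels matter.

#' Construct a survival table
#'
#' @param subject_id character vector.
#' @param time positive follow-up times (days).
#' @param event 0/1 event indicators.
#' @param endpoint endpoint label.
#' @return data.frame of class `survival_table`.
#' @export
survival_table <- function(subject_id, time, event, endpoint = "OS") {
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  structure(data.frame(subject_id = subject_id, time = as.numeric(time),
                       event = as.integer(event), endpoint = endpoint,
                       stringsAsFactors = FALSE),
            class = c("survival_table", "data.frame"))
}

#' Risk set at a subject's event time
#'
#' The risk set at event time T_i is every subject still under observation,
#' i.e. {j : T_j >= T_i}; under the Breslow tie convention subjects with tied
#' event times share the full risk set. Always contains i itself.
#'
#' @param time follow-up times.
#' @param event 0/1 indicators.
#' @param i index of an event subject.
#' @return integer index vector.
#' @export
risk_set <- function(time, event, i) {
  if (event[i] != 1) stop("subject ", i, " is censored; risk sets are indexed by events")
  which(time >= time[i])
}

# expand a per-subject score vector or n x K matrix against K event-time columns
expand_scores <- function(scores, n, K) {
  if (is.matrix(scores)) {
    if (nrow(scores) != n || ncol(scores) != K)
      stop("scores matrix must be n_subjects x n_event_times")
    scores
  } else {
    if (length(scores) != n) stop("scores length must equal n_subjects")
    matrix(scores, n, K)
  }
}

#' Time-indexed sigmoid partial-likelihood loss
#'
#' For each event subject i with event time T_i, the loss contrasts
#' sigmoid(N(y_i, T_i)) against the summed sigmoid scores of the full risk set
#' evaluated at the same time T_i:
#' loss = -(1/N_events) * sum_i [ ln s(N_i(T_i)) - ln sum_{j in R(T_i)} s(N_j(T_i)) ].
#' The baseline hazard cancels and never enters. With `link = "exp"` and
#' time-invariant scores the loss reduces exactly to the Cox partial
#' likelihood ([cox_loss]).
#'
#' @param scores either a length-n vector (time-invariant scores) or an
#'   n x K matrix whose k-th column holds N(y_j, t_k) at the k-th sorted
#'   unique event time.
#' @param time follow-up times.
#' @param event 0/1 indicators; at least one event required.
#' @param link `"sigmoid"` (default) or `"exp"`.
#' @param return_grad also return the analytic gradient wrt `scores`.
#' @return nonnegative scalar loss, or list(loss, grad) when `return_grad`.
#' @export
proposed_loss <- function(scores, time, event, link = c("sigmoid", "exp"),
                          return_grad = FALSE) {
  link <- match.arg(link)
  n <- length(time)
  if (sum(event) == 0) stop("loss undefined: zero events")
  ev_times <- sort(unique(time[event == 1]))
  K <- length(ev_times)
  S <- expand_scores(scores, n, K)
  if (any(!is.finite(S))) stop("NaN/non-finite scores")
  logf <- if (link == "sigmoid") log_sigmoid else identity
  ev_idx <- which(event == 1)
  total <- 0
  grad <- if (return_grad) matrix(0, n, K) else NULL
  for (i in ev_idx) {
    k <- match(time[i], ev_times)
    rs <- which(time >= time[i])
    ls <- logf(S[rs, k])
    lse <- logsumexp(ls)
    total <- total + (logf(S[i, k]) - lse)
    if (return_grad) {
      w <- exp(ls - lse)                       # softmax over the risk set
      if (link == "sigmoid") {
        # d log sigma(x) / dx = 1 - sigma(x); d sigma / dx = sigma(1-sigma)
        grad[i, k] <- grad[i, k] + (1 - sigmoid(S[i, k]))
        grad[rs, k] <- grad[rs, k] - w * (1 - sigmoid(S[rs, k]))
      } else {
        grad[i, k] <- grad[i, k] + 1
        grad[rs, k] <- grad[rs, k] - w
      }
    }
  }
  ne <- length(ev_idx)
  loss <- -total / ne
  if (!return_grad) return(loss)
  grad <- -grad / ne
  if (!is.matrix(scores)) grad <- rowSums(grad)
  list(loss = loss, grad = grad)
}

#' Cox partial-likelihood loss (Breslow ties)
#'
#' Negative mean log partial likelihood with exponential link and
#' time-invariant scores, log-sum-exp stabilized. Shift-invariant: adding a
#' constant to every score leaves it unchanged.
#'
#' @param scores length-n numeric scores.
#' @param time,event follow-up times and 0/1 indicators.
#' @param return_grad also return the analytic gradient.
#' @return scalar loss, or list(loss, grad).
#' @export
cox_loss <- function(scores, time, event, return_grad = FALSE) {
  n <- length(time)
  if (sum(event) == 0) stop("loss undefined: zero events")
  stopifnot(length(scores) == n)
  ev_idx <- which(event == 1)
  total <- 0
  grad <- if (return_grad) numeric(n) else NULL
  for (i in ev_idx) {
    rs <- which(time >= time[i])
    lse <- logsumexp(scores[rs])
    total <- total + scores[i] - lse
    if (return_grad) {
      grad[i] <- grad[i] + 1
      grad[rs] <- grad[rs] - exp(scores[rs] - lse)
    }
  }
  ne <- length(ev_idx)
  if (!return_grad) return(-total / ne)
  list(loss = -total / ne, grad = -grad / ne)
}

#' Focal loss on event probabilities
#'
#' Mean over subjects of -(1 - p_t)^gamma * ln(p_t) where p_t is the predicted
#' probability of the observed outcome: p for events, 1 - p for censored.
#' gamma = 0 reduces exactly to binary cross-entropy.
#'
#' @param event_prob probabilities in (0, 1), e.g. sigmoid(N(y_i, T_i)).
#' @param event 0/1 indicators.
#' @param gamma focusing exponent (default 2).
#' @param return_grad also return the gradient wrt `event_prob`.
#' @return scalar loss, or list(loss, grad).
#' @export
focal_loss <- function(event_prob, event, gamma = 2, return_grad = FALSE) {
  if (any(event_prob <= 0 | event_prob >= 1)) stop("probabilities must lie in (0, 1)")
  n <- length(event_prob)
  pt <- ifelse(event == 1, event_prob, 1 - event_prob)
  loss <- mean(-(1 - pt)^gamma * log(pt))
  if (!return_grad) return(loss)
  dpt <- if (gamma == 0) -1 / pt else
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  grad <- dpt * ifelse(event == 1, 1, -1) / n
  list(loss = loss, grad = grad)
}

#' Weighted combination of the survival losses
#'
#' Default configuration is proposed + focal (the best-performing toggle).
#' The Cox and focal components use each subject's score at its own follow-up
#' time (`scores_own`); the proposed component uses the full time-indexed
#' score matrix.
#'
#' @param scores n x K score matrix (or vector) for [proposed_loss].
#' @param scores_own length-n scores N(y_i, T_i) at each subject's own time.
#' @param time,event follow-up data.
#' @param weights named weights over `c(cox, proposed, focal)`; components
#'   with weight 0 are disabled; all zero is an error.
#' @param gamma focal exponent.
#' @return scalar loss.
#' @export
combined_loss <- function(scores, scores_own, time, event,
                          weights = c(cox = 0, proposed = 1, focal = 1),
                          gamma = 2) {
  w <- c(cox = 0, proposed = 0, focal = 0)
  w[names(weights)] <- weights
  if (all(w == 0)) stop("all loss components disabled")
  total <- 0
  if (w["proposed"] != 0)
    total <- total + w["proposed"] * proposed_loss(scores, time, event)
  if (w["cox"] != 0)
    total <- total + w["cox"] * cox_loss(scores_own, time, event)
  if (w["focal"] != 0)
    total <- total + w["focal"] * focal_loss(sigmoid(scores_own), event, gamma)
  unname(total)
}

#' Harrell's concordance index
#'
#' Over all comparable pairs — (i, j) with E_i = 1 and T_i < T_j, or
#' E_i = 1, E_j = 0 and T_i = T_j — the fraction in which the earlier-failing
#' subject has the higher risk, ties in risk counted 1/2. Pairs of events with
#' tied times are not comparable.
#'
#' @param time,event follow-up data.
#' @param risk per-subject risk scores (higher = worse prognosis).
#' @return concordance in [0, 1].
#' @export
harrell_c <- function(time, event, risk) {
  stopifnot(length(event) == length(time), length(risk) == length(time))
  cnt <- cpp_cindex_counts(as.numeric(time), as.integer(event),
                           as.numeric(risk))
  if (cnt[2] == 0) stop("no comparable pairs")
  cnt[1] / cnt[2]
}

#' Percentile bootstrap confidence interval for a concordance statistic
#'
#' Resamples subjects with replacement B times and takes the 2.5/97.5
#' percentile interval. Resamples with no comparable pairs are skipped with a
#' warning; more than 10% skips is an error.
#'
#' @param time,event,risk as in [harrell_c].
#' @param B bootstrap replicates (reference setting 1000).
#' @param seed integer seed.
#' @param statistic function(time, event, risk) -> scalar.
#' @return list of class `cindex_result`: `estimate`, `ci_lower`, `ci_upper`,
#'   `n_bootstrap`, `n_skipped`.
#' @export
bootstrap_ci <- function(time, event, risk, B = 1000L, seed = 1L,
                         statistic = harrell_c) {
  stopifnot(B >= 1)
  est <- statistic(time, event, risk)
  n <- length(time)
  vals <- numeric(B)
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(time[idx], event[idx], risk[idx]),
                    error = function(e) NA_real_)
      vals[b] <- v
    }
  })
  skipped <- sum(is.na(vals))
  if (skipped > 0)
    warning(skipped, " bootstrap resamples had no comparable pairs and were skipped")
  if (skipped > 0.1 * B) stop("more than 10% of bootstrap resamples skipped")
  q <- stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(estimate = est, ci_lower = q[1], ci_upper = q[2],
                 n_bootstrap = as.integer(B), n_skipped = skipped),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("C-index %.3f (95%% CI %.3f-%.3f; B = %d)\n",
              x$estimate, x$ci_lower, x$ci_upper, x$n_bootstrap))
  invisible(x)
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator S(t) = prod_{t_k <= t} (1 - d_k / n_k), computed
#' with [survival::survfit].
#'
#' @param time,event follow-up data.
#' @return list of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curve <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event),
            class = "km_curve")
}

#' Log-rank test between two groups
#'
#' Standard log-rank statistic on the pooled event-time grid via
#' [survival::survdiff]; p-value from chi-square with 1 df.
#'
#' @param time_a,event_a group A follow-up data.
#' @param time_b,event_b group B follow-up data.
#' @return list: `statistic`, `p_value`.
#' @export
log_rank <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) stop("both groups must be nonempty")
  if (sum(event_a) + sum(event_b) == 0) stop("zero events")
  df <- data.frame(time = c(time_a, time_b), event = c(event_a, event_b),
                   grp = rep(c("A", "B"), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  stat <- sd$chisq
  list(statistic = unname(stat), p_value = unname(stats::pchisq(stat, 1, lower.tail = FALSE)))
}

#' Median-split risk stratification
#'
#' Splits subjects into high- and low-risk groups at the median predicted
#' risk; subjects exactly at the cutoff go to the low group.
#'
#' @param risk per-subject risk scores (>= 2 subjects).
#' @param rule only `"median"` is implemented.
#' @return factor with levels `low`, `high` and attribute `cutoff`.
#' @export
stratify <- function(risk, rule = "median") {
  rule <- match.arg(rule, "median")
  if (length(risk) < 2) stop("need at least 2 subjects")
  if (length(unique(risk)) == 1) stop("cannot stratify: all risks identical")
  cut <- stats::median(risk)
  lab <- factor(ifelse(risk <= cut, "low", "high"), levels = c("low", "high"))
  attr(lab, "cutoff") <- cut
  lab
}

#' L2 distance between predicted event probability and outcome
#'
#' Per subject, |sigmoid(N(y_i, T_i)) - E_i| at the subject's own follow-up
#' time (the scalar L2 distance), plus the cohort mean — a calibration-style
#' diagnostic of how far predictions sit from observed outcomes.
#'
#' @param event_prob predicted event probabilities at each subject's own time.
#' @param event 0/1 indicators.
#' @return list: `distances` (per subject), `mean`.
#' @export
l2_event_distance <- function(event_prob, event) {
  if (length(event_prob) != length(event)) stop("missing score at a subject's time")
  if (anyNA(event_prob)) stop("missing score at a subject's time")
  d <- abs(event_prob - event)
  list(distances = d, mean = mean(d))
}
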