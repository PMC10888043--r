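# shared fixtures and independent oracles

# internal (non-exported) functions used by white-box tests
.ns <- asNamespace("mmsurv")
mha_fwd_i <- .ns$mha_fwd
mhab_fwd_i <- .ns$mhab_fwd
mae_step_i <- .ns$mae_step
maeb_step_i <- .ns$maeb_step
fuse_subject_fwd_i <- .ns$fuse_subject_fwd
fuse_subject_bwd_i <- .ns$fuse_subject_bwd
fuse_batch_fwd_i <- .ns$fuse_batch_fwd
fuse_batch_bwd_i <- .ns$fuse_batch_bwd
tree_map2_i <- .ns$tree_map2
tree_zero_i <- .ns$tree_zero
init_mha_i <- .ns$init_mha
head_fwd_i <- .ns$head_fwd
with_seed_i <- .ns$with_seed

# random right-censored survival fixture with possible ties
make_surv_fixture <- function(n, seed, tie_prob = 0.3, event_prob = 0.7) {
  with_seed_i(seed, {
    time <- sample.int(max(3, round(n * (1 - tie_prob))), n, replace = TRUE) +
      stats::runif(n) * 0
    time <- as.numeric(time)
    event <- stats::rbinom(n, 1, event_prob)
    if (sum(event) == 0) event[sample.int(n, 1)] <- 1L
    risk <- stats::rnorm(n)
    list(time = time, event = event, risk = risk)
  })
}

# exhaustive-pair concordance oracle (independent of the vectorized path)
brute_cindex <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (event[i] == 1 && time[i] < time[j]) ||
        (event[i] == 1 && event[j] == 0 && time[i] == time[j])
      if (!comparable) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# brute-force scaled-dot-product attention, one head
brute_attention <- function(Q, K, V) {
  d <- ncol(Q)
  A <- Q %*% t(K) / sqrt(d)
  P <- t(apply(A, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  if (nrow(A) == 1) P <- matrix(P, 1)
  P %*% V
}

# mha weights realizing plain single-head attention with identity projections
identity_mha <- function(d) {
  list(Wq = diag(d), bq = numeric(d), Wk = diag(d), bk = numeric(d),
       Wv = diag(d), bv = numeric(d), Wo = diag(d), bo = numeric(d))
}

make_record <- function(age = 60, sex = "male", t = "T2", n = "N1",
                        stage = "III") {
  list(age = age, sex = sex, t_stage = t, n_stage = n, m_stage = "M0",
       overall_stage = stage)
}
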