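test_that("cross-attention degenerates correctly on single tokens", {
  d <- 4
  cfg <- fusion_config(d_model = d, heads = 1, n_queries = 2)
  w <- fusion_init(cfg, risk_head_config(time_scale = 10), seed = 1)
  w$xfuse$attn <- identity_mha(d)
  w$xfuse$ff$W2[] <- 0  # silence the feed-forward residual
  w$xfuse$ff$b2[] <- 0
  ct <- matrix(c(1, -2, 0.5, 3), 1)
  pet <- matrix(c(7, 1, -1, 2), 1)
  out <- cross_attention_fuse(ct, pet, cfg, w)
  expect_equal(as.vector(out$tokens), as.vector(pet), tolerance = 1e-12)
  # two CT tokens with equal logits: each output row is the mean of PET tokens
  ct2 <- matrix(0, 2, d)
  pet2 <- matrix(stats::rnorm(8), 2, d)
  out2 <- cross_attention_fuse(ct2, pet2, cfg, w)
  expect_equal(out2$tokens[1, ], colMeans(pet2), tolerance = 1e-12)
  expect_equal(out2$tokens[2, ], colMeans(pet2), tolerance = 1e-12)
})

test_that("cross-attention matches brute-force softmax(QK'/sqrt(d))V", {
  set.seed(11)
  d <- 4
  cfg <- fusion_config(d_model = d, heads = 1)
  w <- fusion_init(cfg, risk_head_config(time_scale = 10), seed = 2)
  w$xfuse$ff$W2[] <- 0
  w$xfuse$ff$b2[] <- 0
  for (r in 1:10) {
    ct <- matrix(stats::rnorm(12), 3, d)
    pet <- matrix(stats::rnorm(12), 3, d)
    out <- cross_attention_fuse(ct, pet, cfg, w)
    p <- w$xfuse$attn
    oracle <- brute_attention(ct %*% p$Wq + rep(p$bq, each = 3),
                              ct %*% p$Wk + rep(p$bk, each = 3),
                              pet %*% p$Wv + rep(p$bv, each = 3)) %*% p$Wo +
      rep(p$bo, each = 3)
    expect_equal(out$tokens, oracle, tolerance = 1e-6)
  }
})

test_that("attention rows are a probability distribution", {
  d <- 8
  cfg <- fusion_config(d_model = d, heads = 4)
  w <- fusion_init(cfg, risk_head_config(time_scale = 10), seed = 3)
  ct <- matrix(stats::rnorm(40), 5, d)
  pet <- matrix(stats::rnorm(40), 5, d)
  out <- cross_attention_fuse(ct, pet, cfg, w)
  P <- out$cache$at$cache$P
  for (h in seq_len(dim(P)[3])) {
    expect_lt(max(abs(rowSums(P[, , h]) - 1)), 1e-6)
  }
  expect_error(cross_attention_fuse(ct, pet[1:3, ], cfg, w), "mismatch")
})

test_that("single-modality mode reduces to self-attention with tied streams", {
  d <- 8
  w <- fusion_init(fusion_config(d_model = d), risk_head_config(time_scale = 1),
                   seed = 4)
  x <- matrix(stats::rnorm(48), 6, d)
  a <- cross_attention_fuse(x, x, fusion_config(mode = "cross_qk_ct_v_pet",
                                                d_model = d), w)
  b <- cross_attention_fuse(x, NULL, fusion_config(mode = "single_ct",
                                                   d_model = d), w)
  expect_equal(a$tokens, b$tokens, tolerance = 1e-12)
})

test_that("clinical encoding is local, binned and vocabulary-checked", {
  d <- 8
  tabs <- mmsurv:::init_clinical_tables(d)
  r1 <- make_record(sex = "male")
  r2 <- make_record(sex = "female")
  t1 <- encode_clinical(r1, tabs)
  t2 <- encode_clinical(r2, tabs)
  expect_equal(dim(t1), c(6L, d))
  expect_equal(t1[-2, ], t2[-2, ])            # only the sex token differs
  expect_false(isTRUE(all.equal(t1[2, ], t2[2, ])))
  # same decade bin -> identical age token
  expect_equal(encode_clinical(make_record(age = 61), tabs)[1, ],
               encode_clinical(make_record(age = 69), tabs)[1, ])
  expect_error(encode_clinical(make_record(age = 17), tabs), "below supported")
  expect_error(encode_clinical(make_record(age = 95), tabs), "above supported")
  expect_error(encode_clinical(make_record(t = "T7"), tabs), "vocabulary")
})

test_that("Q-Former isolates streams and is set-equivariant over image tokens", {
  d <- 8
  cfg <- fusion_config(d_model = d, heads = 2, n_queries = 3, qformer_depth = 1)
  w <- fusion_init(cfg, risk_head_config(time_scale = 1), seed = 5)
  txt <- encode_clinical(make_record(), w$text)
  img <- matrix(stats::rnorm(5 * d), 5, d)
  out <- qformer_fuse(img, txt, cfg, w)
  expect_equal(dim(out$tokens), c(3L, d))
  # permuting image tokens leaves the queries unchanged (no positions on keys)
  out_p <- qformer_fuse(img[c(3, 1, 5, 2, 4), ], txt, cfg, w)
  expect_equal(out$tokens, out_p$tokens, tolerance = 1e-6)
  # zero cross-attention output projection cuts the image path entirely
  w0 <- w
  w0$qblocks[[1]]$xattn$Wo[] <- 0
  w0$qblocks[[1]]$xattn$bo[] <- 0
  a <- qformer_fuse(img, txt, cfg, w0)
  b <- qformer_fuse(matrix(stats::rnorm(5 * d), 5, d), txt, cfg, w0)
  expect_equal(a$tokens, b$tokens, tolerance = 1e-12)
  expect_error(fusion_config(n_queries = 0), "n_queries")
})

test_that("concat_fc fusion keeps block structure and matches hand matmul", {
  d <- 3
  img <- c(1, 2, 3)
  txt <- c(0, 0, 0)
  w <- list(W = rbind(diag(3), matrix(0, 3, 3)), b = numeric(3))
  out <- concat_fc_fuse(img, txt, w)
  expect_equal(out$pre, img)   # identity block, zero text contributes nothing
  set.seed(6)
  w2 <- list(W = matrix(stats::rnorm(6 * 4), 6, 4), b = stats::rnorm(4))
  i2 <- stats::rnorm(3); t2 <- stats::rnorm(3)
  out2 <- concat_fc_fuse(i2, t2, w2)
  pre <- as.vector(c(i2, t2) %*% w2$W) + w2$b
  expect_equal(out2$pre, pre, tolerance = 1e-12)
  expect_equal(out2$out, pre * stats::plogis(1.702 * pre), tolerance = 1e-12)
})

test_that("risk head honours time and degenerate weights", {
  d <- 8
  hcfg <- risk_head_config(time_embed_dim = 8, mlp_widths = 6, time_scale = 100)
  cfg <- fusion_config(d_model = d)
  w <- fusion_init(cfg, hcfg, seed = 7)
  fused <- matrix(stats::rnorm(3 * d), 3, d)
  expect_error(risk_score(fused, -1, hcfg, w), "negative")
  expect_true(is.finite(risk_score(fused, 100, hcfg, w)))  # t = time_scale
  # all-zero head -> score 0 everywhere
  w0 <- w
  w0$head <- mmsurv:::tree_zero(w0$head)
  expect_equal(risk_score(fused, 50, hcfg, w0), 0)
  # time dependence is live: distinct times give distinct scores
  s1 <- risk_score(fused, 10, hcfg, w)
  s2 <- risk_score(fused, 90, hcfg, w)
  expect_gt(abs(s1 - s2), 1e-8)
})

test_that("batched fusion equals the per-subject reference path", {
  set.seed(8)
  d <- 8; B <- 4; L <- 6
  for (mode in c("cross_qk_ct_v_pet", "cross_qk_pet_v_ct", "concat_fc",
                 "single_ct")) {
    for (useq in c(TRUE, FALSE)) {
      cfg <- fusion_config(mode = mode, use_qformer = useq, n_queries = 3,
                           qformer_depth = 2, d_model = d, heads = 2)
      w <- fusion_init(cfg, risk_head_config(time_scale = 1), seed = 9)
      ct <- lapply(1:B, function(i) matrix(stats::rnorm(L * d), L, d))
      pet <- if (mode == "single_ct") NULL else
        lapply(1:B, function(i) matrix(stats::rnorm(L * d), L, d))
      recs <- lapply(1:B, function(i)
        make_record(age = 20 + 15 * i, stage = c("I", "II", "III", "IV")[i]))
      tix <- do.call(rbind, lapply(recs, clinical_index))
      fb <- fuse_batch_fwd_i(do.call(rbind, ct),
                             if (is.null(pet)) NULL else do.call(rbind, pet),
                             L, B, tix, cfg, w)
      gP <- matrix(stats::rnorm(B * d), B, d)
      gb <- fuse_batch_bwd_i(gP, fb$cache, w)
      gref <- NULL
      for (j in 1:B) {
        fw <- fuse_subject_fwd_i(ct[[j]], if (is.null(pet)) NULL else pet[[j]],
                                 recs[[j]], cfg, w)
        expect_equal(fb$pooled[j, ], fw$pooled, tolerance = 1e-10)
        gt <- fuse_subject_bwd_i(gP[j, ], fw$cache, w)
        gref <- if (is.null(gref)) gt else tree_map2_i(`+`, gref, gt)
      }
      diffs <- unlist(tree_map2_i(function(a, b) max(abs(a - b)),
                                  gb[names(gref)], gref))
      expect_lt(max(diffs), 1e-9)
    }
  }
})

test_that("fusion-path analytic gradients match finite differences", {
  set.seed(10)
  d <- 8
  cfg <- fusion_config(n_queries = 3, qformer_depth = 1, d_model = d, heads = 2)
  w <- fusion_init(cfg, risk_head_config(time_scale = 1), seed = 11)
  ct <- matrix(stats::rnorm(5 * d), 5, d)
  pet <- matrix(stats::rnorm(5 * d), 5, d)
  rec <- make_record()
  w0 <- stats::rnorm(d)
  lossfun <- function(W) sum(fuse_subject_fwd_i(ct, pet, rec, cfg, W)$pooled * w0)
  fw <- fuse_subject_fwd_i(ct, pet, rec, cfg, w)
  gt <- fuse_subject_bwd_i(w0, fw$cache, w)
  h <- 1e-6
  check <- function(get, set, g) {
    v <- get(w)
    for (i in sample(length(v), 3)) {
      vv <- v; vv[i] <- v[i] + h; lp <- lossfun(set(w, vv))
      vv[i] <- v[i] - h; lm <- lossfun(set(w, vv))
      expect_equal((lp - lm) / (2 * h), g[i], tolerance = 1e-4)
    }
  }
  check(function(p) p$xfuse$attn$Wv,
        function(p, v) { p$xfuse$attn$Wv[] <- v; p }, gt$xfuse$attn$Wv)
  check(function(p) p$queries,
        function(p, v) { p$queries[] <- v; p }, gt$queries)
  check(function(p) p$qblocks[[1]]$xattn$Wq,
        function(p, v) { p$qblocks[[1]]$xattn$Wq[] <- v; p },
        gt$qblocks[[1]]$xattn$Wq)
})
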