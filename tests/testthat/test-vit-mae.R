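test_that("patchify arithmetic and exact inversion", {
  p224 <- matrix(stats::runif(224^2), 224)
  pat <- patchify(p224, 16)
  expect_equal(dim(pat), c(196L, 256L))
  p64 <- matrix(stats::runif(64^2), 64)
  expect_equal(nrow(patchify(p64, 8)), 64L)
  expect_equal(unpatchify(patchify(p64, 8), 8), p64)
  expect_error(patchify(p64, 7), "divisible")
})

test_that("mask plans are exact, deterministic and uniform", {
  pl <- plan_mask(196, 0.75, seed = 1)
  expect_length(pl$masked_idx, 147L)
  expect_setequal(c(pl$masked_idx, pl$visible_idx), 1:196)
  expect_length(intersect(pl$masked_idx, pl$visible_idx), 0)
  expect_identical(plan_mask(196, 0.75, seed = 9)$masked_idx,
                   plan_mask(196, 0.75, seed = 9)$masked_idx)
  expect_length(plan_mask(10, 0, seed = 1)$masked_idx, 0)
  expect_error(plan_mask(10, 1), "ratio")
  # exchangeability: over many seeds each index is masked ~ratio of the time
  counts <- integer(16)
  for (s in 1:2000) {
    counts[plan_mask(16, 0.5, seed = s)$masked_idx] <-
      counts[plan_mask(16, 0.5, seed = s)$masked_idx] + 1L
  }
  expect_lt(max(abs(counts / 2000 - 0.5)), 0.05)
})

test_that("encoder respects shapes and is set-equivariant over positions", {
  cfg <- vit_config(patch_size = 8, depth = 2, width = 64, heads = 4,
                    decoder_depth = 1, decoder_width = 32)
  pat <- patchify(matrix(stats::runif(64^2), 64), 8)
  w <- vit_init(cfg, 64, seed = 2)
  vis <- sort(sample.int(64, 49))
  out <- vit_encode(pat[vis, ], w, cfg, pos_idx = vis)
  expect_equal(dim(out$tokens), c(49L, 64L))
  # permuting patches together with their positions permutes the output rows
  perm <- sample(seq_along(vis))
  out2 <- vit_encode(pat[vis[perm], ], w, cfg, pos_idx = vis[perm])
  expect_equal(out2$tokens, out$tokens[perm, ], tolerance = 1e-10)
  # zero weights give a constant (zero) map
  w0 <- mmsurv:::tree_zero(w)
  out0 <- vit_encode(pat[vis, ], w0, cfg, pos_idx = vis)
  expect_equal(max(abs(out0$tokens)), 0)
})

test_that("reconstruction loss matches closed forms and hand sums", {
  pl <- plan_mask(4, 0.5, seed = 3)
  target <- matrix(stats::rnorm(4 * 9, sd = 2), 4, 9)
  mu <- rowMeans(target)
  sdv <- sqrt(rowMeans((target - mu)^2) + 1e-6)
  tstd <- (target - mu) / sdv
  expect_equal(mae_reconstruction_loss(tstd, target, pl), 0, tolerance = 1e-12)
  cshift <- 0.37
  expect_equal(mae_reconstruction_loss(tstd + cshift, target, pl), cshift^2,
               tolerance = 1e-12)
  dec <- matrix(stats::rnorm(36), 4, 9)
  hand <- mean((dec[pl$masked_idx, ] - tstd[pl$masked_idx, ])^2)
  expect_equal(mae_reconstruction_loss(dec, target, pl), hand)
  expect_error(mae_reconstruction_loss(dec, target, plan_mask(4, 0, 1)),
               "empty mask")
  # loss is invariant to the ordering of the masked indices
  pl_rev <- pl; pl_rev$masked_idx <- rev(pl$masked_idx)
  expect_equal(mae_reconstruction_loss(dec, target, pl_rev),
               mae_reconstruction_loss(dec, target, pl))
})

test_that("MAE pretraining reduces the reconstruction loss deterministically", {
  set.seed(5)
  cfg <- vit_config(patch_size = 8, depth = 2, width = 32, heads = 2,
                    decoder_depth = 1, decoder_width = 16)
  planes <- lapply(1:24, function(i) {
    z <- matrix(0, 32, 32)
    cx <- sample(8:24, 1); cy <- sample(8:24, 1)
    z[cx + (-4:4), cy + (-4:4)] <- 1
    z + matrix(stats::runif(1024, 0, 0.2), 32)
  })
  fit <- mae_pretrain(planes, cfg, epochs = 12, batch_size = 8, seed = 4)
  expect_length(fit$trace, 12)
  expect_lt(fit$trace[12], fit$trace[1])
  fit2 <- mae_pretrain(planes, cfg, epochs = 12, batch_size = 8, seed = 4)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$weights$enc$embed$W, fit2$weights$enc$embed$W)
  # epochs = 0 returns the initialisation untouched
  fit0 <- mae_pretrain(planes, cfg, epochs = 0, seed = 4)
  expect_length(fit0$trace, 0)
  expect_equal(fit0$weights, vit_init(cfg, 16, mmsurv:::derive_seed(4, "vit_init")))
})

test_that("constant images drive the reconstruction loss to ~0", {
  cfg <- vit_config(patch_size = 8, depth = 1, width = 16, heads = 2,
                    decoder_depth = 1, decoder_width = 16)
  planes <- lapply(1:8, function(i) matrix(0.5, 32, 32))
  fit <- mae_pretrain(planes, cfg, epochs = 10, batch_size = 8, seed = 1)
  expect_lt(tail(fit$trace, 1), 1e-3)
})

test_that("single-image and batched MAE steps agree", {
  cfg <- vit_config(patch_size = 4, depth = 2, width = 8, heads = 2,
                    decoder_depth = 1, decoder_width = 8)
  pats <- lapply(1:3, function(i) patchify(matrix(stats::runif(256), 16), 4))
  params <- vit_init(cfg, 16, seed = 3)
  plans <- lapply(1:3, function(i) plan_mask(16, 0.5, seed = i))
  stb <- maeb_step_i(pats, plans, params, cfg)
  ref_loss <- 0
  ref_grads <- NULL
  for (i in 1:3) {
    st <- mae_step_i(pats[[i]], plans[[i]], params, cfg)
    ref_loss <- ref_loss + st$loss / 3
    g <- mmsurv:::tree_scale(st$grads, 1 / 3)
    ref_grads <- if (is.null(ref_grads)) g else tree_map2_i(`+`, ref_grads, g)
  }
  expect_equal(stb$loss, ref_loss, tolerance = 1e-12)
  diffs <- unlist(tree_map2_i(function(a, b) max(abs(a - b)), stb$grads,
                              ref_grads))
  expect_lt(max(diffs), 1e-10)
})
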