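# Batched (stacked) forward/backward passes used by the training loops.
#
# A batch of B token matrices (L x d each) is stored subject-major as one
# (B*L) x d matrix: rows ((b-1)*L+1):(b*L) belong to item b. Linear layers,
# layer norm and the GELU feed-forward are row-wise, so the stacked versions
# are the unbatched functions applied to the stacked matrix; only attention
# needs a per-item loop. The batched path must agree with the per-item
# functions to float precision (enforced by tests).

## ---- batched transformer block (self-attention) ---------------------------

blockb_fwd <- function(x, L, B, p, heads) {
  l1 <- layernorm_fwd(x, p$ln1)
  at <- mhab_fwd(l1$out, l1$out, l1$out, L, L, B, p$attn, heads)
  x1 <- x + at$out
  l2 <- layernorm_fwd(x1, p$ln2)
  ffo <- ff_fwd(l2$out, p$ff)
  list(out = x1 + ffo$out, cache = list(l1 = l1, at = at, l2 = l2, ff = ffo))
}

blockb_bwd <- function(gy, cache) {
  fb <- ff_bwd(gy, cache$ff$cache)
  l2b <- layernorm_bwd(fb$gx, cache$l2$cache)
  gx1 <- gy + l2b$gx
  ab <- mhab_bwd(gx1, cache$at$cache)
  l1b <- layernorm_bwd(ab$gxq + ab$gxk + ab$gxv, cache$l1$cache)
  list(gparams = list(ln1 = l1b$gparams, attn = ab$gparams,
                      ln2 = l2b$gparams, ff = fb$gparams),
       gx = gx1 + l1b$gx)
}

## ---- batched MAE step ------------------------------------------------------

# patches: list of M patch matrices (same L); plans: list of M mask plans with
# a common visible count. One fused forward/backward over the minibatch.
maeb_step <- function(patches, plans, params, cfg) {
  M <- length(patches)
  L <- nrow(patches[[1]])
  vis_n <- length(plans[[1]]$visible_idx)
  d <- cfg$width
  dw <- cfg$decoder_width
  vis_rows <- unlist(lapply(seq_len(M), function(m)
    (m - 1) * L + plans[[m]]$visible_idx))
  msk_rows <- unlist(lapply(seq_len(M), function(m)
    (m - 1) * L + plans[[m]]$masked_idx))
  vis_pos <- unlist(lapply(plans, `[[`, "visible_idx"))
  pat_all <- do.call(rbind, patches)
  emb <- linear_fwd(pat_all[vis_rows, , drop = FALSE], params$enc$embed)
  x <- emb$out + params$enc$pos[vis_pos, , drop = FALSE]
  ecaches <- vector("list", length(params$enc$blocks))
  for (i in seq_along(params$enc$blocks)) {
    bl <- blockb_fwd(x, vis_n, M, params$enc$blocks[[i]], cfg$heads)
    x <- bl$out
    ecaches[[i]] <- bl$cache
  }
  eln <- layernorm_fwd(x, params$enc$ln)
  demb <- linear_fwd(eln$out, params$dec$embed)
  z <- matrix(rep(params$dec$mask, each = M * L), M * L, dw)
  z[vis_rows, ] <- demb$out
  z <- z + params$dec$pos[rep(seq_len(L), M), , drop = FALSE]
  dcaches <- vector("list", length(params$dec$blocks))
  for (i in seq_along(params$dec$blocks)) {
    bl <- blockb_fwd(z, L, M, params$dec$blocks[[i]], cfg$heads)
    z <- bl$out
    dcaches[[i]] <- bl$cache
  }
  dln <- layernorm_fwd(z, params$dec$ln)
  pred <- linear_fwd(dln$out, params$dec$pred)
  tstd <- standardize_patches(pat_all)
  resid <- pred$out[msk_rows, , drop = FALSE] - tstd[msk_rows, , drop = FALSE]
  # mean over images of the per-image masked MSE (equal mask counts)
  loss <- mean(resid^2)
  gpred <- matrix(0, M * L, ncol(pred$out))
  gpred[msk_rows, ] <- 2 * resid / length(resid)
  pb <- linear_bwd(gpred, pred$cache)
  lnb <- layernorm_bwd(pb$gx, dln$cache)
  gz <- lnb$gx
  gdblocks <- vector("list", length(params$dec$blocks))
  for (i in rev(seq_along(params$dec$blocks))) {
    bb <- blockb_bwd(gz, dcaches[[i]])
    gdblocks[[i]] <- bb$gparams
    gz <- bb$gx
  }
  gpos_dec <- rowsum(gz, rep(seq_len(L), M))
  gmask <- matrix(colSums(gz[msk_rows, , drop = FALSE]), 1)
  deb <- linear_bwd(gz[vis_rows, , drop = FALSE], demb$cache)
  elb <- layernorm_bwd(deb$gx, eln$cache)
  gx <- elb$gx
  geblocks <- vector("list", length(params$enc$blocks))
  for (i in rev(seq_along(params$enc$blocks))) {
    bb <- blockb_bwd(gx, ecaches[[i]])
    geblocks[[i]] <- bb$gparams
    gx <- bb$gx
  }
  gpos_enc <- matrix(0, L, d)
  acc <- rowsum(gx, vis_pos)
  gpos_enc[as.integer(rownames(acc)), ] <- acc
  eb <- linear_bwd(gx, emb$cache)
  list(loss = loss,
       grads = list(enc = list(embed = eb$gparams, pos = gpos_enc,
                               blocks = geblocks, ln = elb$gparams),
                    dec = list(embed = deb$gparams, mask = gmask,
                               pos = gpos_dec, blocks = gdblocks,
                               ln = lnb$gparams, pred = pb$gparams)))
}

## ---- batched fusion forward/backward ---------------------------------------

# ct_stack / pet_stack: (B*L) x d stacked frozen encoder tokens (or NULL).
# text_idx: B x 6 matrix of clinical vocabulary indices.
fuse_batch_fwd <- function(ct_stack, pet_stack, L, B, text_idx, cfg, weights) {
  d <- cfg$d_model
  if (cfg$mode == "concat_fc") {
    pool <- function(st) if (is.null(st)) matrix(0, B, d) else
      rowsum(st, rep(seq_len(B), each = L)) / L
    zc <- cbind(pool(ct_stack), pool(pet_stack))
    pre <- add_rowvec(zc %*% weights$concat$W, weights$concat$b)
    mem <- gelu(pre)
    Lm <- 1L
    xcache <- list(kind = "concat", zc = zc, pre = pre)
  } else {
    src <- switch(cfg$mode,
                  cross_qk_ct_v_pet = list(qk = ct_stack, v = pet_stack),
                  cross_qk_pet_v_ct = list(qk = pet_stack, v = ct_stack),
                  single_pet = list(qk = pet_stack, v = pet_stack),
                  single_ct = list(qk = ct_stack, v = ct_stack))
    at <- mhab_fwd(src$qk, src$qk, src$v, L, L, B, weights$xfuse$attn, cfg$heads)
    ln <- layernorm_fwd(at$out, weights$xfuse$ln)
    ffo <- ff_fwd(ln$out, weights$xfuse$ff)
    mem <- at$out + ffo$out
    Lm <- L
    xcache <- list(kind = "cross", at = at, ln = ln, ff = ffo)
  }
  if (!cfg$use_qformer) {
    pooled <- rowsum(mem, rep(seq_len(B), each = Lm)) / Lm
    return(list(pooled = pooled,
                cache = list(x = xcache, qf = NULL, Lm = Lm, B = B, cfg = cfg)))
  }
  nq <- cfg$n_queries
  FT <- length(.clin_fields)
  Lz <- nq + FT
  # stacked text tokens: row (b-1)*F+f is field f of subject b
  txt <- matrix(0, B * FT, d)
  for (f in seq_len(FT)) {
    tab <- weights$text[[.clin_fields[f]]]
    txt[(seq_len(B) - 1) * FT + f, ] <- tab[text_idx[, f], , drop = FALSE]
  }
  q <- weights$queries[rep(seq_len(nq), B), , drop = FALSE]
  # row indices of queries/text within the stacked [q; t] blocks
  zq_rows <- unlist(lapply(seq_len(B), function(b) (b - 1) * Lz + seq_len(nq)))
  zt_rows <- setdiff(seq_len(B * Lz), zq_rows)
  bcaches <- vector("list", length(weights$qblocks))
  for (i in seq_along(weights$qblocks)) {
    p <- weights$qblocks[[i]]
    z <- matrix(0, B * Lz, d)
    z[zq_rows, ] <- q
    z[zt_rows, ] <- txt
    l1 <- layernorm_fwd(z, p$ln1)
    sa <- mhab_fwd(l1$out, l1$out, l1$out, Lz, Lz, B, p$attn, cfg$heads)
    z1 <- z + sa$out
    q1 <- z1[zq_rows, , drop = FALSE]
    txt <- z1[zt_rows, , drop = FALSE]
    lx <- layernorm_fwd(q1, p$lnx)
    xa <- mhab_fwd(lx$out, mem, mem, nq, Lm, B, p$xattn, cfg$heads)
    q2 <- q1 + xa$out
    l2 <- layernorm_fwd(q2, p$ln2)
    ffo <- ff_fwd(l2$out, p$ff)
    q <- q2 + ffo$out
    bcaches[[i]] <- list(l1 = l1, sa = sa, lx = lx, xa = xa, l2 = l2, ff = ffo)
  }
  qln <- layernorm_fwd(q, weights$qln)
  pooled <- rowsum(qln$out, rep(seq_len(B), each = nq)) / nq
  list(pooled = pooled,
       cache = list(x = xcache, qblocks = bcaches, qln = qln,
                    zq_rows = zq_rows, zt_rows = zt_rows, Lm = Lm, B = B,
                    nq = nq, FT = FT, text_idx = text_idx, cfg = cfg))
}

fuse_batch_bwd <- function(gpooled, cache, weights) {
  cfg <- cache$cfg
  B <- cache$B
  Lm <- cache$Lm
  d <- ncol(gpooled)
  gtree <- list()
  if (cfg$use_qformer) {
    nq <- cache$nq
    FT <- cache$FT
    gq <- (gpooled / nq)[rep(seq_len(B), each = nq), , drop = FALSE]
    qlb <- layernorm_bwd(gq, cache$qln$cache)
    gq <- qlb$gx
    gtree$qln <- qlb$gparams
    gtxt <- matrix(0, B * FT, d)
    gmem <- matrix(0, B * Lm, d)
    gtree$qblocks <- vector("list", length(weights$qblocks))
    for (i in rev(seq_along(weights$qblocks))) {
      cc <- cache$qblocks[[i]]
      fb <- ff_bwd(gq, cc$ff$cache)
      l2b <- layernorm_bwd(fb$gx, cc$l2$cache)
      gq2 <- gq + l2b$gx
      xab <- mhab_bwd(gq2, cc$xa$cache)
      gmem <- gmem + xab$gxk + xab$gxv
      lxb <- layernorm_bwd(xab$gxq, cc$lx$cache)
      gq1 <- gq2 + lxb$gx
      gz1 <- matrix(0, nrow(gq1) + nrow(gtxt), d)
      gz1[cache$zq_rows, ] <- gq1
      gz1[cache$zt_rows, ] <- gtxt
      sab <- mhab_bwd(gz1, cc$sa$cache)
      l1b <- layernorm_bwd(sab$gxq + sab$gxk + sab$gxv, cc$l1$cache)
      gz <- gz1 + l1b$gx
      gq <- gz[cache$zq_rows, , drop = FALSE]
      gtxt <- gz[cache$zt_rows, , drop = FALSE]
      gtree$qblocks[[i]] <- list(ln1 = l1b$gparams, attn = sab$gparams,
                                 lnx = lxb$gparams, xattn = xab$gparams,
                                 ln2 = l2b$gparams, ff = fb$gparams)
    }
    gtree$queries <- rowsum(gq, rep(seq_len(nq), B))
    gtables <- tree_zero(weights$text)
    for (f in seq_len(FT)) {
      fld <- .clin_fields[f]
      gf <- gtxt[(seq_len(B) - 1) * FT + f, , drop = FALSE]
      acc <- rowsum(gf, cache$text_idx[, f])
      gtables[[fld]][as.integer(rownames(acc)), ] <-
        gtables[[fld]][as.integer(rownames(acc)), ] + acc
    }
    gtree$text <- gtables
  } else {
    gmem <- (gpooled / Lm)[rep(seq_len(B), each = Lm), , drop = FALSE]
  }
  if (cache$x$kind == "concat") {
    gpre <- gmem * gelu_grad(cache$x$pre)
    gtree$concat <- list(W = crossprod(cache$x$zc, gpre), b = colSums(gpre))
  } else {
    fb <- ff_bwd(gmem, cache$x$ff$cache)
    lb <- layernorm_bwd(fb$gx, cache$x$ln$cache)
    ab <- mhab_bwd(gmem + lb$gx, cache$x$at$cache)
    gtree$xfuse <- list(attn = ab$gparams, ln = lb$gparams, ff = fb$gparams)
  }
  gtree
}

## ---- factorized pair head ---------------------------------------------------

# Scores for (subject, time) pairs without materialising the full
# cbind(P, TE) row block: the first linear layer factorizes as
# (P W_p)[subj,] + (TE W_t)[col,] + b. Only `pairs` rows are evaluated.
pair_head_fwd <- function(P, TE, subj, col, head) {
  d <- ncol(P)
  W1 <- head$layers[[1]]$W
  Wp <- W1[seq_len(d), , drop = FALSE]
  Wt <- W1[-seq_len(d), , drop = FALSE]
  pre <- (P %*% Wp)[subj, , drop = FALSE] + (TE %*% Wt)[col, , drop = FALSE]
  pre <- add_rowvec(pre, head$layers[[1]]$b)
  nl <- length(head$layers)
  caches <- vector("list", nl)
  caches[[1]] <- list(pre = pre)
  a <- gelu(pre)
  for (i in 2:nl) {
    li <- linear_fwd(a, head$layers[[i]])
    if (i < nl) {
      caches[[i]] <- list(lin = li$cache, pre = li$out)
      a <- gelu(li$out)
    } else {
      caches[[i]] <- list(lin = li$cache, pre = NULL)
      a <- li$out
    }
  }
  list(scores = a[, 1], cache = list(layers = caches, P = P, TE = TE,
                                     subj = subj, col = col, d = d))
}

pair_head_bwd <- function(gscores, cache, head) {
  nl <- length(cache$layers)
  g <- matrix(gscores, ncol = 1)
  glayers <- vector("list", nl)
  for (i in nl:2) {
    if (!is.null(cache$layers[[i]]$pre)) g <- g * gelu_grad(cache$layers[[i]]$pre)
    lb <- linear_bwd(g, cache$layers[[i]]$lin)
    glayers[[i]] <- lb$gparams
    g <- lb$gx
  }
  g <- g * gelu_grad(cache$layers[[1]]$pre)
  d <- cache$d
  W1 <- head$layers[[1]]$W
  Wp <- W1[seq_len(d), , drop = FALSE]
  gsub <- rowsum(g, cache$subj)
  gcol <- rowsum(g, cache$col)
  gP_rows <- as.integer(rownames(gsub))
  gP <- matrix(0, nrow(cache$P), d)
  gP[gP_rows, ] <- tcrossprod(gsub, Wp)
  gW1 <- rbind(crossprod(cache$P[gP_rows, , drop = FALSE], gsub),
               crossprod(cache$TE[as.integer(rownames(gcol)), , drop = FALSE],
                         gcol))
  glayers[[1]] <- list(W = gW1, b = colSums(g))
  list(gparams = list(layers = glayers), gP = gP)
}
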