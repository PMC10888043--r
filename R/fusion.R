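# Multi-modal fusion: cross-attention PET/CT feature fusion, embedding of
# structured clinical covariates as text tokens, Q-Former image-text fusion
# with learnable queries, and the time-indexed risk head.
#
# Convention for the default mode: CT supplies the attention queries and keys
# (after linear projection), PET supplies the values — CT anatomy decides
# where to look, PET metabolism decides what is read out. The fused output is
# softmax(Q K' / sqrt(dk)) V followed by a residual feed-forward block.

#' Fusion configuration
#'
#' @param mode one of `"cross_qk_ct_v_pet"` (default: CT is query/key, PET is
#'   value), `"cross_qk_pet_v_ct"` (roles swapped), `"concat_fc"` (pooled
#'   concatenation + fully connected), `"single_pet"`, `"single_ct"`
#'   (self-attention on one modality).
#' @param use_qformer fuse image features with clinical text through the
#'   Q-Former; when FALSE the pooled image features feed the head directly
#'   (image-only ablation).
#' @param n_queries number of learnable Q-Former query tokens.
#' @param qformer_depth number of Q-Former blocks.
#' @param d_model token dimension (must equal the encoder width).
#' @param heads attention heads.
#' @param mlp_ratio feed-forward hidden multiple.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(mode = c("cross_qk_ct_v_pet", "cross_qk_pet_v_ct",
                                   "concat_fc", "single_pet", "single_ct"),
                          use_qformer = TRUE, n_queries = 8L,
                          qformer_depth = 2L, d_model = 128L, heads = 4L,
                          mlp_ratio = 2) {
  mode <- match.arg(mode)
  if (n_queries < 1) stop("n_queries must be >= 1")
  if (d_model %% heads != 0) stop("d_model must be divisible by heads")
  structure(list(mode = mode, use_qformer = use_qformer,
                 n_queries = as.integer(n_queries),
                 qformer_depth = as.integer(qformer_depth),
                 d_model = as.integer(d_model), heads = as.integer(heads),
                 mlp_ratio = mlp_ratio),
            class = "fusion_config")
}

#' Risk head configuration
#'
#' @param time_embed_dim sinusoidal time-embedding dimension (even).
#' @param mlp_widths integer vector of hidden widths.
#' @param time_scale maximum follow-up (days) used to normalise time to [0,1].
#' @return list of class `risk_head_config`.
#' @export
risk_head_config <- function(time_embed_dim = 16L, mlp_widths = c(64L),
                             time_scale = 4000) {
  if (time_scale <= 0) stop("time_scale must be positive")
  if (time_embed_dim %% 2 != 0) stop("time_embed_dim must be even")
  structure(list(time_embed_dim = as.integer(time_embed_dim),
                 mlp_widths = as.integer(mlp_widths),
                 time_scale = time_scale),
            class = "risk_head_config")
}

## ---- cross-attention fusion ---------------------------------------------

#' Fuse CT and PET token sequences by cross-attention
#'
#' In the default mode queries and keys are linear projections of the CT
#' tokens and values a linear projection of the PET tokens (roles swapped in
#' `cross_qk_pet_v_ct`); single-modality modes feed the same stream as query,
#' key and value, which reduces exactly to self-attention. The attention
#' output passes through a residual feed-forward block.
#'
#' @param ct L x d CT token matrix (may be NULL in `single_pet` mode).
#' @param pet L x d PET token matrix (may be NULL in `single_ct` mode).
#' @param cfg a [fusion_config].
#' @param weights fusion weight tree from [fusion_init] (uses `xfuse`).
#' @return list: `tokens` (fused L x d sequence), `cache`.
#' @export
cross_attention_fuse <- function(ct, pet, cfg, weights) {
  p <- weights$xfuse
  src <- switch(cfg$mode,
                cross_qk_ct_v_pet = list(qk = ct, v = pet),
                cross_qk_pet_v_ct = list(qk = pet, v = ct),
                single_pet = list(qk = pet, v = pet),
                single_ct = list(qk = ct, v = ct),
                stop("cross_attention_fuse not defined for mode ", cfg$mode))
  if (is.null(src$qk) || is.null(src$v)) stop("required modality stream is NULL")
  if (!all(dim(src$qk) == dim(src$v))) stop("token dimension mismatch")
  at <- mha_fwd(src$qk, src$qk, src$v, p$attn, cfg$heads)
  if (any(!is.finite(at$out))) stop("NaN in attention output")
  ln <- layernorm_fwd(at$out, p$ln)
  ffo <- ff_fwd(ln$out, p$ff)
  list(tokens = at$out + ffo$out,
       cache = list(at = at, ln = ln, ff = ffo, mode = cfg$mode))
}

cross_attention_bwd <- function(gy, cache) {
  fb <- ff_bwd(gy, cache$ff$cache)
  lb <- layernorm_bwd(fb$gx, cache$ln$cache)
  ga <- gy + lb$gx
  ab <- mha_bwd(ga, cache$at$cache)
  gqk <- ab$gxq + ab$gxk
  gv <- ab$gxv
  streams <- switch(cache$mode,
                    cross_qk_ct_v_pet = list(gct = gqk, gpet = gv),
                    cross_qk_pet_v_ct = list(gct = gv, gpet = gqk),
                    single_pet = list(gct = NULL, gpet = gqk + gv),
                    single_ct = list(gct = gqk + gv, gpet = NULL))
  c(list(gparams = list(attn = ab$gparams, ln = lb$gparams, ff = fb$gparams)),
    streams)
}

## ---- clinical text stream ------------------------------------------------

.clin_fields <- c("age", "sex", "t", "n", "m", "stage")
.clin_vocab <- c(age = 9L, sex = 2L, t = 4L, n = 4L, m = 1L, stage = 4L)

#' Map a clinical record to per-field vocabulary indices
#'
#' Age is binned by decade (18-19 fall in the first bin); categorical fields
#' are looked up directly. No field is coded as an ordinal scalar.
#'
#' @param record a `clinical_record` (see [simulate_clinical]) or a list/row
#'   with fields age, sex, t_stage, n_stage, m_stage, overall_stage.
#' @return named integer vector of length 6.
#' @export
clinical_index <- function(record) {
  age <- as.numeric(record$age)
  if (is.na(age) || age < 18) stop("age below supported range (18-90)")
  if (age > 90) stop("age above supported range (18-90)")
  idx <- c(age = as.integer(floor(age / 10)),
           sex = match(record$sex, c("male", "female")),
           t = match(record$t_stage, paste0("T", 1:4)),
           n = match(record$n_stage, paste0("N", 0:3)),
           m = match(record$m_stage, "M0"),
           stage = match(record$overall_stage, c("I", "II", "III", "IV")))
  if (anyNA(idx)) stop("category outside vocabulary: ",
                       paste(names(idx)[is.na(idx)], collapse = ", "))
  idx
}

init_clinical_tables <- function(d, sd = 0.02) {
  lapply(.clin_vocab, function(v) init_mat(v, d, sd))
}

#' Embed a clinical record as text tokens
#'
#' One embedding token per field (age decade bin, sex, T, N, M, overall
#' stage), looked up from per-field embedding tables: a 6 x d token matrix.
#'
#' @param record a clinical record (see [clinical_index]).
#' @param tables per-field embedding tables (e.g. `weights$text` from
#'   [fusion_init]).
#' @return 6 x d numeric matrix.
#' @export
encode_clinical <- function(record, tables) {
  idx <- clinical_index(record)
  do.call(rbind, lapply(seq_along(.clin_fields), function(f)
    tables[[.clin_fields[f]]][idx[f], , drop = FALSE]))
}

## ---- Q-Former -------------------------------------------------------------

# one Q-Former block: [queries; text] self-attention, queries cross-attend to
# image memory, feed-forward on queries. Text rows are carried through the
# self-attention residual only.
qformer_block_fwd <- function(q, txt, mem, p, heads) {
  nq <- nrow(q)
  z <- rbind(q, txt)
  l1 <- layernorm_fwd(z, p$ln1)
  sa <- mha_fwd(l1$out, l1$out, l1$out, p$attn, heads)
  z1 <- z + sa$out
  q1 <- z1[seq_len(nq), , drop = FALSE]
  t1 <- z1[-seq_len(nq), , drop = FALSE]
  lx <- layernorm_fwd(q1, p$lnx)
  xa <- mha_fwd(lx$out, mem, mem, p$xattn, heads)
  q2 <- q1 + xa$out
  l2 <- layernorm_fwd(q2, p$ln2)
  ffo <- ff_fwd(l2$out, p$ff)
  list(q = q2 + ffo$out, txt = t1,
       cache = list(l1 = l1, sa = sa, lx = lx, xa = xa, l2 = l2, ff = ffo,
                    nq = nq))
}

qformer_block_bwd <- function(gq, gtxt, cache) {
  nq <- cache$nq
  fb <- ff_bwd(gq, cache$ff$cache)
  l2b <- layernorm_bwd(fb$gx, cache$l2$cache)
  gq2 <- gq + l2b$gx
  xab <- mha_bwd(gq2, cache$xa$cache)
  gmem <- xab$gxk + xab$gxv
  lxb <- layernorm_bwd(xab$gxq, cache$lx$cache)
  gq1 <- gq2 + lxb$gx
  gz1 <- rbind(gq1, gtxt)
  sab <- mha_bwd(gz1, cache$sa$cache)
  l1b <- layernorm_bwd(sab$gxq + sab$gxk + sab$gxv, cache$l1$cache)
  gz <- gz1 + l1b$gx
  list(gparams = list(ln1 = l1b$gparams, attn = sab$gparams,
                      lnx = lxb$gparams, xattn = xab$gparams,
                      ln2 = l2b$gparams, ff = fb$gparams),
       gq = gz[seq_len(nq), , drop = FALSE],
       gtxt = gz[-seq_len(nq), , drop = FALSE],
       gmem = gmem)
}

#' Fuse image features with clinical text through the Q-Former
#'
#' A small set of learnable query tokens self-attends jointly with the text
#' tokens, cross-attends to the image feature sequence, and passes through a
#' feed-forward block, repeated `qformer_depth` times; the output is the final
#' query tokens after layer norm. Attention over image tokens is
#' set-equivariant: permuting the image tokens leaves the output unchanged.
#'
#' @param image_feats L x d image token matrix (fused PET/CT features).
#' @param text 6 x d clinical text tokens from [encode_clinical].
#' @param cfg a [fusion_config] with `use_qformer = TRUE`.
#' @param weights fusion weight tree (uses `queries`, `qblocks`, `qln`).
#' @return list: `tokens` (n_queries x d), `cache`.
#' @export
qformer_fuse <- function(image_feats, text, cfg, weights) {
  if (!cfg$use_qformer) stop("use_qformer is FALSE in this configuration")
  if (any(!is.finite(image_feats))) stop("non-finite image features")
  q <- weights$queries
  txt <- text
  caches <- vector("list", length(weights$qblocks))
  for (i in seq_along(weights$qblocks)) {
    st <- qformer_block_fwd(q, txt, image_feats, weights$qblocks[[i]], cfg$heads)
    q <- st$q
    txt <- st$txt
    caches[[i]] <- st$cache
  }
  ln <- layernorm_fwd(q, weights$qln)
  list(tokens = ln$out, cache = list(blocks = caches, ln = ln))
}

qformer_bwd <- function(gtokens, cache, weights) {
  lb <- layernorm_bwd(gtokens, cache$ln$cache)
  gq <- lb$gx
  gtxt <- matrix(0, length(.clin_fields), ncol(gtokens))
  gmem <- NULL
  gblocks <- vector("list", length(weights$qblocks))
  for (i in rev(seq_along(weights$qblocks))) {
    bb <- qformer_block_bwd(gq, gtxt, cache$blocks[[i]])
    gblocks[[i]] <- bb$gparams
    gq <- bb$gq
    gtxt <- bb$gtxt
    gmem <- if (is.null(gmem)) bb$gmem else gmem + bb$gmem
  }
  list(gparams = list(queries = gq, qblocks = gblocks, qln = lb$gparams),
       gtxt = gtxt, gmem = gmem)
}

## ---- pooled concat + FC ablation ------------------------------------------

#' Concatenate pooled features and apply one linear + nonlinearity
#'
#' Ablation fusion: mean-pooled image vector and mean-pooled text vector are
#' concatenated and mapped through a single linear layer with GELU.
#'
#' @param image_vec pooled image feature vector.
#' @param text_vec pooled text vector (zeros when no text is used).
#' @param weights list with `W` ((d_img + d_text) x d_out) and `b`.
#' @return list: `out` (vector), `pre` (pre-nonlinearity vector).
#' @export
concat_fc_fuse <- function(image_vec, text_vec, weights) {
  z <- c(image_vec, text_vec)
  pre <- as.vector(z %*% weights$W) + weights$b
  list(out = gelu(pre), pre = pre, z = z)
}

## ---- risk head -------------------------------------------------------------

# multi-resolution sinusoidal embedding of normalized time s in [0, 1]
time_embedding <- function(t, dim, time_scale) {
  s <- t / time_scale
  half <- dim %/% 2
  # geometric frequency ladder from pi to 50*pi over the normalized horizon
  freqs <- pi * exp(log(50) * (seq_len(half) - 1) / max(half - 1, 1))
  c(sin(s * freqs), cos(s * freqs))
}

init_head <- function(d_in, cfg_head, sd = 0.05) {
  widths <- c(d_in + cfg_head$time_embed_dim, cfg_head$mlp_widths, 1L)
  list(layers = lapply(seq_len(length(widths) - 1), function(i)
    init_linear(widths[i], widths[i + 1], sd)))
}

# X: B x (d + time_embed_dim) matrix of pooled-feature||time-embedding rows
head_fwd <- function(X, head) {
  caches <- list()
  a <- X
  nl <- length(head$layers)
  for (i in seq_len(nl)) {
    li <- linear_fwd(a, head$layers[[i]])
    if (i < nl) {
      caches[[i]] <- list(lin = li$cache, pre = li$out)
      a <- gelu(li$out)
    } else {
      caches[[i]] <- list(lin = li$cache, pre = NULL)
      a <- li$out
    }
  }
  list(out = a, cache = caches)
}

head_bwd <- function(gout, cache) {
  nl <- length(cache)
  g <- gout
  glayers <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    if (!is.null(cache[[i]]$pre)) g <- g * gelu_grad(cache[[i]]$pre)
    lb <- linear_bwd(g, cache[[i]]$lin)
    glayers[[i]] <- lb$gparams
    g <- lb$gx
  }
  list(gparams = list(layers = glayers), gX = g)
}

#' Time-indexed risk score
#'
#' Mean-pools the fused query tokens, concatenates a multi-resolution
#' sinusoidal embedding of t / time_scale, and applies the MLP head. The
#' returned scalar is the UNLINKED network output N(y, t); the sigmoid link is
#' applied inside the survival loss.
#'
#' @param fused n_tokens x d fused feature matrix (or a vector).
#' @param t nonnegative time (days).
#' @param head_cfg a [risk_head_config].
#' @param weights fusion weight tree (uses `head`).
#' @return scalar risk score.
#' @export
risk_score <- function(fused, t, head_cfg, weights) {
  if (t < 0) stop("negative time")
  pooled <- if (is.matrix(fused)) colMeans(fused) else fused
  x <- c(pooled, time_embedding(t, head_cfg$time_embed_dim, head_cfg$time_scale))
  head_fwd(matrix(x, 1), weights$head)$out[1, 1]
}

## ---- weight initialisation --------------------------------------------------

#' Initialise all fusion-stage weights
#'
#' @param cfg a [fusion_config].
#' @param head_cfg a [risk_head_config].
#' @param seed integer seed.
#' @return nested weight tree: `xfuse`, `concat`, `text`, `queries`,
#'   `qblocks`, `qln`, `head`.
#' @export
fusion_init <- function(cfg, head_cfg, seed = 1L) {
  d <- cfg$d_model
  hid <- round(cfg$mlp_ratio * d)
  with_seed(seed, {
    list(xfuse = list(attn = init_mha(d), ln = init_layernorm(d),
                      ff = init_ff(d, hid)),
         concat = list(W = init_mat(2 * d, d), b = numeric(d)),
         text = init_clinical_tables(d),
         queries = init_mat(cfg$n_queries, d),
         qblocks = lapply(seq_len(cfg$qformer_depth), function(i)
           init_cross_block(d, hid)),
         qln = init_layernorm(d),
         head = init_head(d, head_cfg))
  })
}

## ---- full fusion forward/backward for one subject ---------------------------

# ct_tok / pet_tok: frozen encoder token matrices (L x d) or NULL.
# Returns pooled d-vector feeding the risk head, plus cache.
fuse_subject_fwd <- function(ct_tok, pet_tok, record, cfg, weights) {
  if (cfg$mode == "concat_fc") {
    pi_ct <- if (is.null(ct_tok)) numeric(cfg$d_model) else colMeans(ct_tok)
    pi_pet <- if (is.null(pet_tok)) numeric(cfg$d_model) else colMeans(pet_tok)
    cf <- concat_fc_fuse(pi_ct, pi_pet, weights$concat)
    mem <- matrix(cf$out, 1)
    xcache <- list(kind = "concat", cf = cf)
  } else {
    xf <- cross_attention_fuse(ct_tok, pet_tok, cfg, weights)
    mem <- xf$tokens
    xcache <- list(kind = "cross", xf = xf)
  }
  if (cfg$use_qformer) {
    txt <- encode_clinical(record, weights$text)
    qf <- qformer_fuse(mem, txt, cfg, weights)
    pooled <- colMeans(qf$tokens)
    list(pooled = pooled,
         cache = list(x = xcache, qf = qf, idx = clinical_index(record),
                      n_tok = nrow(qf$tokens), cfg = cfg))
  } else {
    list(pooled = colMeans(mem),
         cache = list(x = xcache, qf = NULL, idx = NULL, n_tok = nrow(mem),
                      cfg = cfg))
  }
}

# gpooled: gradient of the loss wrt the pooled d-vector.
# Returns gradient tree over the trainable fusion weights (head excluded).
fuse_subject_bwd <- function(gpooled, cache, weights) {
  cfg <- cache$cfg
  d <- length(gpooled)
  gtree <- list()
  if (cfg$use_qformer) {
    gtok <- matrix(rep(gpooled / cache$n_tok, each = cache$n_tok),
                   cache$n_tok, d)
    qb <- qformer_bwd(gtok, cache$qf$cache, weights)
    gtree$queries <- qb$gparams$queries
    gtree$qblocks <- qb$gparams$qblocks
    gtree$qln <- qb$gparams$qln
    # scatter text-token grads into the embedding tables
    gtables <- tree_zero(weights$text)
    for (f in seq_along(.clin_fields)) {
      fld <- .clin_fields[f]
      gtables[[fld]][cache$idx[f], ] <-
        gtables[[fld]][cache$idx[f], ] + qb$gtxt[f, ]
    }
    gtree$text <- gtables
    gmem <- qb$gmem
  } else {
    gmem <- matrix(rep(gpooled / cache$n_tok, each = cache$n_tok),
                   cache$n_tok, d)
  }
  if (cache$x$kind == "concat") {
    cf <- cache$x$cf
    gpre <- as.vector(gmem) * gelu_grad(cf$pre)
    gtree$concat <- list(W = outer(cf$z, gpre), b = gpre)
  } else {
    xb <- cross_attention_bwd(gmem, cache$x$xf$cache)
    gtree$xfuse <- xb$gparams
  }
  gtree
}
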