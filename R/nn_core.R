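# Minimal dense neural-net primitives with explicit forward/backward passes.
# Parameters and gradients are nested named lists of numeric matrices/vectors;
# every *_fwd returns list(out, cache) and the matching *_bwd consumes the cache
# and the upstream gradient, returning list(gparams, gx [, gmem]).

sigmoid <- function(x) stats::plogis(x)

# log(sigmoid(x)) = -softplus(-x), computed stably
log_sigmoid <- function(x) stats::plogis(x, log.p = TRUE)

# sigmoid approximation of GELU, x * sigma(1.702 x), and its derivative
gelu <- function(x) {
  if (is.matrix(x)) cpp_gelu(x) else x * stats::plogis(1.702 * x)
}

gelu_grad <- function(x) {
  if (is.matrix(x)) cpp_gelu_grad(x) else {
    s <- stats::plogis(1.702 * x)
    s + 1.702 * x * s * (1 - s)
  }
}

softmax_rows <- function(a) {
  m <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  e <- exp(a - m)
  e / rowSums(e)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

add_rowvec <- function(x, b) x + rep(b, each = nrow(x))

## ---- parameter trees ---------------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(el) tree_map(f, el)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

## ---- AdamW -------------------------------------------------------------

adamw_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  if (weight_decay > 0) {
    params <- tree_map(function(p) p * (1 - lr * weight_decay), params)
  }
  list(params = params, state = state)
}

## ---- initialisation ----------------------------------------------------

init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

init_linear <- function(d_in, d_out, sd = 0.02) {
  list(W = init_mat(d_in, d_out, sd), b = numeric(d_out))
}

init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

init_mha <- function(d, sd = 0.02) {
  list(Wq = init_mat(d, d, sd), bq = numeric(d),
       Wk = init_mat(d, d, sd), bk = numeric(d),
       Wv = init_mat(d, d, sd), bv = numeric(d),
       Wo = init_mat(d, d, sd), bo = numeric(d))
}

init_ff <- function(d, d_hidden, sd = 0.02) {
  list(W1 = init_mat(d, d_hidden, sd), b1 = numeric(d_hidden),
       W2 = init_mat(d_hidden, d, sd), b2 = numeric(d))
}

init_block <- function(d, d_hidden, sd = 0.02) {
  list(ln1 = init_layernorm(d), attn = init_mha(d, sd),
       ln2 = init_layernorm(d), ff = init_ff(d, d_hidden, sd))
}

# block with an extra cross-attention sub-layer (Q-Former style)
init_cross_block <- function(d, d_hidden, sd = 0.02) {
  list(ln1 = init_layernorm(d), attn = init_mha(d, sd),
       lnx = init_layernorm(d), xattn = init_mha(d, sd),
       ln2 = init_layernorm(d), ff = init_ff(d, d_hidden, sd))
}

## ---- linear ------------------------------------------------------------

linear_fwd <- function(x, p) {
  list(out = add_rowvec(x %*% p$W, p$b), cache = list(x = x, p = p))
}

linear_bwd <- function(gy, cache) {
  x <- cache$x; p <- cache$p
  list(gparams = list(W = crossprod(x, gy), b = colSums(gy)),
       gx = tcrossprod(gy, p$W))
}

## ---- layer norm --------------------------------------------------------

layernorm_fwd <- function(x, p, eps = 1e-5) {
  f <- cpp_layernorm_fwd(x, p$g, p$b, eps)
  list(out = f$out, cache = list(xhat = f$xhat, inv = as.vector(f$inv), p = p))
}

layernorm_bwd <- function(gy, cache) {
  b <- cpp_layernorm_bwd(gy, cache$xhat, cache$inv, cache$p$g)
  list(gparams = list(g = as.vector(b$gg), b = as.vector(b$gb)), gx = b$gx)
}

## ---- multi-head attention ----------------------------------------------
# xq: (B*Lq) x d stacked query source; xk/xv: (B*Lk) x d key/value sources.
# The compiled kernel loops over batch items and heads; everything else is
# dense BLAS. mha_fwd/mha_bwd are the single-item (B = 1) case.

mhab_fwd <- function(xq, xk, xv, Lq, Lk, B, p, heads) {
  stopifnot(ncol(xq) %% heads == 0)
  f <- cpp_mhab_fwd(xq, xk, xv, Lq, Lk, B, heads,
                    p$Wq, p$bq, p$Wk, p$bk, p$Wv, p$bv, p$Wo, p$bo)
  list(out = f$out,
       cache = list(xq = xq, xk = xk, xv = xv, Q = f$Q, K = f$K, V = f$V,
                    O = f$O, P = f$P, p = p, heads = heads,
                    Lq = Lq, Lk = Lk, B = B))
}

mhab_bwd <- function(gy, cache) {
  p <- cache$p
  b <- cpp_mhab_bwd(gy, cache$xq, cache$xk, cache$xv, cache$Q, cache$K,
                    cache$V, cache$O, cache$P, cache$Lq, cache$Lk, cache$B,
                    cache$heads, p$Wq, p$Wk, p$Wv, p$Wo)
  list(gparams = list(Wq = b$gWq, bq = as.vector(b$gbq),
                      Wk = b$gWk, bk = as.vector(b$gbk),
                      Wv = b$gWv, bv = as.vector(b$gbv),
                      Wo = b$gWo, bo = as.vector(b$gbo)),
       gxq = b$gxq, gxk = b$gxk, gxv = b$gxv)
}

mha_fwd <- function(xq, xk, xv, p, n_heads) {
  mhab_fwd(xq, xk, xv, nrow(xq), nrow(xk), 1L, p, n_heads)
}

mha_bwd <- function(gy, cache) mhab_bwd(gy, cache)

## ---- feed-forward (GELU MLP) --------------------------------------------

ff_fwd <- function(x, p) {
  h <- add_rowvec(x %*% p$W1, p$b1)
  a <- gelu(h)
  out <- add_rowvec(a %*% p$W2, p$b2)
  list(out = out, cache = list(x = x, h = h, a = a, p = p))
}

ff_bwd <- function(gy, cache) {
  p <- cache$p
  gW2 <- crossprod(cache$a, gy)
  gb2 <- colSums(gy)
  ga <- tcrossprod(gy, p$W2)
  gh <- ga * gelu_grad(cache$h)
  list(gparams = list(W1 = crossprod(cache$x, gh), b1 = colSums(gh),
                      W2 = gW2, b2 = gb2),
       gx = tcrossprod(gh, p$W1))
}

## ---- pre-LN transformer block (self-attention) ---------------------------

block_fwd <- function(x, p, n_heads) {
  l1 <- layernorm_fwd(x, p$ln1)
  at <- mha_fwd(l1$out, l1$out, l1$out, p$attn, n_heads)
  x1 <- x + at$out
  l2 <- layernorm_fwd(x1, p$ln2)
  ffo <- ff_fwd(l2$out, p$ff)
  list(out = x1 + ffo$out, cache = list(l1 = l1, at = at, l2 = l2, ff = ffo))
}

block_bwd <- function(gy, cache) {
  fb <- ff_bwd(gy, cache$ff$cache)
  l2b <- layernorm_bwd(fb$gx, cache$l2$cache)
  gx1 <- gy + l2b$gx
  ab <- mha_bwd(gx1, cache$at$cache)
  gl1 <- ab$gxq + ab$gxk + ab$gxv
  l1b <- layernorm_bwd(gl1, cache$l1$cache)
  list(gparams = list(ln1 = l1b$gparams, attn = ab$gparams,
                      ln2 = l2b$gparams, ff = fb$gparams),
       gx = gx1 + l1b$gx)
}

## ---- pre-LN cross-attention block (queries x attend to memory m) ---------

cross_block_fwd <- function(x, m, p, n_heads) {
  l1 <- layernorm_fwd(x, p$ln1)
  at <- mha_fwd(l1$out, l1$out, l1$out, p$attn, n_heads)
  x1 <- x + at$out
  lx <- layernorm_fwd(x1, p$lnx)
  xa <- mha_fwd(lx$out, m, m, p$xattn, n_heads)
  x2 <- x1 + xa$out
  l2 <- layernorm_fwd(x2, p$ln2)
  ffo <- ff_fwd(l2$out, p$ff)
  list(out = x2 + ffo$out,
       cache = list(l1 = l1, at = at, lx = lx, xa = xa, l2 = l2, ff = ffo))
}

cross_block_bwd <- function(gy, cache) {
  fb <- ff_bwd(gy, cache$ff$cache)
  l2b <- layernorm_bwd(fb$gx, cache$l2$cache)
  gx2 <- gy + l2b$gx
  xab <- mha_bwd(gx2, cache$xa$cache)
  gm <- xab$gxk + xab$gxv
  lxb <- layernorm_bwd(xab$gxq, cache$lx$cache)
  gx1 <- gx2 + lxb$gx
  ab <- mha_bwd(gx1, cache$at$cache)
  l1b <- layernorm_bwd(ab$gxq + ab$gxk + ab$gxv, cache$l1$cache)
  list(gparams = list(ln1 = l1b$gparams, attn = ab$gparams,
                      lnx = lxb$gparams, xattn = xab$gparams,
                      ln2 = l2b$gparams, ff = fb$gparams),
       gx = gx1 + l1b$gx,
       gm = gm)
}

## ---- seeds ---------------------------------------------------------------

#' Derive a reproducible sub-seed from a root seed and a stream label
#'
#' All randomness in the package flows through explicit integer seeds. Distinct
#' pipeline stages draw from named substreams so that, e.g., data simulation
#' and weight initialisation are decoupled yet both are pure functions of the
#' root seed.
#'
#' @param root integer root seed.
#' @param label character stream label.
#' @param k optional integer index within the stream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(root, label, k = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  val <- (as.numeric(root) * 48271 + h * 16807 + as.numeric(k) * 69621)
  as.integer(val %% 2147483646)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
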