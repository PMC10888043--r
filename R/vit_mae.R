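# Patch-transformer encoders and masked-autoencoder pretraining.
#
# The encoder is a pre-LN vision transformer over non-overlapping square
# patches with learned positional embeddings attached to ORIGINAL patch
# positions, so encoding only the visible subset remains position-faithful.
# MAE pretraining reconstructs the masked patches from the visible remainder;
# the reconstruction target is each patch standardized to zero mean and unit
# variance, and the loss is mean squared error over masked positions only.

#' Vision-transformer configuration
#'
#' @param patch_size patch side in pixels.
#' @param depth number of encoder blocks.
#' @param width encoder token dimension (divisible by `heads`).
#' @param heads attention heads.
#' @param decoder_depth,decoder_width MAE decoder size.
#' @param mlp_ratio feed-forward hidden width as a multiple of `width`.
#' @return list of class `vit_config`.
#' @export
vit_config <- function(patch_size = 8L, depth = 4L, width = 128L, heads = 4L,
                       decoder_depth = 2L, decoder_width = 64L, mlp_ratio = 2) {
  if (width %% heads != 0) stop("width must be divisible by heads")
  if (decoder_width %% heads != 0) stop("decoder_width must be divisible by heads")
  structure(list(patch_size = as.integer(patch_size), depth = as.integer(depth),
                 width = as.integer(width), heads = as.integer(heads),
                 decoder_depth = as.integer(decoder_depth),
                 decoder_width = as.integer(decoder_width),
                 mlp_ratio = mlp_ratio),
            class = "vit_config")
}

#' Split a square plane into flattened patches
#'
#' Patches are ordered row-major over the patch grid and each patch is
#' flattened row-major, giving an L x patch_size^2 matrix with
#' L = (side/patch_size)^2. [unpatchify] is its exact inverse.
#'
#' @param plane square numeric matrix (or a `model_input`).
#' @param patch_size patch side; must divide the plane side.
#' @return L x patch_size^2 numeric matrix.
#' @export
patchify <- function(plane, patch_size) {
  if (inherits(plane, "model_input")) plane <- plane$plane
  n <- nrow(plane)
  if (ncol(plane) != n) stop("plane must be square")
  if (n %% patch_size != 0) stop("plane side not divisible by patch_size")
  g <- n %/% patch_size
  out <- matrix(0, g * g, patch_size^2)
  for (l in seq_len(g * g)) {
    r <- (l - 1L) %/% g
    cc <- (l - 1L) %% g
    blk <- plane[(r * patch_size + 1):(r * patch_size + patch_size),
                 (cc * patch_size + 1):(cc * patch_size + patch_size)]
    out[l, ] <- as.vector(t(blk))
  }
  out
}

#' Reassemble a plane from flattened patches
#'
#' @param patches L x patch_size^2 matrix as produced by [patchify].
#' @param patch_size patch side.
#' @return the reconstructed square matrix.
#' @export
unpatchify <- function(patches, patch_size) {
  L <- nrow(patches)
  g <- as.integer(sqrt(L))
  if (g * g != L) stop("patch count is not a perfect square")
  n <- g * patch_size
  plane <- matrix(0, n, n)
  for (l in seq_len(L)) {
    r <- (l - 1L) %/% g
    cc <- (l - 1L) %% g
    plane[(r * patch_size + 1):(r * patch_size + patch_size),
          (cc * patch_size + 1):(cc * patch_size + patch_size)] <-
      matrix(patches[l, ], patch_size, patch_size, byrow = TRUE)
  }
  plane
}

#' Draw a random mask plan
#'
#' Uniformly samples floor(ratio * n_patches) patch indices without
#' replacement; deterministic given the seed.
#'
#' @param n_patches number of patches.
#' @param ratio mask ratio in [0, 1); the reference setting is 0.75.
#' @param seed integer seed.
#' @return list of class `mask_plan`: `n_patches`, `masked_idx`,
#'   `visible_idx`, `ratio`.
#' @export
plan_mask <- function(n_patches, ratio = 0.75, seed = 1L) {
  if (ratio < 0 || ratio >= 1) stop("ratio must be in [0, 1)")
  n_mask <- floor(ratio * n_patches)
  masked <- if (n_mask > 0)
    with_seed(seed, sort(sample.int(n_patches, n_mask))) else integer(0)
  structure(list(n_patches = as.integer(n_patches),
                 masked_idx = as.integer(masked),
                 visible_idx = setdiff(seq_len(n_patches), masked),
                 ratio = ratio),
            class = "mask_plan")
}

#' Initialise ViT + MAE-decoder weights
#'
#' @param cfg a [vit_config].
#' @param n_patches total patches per plane.
#' @param seed integer seed.
#' @return nested parameter list with `enc` and `dec` trees.
#' @export
vit_init <- function(cfg, n_patches, seed = 1L) {
  p2 <- cfg$patch_size^2
  with_seed(seed, {
    enc <- list(embed = init_linear(p2, cfg$width),
                pos = init_mat(n_patches, cfg$width),
                blocks = lapply(seq_len(cfg$depth), function(i)
                  init_block(cfg$width, round(cfg$mlp_ratio * cfg$width))),
                ln = init_layernorm(cfg$width))
    dec <- list(embed = init_linear(cfg$width, cfg$decoder_width),
                mask = init_mat(1, cfg$decoder_width),
                pos = init_mat(n_patches, cfg$decoder_width),
                blocks = lapply(seq_len(cfg$decoder_depth), function(i)
                  init_block(cfg$decoder_width,
                             round(cfg$mlp_ratio * cfg$decoder_width))),
                ln = init_layernorm(cfg$decoder_width),
                pred = init_linear(cfg$decoder_width, p2))
    list(enc = enc, dec = dec)
  })
}

#' Encode patches with the transformer
#'
#' Tokens are linear patch embeddings plus the learned positional embedding of
#' each patch's ORIGINAL position (`pos_idx`), passed through the encoder
#' blocks and a final layer norm. Encoding a visible-only subset is therefore
#' position-faithful.
#'
#' @param patches L_vis x patch_size^2 matrix of (visible) patches.
#' @param weights parameter tree from [vit_init] (the `enc` part is used).
#' @param cfg a [vit_config].
#' @param pos_idx integer positions of the supplied patches in the full grid.
#' @return list: `tokens` (L_vis x width matrix), `cache` (for backprop).
#' @export
vit_encode <- function(patches, weights, cfg, pos_idx = seq_len(nrow(patches))) {
  enc <- weights$enc
  if (ncol(patches) != nrow(enc$embed$W)) stop("patch dimension mismatch")
  emb <- linear_fwd(patches, enc$embed)
  x <- emb$out + enc$pos[pos_idx, , drop = FALSE]
  caches <- vector("list", length(enc$blocks))
  for (i in seq_along(enc$blocks)) {
    bl <- block_fwd(x, enc$blocks[[i]], cfg$heads)
    x <- bl$out
    caches[[i]] <- bl$cache
  }
  ln <- layernorm_fwd(x, enc$ln)
  list(tokens = ln$out,
       cache = list(emb = emb, blocks = caches, ln = ln, pos_idx = pos_idx,
                    cfg = cfg))
}

# backward through vit_encode; returns grads for weights$enc and (unused) input
vit_encode_bwd <- function(gtokens, cache, enc) {
  lb <- layernorm_bwd(gtokens, cache$ln$cache)
  gx <- lb$gx
  gblocks <- vector("list", length(enc$blocks))
  for (i in rev(seq_along(enc$blocks))) {
    bb <- block_bwd(gx, cache$blocks[[i]])
    gblocks[[i]] <- bb$gparams
    gx <- bb$gx
  }
  gpos <- matrix(0, nrow(enc$pos), ncol(enc$pos))
  gpos[cache$pos_idx, ] <- gx
  eb <- linear_bwd(gx, cache$emb$cache)
  list(embed = eb$gparams, pos = gpos, blocks = gblocks, ln = lb$gparams)
}

# standardize each patch (row) to zero mean / unit variance
standardize_patches <- function(target, eps = 1e-6) {
  mu <- rowMeans(target)
  va <- rowMeans((target - mu)^2)
  (target - mu) / sqrt(va + eps)
}

#' MAE reconstruction loss
#'
#' Mean squared error over MASKED patch positions only, with each target patch
#' standardized to zero mean and unit variance before comparison.
#'
#' @param decoded L x patch_size^2 matrix of decoded patches (all positions).
#' @param target L x patch_size^2 matrix of ground-truth patches.
#' @param plan a [plan_mask] result with a nonempty mask set.
#' @return nonnegative scalar.
#' @export
mae_reconstruction_loss <- function(decoded, target, plan) {
  if (length(plan$masked_idx) == 0) stop("empty mask set")
  tstd <- standardize_patches(target)
  d <- decoded[plan$masked_idx, , drop = FALSE] -
    tstd[plan$masked_idx, , drop = FALSE]
  mean(d^2)
}

# one MAE forward+backward on a single plane; returns loss and parameter grads
mae_step <- function(patches, plan, params, cfg, compute_grads = TRUE) {
  L <- nrow(patches)
  vis <- plan$visible_idx
  enc_out <- vit_encode(patches[vis, , drop = FALSE], params, cfg, pos_idx = vis)
  demb <- linear_fwd(enc_out$tokens, params$dec$embed)
  z <- matrix(rep(params$dec$mask, each = L), L, cfg$decoder_width)
  z[vis, ] <- demb$out
  z <- z + params$dec$pos
  dcaches <- vector("list", length(params$dec$blocks))
  for (i in seq_along(params$dec$blocks)) {
    bl <- block_fwd(z, params$dec$blocks[[i]], cfg$heads)
    z <- bl$out
    dcaches[[i]] <- bl$cache
  }
  dln <- layernorm_fwd(z, params$dec$ln)
  pred <- linear_fwd(dln$out, params$dec$pred)
  tstd <- standardize_patches(patches)
  midx <- plan$masked_idx
  resid <- pred$out[midx, , drop = FALSE] - tstd[midx, , drop = FALSE]
  loss <- mean(resid^2)
  if (!compute_grads) return(list(loss = loss))
  gpred <- matrix(0, L, ncol(pred$out))
  gpred[midx, ] <- 2 * resid / length(resid)
  pb <- linear_bwd(gpred, pred$cache)
  lnb <- layernorm_bwd(pb$gx, dln$cache)
  gz <- lnb$gx
  gdblocks <- vector("list", length(params$dec$blocks))
  for (i in rev(seq_along(params$dec$blocks))) {
    bb <- block_bwd(gz, dcaches[[i]])
    gdblocks[[i]] <- bb$gparams
    gz <- bb$gx
  }
  gpos_dec <- gz
  gmask <- matrix(colSums(gz[midx, , drop = FALSE]), 1)
  gdemb_out <- gz[vis, , drop = FALSE]
  deb <- linear_bwd(gdemb_out, demb$cache)
  genc <- vit_encode_bwd(deb$gx, enc_out$cache, params$enc)
  list(loss = loss,
       grads = list(enc = genc,
                    dec = list(embed = deb$gparams, mask = gmask,
                               pos = gpos_dec, blocks = gdblocks,
                               ln = lnb$gparams, pred = pb$gparams)))
}

#' Pretrain a modality encoder with masked autoencoding
#'
#' Runs MAE over a list of 2-D planes of one modality: per image a fresh
#' uniform mask plan is drawn, the visible patches are encoded, a light
#' transformer decoder reconstructs all positions, and the standardized-patch
#' MSE over masked positions is minimised with AdamW (betas (0.9, 0.95),
#' weight decay 1e-2 by default, matching the reference recipe).
#'
#' @param planes list of square numeric matrices (or `model_input`s), one
#'   modality only.
#' @param cfg a [vit_config].
#' @param epochs training epochs (0 returns the initialisation and an empty
#'   trace).
#' @param batch_size minibatch size for gradient accumulation.
#' @param lr AdamW learning rate.
#' @param betas AdamW beta pair.
#' @param weight_decay AdamW decoupled weight decay.
#' @param mask_ratio mask ratio (reference value 0.75).
#' @param seed integer seed controlling init, shuffling and mask plans.
#' @return list of class `mae_fit`: `weights`, `trace` (per-epoch mean loss),
#'   `cfg`, `mask_ratio`, `seed`.
#' @export
mae_pretrain <- function(planes, cfg = vit_config(), epochs = 30L,
                         batch_size = 16L, lr = 1.5e-3, betas = c(0.9, 0.95),
                         weight_decay = 1e-2, mask_ratio = 0.75, seed = 1L) {
  if (length(planes) < 1) stop("need at least one image")
  pat <- lapply(planes, patchify, patch_size = cfg$patch_size)
  L <- nrow(pat[[1]])
  params <- vit_init(cfg, L, derive_seed(seed, "vit_init"))
  if (epochs == 0) {
    return(structure(list(weights = params, trace = numeric(0), cfg = cfg,
                          mask_ratio = mask_ratio, seed = seed),
                     class = "mae_fit"))
  }
  opt <- adamw_init(params)
  trace <- numeric(epochs)
  n <- length(pat)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "shuffle", ep), sample.int(n))
    ep_loss <- 0
    done <- 0L
    while (done < n) {
      take <- ord[(done + 1):min(done + batch_size, n)]
      plans <- lapply(take, function(i)
        plan_mask(L, mask_ratio, derive_seed(seed, "mask", ep * 100000L + i)))
      st <- maeb_step(pat[take], plans, params, cfg)
      if (!is.finite(st$loss)) stop("divergence: NaN/Inf reconstruction loss")
      upd <- adamw_step(params, st$grads, opt, lr = lr, betas = betas,
                        weight_decay = weight_decay)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + st$loss * length(take)
      done <- done + length(take)
    }
    trace[ep] <- ep_loss / n
  }
  structure(list(weights = params, trace = trace, cfg = cfg,
                 mask_ratio = mask_ratio, seed = seed),
            class = "mae_fit")
}
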