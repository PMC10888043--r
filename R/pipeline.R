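# Pipeline orchestration: pretraining -> fusion fine-tuning -> evaluation,
# plus the ablation grid over modality / fusion / Q-Former / loss axes.
# Every stochastic stage draws its seed from the root seed through a named
# substream, so a run report is a pure function of (config, cohort, seed).

#' Build an experiment configuration
#'
#' The `desk` preset runs the full pipeline at laptop scale (64 px inputs,
#' a small ViT, tens of epochs); the `full` preset records the reference-scale
#' training recipe (224 px, ViT-B scale, MAE batch 128 for 1000 epochs, then
#' batch 256 for 300 epochs with 10 warm-up epochs at lr 1e-4) and is intended
#' for full-scale runs on real cohorts.
#'
#' @param seed root seed.
#' @param preset `"desk"` or `"full"`.
#' @param n_subjects cohort size when simulating.
#' @param endpoints endpoints to fit and report.
#' @param modality `"pet+ct"`, `"pet"` or `"ct"`.
#' @param fusion `"cross"` (CT queries/keys, PET values), `"swapped"` or
#'   `"concat_fc"`.
#' @param qformer use the Q-Former image-text fusion.
#' @param loss_weights named weights over cox/proposed/focal components.
#' @param ... replacement values for any top-level config entry (e.g.
#'   `pretrain = list(...)`).
#' @return nested list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, preset = c("desk", "full"),
                              n_subjects = 200L, endpoints = "OS",
                              modality = "pet+ct", fusion = "cross",
                              qformer = TRUE,
                              loss_weights = c(cox = 0, proposed = 1, focal = 1),
                              ...) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    list(input = preprocess_config(input_side = 64L),
         vit = vit_config(patch_size = 8L, depth = 2L, width = 64L, heads = 4L,
                          decoder_depth = 1L, decoder_width = 32L),
         d_model = 64L,
         pretrain = list(epochs = 30L, batch_size = 8L, lr = 3e-3,
                         betas = c(0.9, 0.95), weight_decay = 1e-2,
                         mask_ratio = 0.75),
         finetune = list(epochs = 50L, warmup = 10L, lr = 5e-3, batch_size = 20L,
                         avg_last = 20L, betas = c(0.9, 0.999),
                         weight_decay = 1e-3),
         eval = list(n_bootstrap = 200L),
         fusion_pool = 2L,
         phantom = phantom_params(),
         hazard = hazard_model())
  } else {
    list(input = preprocess_config(input_side = 224L),
         vit = vit_config(patch_size = 16L, depth = 12L, width = 768L,
                          heads = 12L, decoder_depth = 8L, decoder_width = 512L),
         d_model = 768L,
         pretrain = list(epochs = 1000L, batch_size = 128L, lr = 1.5e-4,
                         betas = c(0.9, 0.95), weight_decay = 1e-2,
                         mask_ratio = 0.75),
         finetune = list(epochs = 300L, warmup = 10L, lr = 1e-4, batch_size = 256L, avg_last = 1L,
                         betas = c(0.9, 0.999), weight_decay = 5e-2),
         eval = list(n_bootstrap = 1000L),
         fusion_pool = 1L,
         phantom = phantom_params(image_side = 224L, tumor_radius_range = c(10, 40)),
         hazard = hazard_model())
  }
  cfg <- c(list(seed = as.integer(seed), preset = preset,
                n_subjects = as.integer(n_subjects), endpoints = endpoints,
                split = c(train = 0.8, eval = 0.2),
                modality = match.arg(modality, c("pet+ct", "pet", "ct")),
                fusion = match.arg(fusion, c("cross", "swapped", "concat_fc")),
                qformer = isTRUE(qformer),
                loss_weights = loss_weights,
                n_queries = 8L, qformer_depth = 2L,
                time_embed_dim = 16L, mlp_widths = c(32L)),
           base)
  dots <- list(...)
  for (k in seq_along(dots)) {
    nm <- names(dots)[k]
    dv <- dots[[k]]
    if (is.list(dv) && is.list(cfg[[nm]]) &&
        !inherits(cfg[[nm]], c("preprocess_config", "vit_config",
                               "phantom_params", "hazard_model"))) {
      cfg[[nm]][names(dv)] <- dv
    } else {
      cfg[[nm]] <- dv
    }
  }
  if (cfg$finetune$warmup > cfg$finetune$epochs && cfg$finetune$epochs > 0)
    stop("warmup must not exceed epochs")
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_experiment_config`, an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' @rdname read_experiment_config
#' @param cfg an `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  flat <- cfg
  flat$input <- unclass(flat$input)
  flat$vit <- unclass(flat$vit)
  flat$phantom <- unclass(flat$phantom)
  flat$hazard <- lapply(unclass(flat$hazard), function(x)
    if (!is.null(names(x)) && length(x) > 1) as.list(x) else x)
  yaml::write_yaml(flat, path, precision = 15L)
  invisible(path)
}

fusion_mode_of <- function(cfg) {
  if (cfg$modality == "pet") "single_pet"
  else if (cfg$modality == "ct") "single_ct"
  else switch(cfg$fusion, cross = "cross_qk_ct_v_pet",
              swapped = "cross_qk_pet_v_ct", concat_fc = "concat_fc")
}

fusion_cfg_of <- function(cfg) {
  fusion_config(mode = fusion_mode_of(cfg), use_qformer = cfg$qformer,
                n_queries = cfg$n_queries, qformer_depth = cfg$qformer_depth,
                d_model = cfg$d_model, heads = cfg$vit$heads,
                mlp_ratio = cfg$vit$mlp_ratio)
}

#' Preprocess every cohort volume into 2-D model inputs
#'
#' Bandpass-normalizes each volume and reduces it to the mask-selected axial
#' slice at `input_side` resolution.
#'
#' @param cohort an `mm_cohort` with images.
#' @param cfg a [preprocess_config].
#' @return list with per-modality named lists of planes.
#' @export
cohort_planes <- function(cohort, cfg = preprocess_config(input_side = 64L)) {
  ids <- cohort$clinical$subject_id
  ct <- list(); pet <- list()
  for (id in ids) {
    im <- cohort$images[[id]]
    ct[[id]] <- volume_to_input(bandpass_normalize(im$ct, cfg), im$mask, cfg)$plane
    pet[[id]] <- volume_to_input(bandpass_normalize(im$pet, cfg), im$mask, cfg)$plane
  }
  list(ct = ct, pet = pet)
}

#' Split subject ids into train and evaluation sets
#'
#' @param ids subject ids.
#' @param frac training fraction.
#' @param seed integer seed.
#' @return list with `train` and `eval` id vectors (disjoint).
#' @export
split_cohort <- function(ids, frac = 0.8, seed = 1L) {
  n <- length(ids)
  tr <- with_seed(derive_seed(seed, "split"),
                  sort(sample.int(n, round(frac * n))))
  list(train = ids[tr], eval = ids[-tr])
}

#' Pretrain the per-modality encoders
#'
#' Runs independent MAE pretraining for each modality required by the config
#' (no PET/CT pairing is needed); the resulting encoders are frozen
#' downstream.
#'
#' @param planes output of [cohort_planes] (or a list with `ct`/`pet` plane
#'   lists); only training subjects should be included.
#' @param config an [experiment_config].
#' @return list of class `mm_checkpoints` with `ct` and `pet` `mae_fit`
#'   slots (NULL for unused modalities).
#' @export
run_pretrain <- function(planes, config) {
  need_ct <- config$modality %in% c("ct", "pet+ct")
  need_pet <- config$modality %in% c("pet", "pet+ct")
  fit_one <- function(pl, tag) {
    if (length(pl) < 1) stop("missing images for requested modality ", tag)
    mae_pretrain(pl, config$vit, epochs = config$pretrain$epochs,
                 batch_size = config$pretrain$batch_size,
                 lr = config$pretrain$lr, betas = config$pretrain$betas,
                 weight_decay = config$pretrain$weight_decay,
                 mask_ratio = config$pretrain$mask_ratio,
                 seed = derive_seed(config$seed, paste0("pretrain_", tag)))
  }
  structure(list(ct = if (need_ct) fit_one(planes$ct, "ct") else NULL,
                 pet = if (need_pet) fit_one(planes$pet, "pet") else NULL),
            class = "mm_checkpoints")
}

# frozen encoding of a list of planes -> list of L x width token matrices
encode_planes <- function(planes, fit) {
  lapply(planes, function(pl) {
    vit_encode(patchify(pl, fit$cfg$patch_size), fit$weights, fit$cfg)$tokens
  })
}

tok_at <- function(toks, j) if (is.null(toks)) NULL else toks[[j]]

#' Mean-pool a square token grid
#'
#' Averages each `pool` x `pool` neighborhood of the patch-grid token
#' sequence, reducing L tokens to L / pool^2. Used to run fusion on a coarser
#' grid at desk scale (`pool = 1` is the identity).
#'
#' @param tokens L x d token matrix with L a perfect square.
#' @param pool integer pooling factor dividing sqrt(L).
#' @return pooled token matrix.
#' @export
pool_token_grid <- function(tokens, pool = 1L) {
  if (pool <= 1L) return(tokens)
  L <- nrow(tokens)
  g <- as.integer(round(sqrt(L)))
  if (g * g != L || g %% pool != 0) stop("token grid not divisible by pool")
  gp <- g %/% pool
  l <- seq_len(L) - 1L
  grp <- ((l %/% g) %/% pool) * gp + ((l %% g) %/% pool) + 1L
  rowsum(tokens, grp) / pool^2
}

# sinusoidal embeddings for a vector of times -> length(times) x dim matrix
time_embedding_rows <- function(times, dim, time_scale) {
  do.call(rbind, lapply(times, time_embedding, dim = dim, time_scale = time_scale))
}

#' Fine-tune fusion, Q-Former and risk head under the survival loss
#'
#' Encoders stay frozen; the cross-attention fusion block, clinical embedding
#' tables, Q-Former and risk head train end-to-end by full-batch AdamW under
#' the configured loss combination, with linear learning-rate warm-up.
#'
#' @param cohort an `mm_cohort`.
#' @param planes output of [cohort_planes].
#' @param checkpoints output of [run_pretrain].
#' @param config an [experiment_config].
#' @param endpoint endpoint to fit.
#' @param subjects training subject ids.
#' @return list of class `mm_survival_model`: `weights`, `head_cfg`,
#'   `fusion_cfg`, `trace`, `endpoint`, `train_ids`.
#' @export
run_finetune <- function(cohort, planes, checkpoints, config,
                         endpoint = "OS", subjects = NULL) {
  if (is.null(subjects)) subjects <- cohort$clinical$subject_id
  sv <- cohort$survival
  sv <- sv[sv$endpoint == endpoint & sv$subject_id %in% subjects, ]
  sv <- sv[match(subjects, sv$subject_id), ]
  time <- sv$time_days
  event <- sv$event
  n <- length(subjects)
  fcfg <- fusion_cfg_of(config)
  hcfg <- risk_head_config(time_embed_dim = config$time_embed_dim,
                           mlp_widths = config$mlp_widths,
                           time_scale = max(time) * 1.05)
  pool <- if (is.null(config$fusion_pool)) 1L else config$fusion_pool
  ct_tok <- if (!is.null(checkpoints$ct))
    lapply(encode_planes(planes$ct[subjects], checkpoints$ct),
           pool_token_grid, pool = pool) else NULL
  pet_tok <- if (!is.null(checkpoints$pet))
    lapply(encode_planes(planes$pet[subjects], checkpoints$pet),
           pool_token_grid, pool = pool) else NULL
  records <- lapply(seq_len(n), function(j)
    as.list(cohort$clinical[cohort$clinical$subject_id == subjects[j], ]))
  text_idx <- do.call(rbind, lapply(records, clinical_index))
  L_tok <- if (!is.null(ct_tok)) nrow(ct_tok[[1]]) else nrow(pet_tok[[1]])
  ct_stack <- if (!is.null(ct_tok)) do.call(rbind, ct_tok) else NULL
  pet_stack <- if (!is.null(pet_tok)) do.call(rbind, pet_tok) else NULL
  weights <- fusion_init(fcfg, hcfg, derive_seed(config$seed, "fusion_init"))
  if (config$finetune$epochs == 0) {
    return(structure(list(weights = weights, head_cfg = hcfg, fusion_cfg = fcfg,
                          trace = numeric(0), endpoint = endpoint,
                          train_ids = subjects, fusion_pool = pool),
                     class = "mm_survival_model"))
  }
  if (sum(event) == 0) stop("loss undefined: zero events in the training split")
  TE_own_all <- time_embedding_rows(time, hcfg$time_embed_dim, hcfg$time_scale)
  w <- c(cox = 0, proposed = 0, focal = 0)
  w[names(config$loss_weights)] <- config$loss_weights
  if (all(w == 0)) stop("all loss components disabled")
  opt <- adamw_init(weights)
  trace <- numeric(config$finetune$epochs)
  d <- fcfg$d_model
  bs <- if (is.null(config$finetune$batch_size)) n else
    min(n, config$finetune$batch_size)
  row_block <- function(idx) as.vector(outer(seq_len(L_tok), (idx - 1) * L_tok, "+"))

  # one AdamW step on the minibatch `idx` (risk sets formed within the batch)
  step_fn <- function(idx, lr) {
    nb <- length(idx)
    tb <- time[idx]; eb <- event[idx]
    if (sum(eb) == 0) return(NA_real_)
    rows <- row_block(idx)
    fw <- fuse_batch_fwd(if (is.null(ct_stack)) NULL else ct_stack[rows, , drop = FALSE],
                         if (is.null(pet_stack)) NULL else pet_stack[rows, , drop = FALSE],
                         L_tok, nb, text_idx[idx, , drop = FALSE], fcfg, weights)
    P <- fw$pooled
    gacc <- tree_zero(weights)
    gP <- matrix(0, nb, d)
    lval <- 0
    if (w["proposed"] != 0) {
      ev_times <- sort(unique(tb[eb == 1]))
      K <- length(ev_times)
      TE <- time_embedding_rows(ev_times, hcfg$time_embed_dim, hcfg$time_scale)
      keep <- outer(tb, ev_times, ">=")
      pair_lin <- which(keep)
      pair_subj <- (pair_lin - 1L) %% nb + 1L
      pair_col <- (pair_lin - 1L) %/% nb + 1L
      ph <- pair_head_fwd(P, TE, pair_subj, pair_col, weights$head)
      S <- matrix(0, nb, K)
      S[pair_lin] <- ph$scores
      pl <- proposed_loss(S, tb, eb, return_grad = TRUE)
      lval <- lval + w["proposed"] * pl$loss
      pb <- pair_head_bwd(w["proposed"] * pl$grad[pair_lin], ph$cache,
                          weights$head)
      gacc$head <- tree_add(gacc$head, pb$gparams$layers)
      gP <- gP + pb$gP
    }
    if (w["cox"] != 0 || w["focal"] != 0) {
      ph <- pair_head_fwd(P, TE_own_all[idx, , drop = FALSE],
                          seq_len(nb), seq_len(nb), weights$head)
      s_own <- ph$scores
      g_own <- numeric(nb)
      if (w["cox"] != 0) {
        cl <- cox_loss(s_own, tb, eb, return_grad = TRUE)
        lval <- lval + w["cox"] * cl$loss
        g_own <- g_own + w["cox"] * cl$grad
      }
      if (w["focal"] != 0) {
        p <- sigmoid(s_own)
        fl <- focal_loss(pmin(pmax(p, 1e-12), 1 - 1e-12), eb,
                         return_grad = TRUE)
        lval <- lval + w["focal"] * fl$loss
        g_own <- g_own + w["focal"] * fl$grad * p * (1 - p)
      }
      pb <- pair_head_bwd(g_own, ph$cache, weights$head)
      gacc$head <- tree_add(gacc$head, pb$gparams$layers)
      gP <- gP + pb$gP
    }
    if (!is.finite(lval)) return(NA_real_)
    gt <- fuse_batch_bwd(gP, fw$cache, weights)
    for (nm in names(gt)) gacc[[nm]] <- tree_add(gacc[[nm]], gt[[nm]])
    upd <- adamw_step(weights, gacc, opt, lr = lr,
                      betas = config$finetune$betas,
                      weight_decay = config$finetune$weight_decay)
    weights <<- upd$params
    opt <<- upd$state
    lval
  }

  avg_last <- if (is.null(config$finetune$avg_last)) 10L else
    config$finetune$avg_last
  avg_from <- config$finetune$epochs - min(avg_last, config$finetune$epochs) + 1L
  wsum <- NULL
  n_avg <- 0L
  aborted <- FALSE
  for (ep in seq_len(config$finetune$epochs)) {
    lr <- config$finetune$lr *
      min(1, ep / max(1, config$finetune$warmup))
    ord <- with_seed(derive_seed(config$seed, "ft_shuffle", ep), sample.int(n))
    done <- 0L
    ep_loss <- 0
    nb_used <- 0L
    while (done < n) {
      idx <- ord[(done + 1):min(done + bs, n)]
      done <- done + length(idx)
      lv <- step_fn(idx, lr)
      if (is.na(lv)) next
      if (!is.finite(lv)) {
        warning("non-finite loss at epoch ", ep,
                "; aborting with last good weights")
        aborted <- TRUE
        break
      }
      ep_loss <- ep_loss + lv
      nb_used <- nb_used + 1L
    }
    if (aborted) {
      trace <- trace[seq_len(ep - 1)]
      break
    }
    trace[ep] <- ep_loss / max(1L, nb_used)
    if (ep >= avg_from) {
      wsum <- if (is.null(wsum)) weights else tree_add(wsum, weights)
      n_avg <- n_avg + 1L
    }
  }
  # tail averaging: the returned weights are the mean over the last epochs,
  # which damps minibatch noise in the short desk-scale schedule
  if (n_avg > 0L) weights <- tree_scale(wsum, 1 / n_avg)
  structure(list(weights = weights, head_cfg = hcfg, fusion_cfg = fcfg,
                 trace = trace, endpoint = endpoint, train_ids = subjects,
                 fusion_pool = pool),
            class = "mm_survival_model")
}

#' Predict risk for a set of subjects
#'
#' Computes the pooled fused feature per subject and returns (i) a scalar
#' ranking risk, sigmoid(N(y, t_ref)) at a common reference time (the median
#' follow-up of the scored subjects unless given), and (ii) the event
#' probability sigmoid(N(y_i, T_i)) at each subject's own follow-up time.
#'
#' @param model an `mm_survival_model`.
#' @param cohort an `mm_cohort`.
#' @param planes output of [cohort_planes].
#' @param checkpoints output of [run_pretrain].
#' @param subjects subject ids to score.
#' @param t_ref optional reference time (days).
#' @return list: `risk`, `p_own`, `time`, `event`, `t_ref`.
#' @export
predict_risk <- function(model, cohort, planes, checkpoints, subjects,
                         t_ref = NULL) {
  sv <- cohort$survival
  sv <- sv[sv$endpoint == model$endpoint & sv$subject_id %in% subjects, ]
  sv <- sv[match(subjects, sv$subject_id), ]
  time <- sv$time_days
  event <- sv$event
  if (is.null(t_ref)) t_ref <- stats::median(time)
  fcfg <- model$fusion_cfg
  pool <- if (is.null(model$fusion_pool)) 1L else model$fusion_pool
  ct_tok <- if (!is.null(checkpoints$ct))
    lapply(encode_planes(planes$ct[subjects], checkpoints$ct),
           pool_token_grid, pool = pool) else NULL
  pet_tok <- if (!is.null(checkpoints$pet))
    lapply(encode_planes(planes$pet[subjects], checkpoints$pet),
           pool_token_grid, pool = pool) else NULL
  n <- length(subjects)
  risk <- numeric(n)
  p_own <- numeric(n)
  for (j in seq_len(n)) {
    rec <- as.list(cohort$clinical[cohort$clinical$subject_id == subjects[j], ])
    fw <- fuse_subject_fwd(tok_at(ct_tok, j), tok_at(pet_tok, j), rec, fcfg,
                           model$weights)
    risk[j] <- sigmoid(risk_score(fw$pooled, t_ref, model$head_cfg, model$weights))
    p_own[j] <- sigmoid(risk_score(fw$pooled, time[j], model$head_cfg,
                                   model$weights))
  }
  list(risk = risk, p_own = p_own, time = time, event = event, t_ref = t_ref)
}

#' Evaluate a fitted model on a held-out split
#'
#' Checks id-disjointness against the training subjects, then computes the
#' concordance index with a percentile-bootstrap confidence interval,
#' median-split Kaplan-Meier curves with a log-rank test, and the mean L2
#' distance between predicted event probability and outcome.
#'
#' @param model an `mm_survival_model`.
#' @param cohort,planes,checkpoints as in [predict_risk].
#' @param eval_ids held-out subject ids (disjoint from training ids).
#' @param config an [experiment_config] (bootstrap size, seed).
#' @param out_dir optional directory for JSON/CSV artifacts.
#' @return list of class `mm_eval`: `endpoint`, `c_index` (`cindex_result`),
#'   `logrank`, `mean_l2`, `km` (per risk group), `groups`.
#' @export
run_evaluate <- function(model, cohort, planes, checkpoints, eval_ids, config,
                         out_dir = NULL) {
  if (length(intersect(eval_ids, model$train_ids)) > 0)
    stop("train/eval subject ids overlap")
  pr <- predict_risk(model, cohort, planes, checkpoints, eval_ids)
  ci <- bootstrap_ci(pr$time, pr$event, pr$risk, B = config$eval$n_bootstrap,
                     seed = derive_seed(config$seed, "bootstrap"))
  grp <- stratify(pr$risk)
  lr <- log_rank(pr$time[grp == "high"], pr$event[grp == "high"],
                 pr$time[grp == "low"], pr$event[grp == "low"])
  l2 <- l2_event_distance(pr$p_own, pr$event)
  km <- list(high = km_curve(pr$time[grp == "high"], pr$event[grp == "high"]),
             low = km_curve(pr$time[grp == "low"], pr$event[grp == "low"]))
  res <- structure(list(endpoint = model$endpoint, c_index = ci, logrank = lr,
                        mean_l2 = l2$mean, km = km, groups = grp,
                        risk = pr$risk, time = pr$time, event = pr$event),
                   class = "mm_eval")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      stats::setNames(list(list(c_index = ci$estimate, ci_lower = ci$ci_lower,
                                ci_upper = ci$ci_upper,
                                logrank_p = lr$p_value, mean_l2 = l2$mean)),
                      model$endpoint),
      file.path(out_dir, paste0("metrics_", model$endpoint, ".json")),
      auto_unbox = TRUE, digits = NA)
    for (g in c("high", "low")) {
      utils::write.csv(data.frame(time = km[[g]]$time, survival = km[[g]]$surv,
                                  at_risk = km[[g]]$n_risk),
                       file.path(out_dir, paste0("km_", model$endpoint, "_",
                                                 g, ".csv")),
                       row.names = FALSE)
    }
  }
  res
}

#' Run the complete pipeline on a synthetic cohort
#'
#' Simulates a cohort, splits it, pretrains the encoders on the training
#' images, fine-tunes one survival model per endpoint and evaluates each on
#' the held-out split.
#'
#' @param config an [experiment_config].
#' @param cohort optional pre-built `mm_cohort` (simulated when NULL).
#' @param out_dir optional artifact directory.
#' @return list of class `mm_run_report`: per-endpoint `mm_eval`s, loss
#'   traces, split ids, config.
#' @export
run_experiment <- function(config, cohort = NULL, out_dir = NULL) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$n_subjects, config$phantom, config$hazard,
                              seed = derive_seed(config$seed, "cohort"))
  }
  planes <- cohort_planes(cohort, config$input)
  sp <- split_cohort(cohort$clinical$subject_id, config$split[["train"]],
                     config$seed)
  checkpoints <- run_pretrain(lapply(planes, function(m) m[sp$train]), config)
  evals <- list()
  traces <- list()
  for (ep in config$endpoints) {
    model <- run_finetune(cohort, planes, checkpoints, config, endpoint = ep,
                          subjects = sp$train)
    evals[[ep]] <- run_evaluate(model, cohort, planes, checkpoints, sp$eval,
                                config, out_dir = out_dir)
    traces[[ep]] <- model$trace
  }
  structure(list(evals = evals, traces = traces, split = sp,
                 pretrain_traces = list(ct = checkpoints$ct$trace,
                                        pet = checkpoints$pet$trace),
                 config = config),
            class = "mm_run_report")
}

#' @export
print.mm_run_report <- function(x, ...) {
  cat("<mm_run_report>\n")
  for (ep in names(x$evals)) {
    e <- x$evals[[ep]]
    cat(sprintf("  %s: C = %.3f (%.3f-%.3f), log-rank p = %.3g, mean L2 = %.3f\n",
                ep, e$c_index$estimate, e$c_index$ci_lower, e$c_index$ci_upper,
                e$logrank$p_value, e$mean_l2))
  }
  invisible(x)
}

#' Run an ablation grid
#'
#' One pipeline run per grid cell over subsets of the axes
#' modality / fusion / qformer / loss, sharing the cohort, the split and the
#' root seed; pretrained encoders are shared across cells. Returns a table
#' shaped rows = configurations, columns = endpoints.
#'
#' @param config base [experiment_config].
#' @param axes named list, e.g. `list(modality = c("ct", "pet+ct"))`; allowed
#'   names: modality, fusion, qformer, loss.
#' @param cohort optional pre-built cohort.
#' @return data.frame with one row per cell and one C-index column per
#'   endpoint.
#' @export
run_ablation_grid <- function(config, axes, cohort = NULL) {
  if (length(axes) == 0) stop("empty grid")
  if (!all(names(axes) %in% c("modality", "fusion", "qformer", "loss")))
    stop("axes must be a subset of {modality, fusion, qformer, loss}")
  grid <- expand.grid(axes, stringsAsFactors = FALSE)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$n_subjects, config$phantom, config$hazard,
                              seed = derive_seed(config$seed, "cohort"))
  }
  planes <- cohort_planes(cohort, config$input)
  sp <- split_cohort(cohort$clinical$subject_id, config$split[["train"]],
                     config$seed)
  # pretrain each modality at most once, at the base config's scale
  both <- config; both$modality <- "pet+ct"
  checkpoints <- run_pretrain(lapply(planes, function(m) m[sp$train]), both)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cell <- config
    if (!is.null(grid$modality)) cell$modality <- grid$modality[r]
    if (!is.null(grid$fusion)) cell$fusion <- grid$fusion[r]
    if (!is.null(grid$qformer)) cell$qformer <- as.logical(grid$qformer[r])
    if (!is.null(grid$loss)) {
      cell$loss_weights <- switch(grid$loss[r],
        cox = c(cox = 1, proposed = 0, focal = 0),
        proposed = c(cox = 0, proposed = 1, focal = 0),
        "cox+focal" = c(cox = 1, proposed = 0, focal = 1),
        "proposed+focal" = c(cox = 0, proposed = 1, focal = 1),
        stop("unknown loss configuration ", grid$loss[r]))
    }
    ck <- list(ct = if (cell$modality %in% c("ct", "pet+ct")) checkpoints$ct,
               pet = if (cell$modality %in% c("pet", "pet+ct")) checkpoints$pet)
    out <- grid[r, , drop = FALSE]
    for (ep in config$endpoints) {
      model <- run_finetune(cohort, planes, ck, cell, endpoint = ep,
                            subjects = sp$train)
      ev <- run_evaluate(model, cohort, planes, ck, sp$eval, cell)
      out[[ep]] <- ev$c_index$estimate
    }
    rows[[r]] <- out
  }
  do.call(rbind, rows)
}

#' Save / load pipeline checkpoints
#'
#' Single-file serialized weights together with their config and seed.
#'
#' @param object checkpoints or model object.
#' @param path file path.
#' @return `load_checkpoint` returns the object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
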