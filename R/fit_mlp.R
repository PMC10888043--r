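# A small MLP risk model over tabular covariates trained with the survival
# losses. Used for parameter-recovery checks against a known linear predictor
# and as the lightweight "features only" baseline.

#' Fit an MLP risk model under a survival loss
#'
#' Trains a GELU MLP mapping covariates to a scalar risk score by full-batch
#' AdamW under either the sigmoid partial-likelihood loss or the Cox loss
#' (scores are time-invariant here).
#'
#' @param x n x p covariate matrix.
#' @param time,event follow-up data.
#' @param hidden integer vector of hidden widths.
#' @param loss `"proposed"` or `"cox"`.
#' @param focal_weight additional focal-loss weight on sigmoid(score) vs the
#'   event indicator (0 disables).
#' @param epochs full-batch AdamW steps.
#' @param lr learning rate.
#' @param weight_decay AdamW weight decay.
#' @param gamma focal exponent.
#' @param seed integer seed (initialisation).
#' @return list of class `risk_mlp`: `layers`, `trace`, `loss`.
#' @export
fit_risk_mlp <- function(x, time, event, hidden = c(16L), loss = c("proposed", "cox"),
                         focal_weight = 0, epochs = 300L, lr = 5e-3,
                         weight_decay = 1e-4, gamma = 2, seed = 1L) {
  loss <- match.arg(loss)
  x <- as.matrix(x)
  widths <- c(ncol(x), hidden, 1L)
  params <- with_seed(derive_seed(seed, "mlp_init"), {
    list(layers = lapply(seq_len(length(widths) - 1), function(i)
      init_linear(widths[i], widths[i + 1], sd = 0.1)))
  })
  opt <- adamw_init(params)
  trace <- numeric(epochs)
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    fw <- head_fwd(x, params)
    s <- fw$out[, 1]
    if (loss == "proposed") {
      lg <- proposed_loss(s, time, event, return_grad = TRUE)
    } else {
      lg <- cox_loss(s, time, event, return_grad = TRUE)
    }
    lval <- lg$loss
    gs <- lg$grad
    if (focal_weight > 0) {
      p <- sigmoid(s)
      fl <- focal_loss(p, event, gamma, return_grad = TRUE)
      lval <- lval + focal_weight * fl$loss
      gs <- gs + focal_weight * fl$grad * p * (1 - p)
    }
    if (!is.finite(lval)) stop("divergence: non-finite loss")
    trace[ep] <- lval
    hb <- head_bwd(matrix(gs, n, 1), fw$cache)
    upd <- adamw_step(params, hb$gparams, opt, lr = lr,
                      weight_decay = weight_decay)
    params <- upd$params
    opt <- upd$state
  }
  structure(list(layers = params$layers, trace = trace, loss = loss),
            class = "risk_mlp")
}

#' Predict risk scores from a fitted MLP
#'
#' @param object a `risk_mlp` fit.
#' @param newdata covariate matrix.
#' @param ... unused.
#' @return numeric vector of unlinked risk scores.
#' @export
predict.risk_mlp <- function(object, newdata, ...) {
  head_fwd(as.matrix(newdata), list(layers = object$layers))$out[, 1]
}
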