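# Synthetic phantom cohorts with a known Weibull proportional-hazards ground
# truth. A scalar latent risk per subject drives (i) tumor size on CT,
# (ii) PET hotspot intensity, (iii) the clinical stage distribution, and
# (iv) the hazard — so image, text and outcome streams share signal and
# multi-modal fusion is genuinely informative on simulated data.

#' Phantom generator parameters
#'
#' @param image_side in-plane image side in pixels.
#' @param n_slices number of axial slices per volume.
#' @param n_background_ellipses soft anatomy ellipses per volume.
#' @param tumor_radius_range pixel range (min, max); the realized radius is
#'   `min + (max - min) * sigmoid(latent_risk)`.
#' @param pet_hotspot_gain peak PET hotspot intensity multiplier; the clean
#'   hotspot center value is `pet_hotspot_gain * sigmoid(latent_risk)`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return a list of class `phantom_params`.
#' @export
phantom_params <- function(image_side = 64L, n_slices = 8L,
                           n_background_ellipses = 5L,
                           tumor_radius_range = c(4, 12),
                           pet_hotspot_gain = 4, noise_sd = 0.05) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (tumor_radius_range[2] >= image_side / 2)
    stop("tumor radius range exceeds image bounds")
  structure(list(image_side = as.integer(image_side),
                 n_slices = as.integer(n_slices),
                 n_background_ellipses = as.integer(n_background_ellipses),
                 tumor_radius_range = tumor_radius_range,
                 pet_hotspot_gain = pet_hotspot_gain, noise_sd = noise_sd),
            class = "phantom_params")
}

#' Weibull proportional-hazards simulation model
#'
#' Event times follow S(t) = exp(-(rate * t)^shape * exp(beta'x)) with
#' independent exponential censoring. The exponential baseline is the special
#' case `shape = 1`, which gives closed-form checks.
#'
#' @param shape Weibull shape (kappa), > 0.
#' @param rate Weibull rate (rho), per day, > 0.
#' @param beta named coefficients over (latent, age_z, stage_z).
#' @param censor_rate exponential censoring rate per day, > 0. The default is
#'   calibrated so roughly 70% of OS outcomes are events (~30% censoring).
#' @param endpoint_scale multiplicative scaling of beta per endpoint.
#' @param target_event_fraction documented event fraction the default
#'   censor_rate aims for on the OS endpoint.
#' @return a list of class `hazard_model`.
#' @export
hazard_model <- function(shape = 1.3, rate = 1 / 1200,
                         beta = c(latent = 1.1, age_z = 0.25, stage_z = 0.35),
                         censor_rate = 3.2e-4,
                         endpoint_scale = c(OS = 1, RFS = 0.7, MFS = 0.8, PFS = 0.9),
                         target_event_fraction = 0.70) {
  if (shape <= 0 || rate <= 0 || censor_rate <= 0)
    stop("shape, rate and censor_rate must be positive")
  structure(list(shape = shape, rate = rate, beta = beta,
                 censor_rate = censor_rate, endpoint_scale = endpoint_scale,
                 target_event_fraction = target_event_fraction),
            class = "hazard_model")
}

# soft additive ellipse on a side x side grid
add_ellipse <- function(img, cx, cy, rx, ry, amp) {
  s <- nrow(img)
  xg <- matrix(seq_len(s), s, s, byrow = TRUE)
  yg <- matrix(seq_len(s), s, s)
  d2 <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2
  img + amp * exp(-d2)
}

#' Simulate a co-registered PET/CT phantom pair
#'
#' CT shows soft elliptical anatomy plus a tumor disc whose radius increases
#' with `latent_risk`; PET shows the same geometry with a hotspot whose clean
#' peak intensity is `pet_hotspot_gain * sigmoid(latent_risk)`. Gaussian noise
#' of sd `noise_sd` is added to both. A binary tumor mask on the same grid is
#' returned alongside.
#'
#' @param params a [phantom_params].
#' @param latent_risk finite scalar latent risk.
#' @param seed integer seed; the pair is a pure function of (params,
#'   latent_risk, seed).
#' @return list with [image_volume] fields `ct`, `pet`, `mask`.
#' @export
simulate_phantom_pair <- function(params, latent_risk, seed) {
  stopifnot(inherits(params, "phantom_params"), is.finite(latent_risk))
  s <- params$image_side
  nz <- params$n_slices
  r <- params$tumor_radius_range[1] +
    diff(params$tumor_radius_range) * sigmoid(latent_risk)
  if (r >= s / 2) stop("tumor radius exceeds image bounds")
  with_seed(seed, {
    # anatomy shared by both modalities
    anat <- matrix(0.15, s, s)
    anat <- add_ellipse(anat, s / 2, s / 2, s / 2.6, s / 2.2, 0.25)
    for (k in seq_len(params$n_background_ellipses)) {
      anat <- add_ellipse(anat,
                          stats::runif(1, s * 0.25, s * 0.75),
                          stats::runif(1, s * 0.25, s * 0.75),
                          stats::runif(1, s * 0.05, s * 0.18),
                          stats::runif(1, s * 0.05, s * 0.18),
                          stats::runif(1, 0.05, 0.18))
    }
    # tumor center on an exact pixel so the clean hotspot peak is attained
    cx <- round(s / 2 + stats::runif(1, -s * 0.08, s * 0.08))
    cy <- round(s / 2 + stats::runif(1, -s * 0.08, s * 0.08))
    z0 <- (nz + 1) / 2
    zh <- max(1.5, nz / 3)
    xg <- matrix(seq_len(s), s, s, byrow = TRUE)
    yg <- matrix(seq_len(s), s, s)
    ct <- array(0, dim = c(nz, s, s))
    pet <- array(0, dim = c(nz, s, s))
    msk <- array(0, dim = c(nz, s, s))
    peak <- params$pet_hotspot_gain * sigmoid(latent_risk)
    for (z in seq_len(nz)) {
      frac <- 1 - ((z - z0) / zh)^2
      rz <- if (frac > 0) r * sqrt(frac) else 0
      d2 <- (xg - cx)^2 + (yg - cy)^2
      inside <- d2 <= rz^2
      ct_sl <- anat
      ct_sl[inside] <- 0.65
      # smooth radial hotspot profile, 1 at the tumor center
      prof <- if (rz > 0) exp(-d2 / (2 * (rz / 1.6)^2)) * inside else matrix(0, s, s)
      pet_sl <- 0.25 * anat * (1 - prof) + peak * prof
      ct[z, , ] <- ct_sl
      pet[z, , ] <- pet_sl
      msk[z, , ] <- inside * 1
    }
    if (params$noise_sd > 0) {
      ct <- ct + array(stats::rnorm(length(ct), sd = params$noise_sd), dim = dim(ct))
      pet <- pet + array(stats::rnorm(length(pet), sd = params$noise_sd), dim = dim(pet))
    }
    list(ct = image_volume(ct, c(3, 1, 1), "CT", "phantom"),
         pet = image_volume(pet, c(3, 4, 4), "PET", "phantom"),
         mask = image_volume(msk, c(3, 1, 1), "CT", "phantom"))
  })
}

# cumulative logits reproducing stage margins I/II/III/IV ~ 4/9/19/68% at
# latent risk 0 through the deterministic (T, N) -> overall stage map
.t_cumlogit <- stats::qlogis(c(0.10, 0.45, 0.72))
.n_cumlogit <- stats::qlogis(c(0.20, 0.40, 0.90))

sample_ordinal <- function(cumlogit, shift) {
  u <- stats::runif(1)
  1L + sum(u > stats::plogis(cumlogit - shift))
}

#' Map T and N categories to an overall stage
#'
#' Fixed monotone map for M0 disease: stage IV if T4 or N2-N3; stage III if T3
#' or N1; stage II if T2; otherwise stage I.
#'
#' @param t_stage integer 1..4 (T1..T4).
#' @param n_stage integer 0..3 (N0..N3).
#' @return integer overall stage 1..4.
#' @export
overall_stage <- function(t_stage, n_stage) {
  ifelse(t_stage == 4 | n_stage >= 2, 4L,
         ifelse(t_stage == 3 | n_stage == 1, 3L,
                ifelse(t_stage == 2, 2L, 1L)))
}

#' Simulate a clinical record
#'
#' Age is normal(60, 10) truncated to [18, 90]; sex is Bernoulli with
#' P(male) = 0.79; T and N stages are proportional-odds categorical draws whose
#' cumulative log-odds are shifted by `latent_risk`; M is fixed at M0 (no
#' distant metastasis at diagnosis); the overall stage follows the fixed
#' monotone map [overall_stage].
#'
#' @param latent_risk finite scalar.
#' @param seed integer seed.
#' @return a list of class `clinical_record` with fields `age`, `sex`,
#'   `t_stage` ("T1".."T4"), `n_stage` ("N0".."N3"), `m_stage` ("M0"),
#'   `overall_stage` ("I".."IV").
#' @export
simulate_clinical <- function(latent_risk, seed) {
  with_seed(seed, {
    age <- stats::rnorm(1, 60, 10)
    while (age < 18 || age > 90) age <- stats::rnorm(1, 60, 10)
    sex <- if (stats::runif(1) < 0.79) "male" else "female"
    tt <- sample_ordinal(.t_cumlogit, latent_risk)
    nn <- sample_ordinal(.n_cumlogit, latent_risk) - 1L
    st <- overall_stage(tt, nn)
    structure(list(age = as.integer(round(age)), sex = sex,
                   t_stage = paste0("T", tt), n_stage = paste0("N", nn),
                   m_stage = "M0",
                   overall_stage = c("I", "II", "III", "IV")[st]),
              class = "clinical_record")
  })
}

#' Simulate one survival outcome under the Weibull PH model
#'
#' The event time is drawn by inverse-transform sampling from
#' S(t) = exp(-(rate * t)^shape * exp(lp)) where lp = endpoint_scale *
#' beta'x; the censoring time is exponential with `censor_rate`; the observed
#' time is the minimum and the event indicator marks which came first.
#'
#' @param model a [hazard_model].
#' @param covariates numeric vector matching `model$beta`.
#' @param endpoint one of "OS", "RFS", "MFS", "PFS".
#' @param seed integer seed.
#' @return list of class `survival_outcome`: `endpoint`, `time` (days),
#'   `event` (0/1).
#' @export
simulate_survival <- function(model, covariates, endpoint = "OS", seed) {
  stopifnot(inherits(model, "hazard_model"))
  if (length(covariates) != length(model$beta))
    stop("covariates length does not match beta")
  endpoint <- match.arg(endpoint, names(model$endpoint_scale))
  lp <- sum(model$beta * covariates) * model$endpoint_scale[[endpoint]]
  with_seed(seed, {
    u <- stats::runif(1)
    t_event <- (1 / model$rate) * (-log(u) * exp(-lp))^(1 / model$shape)
    t_cens <- stats::rexp(1, model$censor_rate)
    structure(list(endpoint = endpoint,
                   time = max(min(t_event, t_cens), 1e-8),
                   event = as.integer(t_event <= t_cens)),
              class = "survival_outcome")
  })
}

# standardized covariate vector used by the hazard model
clinical_covariates <- function(latent, age, stage_num) {
  c(latent = latent, age_z = (age - 60) / 10, stage_z = (stage_num - 3) / 1)
}

#' Simulate a complete in-memory cohort
#'
#' Draws per-subject latent risks from N(0, 1) and generates paired PET/CT
#' phantoms, clinical records and survival outcomes for the requested
#' endpoints. The result is a pure function of (n, params, model, seed).
#'
#' @param n number of subjects.
#' @param params a [phantom_params].
#' @param model a [hazard_model].
#' @param seed integer root seed.
#' @param endpoints endpoints to simulate.
#' @param images logical; generate phantom image volumes (TRUE) or only
#'   tabular data (FALSE).
#' @return list of class `mm_cohort` with fields `clinical` (data.frame),
#'   `survival` (data.frame: subject_id, endpoint, time_days, event),
#'   `images` (per-subject list of ct/pet/mask volumes or NULL), `latent`,
#'   `params`, `model`, `seed`.
#' @export
simulate_cohort <- function(n, params = phantom_params(), model = hazard_model(),
                            seed = 1L, endpoints = c("OS", "RFS", "MFS", "PFS"),
                            images = TRUE) {
  ids <- sprintf("S%04d", seq_len(n))
  latent <- with_seed(derive_seed(seed, "latent"), stats::rnorm(n))
  clin <- vector("list", n)
  imgs <- if (images) vector("list", n) else NULL
  surv <- list()
  for (i in seq_len(n)) {
    rec <- simulate_clinical(latent[i], derive_seed(seed, "clinical", i))
    clin[[i]] <- data.frame(subject_id = ids[i], age = rec$age, sex = rec$sex,
                            t_stage = rec$t_stage, n_stage = rec$n_stage,
                            m_stage = rec$m_stage,
                            overall_stage = rec$overall_stage,
                            stringsAsFactors = FALSE)
    if (images) {
      pair <- simulate_phantom_pair(params, latent[i], derive_seed(seed, "image", i))
      pair$ct$subject_id <- ids[i]
      pair$pet$subject_id <- ids[i]
      pair$mask$subject_id <- ids[i]
      imgs[[i]] <- pair
    }
    xcov <- clinical_covariates(latent[i], rec$age,
                                match(rec$overall_stage, c("I", "II", "III", "IV")))
    for (ep in endpoints) {
      out <- simulate_survival(model, xcov, ep,
                               derive_seed(seed, paste0("surv_", ep), i))
      surv[[length(surv) + 1L]] <- data.frame(subject_id = ids[i], endpoint = ep,
                                              time_days = out$time,
                                              event = out$event,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!is.null(imgs)) names(imgs) <- ids
  structure(list(clinical = do.call(rbind, clin),
                 survival = do.call(rbind, surv),
                 images = imgs, latent = stats::setNames(latent, ids),
                 params = params, model = model, seed = seed),
            class = "mm_cohort")
}

#' Write a cohort to disk
#'
#' Writes per-subject PET/CT/mask NIfTI volumes, one clinical CSV, one survival
#' CSV per endpoint, and a JSON manifest recording all generator parameters and
#' the seed.
#'
#' @param n number of subjects.
#' @param params a [phantom_params].
#' @param model a [hazard_model].
#' @param out_dir output directory.
#' @param seed integer root seed.
#' @param endpoints endpoints to simulate.
#' @param overwrite overwrite an existing manifest.
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(n, params = phantom_params(), model = hazard_model(),
                         out_dir, seed = 1L,
                         endpoints = c("OS", "RFS", "MFS", "PFS"),
                         overwrite = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest exists at ", manifest_path, "; use overwrite = TRUE")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n, params, model, seed, endpoints, images = TRUE)
  for (id in cohort$clinical$subject_id) {
    write_volume(cohort$images[[id]]$ct,
                 file.path(out_dir, "images", paste0(id, "_CT.nii.gz")))
    write_volume(cohort$images[[id]]$pet,
                 file.path(out_dir, "images", paste0(id, "_PET.nii.gz")))
    write_volume(cohort$images[[id]]$mask,
                 file.path(out_dir, "images", paste0(id, "_mask.nii.gz")))
  }
  utils::write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  for (ep in endpoints) {
    utils::write.csv(cohort$survival[cohort$survival$endpoint == ep, ],
                     file.path(out_dir, paste0("survival_", ep, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(n = n, seed = seed, endpoints = as.list(endpoints),
                   phantom_params = unclass(cohort$params),
                   hazard_model = unclass(cohort$model),
                   latent = as.list(cohort$latent))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @param images read the image volumes too.
#' @return an `mm_cohort` list (without latent ground truth in the images).
#' @export
read_cohort <- function(dir, images = TRUE) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  svs <- list.files(dir, pattern = "^survival_.*\\.csv$", full.names = TRUE)
  surv <- do.call(rbind, lapply(svs, utils::read.csv, stringsAsFactors = FALSE))
  imgs <- NULL
  if (images) {
    imgs <- lapply(clin$subject_id, function(id) {
      list(ct = read_volume(file.path(dir, "images", paste0(id, "_CT.nii.gz")),
                            "CT", id),
           pet = read_volume(file.path(dir, "images", paste0(id, "_PET.nii.gz")),
                             "PET", id),
           mask = read_volume(file.path(dir, "images", paste0(id, "_mask.nii.gz")),
                              "CT", id))
    })
    names(imgs) <- clin$subject_id
  }
  structure(list(clinical = clin, survival = surv, images = imgs,
                 latent = unlist(manifest$latent),
                 params = do.call(phantom_params, manifest$phantom_params[
                   c("image_side", "n_slices", "n_background_ellipses",
                     "tumor_radius_range", "pet_hotspot_gain", "noise_sd")]),
                 model = do.call(hazard_model, manifest$hazard_model[
                   c("shape", "rate", "beta", "censor_rate", "endpoint_scale",
                     "target_event_fraction")]),
                 seed = manifest$seed),
            class = "mm_cohort")
}
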