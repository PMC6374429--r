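#' Training configuration
#'
#' Hyperparameters for the two-step procedure: stage 1 trains one GRU
#' classifier per modality (pre-trained on CN/AD auxiliaries, then continued
#' with horizon-labelled MCI subjects); stage 2 fits an l1-regularised
#' logistic head on the concatenated representations. Training is
#' deterministic given the seed and data order.
#'
#' @param learning_rate Constant gradient-descent step size.
#' @param epochs_pretrain,epochs_main Full-batch epochs for the CN/AD
#'   pre-training phase and the main phase.
#' @param batch_size Mini-batch size; `NULL` (default) means full batch.
#' @param l1_strength Lasso penalty lambda for the fusion head; `NULL`
#'   selects it by an inner 3-fold grid search over `10^seq(-3, 1, 1)`.
#' @param standardize Z-score features with training-set statistics before
#'   encoding (recommended: the modalities mix units).
#' @param missing_policy How a missing modality enters fusion: `"zero"`
#'   (zero vector, the neutral point of the standardized representation
#'   space) or `"mean"` (training-set mean representation).
#' @param seed Integer seed for parameter initialisation.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.5, epochs_pretrain = 30L,
                         epochs_main = 60L, batch_size = NULL,
                         l1_strength = NULL, standardize = TRUE,
                         missing_policy = c("zero", "mean"), seed = 1L) {
  stopifnot(learning_rate > 0, epochs_pretrain >= 0, epochs_main >= 0,
            is.null(l1_strength) || l1_strength >= 0)
  structure(list(
    learning_rate = learning_rate,
    epochs_pretrain = as.integer(epochs_pretrain),
    epochs_main = as.integer(epochs_main),
    batch_size = batch_size,
    l1_strength = l1_strength,
    standardize = isTRUE(standardize),
    missing_policy = match.arg(missing_policy),
    seed = as.integer(seed)
  ), class = "train_config")
}

# Pooled per-feature mean/sd over the observation rows of the given subjects
fit_standardization <- function(cohort, modality, subject_ids) {
  spec <- cohort$registry[cohort$registry$modality == modality, ]
  rows <- cohort$visits$modality == modality &
    cohort$visits$subject_id %in% subject_ids
  obs <- as.matrix(cohort$visits[rows, paste0("f", seq_len(spec$n_features)),
                                 drop = FALSE])
  center <- colMeans(obs)
  scale <- apply(obs, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = as.numeric(center), scale = as.numeric(scale))
}

standardize_obs <- function(obs, std) {
  sweep(sweep(obs, 2, std$center), 2, std$scale, "/")
}

subjects_with_modality <- function(cohort, modality) {
  unique(cohort$visits$subject_id[cohort$visits$modality == modality])
}

# class coding used throughout: 1 = non-converter side (CN), 2 = converter
# side (AD / MCI-C)
stage1_labels <- function(cohort, ids, dt) {
  s <- cohort$subjects[match(ids, cohort$subjects$subject_id), ]
  lab <- integer(length(ids))
  lab[s$baseline_group == "CN"] <- 1L
  lab[s$baseline_group == "AD"] <- 2L
  mci <- which(s$baseline_group == "MCI")
  for (i in mci) {
    dl <- derive_label(s[i, ], dt)
    lab[i] <- switch(dl, converter = 2L, non_converter = 1L, 0L)
  }
  lab
}

#' Train one modality's GRU encoder
#'
#' Stage-1 training for a single modality: z-scoring statistics are fitted
#' on the training subjects only; the GRU classifier is pre-trained on CN
#' (non-converter class) and AD (converter class) subjects possessing the
#' modality, then training continues with the eligible MCI subjects labelled
#' at horizon `dt` added to the batch. Subjects lacking the modality are
#' simply excluded, so non-overlapping samples still contribute to their own
#' modality's encoder.
#'
#' @param cohort Training cohort (must not contain held-out test subjects).
#' @param modality Modality name.
#' @param dt Prediction horizon in months for MCI labelling.
#' @param config A [train_config()].
#' @return An `mmgru_encoder`: modality spec, GRU parameters,
#'   standardization, and the pre-training / main-phase loss traces.
#' @export
train_modality_gru <- function(cohort, modality, dt, config = train_config()) {
  reg_idx <- match(modality, cohort$registry$modality)
  if (is.na(reg_idx)) {
    rlang::abort(paste0("unknown modality: ", modality),
                 class = "mmgru_unknown_modality")
  }
  spec <- cohort$registry[reg_idx, ]

  ids <- subjects_with_modality(cohort, modality)
  if (length(ids) == 0) {
    rlang::abort(paste0("no subject has modality ", modality),
                 class = "mmgru_empty_training_set")
  }
  labels <- stage1_labels(cohort, ids, dt)
  keep <- labels > 0L                     # drop horizon-ineligible MCI
  ids <- ids[keep]; labels <- labels[keep]
  groups <- cohort$subjects$baseline_group[match(ids,
                                                 cohort$subjects$subject_id)]
  mci_labels <- labels[groups == "MCI"]
  if (length(mci_labels) > 0 && length(unique(mci_labels)) < 2) {
    rlang::abort("MCI training set contains a single class",
                 class = "mmgru_single_class")
  }
  if (length(unique(labels)) < 2) {
    rlang::abort("training set contains a single class",
                 class = "mmgru_single_class")
  }

  std <- if (config$standardize) {
    fit_standardization(cohort, modality, ids)
  } else {
    list(center = rep(0, spec$n_features), scale = rep(1, spec$n_features))
  }
  seqs <- lapply(ids, function(id) {
    standardize_obs(get_sequence(cohort, id, modality)$observations, std)
  })

  params <- init_gru_params(spec$n_features, spec$hidden_dim, 2L,
                            seed = config$seed + 131L * reg_idx)

  aux <- groups %in% c("CN", "AD")
  loss_pre <- numeric(0)
  if (any(aux) && length(unique(labels[aux])) == 2 &&
      config$epochs_pretrain > 0) {
    params <- run_epochs(params, new_batch(seqs[aux], labels[aux]), config,
                         config$epochs_pretrain)
    loss_pre <- attr(params, "loss_trace")
  }
  params <- run_epochs(params, new_batch(seqs, labels), config,
                       config$epochs_main)
  loss_main <- attr(params, "loss_trace")
  attr(params, "loss_trace") <- NULL

  structure(list(spec = spec, params = params,
                 standardization = std,
                 n_train = length(ids),
                 train_ids = ids,
                 loss_pretrain = loss_pre, loss_main = loss_main),
            class = "mmgru_encoder")
}

# full-batch, or fixed-order mini-batches when batch_size is set
run_epochs <- function(params, batch, config, epochs) {
  if (epochs == 0) {
    attr(params, "loss_trace") <- batch_loss(params, batch)
    return(params)
  }
  if (is.null(config$batch_size) ||
      config$batch_size >= length(batch$labels)) {
    return(train_gd(params, batch, epochs, config$learning_rate))
  }
  n <- length(batch$labels)
  starts <- seq(1, n, by = config$batch_size)
  trace <- numeric(0)
  for (e in seq_len(epochs)) {
    trace <- c(trace, batch_loss(params, batch))
    for (s in starts) {
      idx <- s:min(s + config$batch_size - 1, n)
      sub <- new_batch(batch$sequences[idx], batch$labels[idx])
      g <- bptt_gradients(params, sub)
      v <- params_to_vector(params) -
        config$learning_rate * params_to_vector(g)
      params <- vector_to_params(v, params)
    }
  }
  attr(params, "loss_trace") <- c(trace, batch_loss(params, batch))
  params
}

#' Fixed-size representation of one subject under a trained encoder
#'
#' @param encoder An `mmgru_encoder`.
#' @param cohort Cohort holding the subject's visits.
#' @param subject_id Subject identifier.
#' @return Hidden vector of length `hidden_dim`, or `NULL` when the subject
#'   lacks the modality.
#' @export
extract_representation <- function(encoder, cohort, subject_id) {
  seq_ <- get_sequence(cohort, subject_id, encoder$spec$modality)
  if (is.null(seq_)) return(NULL)
  encode_sequence(encoder$params,
                  standardize_obs(seq_$observations,
                                  encoder$standardization))
}

#' Concatenated multi-modal feature vectors
#'
#' Joins each encoder's fixed-size representation in the order the encoders
#' are given (canonically cognitive, demographics, CSF, MRI). A missing
#' modality contributes according to `missing_policy`: a zero vector
#' (default) or the encoder's training-set mean representation. The feature
#' length is always the sum of the hidden dimensions (18 under the default
#' registry).
#'
#' @param encoders List of trained `mmgru_encoder`s.
#' @param cohort Cohort holding the subjects' visits.
#' @param subject_ids Character vector of subjects.
#' @param missing_policy `"zero"` or `"mean"`.
#' @return N x sum(hidden_dim) numeric matrix, rownames = subject ids.
#' @export
assemble_features <- function(encoders, cohort, subject_ids,
                              missing_policy = "zero") {
  fill <- lapply(encoders, function(enc) {
    if (missing_policy == "mean") {
      reps <- lapply(enc$train_ids, function(id) {
        extract_representation(enc, cohort, id)
      })
      reps <- reps[!vapply(reps, is.null, logical(1))]
      if (length(reps) > 0) {
        colMeans(do.call(rbind, reps))
      } else {
        rep(0, enc$spec$hidden_dim)
      }
    } else {
      rep(0, enc$spec$hidden_dim)
    }
  })
  rows <- lapply(subject_ids, function(id) {
    unlist(lapply(seq_along(encoders), function(j) {
      r <- extract_representation(encoders[[j]], cohort, id)
      if (is.null(r)) fill[[j]] else r
    }), use.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- subject_ids
  out
}

#' L1-regularised logistic regression
#'
#' Minimises `mean(log(1 + exp(-y_pm * (X w + b)))) + lambda * ||w||_1`
#' (intercept unpenalised) by proximal gradient descent with Nesterov
#' acceleration (FISTA) and soft-thresholding, from a zero start;
#' deterministic given the inputs. At large lambda all weights are exactly
#' zero and the intercept converges to the log-odds of the class balance.
#'
#' @param x N x D feature matrix.
#' @param y Binary labels (0 = non-converter, 1 = converter).
#' @param lambda Non-negative penalty.
#' @param max_iter,tol Iteration cap and parameter-change tolerance.
#' @return An `mmgru_fusion` model: `weights`, `intercept`, `lambda`.
#' @export
fit_l1_logistic <- function(x, y, lambda, max_iter = 20000L, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)), lambda >= 0)
  if (length(unique(y)) < 2) {
    rlang::abort("fusion training labels contain a single class",
                 class = "mmgru_single_class")
  }
  n <- nrow(x); d <- ncol(x)
  xa <- cbind(1, x)
  lip <- 0.25 * max(eigen(crossprod(xa) / n, symmetric = TRUE,
                          only.values = TRUE)$values)
  step <- 1 / max(lip, 1e-12)
  w <- rep(0, d); b <- 0
  wv <- w; bv <- b; tk <- 1
  soft <- function(v, k) sign(v) * pmax(abs(v) - k, 0)
  for (it in seq_len(max_iter)) {
    p <- sigmoid(as.numeric(xa %*% c(bv, wv)))
    r <- (p - y) / n
    gw <- as.numeric(crossprod(x, r))
    gb <- sum(r)
    w_new <- soft(wv - step * gw, step * lambda)
    b_new <- bv - step * gb
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    wv <- w_new + ((tk - 1) / tk_new) * (w_new - w)
    bv <- b_new + ((tk - 1) / tk_new) * (b_new - b)
    delta <- max(abs(c(w_new - w, b_new - b)))
    w <- w_new; b <- b_new; tk <- tk_new
    if (delta < tol) break
  }
  structure(list(weights = w, intercept = b, lambda = lambda),
            class = "mmgru_fusion")
}

# inner stratified grid search for lambda, minimising validation log-loss
select_lambda <- function(x, y, grid = 10^seq(-3, 1, by = 0.5), k = 3L,
                          seed = 1L) {
  folds <- make_folds(tibble::tibble(
    subject_id = as.character(seq_along(y)), label = y
  ), k = k, repeats = 1L, seed = seed)[[1]]
  ll <- vapply(grid, function(lam) {
    mean(vapply(seq_len(k), function(f) {
      te <- as.integer(folds$subject_id[folds$fold == f])
      tr <- setdiff(seq_along(y), te)
      if (length(unique(y[tr])) < 2) return(NA_real_)
      m <- fit_l1_logistic(x[tr, , drop = FALSE], y[tr], lam,
                           max_iter = 4000L, tol = 1e-8)
      p <- predict_conversion(m, x[te, , drop = FALSE])
      -mean(y[te] * log(pmax(p, 1e-12)) +
              (1 - y[te]) * log(pmax(1 - p, 1e-12)))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  # prefer the sparser (larger) lambda on ties
  grid[max(which(ll <= min(ll) + 1e-12))]
}

#' Predicted conversion probability
#'
#' `logistic(intercept + weights . features)` for one feature vector or the
#' rows of a feature matrix.
#'
#' @param model An `mmgru_fusion`.
#' @param features Numeric vector of the model's feature length, or a matrix
#'   with that many columns.
#' @return Probability (vector) in (0, 1).
#' @export
predict_conversion <- function(model, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$weights)) {
    rlang::abort("feature length does not match fusion model",
                 class = "mmgru_shape_error")
  }
  as.numeric(sigmoid(model$intercept + features %*% model$weights))
}

#' Fit the full two-stage multi-modal model
#'
#' Stage 1 trains one GRU encoder per requested modality on every training
#' subject possessing it (CN/AD pre-training, then horizon-labelled MCI);
#' stage 2 concatenates the representations of the eligible training MCI
#' subjects and fits the l1-regularised logistic head. Stage 2 never touches
#' encoder parameters.
#'
#' @param cohort Training cohort (already restricted to training subjects).
#' @param dt Prediction horizon in months.
#' @param modalities Modalities to encode, in concatenation order.
#' @param config A [train_config()].
#' @return An `mmgru_model` with elements `encoders`, `fusion`,
#'   `modalities`, `dt`, `config`.
#' @export
fit_mmgru <- function(cohort, dt, modalities = cohort$registry$modality,
                      config = train_config()) {
  encoders <- lapply(modalities, function(m) {
    train_modality_gru(cohort, m, dt, config)
  })
  names(encoders) <- modalities

  s <- cohort$subjects
  mci_ids <- s$subject_id[s$baseline_group == "MCI"]
  lab <- vapply(mci_ids, function(id) {
    derive_label(s[s$subject_id == id, ], dt)
  }, character(1))
  keep <- lab != "ineligible"
  mci_ids <- mci_ids[keep]
  y <- as.integer(lab[keep] == "converter")
  feats <- assemble_features(encoders, cohort, mci_ids,
                             config$missing_policy)
  lambda <- config$l1_strength %||%
    select_lambda(feats, y, seed = config$seed)
  fusion <- fit_l1_logistic(feats, y, lambda)
  structure(list(encoders = encoders, fusion = fusion,
                 modalities = modalities, dt = dt, config = config),
            class = "mmgru_model")
}

#' Predict conversion probabilities for subjects
#'
#' @param object An `mmgru_model`.
#' @param cohort Cohort holding the subjects' visits.
#' @param subject_ids Subjects to score.
#' @param ... Unused.
#' @return Tibble with `subject_id` and `p_conversion`.
#' @export
predict.mmgru_model <- function(object, cohort, subject_ids, ...) {
  feats <- assemble_features(object$encoders, cohort, subject_ids,
                             object$config$missing_policy)
  tibble::tibble(subject_id = subject_ids,
                 p_conversion = predict_conversion(object$fusion, feats))
}
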