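#' Horizon-windowed conversion label
#'
#' Labels an MCI subject at prediction horizon `dt` months from baseline:
#' `converter` if conversion occurred by `dt`; `non_converter` if no
#' conversion by `dt` and follow-up reaches at least `dt` (subjects
#' converting after `dt` had not converted within the window and count as
#' non-converters at that horizon); `ineligible` when an unconverted
#' subject's follow-up is shorter than `dt`, since the window cannot be
#' observed.
#'
#' @param subject One-row subject tibble (or list) with `baseline_group`,
#'   `conversion_month`, `followup_month`.
#' @param dt Horizon in months.
#' @return `"converter"`, `"non_converter"` or `"ineligible"`.
#' @export
derive_label <- function(subject, dt) {
  if (subject$baseline_group[[1]] != "MCI") {
    rlang::abort("conversion labels are defined for MCI subjects only",
                 class = "mmgru_not_mci")
  }
  conv <- subject$conversion_month[[1]]
  if (!is.na(conv) && conv <= dt) return("converter")
  if (subject$followup_month[[1]] >= dt) return("non_converter")
  "ineligible"
}

# label every MCI subject of a cohort at horizon dt; drops ineligible rows
eligible_mci <- function(cohort, dt) {
  s <- cohort$subjects[cohort$subjects$baseline_group == "MCI", ]
  if (nrow(s) == 0) {
    return(tibble::tibble(subject_id = character(), label = integer()))
  }
  lab <- vapply(seq_len(nrow(s)), function(i) derive_label(s[i, ], dt),
                character(1))
  tibble::tibble(subject_id = s$subject_id, label = as.integer(
    lab == "converter"
  ))[lab != "ineligible", ]
}

#' Repeated stratified fold assignments
#'
#' Per repeat, partitions the labelled subjects into `k` folds so that every
#' fold's converter count is within one subject of an even split (the same
#' converter / non-converter ratio in every fold, up to integer rounding).
#' Deterministic given the seed; each repeat uses a distinct shuffle.
#'
#' @param labelled Tibble with `subject_id` and binary `label`
#'   (1 = converter).
#' @param k Number of folds (>= 2).
#' @param repeats Number of repetitions.
#' @param seed Integer seed (independent of any training seed).
#' @return List of length `repeats`; each element a tibble `subject_id`,
#'   `label`, `fold`.
#' @export
make_folds <- function(labelled, k = 5L, repeats = 10L, seed = 1L) {
  stopifnot(k >= 2)
  if (nrow(labelled) < k) {
    rlang::abort("fewer subjects than folds", class = "mmgru_too_few_subjects")
  }
  if (length(unique(labelled$label)) < 2) {
    rlang::abort("both classes must be present to stratify folds",
                 class = "mmgru_single_class")
  }
  withr::with_seed(seed, lapply(seq_len(repeats), function(r) {
    pos <- sample(labelled$subject_id[labelled$label == 1])
    neg <- sample(labelled$subject_id[labelled$label == 0])
    ordered_ids <- c(pos, neg)
    # one round-robin stream across the class-ordered ids keeps both the
    # fold sizes and the per-fold converter counts within 1 of even
    assign <- rep(seq_len(k), length.out = length(ordered_ids))
    tibble::tibble(
      subject_id = ordered_ids,
      label = c(rep(1L, length(pos)), rep(0L, length(neg))),
      fold = assign
    )
  }))
}

#' Experimental scheme
#'
#' The three training-data compositions compared in the study: `baseline`
#' uses all four modalities but truncates every sequence to the baseline
#' visit; `single_modal` uses one modality with full sequences; `proposed`
#' uses all four modalities with full sequences.
#'
#' @param name `"proposed"`, `"baseline"` or `"single_modal"`.
#' @param modality Modality for `single_modal`.
#' @param registry Modality registry.
#' @return An `mmgru_scheme`.
#' @export
scheme <- function(name = c("proposed", "baseline", "single_modal"),
                   modality = NULL, registry = modality_registry()) {
  name <- match.arg(name)
  if (name == "single_modal") {
    if (is.null(modality) || !modality %in% registry$modality) {
      rlang::abort("single_modal scheme needs a registered modality",
                   class = "mmgru_scheme_error")
    }
    modalities <- modality
  } else {
    modalities <- registry$modality
  }
  structure(list(
    name = name,
    label = if (name == "single_modal") paste0("single:", modality) else name,
    modalities = modalities,
    truncate = name == "baseline",
    uses_longitudinal = name != "baseline"
  ), class = "mmgru_scheme")
}

#' Classification metrics at a fixed threshold
#'
#' Accuracy at the 0.5 threshold (probability strictly above predicts
#' conversion), sensitivity (true-positive rate among converters),
#' specificity (true-negative rate among non-converters) and AUC via the
#' Mann-Whitney rank statistic with ties averaged.
#'
#' @param labels Binary labels (1 = converter).
#' @param probabilities Predicted conversion probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(probabilities))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("sensitivity/specificity/AUC need both classes present",
                 class = "mmgru_single_class")
  }
  pred <- as.integer(probabilities > threshold)
  r <- rank(probabilities, ties.method = "average")
  list(
    accuracy = mean(pred == labels),
    sensitivity = sum(pred == 1 & labels == 1) / n_pos,
    specificity = sum(pred == 0 & labels == 0) / n_neg,
    auc = (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  )
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; insensitive to class imbalance.
#'
#' @param sensitivity,specificity Values in `[0, 1]`.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    rlang::abort("sensitivity and specificity must lie in [0, 1]",
                 class = "mmgru_out_of_range")
  }
  (sensitivity + specificity) / 2
}

#' Paired t-test between per-fold metric vectors
#'
#' Classical paired t on the differences, paired by (repeat, fold); p from
#' the t distribution with n - 1 degrees of freedom. With zero variance of
#' the differences the statistic is degenerate: p = 1 when the vectors are
#' identical (t = 0), p = 0 for a constant nonzero shift (t = +/-Inf by the
#' sign of the shift).
#'
#' @param metric_a,metric_b Equal-length numeric vectors (>= 2).
#' @return List `t`, `p`, `df`.
#' @export
paired_t_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2)
  d <- metric_a - metric_b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1), df = n - 1)
}

#' Cross-validation settings
#' @param k Folds. @param repeats Repetitions.
#' @param seed Fold-assignment seed (kept separate from training seeds so CV
#'   structure and initialisation vary independently).
#' @return A list.
#' @export
cv_config <- function(k = 5L, repeats = 10L, seed = 42L) {
  list(k = as.integer(k), repeats = as.integer(repeats),
       seed = as.integer(seed))
}

#' Run one scheme at one horizon under repeated stratified CV
#'
#' For each repeat x fold: stage 1 trains on all CN/AD subjects plus the
#' training-fold MCI subjects (under the scheme's modality and truncation
#' rules), stage 2 on the training-fold MCI, and the held-out MCI fold alone
#' is scored. CN/AD auxiliaries enter every training split and no test
#' split; the absence of train/test overlap and the prevalence identity
#' `ACC = prev * SEN + (1 - prev) * SPE` are asserted on every fold.
#'
#' @param cohort An `mmgru_cohort`.
#' @param scheme_ An [scheme()].
#' @param dt Horizon in months.
#' @param config A [train_config()].
#' @param cv A [cv_config()].
#' @return An `mmgru_eval` with per-repeat-per-fold metric records.
#' @export
run_scheme <- function(cohort, scheme_, dt, config = train_config(),
                       cv = cv_config()) {
  stopifnot(inherits(scheme_, "mmgru_scheme"))
  data_cohort <- if (scheme_$truncate) truncate_to_baseline(cohort) else cohort
  labelled <- eligible_mci(data_cohort, dt)
  folds <- make_folds(labelled, cv$k, cv$repeats, cv$seed)
  aux_ids <- data_cohort$subjects$subject_id[
    data_cohort$subjects$baseline_group %in% c("CN", "AD")
  ]
  records <- list()
  for (r in seq_len(cv$repeats)) {
    fr <- folds[[r]]
    for (f in seq_len(cv$k)) {
      test_ids <- fr$subject_id[fr$fold == f]
      train_mci <- fr$subject_id[fr$fold != f]
      train_ids <- c(aux_ids, train_mci)
      if (length(test_ids) == 0) {
        rlang::abort("empty test fold", class = "mmgru_empty_fold")
      }
      stopifnot(length(intersect(test_ids, train_ids)) == 0)

      fold_config <- config
      fold_config$seed <- config$seed + 1000L * r + 10L * f
      model <- fit_mmgru(subset_cohort(data_cohort, train_ids), dt,
                         modalities = scheme_$modalities,
                         config = fold_config)
      preds <- predict(model, data_cohort, test_ids)
      truth <- fr$label[match(test_ids, fr$subject_id)]
      m <- compute_metrics(truth, preds$p_conversion)
      prev <- mean(truth == 1)
      stopifnot(abs(m$accuracy -
                      (prev * m$sensitivity + (1 - prev) * m$specificity))
                < 1e-12)
      records[[length(records) + 1L]] <- tibble::tibble(
        repeat_ = r, fold = f, n_test = length(test_ids), prevalence = prev,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, auc = m$auc
      )
    }
  }
  structure(list(dt = dt, scheme = scheme_$label,
                 records = dplyr::bind_rows(records)),
            class = "mmgru_eval")
}

#' @export
print.mmgru_eval <- function(x, ...) {
  cat("<mmgru_eval> scheme=", x$scheme, " dt=", x$dt, "m, ",
      nrow(x$records), " fold records\n", sep = "")
  agg <- glance(x)
  cat(sprintf("  ACC %.3f+/-%.3f  SEN %.3f+/-%.3f  SPE %.3f+/-%.3f  AUC %.3f+/-%.3f\n",
              agg$accuracy, agg$accuracy_sd, agg$sensitivity,
              agg$sensitivity_sd, agg$specificity, agg$specificity_sd,
              agg$auc, agg$auc_sd))
  invisible(x)
}

#' Tabular report over evaluation results
#'
#' Aggregates per-(horizon, scheme) means and sds over the repeat x fold
#' records and, where a `proposed` result is present for the horizon, the
#' paired t-test p-value of every other scheme against it for each metric.
#'
#' @param results List of `mmgru_eval` objects.
#' @return An `mmgru_report`: tibbles `table` (dt, scheme, metric, mean, sd)
#'   and `comparisons` (dt, scheme, metric, t, p).
#' @export
report <- function(results) {
  stopifnot(length(results) >= 1)
  metrics <- c("accuracy", "sensitivity", "specificity", "auc")
  table <- purrr::map_dfr(results, function(res) {
    purrr::map_dfr(metrics, function(m) {
      tibble::tibble(dt = res$dt, scheme = res$scheme, metric = m,
                     mean = mean(res$records[[m]]),
                     sd = stats::sd(res$records[[m]]))
    })
  })
  comparisons <- purrr::map_dfr(results, function(res) {
    if (res$scheme == "proposed") return(NULL)
    prop <- purrr::detect(results, function(r)
      r$scheme == "proposed" && r$dt == res$dt)
    if (is.null(prop)) return(NULL)
    purrr::map_dfr(metrics, function(m) {
      tt <- paired_t_test(prop$records[[m]], res$records[[m]])
      tibble::tibble(dt = res$dt, scheme = res$scheme, metric = m,
                     t = tt$t, p = tt$p)
    })
  })
  structure(list(table = table, comparisons = comparisons),
            class = "mmgru_report")
}

#' @export
print.mmgru_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$table,
                  value = sprintf("%.3f +/- %.3f", .data$mean, .data$sd)),
    id_cols = c("scheme", "metric"), names_from = "dt",
    values_from = "value", names_prefix = "dt="
  )
  print(wide, n = Inf)
  invisible(x)
}

#' Write a report to CSV and JSON
#'
#' @param x An `mmgru_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "metrics.csv"),
             comparisons = file.path(dir, "comparisons.csv"),
             json = file.path(dir, "report.json"))
  readr::write_csv(x$table, paths[["table"]])
  readr::write_csv(x$comparisons, paths[["comparisons"]])
  jsonlite::write_json(list(table = x$table, comparisons = x$comparisons),
                       paths[["json"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read back a JSON report
#' @param path Path to `report.json`.
#' @return An `mmgru_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = tibble::as_tibble(raw$table),
                 comparisons = tibble::as_tibble(raw$comparisons)),
            class = "mmgru_report")
}
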