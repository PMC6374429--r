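mci_subject <- function(conversion, followup) {
  tibble::tibble(subject_id = "x", baseline_group = "MCI",
                 conversion_month = conversion, followup_month = followup)
}

test_that("horizon labels follow the windowing rule", {
  expect_equal(derive_label(mci_subject(6, 36), dt = 12), "converter")
  expect_equal(derive_label(mci_subject(NA, 36), dt = 24), "non_converter")
  expect_equal(derive_label(mci_subject(NA, 12), dt = 24), "ineligible")
  # conversion after the window counts as non-converter at that horizon
  expect_equal(derive_label(mci_subject(30, 36), dt = 24), "non_converter")
  cn <- tibble::tibble(subject_id = "c", baseline_group = "CN",
                       conversion_month = NA_real_, followup_month = 36)
  expect_error(derive_label(cn, 12), class = "mmgru_not_mci")
})

test_that("stratified folds partition and balance exactly", {
  labelled <- tibble::tibble(subject_id = paste0("s", 1:10),
                             label = c(rep(1L, 4), rep(0L, 6)))
  folds <- make_folds(labelled, k = 5, repeats = 3, seed = 2)
  for (fr in folds) {
    # exhaustive check of the partition
    expect_setequal(fr$subject_id, labelled$subject_id)
    sizes <- table(fr$fold)
    expect_true(all(sizes == 2))
    conv <- tapply(fr$label, fr$fold, sum)
    expect_lte(max(conv) - min(conv), 1)
  }
  # deterministic under the seed, distinct across repeats
  folds2 <- make_folds(labelled, k = 5, repeats = 3, seed = 2)
  expect_identical(folds, folds2)
  expect_false(identical(folds[[1]], folds[[2]]))
  expect_error(make_folds(labelled[1:3, ], k = 5),
               class = "mmgru_too_few_subjects")
  expect_error(make_folds(dplyr::mutate(labelled, label = 1L), k = 5),
               class = "mmgru_single_class")
})

test_that("metrics have their closed forms and the AUC matches brute force", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, auc = 1))
  flat <- compute_metrics(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(flat$auc, 0.5)
  # 6-sample hand case vs exhaustive pair counting
  labels <- c(1, 1, 1, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  m <- compute_metrics(labels, probs)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  brute <- mean(ifelse(probs[pairs$p] > probs[pairs$n], 1,
                       ifelse(probs[pairs$p] == probs[pairs$n], 0.5, 0)))
  expect_equal(m$auc, brute)
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)),
               class = "mmgru_single_class")
})

test_that("AUC agrees with an independent implementation and is
           rank-invariant", {
  withr::with_seed(9, {
    labels <- rbinom(40, 1, 0.4)
    probs <- runif(40)
  })
  m <- compute_metrics(labels, probs)
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(labels, probs,
                                    direction = "<", quiet = TRUE))
  expect_equal(m$auc, as.numeric(ref), tolerance = 1e-12)
  # invariant under a strictly monotone transform of the probabilities
  m2 <- compute_metrics(labels, plogis(5 * qlogis(pmin(pmax(probs, 1e-6),
                                                       1 - 1e-6))))
  expect_equal(m2$auc, m$auc, tolerance = 1e-12)
})

test_that("balanced accuracy averages sensitivity and specificity", {
  expect_equal(balanced_accuracy(0.84, 0.80), 0.82)
  expect_equal(balanced_accuracy(1, 1), 1)
  s <- seq(0, 1, by = 0.1)
  expect_equal(balanced_accuracy(s, s), s)
  expect_error(balanced_accuracy(1.2, 0.5), class = "mmgru_out_of_range")
})

test_that("paired t-test matches the textbook formula and handles
           degenerate branches", {
  a <- c(0.80, 0.82, 0.78, 0.85, 0.81)
  b <- c(0.75, 0.80, 0.74, 0.80, 0.79)
  res <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # identical vectors: zero-variance branch, t = 0, p = 1
  same <- paired_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant nonzero shift: infinite statistic by sign convention
  shift <- paired_t_test(a + 0.1, a)
  expect_equal(shift$t, Inf)
  expect_equal(shift$p, 0)
})

test_that("report aggregates equal a recount from raw records", {
  co <- small_sim_cohort()
  cfg <- fast_config()
  cv <- cv_config(k = 3, repeats = 2, seed = 11)
  res_p <- run_scheme(co, scheme("proposed"), dt = 24, config = cfg, cv = cv)
  res_b <- run_scheme(co, scheme("baseline"), dt = 24, config = cfg, cv = cv)
  expect_equal(nrow(res_p$records), 6)  # repeats x folds
  rep_ <- report(list(res_p, res_b))
  row <- rep_$table[rep_$table$scheme == "proposed" &
                      rep_$table$metric == "accuracy", ]
  expect_equal(row$mean, mean(res_p$records$accuracy))
  expect_equal(row$sd, sd(res_p$records$accuracy))
  cmp <- rep_$comparisons[rep_$comparisons$metric == "accuracy", ]
  tt <- paired_t_test(res_p$records$accuracy, res_b$records$accuracy)
  expect_equal(cmp$p, tt$p)
  # JSON round-trips losslessly
  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  back <- read_report(file.path(dir, "report.json"))
  expect_equal(back$table$mean, rep_$table$mean, tolerance = 1e-12)

  # single result still renders
  rep1 <- report(list(res_p))
  expect_equal(nrow(rep1$table), 4)
})

test_that("baseline scheme equals proposed on an already length-one cohort", {
  cfg_sim <- sim_config(n_cn = 30L, n_mci_c = 25L, n_mci_nc = 40L,
                        n_ad = 25L,
                        length_mean = c(cognitive = 1, demographics = 1,
                                        csf = 1, mri = 1),
                        length_sd = c(cognitive = 0, demographics = 0,
                                      csf = 0, mri = 0),
                        seed = 31L)
  co <- simulate_cohort(cfg_sim)
  cfg <- fast_config()
  cv <- cv_config(k = 3, repeats = 1, seed = 4)
  res_p <- run_scheme(co, scheme("proposed"), dt = 24, config = cfg, cv = cv)
  res_b <- run_scheme(co, scheme("baseline"), dt = 24, config = cfg, cv = cv)
  expect_equal(res_b$records, res_p$records)
})

test_that("tidy, glance, autoplot and ROC export expose results coherently", {
  rec <- tibble::tibble(repeat_ = c(1L, 1L), fold = 1:2, n_test = 10L,
                        prevalence = 0.3,
                        accuracy = c(0.8, 0.9), sensitivity = c(0.5, 0.7),
                        specificity = c(0.9, 0.95), auc = c(0.7, 0.8))
  ev <- structure(list(dt = 24, scheme = "proposed", records = rec),
                  class = "mmgru_eval")
  td <- tidy(ev)
  expect_equal(td$accuracy, rec$accuracy)
  expect_equal(unique(td$scheme), "proposed")
  gl <- glance(ev)
  expect_equal(gl$accuracy, 0.85)
  expect_equal(gl$n_records, 2L)
  expect_s3_class(autoplot(ev), "ggplot")

  labels <- c(1, 1, 1, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  rp <- roc_points(labels, probs)
  expect_equal(rp$fpr[1], 0)
  expect_equal(rp$tpr[nrow(rp)], 1)
  # trapezoid area under the ROC equals the rank-statistic AUC
  area <- sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2)
  expect_equal(area, compute_metrics(labels, probs)$auc, tolerance = 1e-12)
})

test_that("no CN/AD subject ever enters a test fold", {
  co <- small_sim_cohort()
  labelled <- mmgru:::eligible_mci(co, 24)
  aux <- co$subjects$subject_id[co$subjects$baseline_group != "MCI"]
  folds <- make_folds(labelled, k = 3, repeats = 2, seed = 8)
  for (fr in folds) {
    expect_length(intersect(fr$subject_id, aux), 0)
  }
})
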