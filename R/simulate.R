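#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Each subject carries a
#' latent disease severity that is linear in time,
#' `s_i(t) = a_i + b_i * t` (t in months from baseline), with the intercept
#' and slope drawn per diagnostic group; an MCI subject converts at the first
#' visit-grid time within follow-up at which severity reaches
#' `conversion_threshold`. Biomarker modalities observe severity through a
#' per-modality loading vector plus Gaussian noise; demographics are
#' severity-independent except an APOE-epsilon4-like binary whose frequency
#' rises with disease group. Group sizes default to the composition of a
#' typical large amnestic-MCI study cohort (415 CN, 307 MCI converters,
#' 558 MCI non-converters, 338 AD), and sequence lengths to per-modality
#' moments in the same spirit (cognitive 3.7 +/- 1.32 visits, CSF
#' 1.4 +/- 0.5, demographics and MRI single-visit).
#'
#' @param n_cn,n_mci_c,n_mci_nc,n_ad Group sizes.
#' @param visit_spacing_months Spacing of the visit grid (months).
#' @param length_mean,length_sd Named per-modality sequence-length moments;
#'   lengths are drawn normal, rounded, truncated to >= 1 (non-longitudinal
#'   modalities are always length one).
#' @param loading Named list of per-modality loading vectors (one entry per
#'   feature) mapping severity to the observation mean.
#' @param noise_sd Named per-modality observation noise standard deviations.
#' @param severity_intercept_mean,severity_intercept_sd Per-group (CN/MCI/AD)
#'   mean and shared sd of the severity intercept `a_i`.
#' @param severity_slope_mean,severity_slope_sd Per-group mean and shared sd
#'   of the monthly severity slope `b_i`.
#' @param conversion_threshold Severity level defining conversion.
#' @param severity_margin MCI candidates whose end-of-follow-up severity
#'   falls within this distance of the threshold are rejected (default 0,
#'   no rejection). A positive margin creates a class gap, used by the
#'   separable ceiling-check configuration: without it, subjects can sit
#'   arbitrarily close to the decision boundary and no classifier trained
#'   on finite samples can reach perfect accuracy.
#' @param followup_months Pool of follow-up lengths sampled uniformly.
#' @param modality_presence_prob Named per-modality probability that a
#'   subject has the modality at all (demographics always present).
#' @param apoe_prob Probability of the APOE-like risk allele per group
#'   (CN, MCI_NC, MCI_C, AD).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param registry Modality registry.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cn = 415L, n_mci_c = 307L, n_mci_nc = 558L,
                       n_ad = 338L,
                       visit_spacing_months = 6,
                       length_mean = c(cognitive = 3.7, demographics = 1,
                                       csf = 1.4, mri = 1),
                       length_sd = c(cognitive = 1.32, demographics = 0,
                                     csf = 0.5, mri = 0),
                       loading = list(
                         cognitive = c(-0.8, -0.5),
                         demographics = c(0, 0, 0, 0),
                         csf = c(-0.7, 0.6, 0.6, 0.35, -0.3),
                         mri = c(-0.6, -0.5, -0.35)
                       ),
                       noise_sd = c(cognitive = 0.6, demographics = 0,
                                    csf = 0.6, mri = 0.6),
                       severity_intercept_mean = c(CN = -2, MCI = 0, AD = 2),
                       severity_intercept_sd = 0.6,
                       severity_slope_mean = c(CN = 0.005, MCI = 0.035,
                                               AD = 0.04),
                       severity_slope_sd = 0.02,
                       conversion_threshold = 1.2,
                       severity_margin = 0,
                       followup_months = seq(24, 60, by = 6),
                       modality_presence_prob = c(cognitive = 0.9,
                                                  demographics = 1,
                                                  csf = 0.6, mri = 0.85),
                       apoe_prob = c(CN = 0.275, MCI_NC = 0.418,
                                     MCI_C = 0.658, AD = 0.666),
                       seed = 1L,
                       registry = modality_registry()) {
  config <- list(
    n_cn = as.integer(n_cn), n_mci_c = as.integer(n_mci_c),
    n_mci_nc = as.integer(n_mci_nc), n_ad = as.integer(n_ad),
    visit_spacing_months = visit_spacing_months,
    length_mean = length_mean, length_sd = length_sd,
    loading = loading, noise_sd = noise_sd,
    severity_intercept_mean = severity_intercept_mean,
    severity_intercept_sd = severity_intercept_sd,
    severity_slope_mean = severity_slope_mean,
    severity_slope_sd = severity_slope_sd,
    conversion_threshold = conversion_threshold,
    severity_margin = severity_margin,
    followup_months = followup_months,
    modality_presence_prob = modality_presence_prob,
    apoe_prob = apoe_prob,
    seed = as.integer(seed),
    registry = registry
  )
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  counts <- c(config$n_cn, config$n_mci_c, config$n_mci_nc, config$n_ad)
  if (any(counts < 0)) {
    rlang::abort("group sizes must be >= 0", class = "mmgru_sim_config_error")
  }
  if (any(config$length_sd < 0) || any(config$noise_sd < 0) ||
      config$severity_intercept_sd < 0 || config$severity_slope_sd < 0) {
    rlang::abort("standard deviations must be >= 0",
                 class = "mmgru_sim_config_error")
  }
  p <- config$modality_presence_prob
  if (any(p < 0 | p > 1) || any(config$apoe_prob < 0 | config$apoe_prob > 1)) {
    rlang::abort("probabilities must lie in [0, 1]",
                 class = "mmgru_sim_config_error")
  }
  mods <- config$registry$modality
  for (field in c("length_mean", "length_sd", "noise_sd",
                  "modality_presence_prob")) {
    if (!all(mods %in% names(config[[field]]))) {
      rlang::abort(paste0(field, " must name every registered modality"),
                   class = "mmgru_sim_config_error")
    }
  }
  for (i in seq_len(nrow(config$registry))) {
    mod <- config$registry$modality[i]
    if (length(config$loading[[mod]]) != config$registry$n_features[i]) {
      rlang::abort(paste0("loading vector for ", mod,
                          " must have ", config$registry$n_features[i],
                          " entries"),
                   class = "mmgru_sim_config_error")
    }
  }
  invisible(config)
}

#' First visit-grid month at which severity reaches a threshold
#'
#' Conversion is defined on the visit grid (0, spacing, 2*spacing, ...)
#' within follow-up, mirroring that diagnoses are made at visits.
#'
#' @param intercept,slope Severity line parameters (vectors recycle).
#' @param followup Follow-up length in months.
#' @param spacing Visit-grid spacing in months.
#' @param threshold Severity threshold defining conversion.
#' @return Numeric vector of conversion months, NA where severity never
#'   reaches the threshold on the grid within follow-up.
#' @export
conversion_on_grid <- function(intercept, slope, followup, spacing,
                               threshold) {
  n <- max(length(intercept), length(slope), length(followup))
  intercept <- rep_len(intercept, n)
  slope <- rep_len(slope, n)
  followup <- rep_len(followup, n)
  vapply(seq_len(n), function(i) {
    grid <- seq(0, followup[i], by = spacing)
    hit <- grid[intercept[i] + slope[i] * grid >= threshold]
    if (length(hit) == 0) NA_real_ else hit[1]
  }, numeric(1))
}

#' Draw a pool of MCI severity trajectories
#'
#' The raw generative draw for MCI subjects before converter/non-converter
#' quotas are enforced: severity intercept, slope, follow-up length, and the
#' resulting conversion month (NA if none). Useful for studying how the
#' converter fraction responds to the conversion threshold.
#'
#' @param config A [sim_config()].
#' @param n Pool size.
#' @param seed Seed for this draw (defaults to the config seed).
#' @return Tibble with columns `intercept`, `slope`, `followup_month`,
#'   `conversion_month`.
#' @export
simulate_mci_pool <- function(config, n, seed = config$seed) {
  withr::with_seed(seed, draw_mci_pool(config, n))
}

draw_mci_pool <- function(config, n) {
  a <- stats::rnorm(n, config$severity_intercept_mean[["MCI"]],
                    config$severity_intercept_sd)
  b <- stats::rnorm(n, config$severity_slope_mean[["MCI"]],
                    config$severity_slope_sd)
  fu <- config$followup_months[
    sample.int(length(config$followup_months), n, replace = TRUE)]
  conv <- conversion_on_grid(a, b, fu, config$visit_spacing_months,
                             config$conversion_threshold)
  pool <- tibble::tibble(intercept = a, slope = b, followup_month = fu,
                         conversion_month = conv)
  if (config$severity_margin > 0) {
    end_sev <- a + b * fu
    pool <- pool[abs(end_sev - config$conversion_threshold) >=
                   config$severity_margin, , drop = FALSE]
  }
  pool
}

draw_lengths <- function(config, modality, n, longitudinal) {
  if (!longitudinal) return(rep(1L, n))
  raw <- stats::rnorm(n, config$length_mean[[modality]],
                      config$length_sd[[modality]])
  pmax(1L, as.integer(round(raw)))
}

#' Simulate a synthetic multi-modal cohort
#'
#' Runs the latent-severity generative model of [sim_config()]: per-group
#' severity lines, grid-defined conversion events with converter /
#' non-converter counts enforced by rejection sampling, per-modality noisy
#' linear emissions, normally distributed (rounded, >= 1) sequence lengths
#' on a regular visit grid, and independent block modality missingness
#' (demographics always observed). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An `mmgru_cohort`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  # --- subject-level draws -------------------------------------------------
  draw_plain <- function(grp, n, prefix) {
    if (n == 0) {
      return(tibble::tibble(subject_id = character(), group = character(),
                            intercept = numeric(), slope = numeric(),
                            followup_month = numeric(),
                            conversion_month = numeric()))
    }
    tibble::tibble(
      subject_id = sprintf("%s%04d", prefix, seq_len(n)),
      group = grp,
      intercept = stats::rnorm(n, config$severity_intercept_mean[[grp]],
                               config$severity_intercept_sd),
      slope = stats::rnorm(n, config$severity_slope_mean[[grp]],
                           config$severity_slope_sd),
      followup_month = config$followup_months[
        sample.int(length(config$followup_months), n, replace = TRUE)],
      conversion_month = NA_real_
    )
  }
  cn <- draw_plain("CN", config$n_cn, "CN")
  ad <- draw_plain("AD", config$n_ad, "AD")

  # MCI: rejection sampling until the converter / non-converter quotas fill
  need_c <- config$n_mci_c
  need_nc <- config$n_mci_nc
  acc_c <- list()
  acc_nc <- list()
  got_c <- 0L
  got_nc <- 0L
  max_draws <- 60L * max(need_c + need_nc, 50L)
  drawn <- 0L
  while ((got_c < need_c || got_nc < need_nc) && drawn < max_draws) {
    batch_n <- max(100L, 2L * (need_c - got_c + need_nc - got_nc))
    pool <- draw_mci_pool(config, batch_n)
    drawn <- drawn + batch_n
    is_c <- !is.na(pool$conversion_month)
    if (got_c < need_c && any(is_c)) {
      take <- utils::head(which(is_c), need_c - got_c)
      acc_c[[length(acc_c) + 1L]] <- pool[take, , drop = FALSE]
      got_c <- got_c + length(take)
    }
    if (got_nc < need_nc && any(!is_c)) {
      take <- utils::head(which(!is_c), need_nc - got_nc)
      acc_nc[[length(acc_nc) + 1L]] <- pool[take, , drop = FALSE]
      got_nc <- got_nc + length(take)
    }
  }
  if (got_c < need_c || got_nc < need_nc) {
    rlang::abort(paste0(
      "infeasible simulation config: after ", drawn, " MCI draws only ",
      got_c, "/", need_c, " converters and ", got_nc, "/", need_nc,
      " non-converters were produced"
    ), class = "mmgru_sim_infeasible")
  }
  mci <- dplyr::bind_rows(dplyr::bind_rows(acc_c), dplyr::bind_rows(acc_nc))
  if (nrow(mci) > 0) {
    mci$subject_id <- sprintf("MCI%04d", seq_len(nrow(mci)))
    mci$group <- "MCI"
    mci <- mci[, names(cn)]
  } else {
    mci <- cn[0, ]
  }

  subj <- dplyr::bind_rows(cn, mci, ad)
  if (nrow(subj) == 0) {
    rlang::abort("simulation config requests zero subjects",
                 class = "mmgru_sim_infeasible")
  }

  apoe_group <- dplyr::case_when(
    subj$group == "CN" ~ "CN",
    subj$group == "AD" ~ "AD",
    !is.na(subj$conversion_month) ~ "MCI_C",
    TRUE ~ "MCI_NC"
  )
  subj$apoe <- stats::rbinom(nrow(subj), 1L, config$apoe_prob[apoe_group])

  # --- visit-level emissions ----------------------------------------------
  registry <- config$registry
  fcols <- feature_cols(registry)
  spacing <- config$visit_spacing_months
  visit_parts <- vector("list", nrow(registry))

  for (i in seq_len(nrow(registry))) {
    mod <- registry$modality[i]
    k <- registry$n_features[i]
    p <- config$modality_presence_prob[[mod]]
    present <- if (mod == "demographics") {
      rep(TRUE, nrow(subj))
    } else {
      stats::rbinom(nrow(subj), 1L, p) == 1L
    }
    idx <- which(present)
    if (length(idx) == 0) next
    lens <- draw_lengths(config, mod, length(idx), registry$longitudinal[i])
    row_subject <- rep(subj$subject_id[idx], lens)
    step <- sequence(lens) - 1L
    months <- step * spacing
    sev <- rep(subj$intercept[idx], lens) + rep(subj$slope[idx], lens) * months

    if (mod == "demographics") {
      n_i <- length(idx)
      obs <- cbind(
        stats::rnorm(n_i, 73, 7),                    # age
        stats::rbinom(n_i, 1L, 0.5),                 # sex
        stats::rnorm(n_i, 16, 2.8),                  # education
        subj$apoe[idx]                               # APOE-like allele
      )
    } else {
      lam <- config$loading[[mod]]
      obs <- outer(sev, lam)
      if (config$noise_sd[[mod]] > 0) {
        obs <- obs + matrix(stats::rnorm(length(obs), 0,
                                         config$noise_sd[[mod]]),
                            nrow = nrow(obs))
      }
    }
    part <- tibble::tibble(subject_id = row_subject, modality = mod,
                           visit_month = months)
    for (j in seq_along(fcols)) {
      part[[fcols[j]]] <- if (j <= k) obs[, j] else NA_real_
    }
    visit_parts[[i]] <- part
  }

  visits <- dplyr::bind_rows(visit_parts)
  subjects <- tibble::tibble(
    subject_id = subj$subject_id,
    baseline_group = subj$group,
    conversion_month = subj$conversion_month,
    followup_month = subj$followup_month
  )
  # demographics is always present, so every subject has >= 1 sequence
  new_cohort(subjects, visits, registry)
}

#' Summarise a cohort
#'
#' The standard cohort-description table: per modality the number of
#' subjects observed and the mean and sd of sequence length; per diagnostic
#' group (with the MCI converter / non-converter split) the subject count.
#'
#' @param cohort An `mmgru_cohort`.
#' @return A list of class `mmgru_cohort_summary` with tibbles `modalities`
#'   (`modality`, `n_subjects`, `mean_length`, `sd_length`) and `groups`
#'   (`group`, `n`).
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  modalities <- cohort$visits |>
    dplyr::count(.data$modality, .data$subject_id, name = "length") |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_length = mean(.data$length),
      sd_length = ifelse(dplyr::n() > 1, stats::sd(.data$length), 0),
      .groups = "drop"
    )
  modalities <- dplyr::left_join(
    tibble::tibble(modality = cohort$registry$modality), modalities,
    by = "modality"
  ) |>
    dplyr::mutate(n_subjects = dplyr::coalesce(.data$n_subjects, 0L))

  s <- cohort$subjects
  groups <- tibble::tibble(
    group = c("CN", "MCI", "MCI-C", "MCI-NC", "AD"),
    n = c(sum(s$baseline_group == "CN"),
          sum(s$baseline_group == "MCI"),
          sum(s$baseline_group == "MCI" & !is.na(s$conversion_month)),
          sum(s$baseline_group == "MCI" & is.na(s$conversion_month)),
          sum(s$baseline_group == "AD"))
  )
  structure(list(modalities = modalities, groups = groups),
            class = "mmgru_cohort_summary")
}

#' @export
print.mmgru_cohort_summary <- function(x, ...) {
  cat("Cohort summary\n\nGroups:\n")
  print(x$groups)
  cat("\nModalities:\n")
  print(x$modalities)
  invisible(x)
}

#' Stock benchmark configuration
#'
#' A desk-scale cohort (580 subjects, preserving the study's group
#' proportions) with complementary modality signals: the severity loadings
#' are balanced across the three biomarker modalities and the observation
#' noise is raised so that no single modality carries enough signal on its
#' own, the regime in which late fusion of all modalities is expected to
#' beat every single-modality model. Used for scheme-ordering experiments
#' where the full-size cohort would be unnecessarily slow.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
benchmark_config <- function(seed = 20260101L) {
  sim_config(n_cn = 150L, n_mci_c = 110L, n_mci_nc = 200L, n_ad = 120L,
             loading = list(
               cognitive = c(-0.5, -0.35),
               demographics = c(0, 0, 0, 0),
               csf = c(-0.5, 0.45, 0.45, 0.3, -0.25),
               mri = c(-0.5, -0.45, -0.3)
             ),
             noise_sd = c(cognitive = 1, demographics = 0, csf = 1, mri = 1),
             seed = seed)
}

#' Noise-free separable configuration
#'
#' A degenerate configuration with zero observation noise, complete
#' modality presence, a fixed 24-month follow-up, complete 5-visit
#' longitudinal sequences and a positive severity margin at the conversion
#' threshold, under which the MCI converter label is exactly a threshold on
#' the final cognitive observation with a class gap. Serves as a ceiling
#' check: any sensible classifier should reach perfect accuracy here.
#'
#' @param n_cn,n_mci_c,n_mci_nc,n_ad Group sizes.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
separable_config <- function(n_cn = 60L, n_mci_c = 50L, n_mci_nc = 50L,
                             n_ad = 60L, seed = 20260102L) {
  sim_config(
    n_cn = n_cn, n_mci_c = n_mci_c, n_mci_nc = n_mci_nc, n_ad = n_ad,
    length_mean = c(cognitive = 5, demographics = 1, csf = 5, mri = 1),
    length_sd = c(cognitive = 0, demographics = 0, csf = 0, mri = 0),
    noise_sd = c(cognitive = 0, demographics = 0, csf = 0, mri = 0),
    severity_slope_mean = c(CN = 0.005, MCI = 0.05, AD = 0.05),
    severity_slope_sd = 0.008,
    severity_margin = 0.3,
    followup_months = 24,
    modality_presence_prob = c(cognitive = 1, demographics = 1, csf = 1,
                               mri = 1),
    seed = seed
  )
}
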