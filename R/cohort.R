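#' Construct a longitudinal multi-modal cohort
#'
#' A cohort bundles a subject table, a long-format visit table and a modality
#' registry. Subjects carry a baseline diagnosis (CN, MCI or AD), an optional
#' conversion month (MCI only) and a follow-up length; visits carry one row
#' per (subject, modality, month) with feature values in columns `f1..fk`.
#' Missing modalities are first-class: a subject simply has no rows for that
#' modality, never an all-NA row.
#'
#' @param subjects Tibble with columns `subject_id`, `baseline_group`
#'   (one of "CN", "MCI", "AD"), `conversion_month` (NA when none),
#'   `followup_month`.
#' @param visits Tibble with columns `subject_id`, `modality`, `visit_month`
#'   and feature columns `f1..fk` where `k = max(registry$n_features)`.
#' @param registry Modality registry; defaults to [modality_registry()].
#' @return An object of class `mmgru_cohort`.
#' @export
new_cohort <- function(subjects, visits, registry = modality_registry()) {
  cohort <- structure(
    list(
      subjects = tibble::as_tibble(subjects),
      visits   = dplyr::arrange(tibble::as_tibble(visits),
                                .data$subject_id, .data$modality,
                                .data$visit_month),
      registry = tibble::as_tibble(registry)
    ),
    class = "mmgru_cohort"
  )
  validate_cohort(cohort)
  cohort
}

#' Validate cohort invariants
#'
#' Checks, with a distinct error per violation class: unique subject ids;
#' baseline groups in {CN, MCI, AD}; conversion months only for MCI and never
#' past follow-up; every subject having at least one modality sequence;
#' visits referencing registered subjects/modalities with the registered
#' feature width (no NA inside the active columns, all-NA outside); no
#' duplicated (subject, modality, month); and length-one sequences for
#' non-longitudinal modalities.
#'
#' @param cohort An `mmgru_cohort`.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "mmgru_cohort"))
  subjects <- cohort$subjects
  visits <- cohort$visits
  registry <- validate_registry(cohort$registry)

  if (anyDuplicated(subjects$subject_id)) {
    dup <- subjects$subject_id[duplicated(subjects$subject_id)][1]
    rlang::abort(paste0("duplicate subject id: ", dup),
                 class = "mmgru_duplicate_subject")
  }
  bad_group <- setdiff(unique(subjects$baseline_group), c("CN", "MCI", "AD"))
  if (length(bad_group) > 0) {
    rlang::abort(paste0("unknown baseline group: ", bad_group[1]),
                 class = "mmgru_bad_group")
  }
  conv <- !is.na(subjects$conversion_month)
  if (any(conv & subjects$baseline_group != "MCI")) {
    rlang::abort("conversion_month is only meaningful for MCI subjects",
                 class = "mmgru_conversion_nonmci")
  }
  if (any(conv & subjects$conversion_month > subjects$followup_month)) {
    rlang::abort("conversion_month exceeds followup_month",
                 class = "mmgru_conversion_after_followup")
  }
  if (any(subjects$followup_month < 0)) {
    rlang::abort("followup_month must be >= 0",
                 class = "mmgru_negative_followup")
  }

  orphan <- setdiff(unique(visits$subject_id), subjects$subject_id)
  if (length(orphan) > 0) {
    rlang::abort(paste0("visit rows for unknown subject: ", orphan[1]),
                 class = "mmgru_orphan_visit")
  }
  unknown_mod <- setdiff(unique(visits$modality), registry$modality)
  if (length(unknown_mod) > 0) {
    rlang::abort(paste0("unregistered modality in visits: ", unknown_mod[1]),
                 class = "mmgru_unknown_modality")
  }
  no_seq <- setdiff(subjects$subject_id, unique(visits$subject_id))
  if (length(no_seq) > 0) {
    rlang::abort(paste0("subject without any modality sequence: ", no_seq[1]),
                 class = "mmgru_empty_subject")
  }
  if (any(visits$visit_month < 0)) {
    rlang::abort("visit_month must be >= 0", class = "mmgru_negative_month")
  }

  key <- paste(visits$subject_id, visits$modality, visits$visit_month)
  if (anyDuplicated(key)) {
    rlang::abort(paste0("duplicate (subject, modality, month) row: ",
                        key[duplicated(key)][1]),
                 class = "mmgru_duplicate_visit")
  }

  fcols <- feature_cols(registry)
  missing_cols <- setdiff(fcols, names(visits))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("visit table lacks feature column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mmgru_missing_feature_cols")
  }
  for (i in seq_len(nrow(registry))) {
    mod <- registry$modality[i]
    k <- registry$n_features[i]
    rows <- visits$modality == mod
    if (!any(rows)) next
    active <- as.matrix(visits[rows, fcols[seq_len(k)], drop = FALSE])
    if (anyNA(active)) {
      rlang::abort(paste0("NA feature value inside provided ", mod, " rows"),
                   class = "mmgru_na_feature")
    }
    if (k < length(fcols)) {
      trailing <- as.matrix(visits[rows, fcols[(k + 1):length(fcols)],
                                   drop = FALSE])
      if (!all(is.na(trailing))) {
        rlang::abort(paste0("feature count mismatch for modality ", mod,
                            ": values beyond registered width ", k),
                     class = "mmgru_feature_width")
      }
    }
    if (!registry$longitudinal[i]) {
      per_subj <- table(visits$subject_id[rows])
      if (any(per_subj > 1)) {
        rlang::abort(paste0("non-longitudinal modality ", mod,
                            " has more than one visit for subject ",
                            names(per_subj)[per_subj > 1][1]),
                     class = "mmgru_nonlongitudinal_repeat")
      }
    }
  }
  invisible(cohort)
}

#' @export
print.mmgru_cohort <- function(x, ...) {
  grp <- table(factor(x$subjects$baseline_group, c("CN", "MCI", "AD")))
  cat("<mmgru_cohort> ", nrow(x$subjects), " subjects (CN ", grp[["CN"]],
      ", MCI ", grp[["MCI"]], ", AD ", grp[["AD"]], "), ",
      nrow(x$visits), " visit rows, ",
      nrow(x$registry), " modalities\n", sep = "")
  invisible(x)
}

#' Extract one subject's sequence for one modality
#'
#' @param cohort An `mmgru_cohort`.
#' @param subject_id Subject identifier.
#' @param modality Modality name.
#' @return `NULL` when the subject lacks the modality; otherwise a list with
#'   `visit_months` (strictly increasing) and `observations`
#'   (T x n_features matrix).
#' @export
get_sequence <- function(cohort, subject_id, modality) {
  spec <- cohort$registry[cohort$registry$modality == modality, ]
  if (nrow(spec) == 0) {
    rlang::abort(paste0("unknown modality: ", modality),
                 class = "mmgru_unknown_modality")
  }
  rows <- cohort$visits$subject_id == subject_id &
    cohort$visits$modality == modality
  if (!any(rows)) return(NULL)
  sub <- cohort$visits[rows, , drop = FALSE]
  sub <- sub[order(sub$visit_month), , drop = FALSE]
  obs <- as.matrix(sub[, paste0("f", seq_len(spec$n_features)), drop = FALSE])
  dimnames(obs) <- NULL
  list(visit_months = sub$visit_month, observations = obs)
}

#' Read a cohort from CSV files
#'
#' Expects the two-file layout written by [write_cohort()]: a subject table
#' (`subject_id, baseline_group, conversion_month, followup_month`; empty
#' conversion_month means none) and a long-format visit table
#' (`subject_id, modality, visit_month, f1..fk`). Visit rows may arrive in
#' any order; sequences come out sorted by month.
#'
#' @param visit_file,subject_file Paths to the CSV files.
#' @param registry Modality registry; defaults to [modality_registry()].
#' @return An `mmgru_cohort`.
#' @export
read_cohort <- function(visit_file, subject_file,
                        registry = modality_registry()) {
  # numeric fields are parsed as text and converted with strtod, which is
  # correctly rounded, so that write_cohort -> read_cohort is bit-exact
  to_double <- function(df, cols) {
    for (nm in cols) df[[nm]] <- as.numeric(df[[nm]])
    df
  }
  subjects <- readr::read_csv(
    subject_file,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      baseline_group = readr::col_character(),
      .default = readr::col_character()
    )
  ) |>
    to_double(c("conversion_month", "followup_month"))
  fcols <- feature_cols(registry)
  visits <- readr::read_csv(
    visit_file,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      modality = readr::col_character(),
      .default = readr::col_character()
    )
  ) |>
    to_double(c("visit_month", fcols))
  new_cohort(subjects, visits, registry)
}

#' Write a cohort to CSV files
#'
#' Writes `<stem>_subjects.csv` and `<stem>_visits.csv` such that
#' [read_cohort()] reproduces an identical cohort (full numeric precision).
#'
#' @param cohort A valid `mmgru_cohort`.
#' @param stem Path stem for the two files.
#' @return Invisibly, a named character vector with the two paths.
#' @export
write_cohort <- function(cohort, stem) {
  validate_cohort(cohort)
  dir <- dirname(stem)
  if (!dir.exists(dir)) {
    rlang::abort(paste0("directory does not exist: ", dir),
                 class = "mmgru_unwritable_path")
  }
  paths <- c(subjects = paste0(stem, "_subjects.csv"),
             visits = paste0(stem, "_visits.csv"))
  # doubles are written with 17 significant digits so that reading the file
  # back reproduces every value bit for bit
  full_precision <- function(df) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) {
        df[[nm]] <- ifelse(is.na(df[[nm]]), NA_character_,
                           sprintf("%.17g", df[[nm]]))
      }
    }
    df
  }
  readr::write_csv(full_precision(cohort$subjects), paths[["subjects"]],
                   na = "")
  readr::write_csv(full_precision(cohort$visits), paths[["visits"]], na = "")
  invisible(paths)
}

#' Truncate every sequence to its baseline visit
#'
#' Used by the cross-sectional comparison scheme: each subject/modality keeps
#' only its earliest visit.
#'
#' @param cohort An `mmgru_cohort`.
#' @return A cohort whose sequences all have length one.
#' @export
truncate_to_baseline <- function(cohort) {
  visits <- cohort$visits |>
    dplyr::group_by(.data$subject_id, .data$modality) |>
    dplyr::slice_min(.data$visit_month, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  new_cohort(cohort$subjects, visits, cohort$registry)
}

#' Restrict a cohort to a subset of subjects
#' @param cohort An `mmgru_cohort`.
#' @param ids Subject ids to keep.
#' @return A cohort containing only those subjects.
#' @export
subset_cohort <- function(cohort, ids) {
  new_cohort(
    cohort$subjects[cohort$subjects$subject_id %in% ids, , drop = FALSE],
    cohort$visits[cohort$visits$subject_id %in% ids, , drop = FALSE],
    cohort$registry
  )
}
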