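#' Default modality registry
#'
#' The four data modalities used for MCI-to-AD conversion prediction, with
#' their feature counts, encoder hidden dimensions, and whether repeated
#' visits are collected. Cognitive scores (ADNI-MEM/ADNI-EF composites) and
#' CSF analytes are longitudinal; demographics and MRI-derived phenotypes
#' enter as length-one sequences. The CSF and MRI feature counts are wider
#' than the named analytes (Abeta 1-42, t-tau, p-tau; hippocampal volume,
#' entorhinal thickness) to leave room for derived quantities such as ratios.
#'
#' @return A tibble with columns `modality`, `n_features`, `hidden_dim`,
#'   `longitudinal`, one row per modality in canonical concatenation order
#'   (cognitive, demographics, csf, mri).
#' @export
#' @examples
#' modality_registry()
modality_registry <- function() {
  tibble::tibble(
    modality     = c("cognitive", "demographics", "csf", "mri"),
    n_features   = c(2L, 4L, 5L, 3L),
    hidden_dim   = c(3L, 5L, 6L, 4L),
    longitudinal = c(TRUE, FALSE, TRUE, FALSE)
  )
}

#' Validate a modality registry
#'
#' @param registry A tibble shaped like [modality_registry()].
#' @return The registry, invisibly, or an error describing the violated
#'   invariant.
#' @export
validate_registry <- function(registry) {
  required <- c("modality", "n_features", "hidden_dim", "longitudinal")
  missing <- setdiff(required, names(registry))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "registry is missing column(s): ", paste(missing, collapse = ", ")
    ), class = "mmgru_registry_error")
  }
  if (anyDuplicated(registry$modality)) {
    rlang::abort("registry modality names must be unique",
                 class = "mmgru_registry_error")
  }
  if (any(registry$n_features < 1) || any(registry$hidden_dim < 1)) {
    rlang::abort("registry n_features and hidden_dim must be >= 1",
                 class = "mmgru_registry_error")
  }
  invisible(registry)
}

#' Registry feature columns
#'
#' Feature columns in visit tables are named `f1..fk` with `k` the widest
#' modality in the registry; narrower modalities leave trailing columns NA.
#' @param registry Registry tibble.
#' @return Character vector of feature column names.
#' @keywords internal
feature_cols <- function(registry) {
  paste0("f", seq_len(max(registry$n_features)))
}
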