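# Small fixtures shared across test files. Everything is generated in code.

# a hand-built 2-subject, 2-modality cohort (3 visit rows total)
toy_cohort <- function() {
  subjects <- tibble::tibble(
    subject_id = c("s1", "s2"),
    baseline_group = c("MCI", "CN"),
    conversion_month = c(12, NA),
    followup_month = c(36, 24)
  )
  visits <- tibble::tibble(
    subject_id = c("s1", "s1", "s2"),
    modality = c("cognitive", "cognitive", "demographics"),
    visit_month = c(0, 6, 0),
    f1 = c(0.5, 0.1, 70),
    f2 = c(-0.2, -0.6, 1),
    f3 = c(NA, NA, 16),
    f4 = c(NA, NA, 0),
    f5 = NA_real_
  )
  new_cohort(subjects, visits)
}

# small simulated cohort reused by training/evaluation tests
small_sim_cohort <- function(seed = 3L) {
  simulate_cohort(sim_config(n_cn = 40L, n_mci_c = 35L, n_mci_nc = 55L,
                             n_ad = 35L, seed = seed))
}

# quick training settings for tests that only need a trained object
fast_config <- function(seed = 5L, ...) {
  train_config(epochs_pretrain = 5L, epochs_main = 10L, l1_strength = 0.01,
               seed = seed, ...)
}

# stage-1 class labels (1 = CN / non-converter, 2 = AD / converter),
# recomputed from public pieces so tests do not lean on internals
stage1_labels_for_test <- function(cohort, ids, dt) {
  vapply(ids, function(id) {
    s <- cohort$subjects[cohort$subjects$subject_id == id, ]
    if (s$baseline_group == "CN") return(1L)
    if (s$baseline_group == "AD") return(2L)
    switch(derive_label(s, dt), converter = 2L, non_converter = 1L, 0L)
  }, integer(1))
}

random_gru <- function(n_features = 2L, hidden = 3L, seed = 1L) {
  init_gru_params(n_features, hidden, 2L, seed = seed)
}

random_batch <- function(n = 3L, n_features = 2L, tmax = 3L, seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample.int(tmax, n, replace = TRUE)
    new_batch(lapply(lens, function(t) matrix(rnorm(t * n_features), t)),
              sample(1:2, n, replace = TRUE))
  })
}
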