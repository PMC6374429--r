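test_that("zero epochs in both phases returns the seeded initialisation", {
  co <- small_sim_cohort()
  cfg <- train_config(epochs_pretrain = 0L, epochs_main = 0L,
                      l1_strength = 0.1, seed = 5L)
  enc <- train_modality_gru(co, "cognitive", dt = 24, config = cfg)
  idx <- match("cognitive", co$registry$modality)
  init <- init_gru_params(2L, 3L, seed = cfg$seed + 131L * idx)
  expect_identical(unclass(enc$params), unclass(init))
})

test_that("training reduces the loss on a fixed simulated batch", {
  co <- small_sim_cohort()
  enc <- train_modality_gru(co, "cognitive", dt = 24, config = fast_config())
  expect_lt(tail(enc$loss_main, 1), enc$loss_main[1])
  expect_lt(tail(enc$loss_pretrain, 1), enc$loss_pretrain[1])
})

test_that("a single-modality GRU reaches ceiling accuracy on separable data", {
  co <- simulate_cohort(separable_config())
  cfg <- train_config(seed = 5L, l1_strength = 1e-3)
  enc <- train_modality_gru(co, "cognitive", dt = 24, config = cfg)
  # training-set accuracy of the stage-1 classifier itself
  ids <- enc$train_ids
  lab <- stage1_labels_for_test(co, ids, 24)
  probs <- vapply(ids, function(id) {
    h <- extract_representation(enc, co, id)
    classify(h, enc$params$W_y)[2]
  }, numeric(1))
  expect_gte(mean((probs > 0.5) == (lab == 2L)), 0.99)
})

test_that("representations are absent, right-sized and pure", {
  co <- small_sim_cohort()
  cfg <- fast_config()
  enc_demo <- train_modality_gru(co, "demographics", dt = 24, config = cfg)
  expect_length(extract_representation(enc_demo, co,
                                       co$subjects$subject_id[1]), 5)
  enc_csf <- train_modality_gru(co, "csf", dt = 24, config = cfg)
  no_csf <- setdiff(co$subjects$subject_id,
                    unique(co$visits$subject_id[co$visits$modality == "csf"]))
  expect_null(extract_representation(enc_csf, co, no_csf[1]))
  r1 <- extract_representation(enc_demo, co, co$subjects$subject_id[2])
  r2 <- extract_representation(enc_demo, co, co$subjects$subject_id[2])
  expect_identical(r1, r2)
})

test_that("assembled features concatenate hidden blocks in registry order", {
  co <- small_sim_cohort()
  cfg <- fast_config()
  mods <- co$registry$modality
  encoders <- lapply(mods, function(m)
    train_modality_gru(co, m, dt = 24, config = cfg))
  names(encoders) <- mods
  ids <- co$subjects$subject_id[1:5]
  feats <- assemble_features(encoders, co, ids)
  expect_equal(ncol(feats), 3 + 5 + 6 + 4)
  # a subject with only demographics is zero outside its block
  only_demo <- co$subjects$subject_id[vapply(co$subjects$subject_id,
    function(id) {
      mods_i <- unique(co$visits$modality[co$visits$subject_id == id])
      identical(mods_i, "demographics")
    }, logical(1))]
  if (length(only_demo) > 0) {
    f <- assemble_features(encoders, co, only_demo[1])
    expect_true(all(f[1, 1:3] == 0))            # cognitive block
    expect_true(all(f[1, 9:18] == 0))           # csf + mri blocks
    expect_true(any(f[1, 4:8] != 0))            # demographics block
  }
  # permuting the encoder order permutes the blocks correspondingly
  perm <- assemble_features(encoders[c("csf", "cognitive")], co, ids)
  expect_equal(perm[, 1:6], feats[, 9:14], ignore_attr = TRUE)
  expect_equal(perm[, 7:9], feats[, 1:3], ignore_attr = TRUE)
})

test_that("l1 logistic head behaves across the penalty range", {
  withr::with_seed(42, {
    x <- matrix(rnorm(60), 20, 3)
    y <- as.integer(x[, 1] + 0.5 * rnorm(20) > 0)
  })
  # penalty-dominated limit: zero weights, intercept = class log-odds
  big <- fit_l1_logistic(x, y, lambda = 50)
  expect_equal(big$weights, rep(0, 3))
  expect_equal(big$intercept, log(mean(y) / (1 - mean(y))), tolerance = 1e-6)
  # sign consistency on a perfectly correlated single feature
  x1 <- matrix(seq(-1, 1, length.out = 10), 10, 1)
  y1 <- as.integer(x1[, 1] > 0)
  m1 <- fit_l1_logistic(x1, y1, lambda = 0.01)
  expect_gt(m1$weights[1], 0)
  # lambda path: number of nonzero weights is non-increasing
  nz <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.3, 1),
               function(l) sum(fit_l1_logistic(x, y, l)$weights != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("l1 solution matches an independent convex solver (glmnet)", {
  skip_if_not_installed("glmnet")
  withr::with_seed(2, {
    x <- matrix(rnorm(60), 20, 3)
    y <- as.integer(x[, 1] - x[, 2] + 0.3 * rnorm(20) > 0)
  })
  lam <- 0.05
  ours <- fit_l1_logistic(x, y, lam)
  ref <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lam, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e6)
  expect_equal(ours$weights, as.numeric(ref$beta), tolerance = 1e-4)
  expect_equal(ours$intercept, as.numeric(ref$a0), tolerance = 1e-4)
})

test_that("predict_conversion is the logistic of the linear score", {
  m <- structure(list(weights = c(0, 0), intercept = 0, lambda = 1),
                 class = "mmgru_fusion")
  expect_equal(predict_conversion(m, c(3, -4)), 0.5)
  m2 <- structure(list(weights = c(0.8, -0.3), intercept = 0.2, lambda = 1),
                  class = "mmgru_fusion")
  # hand evaluation on a printed toy weight vector
  expect_equal(predict_conversion(m2, c(1, 2)),
               1 / (1 + exp(-(0.2 + 0.8 - 0.6))), tolerance = 1e-14)
  # monotone in a positively weighted feature
  p_lo <- predict_conversion(m2, c(0, 1))
  p_hi <- predict_conversion(m2, c(2, 1))
  expect_gt(p_hi, p_lo)
  expect_error(predict_conversion(m2, c(1, 2, 3)),
               class = "mmgru_shape_error")
})

test_that("stage-2 fitting never touches encoder parameters", {
  co <- small_sim_cohort()
  cfg <- fast_config()
  model <- fit_mmgru(co, dt = 24, config = cfg)
  # retraining the encoders alone reproduces the model's encoders bit for bit
  for (m in co$registry$modality) {
    solo <- train_modality_gru(co, m, dt = 24, config = cfg)
    expect_identical(unclass(model$encoders[[m]]$params),
                     unclass(solo$params))
  }
})

test_that("dropping one subject's CSF affects only the CSF encoder", {
  co <- small_sim_cohort()
  csf_ids <- unique(co$visits$subject_id[co$visits$modality == "csf"])
  victim <- csf_ids[1]
  co2 <- new_cohort(co$subjects,
                    co$visits[!(co$visits$subject_id == victim &
                                  co$visits$modality == "csf"), ],
                    co$registry)
  cfg <- fast_config()
  for (m in co$registry$modality) {
    n1 <- train_modality_gru(co, m, dt = 24, config = cfg)$n_train
    n2 <- train_modality_gru(co2, m, dt = 24, config = cfg)$n_train
    if (m == "csf") expect_equal(n1 - n2, 1L) else expect_equal(n1, n2)
  }
})

test_that("end-to-end fitting is deterministic under a fixed seed", {
  co <- small_sim_cohort()
  cfg <- fast_config()
  m1 <- fit_mmgru(co, dt = 24, config = cfg)
  m2 <- fit_mmgru(co, dt = 24, config = cfg)
  expect_identical(m1$fusion$weights, m2$fusion$weights)
  expect_identical(lapply(m1$encoders, function(e) unclass(e$params)),
                   lapply(m2$encoders, function(e) unclass(e$params)))
})

test_that("a fitted model survives a JSON round-trip", {
  co <- small_sim_cohort()
  model <- fit_mmgru(co, dt = 24, config = fast_config())
  path <- file.path(withr::local_tempdir(), "model.json")
  write_mmgru_model(model, path)
  back <- read_mmgru_model(path)
  ids <- co$subjects$subject_id[co$subjects$baseline_group == "MCI"][1:10]
  expect_equal(predict(back, co, ids)$p_conversion,
               predict(model, co, ids)$p_conversion, tolerance = 1e-12)
})
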