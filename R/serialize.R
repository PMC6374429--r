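#' Save a fitted two-stage model as JSON
#'
#' Parameters are stored as a flat key -> array map (values plus dims) with
#' full numeric precision, alongside a header recording the modality order,
#' horizon, missing-modality policy and lasso penalty.
#'
#' @param model An `mmgru_model`.
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_mmgru_model <- function(model, path) {
  pack_params <- function(p) {
    lapply(unclass(p), function(x) {
      list(values = as.numeric(x),
           dim = if (is.matrix(x)) dim(x) else length(x))
    })
  }
  payload <- list(
    header = list(
      modalities = model$modalities,
      dt = model$dt,
      missing_policy = model$config$missing_policy,
      lambda = model$fusion$lambda
    ),
    encoders = lapply(model$encoders, function(enc) {
      list(spec = as.list(enc$spec),
           standardization = enc$standardization,
           params = pack_params(enc$params))
    }),
    fusion = list(weights = model$fusion$weights,
                  intercept = model$fusion$intercept,
                  lambda = model$fusion$lambda),
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [write_mmgru_model()]
#'
#' @param path Path to the JSON file.
#' @return An `mmgru_model` (without loss traces; predictions are
#'   identical to the saved model's).
#' @export
read_mmgru_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack_params <- function(pp) {
    mats <- lapply(pp, function(e) {
      if (length(e$dim) == 2) matrix(e$values, e$dim[1], e$dim[2])
      else as.numeric(e$values)
    })
    do.call(gru_params, mats[c("W_z", "U_z", "b_z", "W_r", "U_r", "b_r",
                               "W_c", "U_c", "b_c", "W_y")])
  }
  encoders <- lapply(raw$encoders, function(enc) {
    structure(list(
      spec = tibble::as_tibble(enc$spec),
      params = unpack_params(enc$params),
      standardization = list(center = as.numeric(enc$standardization$center),
                             scale = as.numeric(enc$standardization$scale)),
      n_train = NA_integer_, train_ids = character(0),
      loss_pretrain = numeric(0), loss_main = numeric(0)
    ), class = "mmgru_encoder")
  })
  names(encoders) <- raw$header$modalities
  config <- raw$config
  config$batch_size <- config$batch_size %||% NULL
  config$l1_strength <- config$l1_strength %||% NULL
  class(config) <- "train_config"
  structure(list(
    encoders = encoders,
    fusion = structure(list(weights = as.numeric(raw$fusion$weights),
                            intercept = raw$fusion$intercept,
                            lambda = raw$fusion$lambda),
                       class = "mmgru_fusion"),
    modalities = raw$header$modalities,
    dt = raw$header$dt,
    config = config
  ), class = "mmgru_model")
}
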