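#' Hyperbolic tangent activation
#'
#' The elementwise non-linearity of the recurrent cells,
#' `tanh(x) = 2 / (1 + exp(-2x)) - 1`, evaluated stably for large `|x|`.
#'
#' @param x Numeric vector or matrix.
#' @return Values in (-1, 1), same shape as `x`.
#' @export
tanh_activation <- function(x) {
  stopifnot(all(is.finite(x)))
  tanh(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax
#'
#' Maps an arbitrary real vector to a probability vector,
#' `softmax(u)_i = exp(u_i) / sum_k exp(u_k)`, computed with max
#' subtraction so large inputs do not overflow. Shift-invariant:
#' `softmax(u + c) == softmax(u)`.
#'
#' @param u Numeric vector.
#' @return Probability vector of the same length (positive, sums to 1).
#' @export
softmax <- function(u) {
  stopifnot(all(is.finite(u)))
  z <- exp(u - max(u))
  z / sum(z)
}

# row-wise softmax for an N x C logit matrix
row_softmax <- function(U) {
  Z <- exp(U - apply(U, 1, max))
  Z / rowSums(Z)
}

#' Vanilla RNN parameters
#'
#' Weight matrices of the plain recurrent unit: recurrent `W_h`
#' (hidden x hidden), input `W_x` (hidden x n_features) and output head
#' `W_y` (n_classes x hidden). The plain cell carries no bias terms.
#'
#' @param W_h,W_x,W_y Numeric matrices with consistent shapes.
#' @return An object of class `mmgru_rnn_params`.
#' @export
rnn_params <- function(W_h, W_x, W_y) {
  stopifnot(is.matrix(W_h), is.matrix(W_x), is.matrix(W_y))
  h <- nrow(W_h)
  if (ncol(W_h) != h || nrow(W_x) != h || ncol(W_y) != h) {
    rlang::abort("inconsistent RNN parameter shapes",
                 class = "mmgru_shape_error")
  }
  if (!all(is.finite(W_h)) || !all(is.finite(W_x)) || !all(is.finite(W_y))) {
    rlang::abort("RNN parameters must be finite", class = "mmgru_shape_error")
  }
  structure(list(W_h = W_h, W_x = W_x, W_y = W_y),
            class = c("mmgru_rnn_params", "mmgru_params"))
}

#' GRU parameters
#'
#' Standard gated recurrent unit weights: for each of the update gate (z),
#' reset gate (r) and candidate state (c) an input matrix `W_*`
#' (hidden x n_features), a recurrent matrix `U_*` (hidden x hidden) and a
#' bias `b_*` (hidden), plus the output head `W_y` (n_classes x hidden).
#'
#' @param W_z,U_z,b_z,W_r,U_r,b_r,W_c,U_c,b_c,W_y Gate weights as above.
#' @return An object of class `mmgru_gru_params`.
#' @export
gru_params <- function(W_z, U_z, b_z, W_r, U_r, b_r, W_c, U_c, b_c, W_y) {
  h <- nrow(W_z)
  ok <- is.matrix(W_z) && is.matrix(W_r) && is.matrix(W_c) &&
    all(vapply(list(U_z, U_r, U_c), function(U)
      is.matrix(U) && all(dim(U) == c(h, h)), logical(1))) &&
    all(vapply(list(W_r, W_c), function(W)
      all(dim(W) == dim(W_z)), logical(1))) &&
    all(vapply(list(b_z, b_r, b_c), function(b)
      is.numeric(b) && length(b) == h, logical(1))) &&
    is.matrix(W_y) && ncol(W_y) == h
  if (!ok) {
    rlang::abort("inconsistent GRU parameter shapes",
                 class = "mmgru_shape_error")
  }
  p <- list(W_z = W_z, U_z = U_z, b_z = b_z,
            W_r = W_r, U_r = U_r, b_r = b_r,
            W_c = W_c, U_c = U_c, b_c = b_c, W_y = W_y)
  if (!all(vapply(p, function(x) all(is.finite(x)), logical(1)))) {
    rlang::abort("GRU parameters must be finite", class = "mmgru_shape_error")
  }
  structure(p, class = c("mmgru_gru_params", "mmgru_params"))
}

# uniform(-1, 1) / sqrt(fan_in) initialisation, deterministic under seed
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

#' Seeded random initialisation of RNN parameters
#' @param n_features,hidden_dim,n_classes Dimensions.
#' @param seed Integer seed.
#' @return An `mmgru_rnn_params`.
#' @export
init_rnn_params <- function(n_features, hidden_dim, n_classes = 2L,
                            seed = 1L) {
  withr::with_seed(seed, rnn_params(
    W_h = init_mat(hidden_dim, hidden_dim, hidden_dim),
    W_x = init_mat(hidden_dim, n_features, n_features),
    W_y = init_mat(n_classes, hidden_dim, hidden_dim)
  ))
}

#' Seeded random initialisation of GRU parameters
#' @inheritParams init_rnn_params
#' @return An `mmgru_gru_params` (biases start at zero).
#' @export
init_gru_params <- function(n_features, hidden_dim, n_classes = 2L,
                            seed = 1L) {
  withr::with_seed(seed, gru_params(
    W_z = init_mat(hidden_dim, n_features, n_features),
    U_z = init_mat(hidden_dim, hidden_dim, hidden_dim),
    b_z = rep(0, hidden_dim),
    W_r = init_mat(hidden_dim, n_features, n_features),
    U_r = init_mat(hidden_dim, hidden_dim, hidden_dim),
    b_r = rep(0, hidden_dim),
    W_c = init_mat(hidden_dim, n_features, n_features),
    U_c = init_mat(hidden_dim, hidden_dim, hidden_dim),
    b_c = rep(0, hidden_dim),
    W_y = init_mat(n_classes, hidden_dim, hidden_dim)
  ))
}

check_step_shapes <- function(n_in, h_len, x_len, h_dim) {
  if (x_len != n_in || h_len != h_dim) {
    rlang::abort("shape mismatch between parameters and step inputs",
                 class = "mmgru_shape_error")
  }
}

#' One vanilla RNN step
#'
#' `h_t = tanh(W_h h_prev + W_x x_t)`.
#'
#' @param params An `mmgru_rnn_params`.
#' @param h_prev Hidden state vector.
#' @param x_t Feature vector for the current visit.
#' @return New hidden state vector.
#' @export
rnn_step <- function(params, h_prev, x_t) {
  check_step_shapes(ncol(params$W_x), length(h_prev), length(x_t),
                    nrow(params$W_h))
  as.numeric(tanh_activation(params$W_h %*% h_prev + params$W_x %*% x_t))
}

#' One GRU step
#'
#' Standard gated update:
#' `z = logistic(W_z x + U_z h_prev + b_z)`,
#' `r = logistic(W_r x + U_r h_prev + b_r)`,
#' `h~ = tanh(W_c x + U_c (r * h_prev) + b_c)`,
#' `h = (1 - z) * h_prev + z * h~`.
#'
#' @param params An `mmgru_gru_params`.
#' @param h_prev Hidden state vector.
#' @param x_t Feature vector for the current visit.
#' @return New hidden state vector.
#' @export
gru_step <- function(params, h_prev, x_t) {
  check_step_shapes(ncol(params$W_z), length(h_prev), length(x_t),
                    nrow(params$U_z))
  z <- sigmoid(as.numeric(params$W_z %*% x_t + params$U_z %*% h_prev +
                            params$b_z))
  r <- sigmoid(as.numeric(params$W_r %*% x_t + params$U_r %*% h_prev +
                            params$b_r))
  hc <- tanh_activation(as.numeric(params$W_c %*% x_t +
                                     params$U_c %*% (r * h_prev) +
                                     params$b_c))
  (1 - z) * h_prev + z * hc
}

#' Encode a visit sequence into a fixed-size representation
#'
#' Starts from the zero hidden state and applies the cell over visits in
#' time order; the final hidden state is a fixed-size representation
#' whatever the sequence length.
#'
#' @param params An `mmgru_rnn_params` or `mmgru_gru_params`.
#' @param observations T x n_features matrix (or a ModalitySequence list
#'   with an `observations` element), rows in time order, T >= 1.
#' @return Hidden state vector `h_T`.
#' @export
encode_sequence <- function(params, observations) {
  if (is.list(observations) && !is.null(observations$observations)) {
    observations <- observations$observations
  }
  if (!is.matrix(observations)) observations <- matrix(observations, nrow = 1)
  if (nrow(observations) < 1) {
    rlang::abort("cannot encode an empty sequence",
                 class = "mmgru_empty_sequence")
  }
  step <- if (inherits(params, "mmgru_gru_params")) gru_step else rnn_step
  hdim <- if (inherits(params, "mmgru_gru_params")) nrow(params$U_z)
          else nrow(params$W_h)
  h <- rep(0, hdim)
  for (t in seq_len(nrow(observations))) {
    h <- step(params, h, observations[t, ])
  }
  h
}

#' Class probabilities from a hidden state
#'
#' `y_hat = softmax(W_y h)`; with two classes the second entry is the
#' converter probability.
#'
#' @param h_T Hidden state vector.
#' @param W_y Output head matrix (n_classes x hidden).
#' @return Probability vector over classes.
#' @export
classify <- function(h_T, W_y) {
  if (ncol(W_y) != length(h_T)) {
    rlang::abort("shape mismatch between W_y and hidden state",
                 class = "mmgru_shape_error")
  }
  softmax(as.numeric(W_y %*% h_T))
}

#' Cross-entropy loss
#'
#' Negative mean log-likelihood over a batch,
#' `L = -(1/N) sum_n sum_c y_{n,c} log y_hat_{n,c}`; zero exactly when every
#' prediction puts all mass on the true class. Predicted probabilities are
#' clipped at 1e-12 before the log.
#'
#' @param y Integer class labels (1-based) of length N, or an N x C one-hot
#'   matrix.
#' @param y_hat N x C matrix of predicted probability vectors.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(y, y_hat) {
  if (!is.matrix(y_hat)) y_hat <- matrix(y_hat, nrow = 1)
  if (!is.matrix(y)) {
    if (length(y) == 0) {
      rlang::abort("cross_entropy needs at least one sample",
                   class = "mmgru_empty_batch")
    }
    y <- one_hot(y, ncol(y_hat))
  }
  if (nrow(y) == 0) {
    rlang::abort("cross_entropy needs at least one sample",
                 class = "mmgru_empty_batch")
  }
  stopifnot(all(dim(y) == dim(y_hat)))
  -mean(rowSums(y * log(pmax(y_hat, 1e-12))))
}

one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}
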