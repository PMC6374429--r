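#' Assemble a labelled sequence batch
#'
#' @param sequences List of T x n_features matrices (T may differ).
#' @param labels Integer class labels (1-based), one per sequence.
#' @return A list of class `mmgru_batch`.
#' @export
new_batch <- function(sequences, labels) {
  stopifnot(length(sequences) == length(labels), length(sequences) >= 1)
  sequences <- lapply(sequences, function(s) {
    if (is.list(s) && !is.null(s$observations)) s <- s$observations
    if (!is.matrix(s)) s <- matrix(s, nrow = 1)
    s
  })
  structure(list(sequences = sequences, labels = as.integer(labels)),
            class = "mmgru_batch")
}

# Pad variable-length sequences into an N x Tmax x F array plus an
# N x Tmax activity mask (1 while the sequence is still running). After a
# sequence ends its hidden state is frozen, so the state at Tmax equals the
# state at the sequence's own final visit.
pack_batch <- function(batch, n_features) {
  n <- length(batch$sequences)
  lens <- vapply(batch$sequences, nrow, integer(1))
  tmax <- max(lens)
  X <- array(0, dim = c(n, tmax, n_features))
  mask <- matrix(0, n, tmax)
  for (i in seq_len(n)) {
    s <- batch$sequences[[i]]
    if (ncol(s) != n_features) {
      rlang::abort("sequence feature width does not match parameters",
                   class = "mmgru_shape_error")
    }
    X[i, seq_len(lens[i]), ] <- s
    mask[i, seq_len(lens[i])] <- 1
  }
  list(X = X, mask = mask, tmax = tmax, n = n)
}

slice_t <- function(X, t) matrix(X[, t, ], nrow = dim(X)[1])

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Batched forward pass. Returns final hidden states, per-step caches for
# backpropagation, and class probabilities.
forward_batch <- function(params, batch) {
  UseMethod("forward_batch")
}

#' @export
forward_batch.mmgru_gru_params <- function(params, batch) {
  pk <- pack_batch(batch, ncol(params$W_z))
  hdim <- nrow(params$U_z)
  H <- matrix(0, pk$n, hdim)
  cache <- vector("list", pk$tmax)
  for (t in seq_len(pk$tmax)) {
    xt <- slice_t(pk$X, t)
    h_prev <- H
    Z <- sigmoid(add_bias(xt %*% t(params$W_z) + h_prev %*% t(params$U_z),
                          params$b_z))
    R <- sigmoid(add_bias(xt %*% t(params$W_r) + h_prev %*% t(params$U_r),
                          params$b_r))
    Hc <- tanh(add_bias(xt %*% t(params$W_c) +
                          (R * h_prev) %*% t(params$U_c), params$b_c))
    Hnew <- (1 - Z) * h_prev + Z * Hc
    m <- pk$mask[, t]
    H <- m * Hnew + (1 - m) * h_prev
    cache[[t]] <- list(x = xt, h_prev = h_prev, Z = Z, R = R, Hc = Hc, m = m)
  }
  probs <- row_softmax(H %*% t(params$W_y))
  list(H = H, probs = probs, cache = cache, pk = pk)
}

#' @export
forward_batch.mmgru_rnn_params <- function(params, batch) {
  pk <- pack_batch(batch, ncol(params$W_x))
  hdim <- nrow(params$W_h)
  H <- matrix(0, pk$n, hdim)
  cache <- vector("list", pk$tmax)
  for (t in seq_len(pk$tmax)) {
    xt <- slice_t(pk$X, t)
    h_prev <- H
    Hnew <- tanh(xt %*% t(params$W_x) + h_prev %*% t(params$W_h))
    m <- pk$mask[, t]
    H <- m * Hnew + (1 - m) * h_prev
    cache[[t]] <- list(x = xt, h_prev = h_prev, Hnew = Hnew, m = m)
  }
  probs <- row_softmax(H %*% t(params$W_y))
  list(H = H, probs = probs, cache = cache, pk = pk)
}

#' Batch cross-entropy loss of a recurrent classifier
#'
#' Encodes every sequence in the batch from the zero initial state and
#' evaluates the cross-entropy of the final-step class probabilities (only
#' the last output enters the loss).
#'
#' @param params An `mmgru_rnn_params` or `mmgru_gru_params`.
#' @param batch An [new_batch()] object.
#' @return Scalar loss.
#' @export
batch_loss <- function(params, batch) {
  fw <- forward_batch(params, batch)
  cross_entropy(batch$labels, fw$probs)
}

#' Exact gradients via backpropagation through time
#'
#' Reverse-mode differentiation of the batch cross-entropy with respect to
#' every parameter tensor, unrolled over the full sequence length. The
#' result matches central-difference numerical differentiation of
#' [batch_loss()] (see [check_gradients()]).
#'
#' @param params An `mmgru_rnn_params` or `mmgru_gru_params`.
#' @param batch An [new_batch()] object.
#' @return Named list of gradients with the same shapes as `params`, plus
#'   attribute `loss` carrying the forward loss.
#' @export
bptt_gradients <- function(params, batch) {
  UseMethod("bptt_gradients")
}

#' @export
bptt_gradients.mmgru_gru_params <- function(params, batch) {
  fw <- forward_batch(params, batch)
  n <- fw$pk$n
  Y <- one_hot(batch$labels, nrow(params$W_y))
  G <- (fw$probs - Y) / n                       # d loss / d logits
  g <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  g$W_y <- t(G) %*% fw$H
  dH <- G %*% params$W_y
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    dHa <- cc$m * dH
    dZ <- dHa * (cc$Hc - cc$h_prev)
    dHc <- dHa * cc$Z
    dh_prev <- dHa * (1 - cc$Z)
    dHc_pre <- dHc * (1 - cc$Hc^2)
    g$W_c <- g$W_c + t(dHc_pre) %*% cc$x
    g$U_c <- g$U_c + t(dHc_pre) %*% (cc$R * cc$h_prev)
    g$b_c <- g$b_c + colSums(dHc_pre)
    dRH <- dHc_pre %*% params$U_c                # d/d (R * h_prev)
    dR <- dRH * cc$h_prev
    dh_prev <- dh_prev + dRH * cc$R
    dZ_pre <- dZ * cc$Z * (1 - cc$Z)
    dR_pre <- dR * cc$R * (1 - cc$R)
    g$W_z <- g$W_z + t(dZ_pre) %*% cc$x
    g$U_z <- g$U_z + t(dZ_pre) %*% cc$h_prev
    g$b_z <- g$b_z + colSums(dZ_pre)
    g$W_r <- g$W_r + t(dR_pre) %*% cc$x
    g$U_r <- g$U_r + t(dR_pre) %*% cc$h_prev
    g$b_r <- g$b_r + colSums(dR_pre)
    dh_prev <- dh_prev + dZ_pre %*% params$U_z + dR_pre %*% params$U_r
    dH <- dh_prev + (1 - cc$m) * dH
  }
  structure(g, loss = cross_entropy(batch$labels, fw$probs))
}

#' @export
bptt_gradients.mmgru_rnn_params <- function(params, batch) {
  fw <- forward_batch(params, batch)
  n <- fw$pk$n
  Y <- one_hot(batch$labels, nrow(params$W_y))
  G <- (fw$probs - Y) / n
  g <- list(W_h = matrix(0, nrow(params$W_h), ncol(params$W_h)),
            W_x = matrix(0, nrow(params$W_x), ncol(params$W_x)),
            W_y = t(G) %*% fw$H)
  dH <- G %*% params$W_y
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    dHa <- cc$m * dH
    dpre <- dHa * (1 - cc$Hnew^2)
    g$W_h <- g$W_h + t(dpre) %*% cc$h_prev
    g$W_x <- g$W_x + t(dpre) %*% cc$x
    dH <- dpre %*% params$W_h + (1 - cc$m) * dH
  }
  structure(g, loss = cross_entropy(batch$labels, fw$probs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten / unflatten parameter structures (serialisation, finite
# differences, gradient-descent updates)
params_to_vector <- function(params) {
  unlist(lapply(unclass(params), as.numeric), use.names = FALSE)
}

vector_to_params <- function(v, template) {
  out <- unclass(template)
  i <- 0L
  for (nm in names(out)) {
    len <- length(out[[nm]])
    vals <- v[(i + 1L):(i + len)]
    out[[nm]] <- if (is.matrix(out[[nm]])) {
      matrix(vals, nrow(out[[nm]]), ncol(out[[nm]]))
    } else {
      vals
    }
    i <- i + len
  }
  class(out) <- class(template)
  out
}

#' Compare BPTT gradients with central finite differences
#'
#' Numerically differentiates [batch_loss()] entry by entry and reports the
#' worst relative discrepancy against [bptt_gradients()],
#' `|g - g_num| / (|g| + |g_num| + 1e-4)`. The additive scale floor absorbs
#' finite-difference round-off on near-zero entries without affecting
#' entries of ordinary magnitude; the default step is near the optimum
#' `cbrt(machine eps)` for central differences.
#'
#' @param params Parameter structure.
#' @param batch An [new_batch()] object.
#' @param eps Central-difference step.
#' @return Maximum relative discrepancy (scalar).
#' @export
check_gradients <- function(params, batch, eps = 6e-6) {
  g <- params_to_vector(bptt_gradients(params, batch))
  v <- params_to_vector(params)
  g_num <- vapply(seq_along(v), function(i) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    (batch_loss(vector_to_params(vp, params), batch) -
       batch_loss(vector_to_params(vm, params), batch)) / (2 * eps)
  }, numeric(1))
  max(abs(g - g_num) / (abs(g) + abs(g_num) + 1e-4))
}

#' Full-batch gradient descent on a labelled sequence batch
#'
#' Constant-learning-rate deterministic gradient descent minimising
#' [batch_loss()]; the optimiser the two-step training procedure uses for
#' each modality encoder.
#'
#' @param params Initial parameter structure.
#' @param batch An [new_batch()] object.
#' @param epochs Number of full-batch updates (0 returns `params` unchanged).
#' @param learning_rate Step size.
#' @return Updated parameters with attribute `loss_trace` (loss before each
#'   update, plus the final loss; length `epochs + 1`).
#' @export
train_gd <- function(params, batch, epochs, learning_rate) {
  trace <- numeric(epochs + 1L)
  if (epochs > 0) {
    for (e in seq_len(epochs)) {
      g <- bptt_gradients(params, batch)
      trace[e] <- attr(g, "loss")
      v <- params_to_vector(params) -
        learning_rate * params_to_vector(g)
      params <- vector_to_params(v, params)
    }
  }
  trace[epochs + 1L] <- batch_loss(params, batch)
  attr(params, "loss_trace") <- trace
  params
}
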