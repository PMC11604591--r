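#' Model parameters for the recurrent attention agent
#'
#' Initializes all trainable weights: the glimpse network (patch and
#' location projections to 128-dim hidden layers, combined into a 256-dim
#' glimpse feature `g`), the GRU core (hidden size 256 by default), the
#' location head (hidden -> 2, tanh-squashed policy mean), the action head
#' (hidden -> C softmax) and the baseline head (hidden -> 1 state value).
#' Weights are drawn uniformly in +/- 1/sqrt(fan_in); biases start at zero.
#'
#' @param input_dim Length of the flattened glimpse stack
#'   (`k * base_rows * base_cols`).
#' @param n_classes Number of classes C.
#' @param hidden GRU hidden size (default 256).
#' @param glimpse_hidden Width of the patch projection `h_MS` (default 128).
#' @param loc_hidden Width of the location projection `h_l` (default 128).
#' @param g_dim Width of the combined glimpse feature `g` (default 256).
#' @param sigma Fixed standard deviation of the Gaussian location policy, in
#'   normalized coordinate units.
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `ram_params`: a named list of weight matrices
#'   and bias vectors plus the dimension settings.
#' @export
ram_params <- function(input_dim, n_classes, hidden = 256L,
                       glimpse_hidden = 128L, loc_hidden = 128L,
                       g_dim = 256L, sigma = 0.17, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (input_dim < 1L || n_classes < 2L) stop("invalid dimensions")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  u <- function(nin, nout) {
    b <- 1 / sqrt(nin)
    matrix(stats::runif(nin * nout, -b, b), nin, nout)
  }
  p <- list(
    # glimpse network
    W_g  = u(input_dim, glimpse_hidden), b_g  = numeric(glimpse_hidden),
    W_lp = u(2L, loc_hidden),            b_lp = numeric(loc_hidden),
    W_gg = u(glimpse_hidden, g_dim),
    W_lg = u(loc_hidden, g_dim),         b_out = numeric(g_dim),
    # GRU core
    W_z = u(g_dim, hidden), U_z = u(hidden, hidden), b_z = numeric(hidden),
    W_r = u(g_dim, hidden), U_r = u(hidden, hidden), b_r = numeric(hidden),
    W_c = u(g_dim, hidden), U_c = u(hidden, hidden), b_c = numeric(hidden),
    # heads
    W_loc = u(hidden, 2L),        b_loc = numeric(2L),
    W_a   = u(hidden, n_classes), b_a   = numeric(n_classes),
    W_b   = u(hidden, 1L),        b_b   = numeric(1L)
  )
  structure(p, class = "ram_params",
            dims = list(input_dim = as.integer(input_dim),
                        n_classes = as.integer(n_classes),
                        hidden = as.integer(hidden),
                        glimpse_hidden = as.integer(glimpse_hidden),
                        loc_hidden = as.integer(loc_hidden),
                        g_dim = as.integer(g_dim)),
            sigma = as.numeric(sigma))
}

#' @export
print.ram_params <- function(x, ...) {
  d <- attr(x, "dims")
  n <- sum(vapply(x, length, integer(1)))
  cat(sprintf("<ram_params> input %d -> g %d -> GRU %d -> %d classes; %d parameters; sigma = %g\n",
              d$input_dim, d$g_dim, d$hidden, d$n_classes, n, attr(x, "sigma")))
  invisible(x)
}

# trainable arrays, in a fixed order used by the optimizer
param_names <- function() c("W_g", "b_g", "W_lp", "b_lp", "W_gg", "W_lg", "b_out",
                            "W_z", "U_z", "b_z", "W_r", "U_r", "b_r",
                            "W_c", "U_c", "b_c",
                            "W_loc", "b_loc", "W_a", "b_a", "W_b", "b_b")

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# batched affine map: X (B x nin) %*% W (nin x nout) + b (nout)
affine <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

check_params <- function(params) {
  if (!inherits(params, "ram_params")) stop("params must be a ram_params object")
}

## ---- batched forward primitives (rows = samples) -------------------------

glimpse_forward_batch <- function(X, L, params) {
  A1 <- affine(X, params$W_g, params$b_g); Hms <- relu(A1)
  A2 <- affine(L, params$W_lp, params$b_lp); Hl <- relu(A2)
  A3 <- sweep(Hms %*% params$W_gg + Hl %*% params$W_lg, 2L, params$b_out, "+")
  list(G = relu(A3), A1 = A1, A2 = A2, A3 = A3, Hms = Hms, Hl = Hl)
}

gru_step_batch <- function(H, G, params) {
  Z <- sigmoid(affine(G, params$W_z, params$b_z) + H %*% params$U_z)
  R <- sigmoid(affine(G, params$W_r, params$b_r) + H %*% params$U_r)
  RH <- R * H
  C <- tanh(affine(G, params$W_c, params$b_c) + RH %*% params$U_c)
  list(H = (1 - Z) * H + Z * C, Z = Z, R = R, C = C, RH = RH)
}

softmax_rows <- function(Logits) {
  m <- apply(Logits, 1L, max)
  e <- exp(Logits - m)
  e / rowSums(e)
}

## ---- single-sample user-facing ops ---------------------------------------

#' Glimpse network forward pass
#'
#' Computes the glimpse feature
#' `g = ReLU(Linear(h_MS) + Linear(h_l))` with
#' `h_MS = ReLU(Linear(flattened patches))` and `h_l = ReLU(Linear(loc))`.
#'
#' @param stack A `glimpse_stack` (or any numeric array of the configured
#'   input length).
#' @param loc Numeric length-2 location in \[-1, +1\]^2 (the location the
#'   stack was extracted at).
#' @param params A [ram_params()] object.
#' @return Numeric vector of length `g_dim` (non-negative).
#' @export
glimpse_forward <- function(stack, loc, params) {
  check_params(params)
  x <- as.numeric(stack)
  d <- attr(params, "dims")
  if (length(x) != d$input_dim)
    stop(sprintf("glimpse stack length %d does not match input_dim %d",
                 length(x), d$input_dim))
  fw <- glimpse_forward_batch(matrix(x, 1L), matrix(clip_location(loc), 1L), params)
  as.numeric(fw$G)
}

#' One GRU update step
#'
#' Standard gated recurrent unit:
#' `z = sigmoid(W_z g + U_z h + b_z)`, `r = sigmoid(W_r g + U_r h + b_r)`,
#' `c = tanh(W_c g + U_c (r * h) + b_c)`, `h' = (1 - z) * h + z * c`.
#'
#' @param h_prev Hidden state vector (length `hidden`).
#' @param g Glimpse feature vector (length `g_dim`).
#' @param params A [ram_params()] object.
#' @return The updated hidden state.
#' @export
gru_step <- function(h_prev, g, params) {
  check_params(params)
  d <- attr(params, "dims")
  if (length(h_prev) != d$hidden || length(g) != d$g_dim)
    stop("gru_step: dimension mismatch")
  st <- gru_step_batch(matrix(h_prev, 1L), matrix(g, 1L), params)
  as.numeric(st$H)
}

#' Location-policy mean
#'
#' Affine map of the hidden state to two values, squashed by `tanh` so the
#' policy mean stays inside the valid coordinate box.
#'
#' @inheritParams gru_step
#' @param h Hidden state vector.
#' @return Numeric length-2 vector in (-1, 1)^2.
#' @export
location_mean <- function(h, params) {
  check_params(params)
  tanh(as.numeric(matrix(h, 1L) %*% params$W_loc) + params$b_loc)
}

#' Classification probabilities
#'
#' Softmax of an affine map of the hidden state.
#'
#' @inheritParams location_mean
#' @return Probability vector over the C classes.
#' @export
classify <- function(h, params) {
  check_params(params)
  as.numeric(softmax_rows(affine(matrix(h, 1L), params$W_a, params$b_a)))
}

#' State-value baseline
#'
#' Scalar affine map of the hidden state estimating the expected return from
#' that state; used to reduce REINFORCE gradient variance.
#'
#' @inheritParams location_mean
#' @return A single numeric value.
#' @export
baseline_value <- function(h, params) {
  check_params(params)
  as.numeric(matrix(h, 1L) %*% params$W_b) + params$b_b
}

## ---- differentiable chain for gradient checking --------------------------

# Forward + analytic gradients of loss = cross-entropy(classify(gru_step(h0,
# glimpse_forward(x, l)))) w.r.t. every parameter array on the path. Used by
# tests to validate backpropagation against finite differences; the training
# loop reuses the same primitive equations over T steps.
chain_forward_loss <- function(params, x, loc, h0, label) {
  X <- matrix(x, 1L); L <- matrix(loc, 1L); H0 <- matrix(h0, 1L)
  fw <- glimpse_forward_batch(X, L, params)
  st <- gru_step_batch(H0, fw$G, params)
  P <- softmax_rows(affine(st$H, params$W_a, params$b_a))
  list(loss = -log(P[1L, label + 1L]), probs = as.numeric(P), fw = fw, st = st, H = st$H)
}

chain_backward <- function(params, x, loc, h0, label, cache) {
  X <- matrix(x, 1L); L <- matrix(loc, 1L); H0 <- matrix(h0, 1L)
  fw <- cache$fw; st <- cache$st
  P <- matrix(cache$probs, 1L)
  Y <- matrix(0, 1L, length(cache$probs)); Y[1L, label + 1L] <- 1
  dLogits <- P - Y
  g <- empty_grads(params)
  g$W_a <- t(st$H) %*% dLogits; g$b_a <- as.numeric(dLogits)
  dH <- dLogits %*% t(params$W_a)
  bk <- gru_backward_batch(params, H0, fw$G, st, dH)
  g <- accumulate_gru_grads(g, bk)
  gb <- glimpse_backward_batch(params, X, L, fw, bk$dG)
  g <- accumulate_glimpse_grads(g, gb)
  g
}

empty_grads <- function(params) {
  g <- lapply(params[param_names()], function(a) a * 0)
  g
}

# GRU backward for one step: given dH (B x nh) w.r.t. the new state, return
# gradients for GRU weights, dG, and dH_prev.
gru_backward_batch <- function(params, Hprev, G, st, dH) {
  Z <- st$Z; R <- st$R; C <- st$C; RH <- st$RH
  dZ <- dH * (C - Hprev)
  dC <- dH * Z
  dHprev <- dH * (1 - Z)
  dAc <- dC * (1 - C^2)
  dW_c <- t(G) %*% dAc; dU_c <- t(RH) %*% dAc; db_c <- colSums(dAc)
  dG <- dAc %*% t(params$W_c)
  dRH <- dAc %*% t(params$U_c)
  dR <- dRH * Hprev
  dHprev <- dHprev + dRH * R
  dAz <- dZ * Z * (1 - Z)
  dW_z <- t(G) %*% dAz; dU_z <- t(Hprev) %*% dAz; db_z <- colSums(dAz)
  dG <- dG + dAz %*% t(params$W_z)
  dHprev <- dHprev + dAz %*% t(params$U_z)
  dAr <- dR * R * (1 - R)
  dW_r <- t(G) %*% dAr; dU_r <- t(Hprev) %*% dAr; db_r <- colSums(dAr)
  dG <- dG + dAr %*% t(params$W_r)
  dHprev <- dHprev + dAr %*% t(params$U_r)
  list(dG = dG, dHprev = dHprev,
       W_z = dW_z, U_z = dU_z, b_z = db_z,
       W_r = dW_r, U_r = dU_r, b_r = db_r,
       W_c = dW_c, U_c = dU_c, b_c = db_c)
}

accumulate_gru_grads <- function(g, bk) {
  for (nm in c("W_z", "U_z", "b_z", "W_r", "U_r", "b_r", "W_c", "U_c", "b_c"))
    g[[nm]] <- g[[nm]] + bk[[nm]]
  g
}

# Glimpse network backward: given dG, return weight grads (no gradient flows
# into the patch data or the location coordinates — hard attention).
glimpse_backward_batch <- function(params, X, L, fw, dG) {
  dA3 <- dG * (fw$A3 > 0)
  dW_gg <- t(fw$Hms) %*% dA3
  dW_lg <- t(fw$Hl) %*% dA3
  db_out <- colSums(dA3)
  dHms <- dA3 %*% t(params$W_gg)
  dHl <- dA3 %*% t(params$W_lg)
  dA1 <- dHms * (fw$A1 > 0)
  dA2 <- dHl * (fw$A2 > 0)
  list(W_g = t(X) %*% dA1, b_g = colSums(dA1),
       W_lp = t(L) %*% dA2, b_lp = colSums(dA2),
       W_gg = dW_gg, W_lg = dW_lg, b_out = db_out)
}

accumulate_glimpse_grads <- function(g, gb) {
  for (nm in c("W_g", "b_g", "W_lp", "b_lp", "W_gg", "W_lg", "b_out"))
    g[[nm]] <- g[[nm]] + gb[[nm]]
  g
}

## ---- checkpoints ---------------------------------------------------------

#' Save model parameters to a JSON checkpoint
#'
#' All parameter arrays (with dimensions), the policy standard deviation,
#' the dimension settings and an optional configuration hash are written to
#' a single JSON file.
#'
#' @param params A [ram_params()] object.
#' @param path Output file path.
#' @param config_hash Optional string identifying the run configuration.
#' @param extra Optional named list of additional scalar metadata.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path, config_hash = NULL, extra = NULL) {
  check_params(params)
  arrays <- lapply(params[param_names()], function(a) {
    if (is.matrix(a)) list(dim = dim(a), data = as.numeric(a))
    else list(dim = length(a), data = as.numeric(a))
  })
  obj <- list(format = "eegram-checkpoint-1",
              dims = attr(params, "dims"),
              sigma = attr(params, "sigma"),
              config_hash = config_hash,
              extra = extra,
              arrays = arrays)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load model parameters from a JSON checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A [ram_params()] object with attribute `config_hash`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "eegram-checkpoint-1")
    stop("not an eegram checkpoint: ", path)
  p <- lapply(param_names(), function(nm) {
    a <- obj$arrays[[nm]]
    if (length(a$dim) == 2L) matrix(a$data, a$dim[1], a$dim[2]) else as.numeric(a$data)
  })
  names(p) <- param_names()
  structure(p, class = "ram_params",
            dims = lapply(obj$dims, as.integer),
            sigma = as.numeric(obj$sigma),
            config_hash = obj$config_hash)
}
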