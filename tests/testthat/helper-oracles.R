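# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops and must stay decoupled from the package
# internals they check.

# Nearest-cell-centre index for one axis; ties toward the grid centre, then
# toward the larger index (matching the documented coordinate convention).
oracle_denorm_axis <- function(coord, extent) {
  centers <- (2 * seq_len(extent) - 1) / extent - 1
  d <- abs(coord - centers)
  cand <- which(d <= min(d) + 1e-12)
  if (length(cand) > 1L) {
    mid <- (extent + 1) / 2
    dm <- abs(cand - mid)
    cand <- cand[dm <= min(dm) + 1e-12]
    cand <- max(cand)
  }
  cand
}

# Brute-force multi-scale glimpse: explicit window loops, explicit padding,
# explicit block binning for the pooling.
oracle_glimpse <- function(signal, loc, k, br, bc, sf = 2L, pad = 0,
                           clamp_rows = FALSE) {
  loc <- pmin(pmax(loc, -1), 1)
  ci <- oracle_denorm_axis(loc[1], nrow(signal))
  cj <- oracle_denorm_axis(loc[2], ncol(signal))
  out <- array(NA_real_, c(k, br, bc))
  for (s in seq_len(k)) {
    wr <- br * sf^(s - 1L); wc <- bc * sf^(s - 1L)
    if (clamp_rows && wr > nrow(signal)) {
      r0 <- 1L; wr <- nrow(signal)
    } else r0 <- ci - wr %/% 2L
    c0 <- cj - wc %/% 2L
    win <- matrix(pad, wr, wc)
    for (a in seq_len(wr)) for (b in seq_len(wc)) {
      rr <- r0 + a - 1L; cc <- c0 + b - 1L
      if (rr >= 1L && rr <= nrow(signal) && cc >= 1L && cc <= ncol(signal))
        win[a, b] <- signal[rr, cc]
    }
    for (a in seq_len(br)) for (b in seq_len(bc)) {
      rows <- which(floor((seq_len(wr) - 1L) * br / wr) + 1L == a)
      cols <- which(floor((seq_len(wc) - 1L) * bc / wc) + 1L == b)
      out[s, a, b] <- mean(win[rows, cols, drop = FALSE])
    }
  }
  out
}

# Energy-based matched-filter classifier for burst epochs: score each class
# by summed squared amplitude in a window around its locus.
oracle_burst_classify <- function(epoch, specs, slack_time = 40L,
                                  slack_channel = 2L) {
  scores <- vapply(specs, function(sp) {
    half <- sp$duration %/% 2L + slack_time
    tt <- max(1L, sp$center_time - half):min(ncol(epoch), sp$center_time + half)
    ch <- max(1L, sp$center_channel - sp$channel_spread - slack_channel):
      min(nrow(epoch), sp$center_channel + sp$channel_spread + slack_channel)
    sum(epoch[ch, tt]^2)
  }, numeric(1))
  which.max(scores) - 1L
}

# Energy centroid of the burst in time on the locus channel group.
oracle_burst_center <- function(epoch, spec) {
  ch <- max(1L, spec$center_channel - spec$channel_spread):
    min(nrow(epoch), spec$center_channel + spec$channel_spread)
  e <- colSums(epoch[ch, , drop = FALSE]^2)
  sum(seq_along(e) * e) / sum(e)
}

# Exhaustive cross-correlation template matcher for glyph canvases.
oracle_find_offset <- function(canvas, template) {
  best <- c(NA_integer_, NA_integer_); best_v <- -Inf
  nr <- nrow(canvas) - nrow(template) + 1L
  nc <- ncol(canvas) - ncol(template) + 1L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    v <- sum(canvas[r:(r + nrow(template) - 1L),
                    cc:(cc + ncol(template) - 1L)] * template)
    if (v > best_v) { best_v <- v; best <- c(r, cc) }
  }
  best
}

# Zero out every trainable array, keeping attributes.
zero_params <- function(params) {
  at <- attributes(params)
  params <- lapply(params, function(a) a * 0)
  attributes(params) <- at
  params
}

# Draw a random instance of the differentiable chain whose ReLU
# pre-activations sit safely away from the kinks, so central finite
# differences with eps = 1e-5 are valid everywhere.
draw_smooth_chain_instance <- function(margin = 1e-3) {
  repeat {
    p <- ram_params(6, 3, hidden = 4, glimpse_hidden = 3, loc_hidden = 3,
                    g_dim = 4)
    x <- rnorm(6); loc <- runif(2, -1, 1); h0 <- 0.5 * rnorm(4)
    label <- sample(0:2, 1)
    cache <- eegram:::chain_forward_loss(p, x, loc, h0, label)
    pre <- c(cache$fw$A1, cache$fw$A2, cache$fw$A3)
    if (min(abs(pre)) > margin)
      return(list(p = p, x = x, loc = loc, h0 = h0, label = label,
                  cache = cache))
  }
}

# Small random parameter set for unit tests.
tiny_params <- function(input_dim = 6L, n_classes = 3L, hidden = 4L,
                        seed = 1) {
  ram_params(input_dim, n_classes, hidden = hidden, glimpse_hidden = 3L,
             loc_hidden = 3L, g_dim = 4L, seed = seed)
}
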