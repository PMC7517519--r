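#' Parameters of the pairwise additive-attention head
#'
#' The attention head scores every ordered pair of regions (n, n') from
#' their encoder features h_n, h_n' via
#' g(n, n') = tanh(W_g h_n + W_g' h_n' + b_g),
#' gates each pair with a sigmoid, alpha(n, n') = sigmoid(W_a g(n, n') +
#' b_a), and fuses l_n = sum_n' alpha(n, n') h_n'. The gate is a
#' per-pair sigmoid threshold, not a softmax: the weights over n' need
#' not sum to one.
#'
#' @param d encoder feature dimension D.
#' @param d_a attention hidden width (defaults to `d`).
#' @param seed optional seed for the Xavier draw.
#' @return list with `Wg`, `Wgp` (d_a x d), `bg` (d_a), `Wa` (length
#'   d_a), `ba` (scalar), class `attention_params`.
#' @export
attention_params <- function(d, d_a = d, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  structure(list(
    Wg = xavier(c(d_a, d), d, d_a),
    Wgp = xavier(c(d_a, d), d, d_a),
    bg = numeric(d_a),
    Wa = as.numeric(xavier(c(d_a), d_a, 1)),
    ba = 0
  ), class = "attention_params")
}

#' Pairwise additive attention scores
#'
#' Computes the hidden score vector of every ordered region pair:
#' entry (n, n', k) = tanh(W_g h_n + W_g' h_n' + b_g)_k. All entries lie
#' in (-1, 1). The self-pair n' = n is included (the fusion sum runs
#' over all n').
#'
#' @param h feature matrix, regions x D (one row per region).
#' @param params an [attention_params()].
#' @return array R x R x d_a.
#' @export
pairwise_scores <- function(h, params) {
  h <- as.matrix(h)
  if (ncol(h) != ncol(params$Wg)) {
    stop("feature width does not match attention parameter shapes")
  }
  r <- nrow(h)
  d_a <- length(params$bg)
  s1 <- h %*% t(params$Wg)  # R x d_a, row n = W_g h_n
  s2 <- h %*% t(params$Wgp) # R x d_a, row n' = W_g' h_n'
  g <- array(0, dim = c(r, r, d_a))
  for (k in seq_len(d_a)) {
    g[, , k] <- tanh(outer(s1[, k], s2[, k], `+`) + params$bg[k])
  }
  g
}

#' Gate weights from pairwise scores
#'
#' With the default sigmoid gate, entry (n, n') =
#' sigmoid(W_a g(n, n') + b_a), strictly inside (0, 1), and no
#' normalization across n' is applied — the gate thresholds each pair
#' independently. A row-softmax variant (weights over n' summing to 1)
#' is available for ablation only; it is a different model class, not
#' the method's gate.
#'
#' @param g score array from [pairwise_scores()].
#' @param params an [attention_params()].
#' @param gate `"sigmoid"` (the method) or `"softmax"` (ablation).
#' @return matrix R x R of attention weights.
#' @export
attention_weights <- function(g, params, gate = c("sigmoid", "softmax")) {
  gate <- match.arg(gate)
  d <- dim(g)
  pre <- matrix(params$ba, d[1], d[2])
  for (k in seq_len(d[3])) {
    pre <- pre + params$Wa[k] * g[, , k]
  }
  if (gate == "sigmoid") {
    sigmoid(pre)
  } else {
    e <- exp(pre - apply(pre, 1, max))
    e / rowSums(e)
  }
}

#' Fuse region features under attention weights
#'
#' Row n of the result is the weighted sum over all regions n' of
#' h_n' with weight alpha(n, n'): the representation of region n under
#' the influence of every other region.
#'
#' @param h feature matrix R x D.
#' @param a weight matrix R x R.
#' @return matrix R x D of fused features.
#' @export
fuse <- function(h, a) {
  h <- as.matrix(h); a <- as.matrix(a)
  if (nrow(h) != ncol(a) || nrow(a) != nrow(h)) {
    stop("attention weight matrix must be R x R for an R-region feature matrix")
  }
  a %*% h
}

#' Full attention pass: scores, weights, fusion
#'
#' Convenience wrapper chaining [pairwise_scores()],
#' [attention_weights()] and [fuse()].
#'
#' @inheritParams pairwise_scores
#' @return list with `weights` (R x R) and `fused` (R x D).
#' @export
attention_fuse <- function(h, params) {
  fw <- attention_forward(as.matrix(h), params)
  list(weights = fw$a, fused = fw$fused)
}

# Fused forward used in training: a single compiled sweep computes the
# gate pre-activations and caches the per-k tanh sheets for backward.
attention_forward <- function(h, params) {
  s1 <- h %*% t(params$Wg)
  s2 <- h %*% t(params$Wgp)
  res <- attention_pre_sheets(s1, s2, params$bg, params$Wa,
                              as.numeric(params$ba))
  a <- sigmoid(res$pre)
  list(fused = a %*% h, a = a, s1 = s1, s2 = s2, h = h,
       sheets = res$sheets)
}

# Backward through the attention head. dfused: R x D. Returns dH and
# parameter gradients.
attention_backward <- function(dfused, params, fw) {
  h <- fw$h; a <- fw$a
  da <- tcrossprod(dfused, h)         # dfused %*% t(h): R x R
  dh <- crossprod(a, dfused)          # t(a) %*% dfused: R x D
  dpre <- da * a * (1 - a)
  bk <- attention_bwd_sheets(dpre, fw$sheets, params$Wa)
  dh <- dh + bk$ds1 %*% params$Wg + bk$ds2 %*% params$Wgp
  grads <- list(Wg = crossprod(bk$ds1, h), Wgp = crossprod(bk$ds2, h),
                bg = as.numeric(bk$dbg), Wa = as.numeric(bk$dwa),
                ba = sum(dpre))
  list(dh = dh, grads = grads)
}

#' Dense (fully connected) fusion head
#'
#' Ablation head: flattens the R x D feature matrix column-major and
#' applies one affine map followed by a rectifier.
#'
#' @param h feature matrix R x D.
#' @param params from [dense_params()].
#' @return numeric vector of length `width`.
#' @export
dense_fuse <- function(h, params) {
  v <- as.numeric(params$W %*% as.vector(as.matrix(h)) + params$b)
  relu(v)
}

#' @rdname dense_fuse
#' @param width output width of the dense layer.
#' @param r,d region count and feature dimension of the incoming matrix.
#' @param seed optional seed.
#' @export
dense_params <- function(width, r, d, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  list(W = xavier(c(width, r * d), r * d, width), b = numeric(width))
}

dense_forward <- function(h, params) {
  x <- as.vector(h)
  pre <- as.numeric(params$W %*% x + params$b)
  list(out = relu(pre), pre = pre, x = x, hdim = dim(h))
}

dense_backward <- function(dout, params, fw) {
  dpre <- dout * (fw$pre > 0)
  dh <- matrix(as.numeric(crossprod(params$W, dpre)),
               nrow = fw$hdim[1], ncol = fw$hdim[2])
  list(dh = dh, grads = list(W = tcrossprod(dpre, fw$x), b = dpre))
}

#' Bidirectional LSTM fusion head
#'
#' Ablation head: treats the R region features (in atlas order) as a
#' length-R sequence of D-vectors, runs a forward and a backward LSTM
#' pass with separate parameters, and concatenates the two final hidden
#' states.
#'
#' @param h feature matrix R x D.
#' @param params from [lstm_params()].
#' @return numeric vector of length `2 * hidden`.
#' @export
bilstm_fuse <- function(h, params) {
  bilstm_forward(as.matrix(h), params)$out
}

#' @rdname bilstm_fuse
#' @param hidden hidden state size of each directional pass.
#' @param d feature dimension of the incoming matrix rows.
#' @param seed optional seed.
#' @export
lstm_params <- function(hidden, d, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  one_dir <- function() {
    list(W = xavier(c(4L * hidden, d), d, 4L * hidden),
         U = xavier(c(4L * hidden, hidden), hidden, 4L * hidden),
         b = numeric(4L * hidden))
  }
  list(fwd = one_dir(), bwd = one_dir())
}

# Single-direction LSTM over the rows of x (steps x d). Gate order in
# the stacked 4h pre-activation: input, forget, output, candidate.
lstm_dir_forward <- function(x, p) {
  hsz <- ncol(p$U)
  steps <- nrow(x)
  h_prev <- numeric(hsz); c_prev <- numeric(hsz)
  cache <- vector("list", steps)
  for (t in seq_len(steps)) {
    z <- as.numeric(p$W %*% x[t, ] + p$U %*% h_prev + p$b)
    i <- sigmoid(z[1:hsz])
    f <- sigmoid(z[(hsz + 1):(2 * hsz)])
    o <- sigmoid(z[(2 * hsz + 1):(3 * hsz)])
    g <- tanh(z[(3 * hsz + 1):(4 * hsz)])
    c_new <- f * c_prev + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c_prev,
                       h_prev = h_prev, tc = tc)
    h_prev <- h_new; c_prev <- c_new
  }
  list(h = h_prev, cache = cache)
}

lstm_dir_backward <- function(dh_final, x, p, fw) {
  hsz <- ncol(p$U)
  steps <- nrow(x)
  dW <- array(0, dim = dim(p$W)); dU <- array(0, dim = dim(p$U))
  db <- numeric(4L * hsz)
  dx <- matrix(0, steps, ncol(x))
  dh <- dh_final; dc <- numeric(hsz)
  for (t in rev(seq_len(steps))) {
    cc <- fw$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc <- dc * cc$f
    dz <- c(di * cc$i * (1 - cc$i),
            df * cc$f * (1 - cc$f),
            do_ * cc$o * (1 - cc$o),
            dg * (1 - cc$g^2))
    dW <- dW + tcrossprod(dz, x[t, ])
    dU <- dU + tcrossprod(dz, cc$h_prev)
    db <- db + dz
    dx[t, ] <- as.numeric(crossprod(p$W, dz))
    dh <- as.numeric(crossprod(p$U, dz))
  }
  list(dx = dx, grads = list(W = dW, U = dU, b = db))
}

bilstm_forward <- function(h, params) {
  fw <- lstm_dir_forward(h, params$fwd)
  bw <- lstm_dir_forward(h[rev(seq_len(nrow(h))), , drop = FALSE],
                         params$bwd)
  list(out = c(fw$h, bw$h), fw = fw, bw = bw, h = h)
}

bilstm_backward <- function(dout, params, fw) {
  hsz <- length(fw$fw$h)
  r <- nrow(fw$h)
  bf <- lstm_dir_backward(dout[1:hsz], fw$h, params$fwd, fw$fw)
  hrev <- fw$h[rev(seq_len(r)), , drop = FALSE]
  bb <- lstm_dir_backward(dout[(hsz + 1):(2 * hsz)], hrev, params$bwd,
                          fw$bw)
  dh <- bf$dx + bb$dx[rev(seq_len(r)), , drop = FALSE]
  list(dh = dh, grads = list(fwd = bf$grads, bwd = bb$grads))
}

#' Mean received attention weight per region
#'
#' For interpretation: the average, over subjects, of the mean weight
#' column n' of the attention matrix — how strongly each region's
#' features are drawn into the fused representations of the others (and
#' itself).
#'
#' @param model a trained model with an attention head (see
#'   [build_model()]).
#' @param subjects list of `roi_ts` objects.
#' @param standardize apply per-region z-scoring first (default TRUE;
#'   use the same setting as training).
#' @return numeric vector of length R.
#' @export
attention_profile <- function(model, subjects, standardize = TRUE) {
  stopifnot(model$head == "attention")
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  total <- NULL
  for (s in subjects) {
    ts <- if (standardize) standardize(s) else s
    h <- encode(ts, model$encoder_config, model$params$encoder)
    fw <- attention_forward(h, model$params$head)
    recv <- colMeans(fw$a)
    total <- if (is.null(total)) recv else total + recv
  }
  total / length(subjects)
}
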