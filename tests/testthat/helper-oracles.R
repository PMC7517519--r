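# Independent scalar reference implementations used as oracles. They are
# deliberately naive (explicit loops, no vectorization) so they share no
# code path with the package internals they check.

# Region-mean extraction by looping over every voxel.
ref_extract <- function(volume, atlas, region_ids) {
  d <- dim(volume)
  n_t <- d[4]
  out <- matrix(0, length(region_ids), n_t)
  for (ri in seq_along(region_ids)) {
    total <- numeric(n_t)
    count <- 0
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (atlas[x, y, z] == region_ids[ri]) {
        count <- count + 1
        for (t in seq_len(n_t)) total[t] <- total[t] + volume[x, y, z, t]
      }
    }
    out[ri, ] <- total / count
  }
  out
}

# Full additive-attention pipeline with scalar triple loops.
ref_attention <- function(h, params) {
  r <- nrow(h); d_a <- length(params$bg)
  alpha <- matrix(0, r, r)
  for (n in seq_len(r)) {
    for (np in seq_len(r)) {
      g <- numeric(d_a)
      for (k in seq_len(d_a)) {
        g[k] <- tanh(sum(params$Wg[k, ] * h[n, ]) +
                     sum(params$Wgp[k, ] * h[np, ]) + params$bg[k])
      }
      alpha[n, np] <- 1 / (1 + exp(-(sum(params$Wa * g) + params$ba)))
    }
  }
  fused <- matrix(0, r, ncol(h))
  for (n in seq_len(r)) {
    for (np in seq_len(r)) {
      fused[n, ] <- fused[n, ] + alpha[n, np] * h[np, ]
    }
  }
  list(weights = alpha, fused = fused)
}

# AUC by exhaustive enumeration of positive-negative pairs.
ref_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Valid 1D convolution + temporal mean for a single filter bank layer,
# computed with explicit loops over regions, filters and time.
ref_encode_1layer <- function(x, w, b, activation = "relu") {
  c_out <- dim(w)[1]; k <- dim(w)[3]
  t_out <- ncol(x) - k + 1
  feats <- matrix(0, nrow(x), c_out)
  for (n in seq_len(nrow(x))) {
    for (o in seq_len(c_out)) {
      acc <- 0
      for (t in seq_len(t_out)) {
        v <- sum(w[o, 1, ] * x[n, t:(t + k - 1)]) + b[o]
        if (activation == "relu") v <- max(v, 0)
        acc <- acc + v
      }
      feats[n, o] <- acc / t_out
    }
  }
  feats
}

# Central finite-difference gradient of a scalar function of a nested
# parameter list, compared leaf-by-leaf against analytic gradients.
max_rel_grad_err <- function(lossfn, params, grads, eps = 1e-6) {
  worst <- 0
  walk <- function(path) {
    leaf <- params; g <- grads
    for (k in path) { leaf <- leaf[[k]]; g <- g[[k]] }
    if (is.list(leaf)) {
      for (nm in names(leaf)) walk(c(path, nm))
      return(invisible())
    }
    for (i in seq_along(leaf)) {
      poke <- function(val) {
        q <- params
        if (length(path) == 1) q[[path[1]]][i] <- val
        else if (length(path) == 2) q[[path[1]]][[path[2]]][i] <- val
        else if (length(path) == 3) q[[path[1]]][[path[2]]][[path[3]]][i] <- val
        else q[[path[1]]][[path[2]]][[path[3]]][[path[4]]][i] <- val
        q
      }
      num <- (lossfn(poke(leaf[i] + eps)) - lossfn(poke(leaf[i] - eps))) /
        (2 * eps)
      worst <<- max(worst, abs(num - g[i]) / max(1, abs(num)))
    }
  }
  for (nm in names(params)) walk(nm)
  worst
}

# Small two-site cohort for fast end-to-end tests.
tiny_cohort <- function(n_regions = 8, effect_size = 2, seed = 11,
                        n_per_class = 6, lengths1 = c(40L, 60L),
                        lengths2 = 50L) {
  sites <- list(
    site_spec("A", n_per_class, n_per_class, lengths1),
    site_spec("B", n_per_class, n_per_class, lengths2, scale = 1.2,
              baseline_shift = 3)
  )
  sig <- signal_spec(n_regions = n_regions,
                     informative_regions = seq_len(max(2, n_regions %/% 3)),
                     effect_size = effect_size, mechanism = "coupling")
  generate_cohort(sites, sig, seed = seed)
}

tiny_encoder <- function() {
  encoder_config(n_layers = 1, filters = 4L, kernel_size = 5,
                 pooling = "none")
}
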