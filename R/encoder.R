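#' Configuration of the shared-weight temporal encoder
#'
#' The first-stage network: a stack of 1D "valid" (unpadded) temporal
#' convolutions applied to each region's series independently, with a
#' single parameter set shared by every region, optionally max-pooled
#' (width 2) between layers, and finished by averaging each final-layer
#' filter's feature map over its valid time positions. The temporal
#' average maps any admissible series length T to a fixed-size feature,
#' which is what lets one model consume runs of different lengths.
#'
#' @param n_layers number of convolutional layers.
#' @param filters integer vector of filter counts, one per layer; the
#'   last entry is the feature dimension D of the encoder output.
#' @param kernel_size temporal kernel width (same for all layers).
#' @param activation `"relu"` (default) or `"identity"`.
#' @param pooling `"max2"` (max-pool width 2, stride 2, between layers)
#'   or `"none"`.
#' @param l2_coefficient default L2 penalty recorded with the config.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 3L, filters = c(32L, 32L, 64L),
                           kernel_size = 7L,
                           activation = c("relu", "identity"),
                           pooling = c("max2", "none"),
                           l2_coefficient = 1e-4) {
  activation <- match.arg(activation)
  pooling <- match.arg(pooling)
  n_layers <- as.integer(n_layers)
  filters <- as.integer(filters)
  kernel_size <- as.integer(kernel_size)
  if (n_layers < 1L) stop("need at least one layer")
  if (length(filters) != n_layers) {
    stop("filters must have one entry per layer")
  }
  if (any(filters < 1L) || kernel_size < 1L) {
    stop("filters and kernel_size must be positive")
  }
  if (l2_coefficient < 0) stop("l2_coefficient must be nonnegative")
  structure(list(n_layers = n_layers, filters = filters,
                 kernel_size = kernel_size, activation = activation,
                 pooling = pooling, l2_coefficient = l2_coefficient),
            class = "encoder_config")
}

#' Minimum admissible series length for an encoder configuration
#'
#' Each convolution consumes `kernel_size - 1` time points and each
#' between-layer pooling halves the remainder; the final feature map
#' must retain at least one valid position.
#'
#' @param config an [encoder_config()].
#' @return integer minimum T.
#' @export
min_input_length <- function(config) {
  t_min <- 1L
  for (i in rev(seq_len(config$n_layers))) {
    t_min <- t_min + config$kernel_size - 1L
    if (i > 1L && config$pooling == "max2") t_min <- 2L * t_min
  }
  t_min
}

#' Count trainable encoder parameters
#'
#' Because the same filter bank serves every region, the count depends
#' only on the configuration, never on the number of regions.
#'
#' @param config an [encoder_config()].
#' @return integer total of weights and biases.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  c_in <- 1L
  total <- 0L
  for (i in seq_len(config$n_layers)) {
    c_out <- config$filters[i]
    total <- total + c_out * c_in * config$kernel_size + c_out
    c_in <- c_out
  }
  total
}

#' Xavier-initialized encoder parameters
#'
#' @param config an [encoder_config()].
#' @param seed optional integer seed (set before drawing).
#' @return nested list of per-layer weights `W` (out x in x kernel) and
#'   biases `b`.
#' @export
encoder_init <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  c_in <- 1L
  layers <- list()
  for (i in seq_len(config$n_layers)) {
    c_out <- config$filters[i]
    k <- config$kernel_size
    layers[[paste0("layer", i)]] <- list(
      W = xavier(c(c_out, c_in, k), fan_in = c_in * k, fan_out = c_out * k),
      b = numeric(c_out)
    )
    c_in <- c_out
  }
  list(layers = layers)
}

# --- internal forward/backward on a stack of series -----------------------
# Activations live in flat time-major matrices: an (N*T) x C matrix whose
# row (t-1)*N + n holds series n at time t. In this layout the im2col
# block for kernel tap j is a contiguous row slice, pooling selects
# strided row blocks, and the temporal average is a single rowsum — all
# single-pass operations, which is what keeps the pure-R training loop
# fast.

conv_forward <- function(a, n, t_in, w, b) {
  c_in <- ncol(a)
  k <- dim(w)[3]; c_out <- dim(w)[1]
  t_out <- t_in - k + 1L
  if (t_out < 1L) stop("series too short for convolution")
  m <- im2col_tm(a, n, t_out, k)
  wmat <- matrix(aperm(w, c(2, 3, 1)), c_in * k, c_out)
  z <- m %*% wmat
  add_bias_inplace(z, b) # z is a fresh product
  list(out = z, m = m, wmat = wmat,
       dims = c(n = n, t_in = t_in, c_in = c_in, t_out = t_out,
                c_out = c_out, k = k))
}

conv_backward <- function(dz, cache, need_da = TRUE) {
  d <- cache$dims
  n <- d[["n"]]; t_in <- d[["t_in"]]; c_in <- d[["c_in"]]
  t_out <- d[["t_out"]]; c_out <- d[["c_out"]]; k <- d[["k"]]
  dwmat <- crossprod(cache$m, dz)
  db <- colSums(dz)
  da <- NULL
  if (need_da) {
    dm <- tcrossprod(dz, cache$wmat)
    da <- col2im_tm(dm, n, t_in, t_out, k, c_in)
  }
  dw <- aperm(array(dwmat, dim = c(c_in, k, c_out)), c(3, 1, 2))
  list(da = da, dW = dw, db = db)
}

pool2_forward <- function(a, n, t_in) {
  t_out <- t_in %/% 2L
  if (t_out < 1L) stop("series too short for pooling")
  rows1 <- rep((seq_len(t_out) * 2L - 2L) * n, each = n) + seq_len(n)
  rows2 <- rows1 + n
  a1 <- a[rows1, , drop = FALSE]
  a2 <- a[rows2, , drop = FALSE]
  mask <- a1 >= a2 # ties go to the earlier position, deterministically
  list(out = pmax(a1, a2), mask = mask, rows1 = rows1, rows2 = rows2,
       t_in = t_in, t_out = t_out)
}

pool2_backward <- function(dz, cache, n, c_out) {
  da <- matrix(0, n * cache$t_in, c_out)
  da[cache$rows1, ] <- dz * cache$mask
  da[cache$rows2, ] <- dz * !cache$mask
  da
}

# Forward over a stack of equal-length series. x: N x T matrix.
encoder_forward <- function(x, config, params) {
  n <- nrow(x); t_in <- ncol(x)
  if (t_in < min_input_length(config)) {
    stop(sprintf("series length %d below the minimum admissible length %d for this encoder",
                 t_in, min_input_length(config)))
  }
  a <- matrix(as.vector(x), n * t_in, 1L) # time-major flat layout
  t_cur <- t_in
  caches <- vector("list", config$n_layers)
  for (i in seq_len(config$n_layers)) {
    cv <- conv_forward(a, n, t_cur, params$layers[[i]]$W,
                       params$layers[[i]]$b)
    z <- cv$out
    t_cur <- cv$dims[["t_out"]]
    act <- NULL
    if (config$activation == "relu") {
      relu_inplace(z) # z is the sole reference to a fresh product
      act <- z # post-relu, pre-pool: doubles as the gradient mask
    }
    pool_cache <- NULL
    if (i < config$n_layers && config$pooling == "max2") {
      pl <- pool2_forward(z, n, t_cur)
      z <- pl$out
      t_cur <- pl$t_out
      pool_cache <- pl[c("mask", "rows1", "rows2", "t_in", "t_out")]
    }
    caches[[i]] <- list(conv = cv[c("m", "wmat", "dims")],
                        act = act, pool = pool_cache)
    a <- z
  }
  feats <- gap_forward(a, n, t_cur)
  list(features = feats, caches = caches, t_final = t_cur, n = n)
}

# Backward from d(features) (N x D) to encoder parameter gradients.
encoder_backward <- function(dfeat, config, params, fw) {
  n <- fw$n
  t_final <- fw$t_final
  dz <- gap_backward(dfeat, t_final)
  grads <- list(layers = vector("list", config$n_layers))
  names(grads$layers) <- names(params$layers)
  for (i in rev(seq_len(config$n_layers))) {
    cache <- fw$caches[[i]]
    if (!is.null(cache$pool)) {
      if (i == config$n_layers) { # pooling only occurs between layers
        stop("internal: unexpected pool cache on final layer")
      }
      dz <- pool2_backward(dz, cache$pool, n, ncol(dz))
    }
    if (!is.null(cache$act)) {
      relu_mask_inplace(dz, cache$act) # dz freshly allocated upstream
    }
    bk <- conv_backward(dz, cache$conv, need_da = i > 1L)
    grads$layers[[i]] <- list(W = bk$dW, b = bk$db)
    dz <- bk$da
  }
  grads
}

#' Encode one subject's series into a fixed-size feature matrix
#'
#' Applies the shared filter bank to each region's series independently
#' and averages each final-layer filter's response over its valid time
#' positions, yielding an R x D matrix whose width D (last layer's filter
#' count) does not depend on the series length.
#'
#' @param ts an `roi_ts` or a plain regions x time matrix.
#' @param config an [encoder_config()].
#' @param params encoder parameters from [encoder_init()] or training.
#' @return numeric matrix, regions x D.
#' @export
encode <- function(ts, config, params) {
  x <- if (inherits(ts, "roi_ts")) ts$values else as.matrix(ts)
  encoder_forward(x, config, params)$features
}

#' Save / load an encoder checkpoint
#'
#' Stores parameters together with the configuration that produced them;
#' loading verifies the stored configuration against an expected one and
#' fails hard on mismatch.
#'
#' @param params encoder parameters.
#' @param config the [encoder_config()] they belong to.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns `list(config, params)`.
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(list(config = config, params = params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_config optional [encoder_config()] the checkpoint must
#'   match.
#' @export
load_checkpoint <- function(path, expected_config = NULL) {
  ck <- readRDS(path)
  if (!is.null(expected_config) &&
      !identical(unclass(ck$config), unclass(expected_config))) {
    stop("checkpoint configuration does not match the expected encoder config")
  }
  ck
}
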