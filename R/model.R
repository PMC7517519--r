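#' Build an end-to-end model
#'
#' Assembles the shared-weight temporal encoder, one of four fusion
#' heads, and a softmax classifier into a trainable model. All weights
#' are Xavier-initialized from the seed, so two builds with the same
#' seed and configuration are identical.
#'
#' Heads:
#' * `"attention"` — pairwise additive attention; the classifier sees
#'   the flattened R x D fused matrix;
#' * `"none"` — the plain SC-CNN: pooled encoder features flattened
#'   straight into the softmax layer;
#' * `"dense"` — one fully connected rectified layer over the flattened
#'   features;
#' * `"lstm"` — bidirectional LSTM over the region sequence.
#'
#' @param encoder_cfg an [encoder_config()].
#' @param head one of `"attention"`, `"none"`, `"dense"`, `"lstm"`.
#' @param n_regions number of regions R every subject carries.
#' @param seed integer seed for initialization.
#' @param d_a attention hidden width (default: encoder feature dim).
#' @param dense_width width of the dense head.
#' @param lstm_hidden per-direction hidden size of the LSTM head.
#' @return An object of class `sccnn_model`.
#' @export
build_model <- function(encoder_cfg = encoder_config(), head = "attention",
                        n_regions, seed = 1L, d_a = NULL,
                        dense_width = 64L, lstm_hidden = 16L) {
  if (!head %in% c("attention", "none", "dense", "lstm")) {
    stop("unknown head: ", head,
         " (expected attention, none, dense or lstm)")
  }
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 1L)
  d <- encoder_cfg$filters[encoder_cfg$n_layers]
  if (is.null(d_a)) d_a <- d
  set.seed(as.integer(seed))
  params <- list(encoder = encoder_init(encoder_cfg))
  cls_in <- switch(head,
    attention = {
      params$head <- unclass(attention_params(d, d_a))
      n_regions * d
    },
    none = {
      params$head <- list()
      n_regions * d
    },
    dense = {
      params$head <- dense_params(dense_width, n_regions, d)
      dense_width
    },
    lstm = {
      params$head <- lstm_params(lstm_hidden, d)
      2L * lstm_hidden
    }
  )
  params$cls <- list(W = xavier(c(cls_in, 2L), cls_in, 2L), b = numeric(2L))
  structure(list(encoder_config = encoder_cfg, head = head,
                 n_regions = n_regions, d = d, d_a = d_a,
                 dense_width = as.integer(dense_width),
                 lstm_hidden = as.integer(lstm_hidden),
                 params = params, step = 0L, opt_state = NULL,
                 history = NULL, seed = as.integer(seed)),
            class = "sccnn_model")
}

#' @export
print.sccnn_model <- function(x, ...) {
  cat(sprintf("<sccnn_model> head=%s | R=%d | D=%d | %d steps trained\n",
              x$head, x$n_regions, x$d, x$step))
  invisible(x)
}

# Encode a list of R x T matrices (possibly mixed T) into per-subject
# feature matrices. Subjects are grouped by length so the unpadded
# convolution and the temporal average are exact for every subject; a
# mixed batch therefore reproduces single-subject encoding bit-for-bit
# up to BLAS accumulation order.
encode_subjects <- function(mats, config, params) {
  lens <- vapply(mats, ncol, integer(1))
  groups <- split(seq_along(mats), lens)
  n_regions <- nrow(mats[[1]])
  feats <- vector("list", length(mats))
  caches <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    x <- do.call(rbind, mats[idx])
    fw <- encoder_forward(x, config, params)
    for (j in seq_along(idx)) {
      rows <- ((j - 1L) * n_regions + 1L):(j * n_regions)
      feats[[idx[j]]] <- fw$features[rows, , drop = FALSE]
    }
    caches[[gi]] <- list(idx = idx, fw = fw)
  }
  list(features = feats, groups = caches, n_regions = n_regions)
}

encoder_backward_subjects <- function(dfeats, config, params, enc) {
  grads <- NULL
  for (g in enc$groups) {
    dmat <- do.call(rbind, dfeats[g$idx])
    gg <- encoder_backward(dmat, config, params, g$fw)
    grads <- param_add(grads, gg)
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass over a list of roi_ts / matrices. Returns class
# probabilities and the caches needed for the backward pass.
model_forward <- function(model, mats) {
  enc <- encode_subjects(mats, model$encoder_config, model$params$encoder)
  b <- length(mats)
  head_caches <- vector("list", b)
  v <- matrix(0, b, nrow(model$params$cls$W))
  for (s in seq_len(b)) {
    h <- enc$features[[s]]
    if (model$head == "attention") {
      fw <- attention_forward(h, model$params$head)
      head_caches[[s]] <- fw
      v[s, ] <- as.vector(fw$fused)
    } else if (model$head == "none") {
      v[s, ] <- as.vector(h)
    } else if (model$head == "dense") {
      fw <- dense_forward(h, model$params$head)
      head_caches[[s]] <- fw
      v[s, ] <- fw$out
    } else {
      fw <- bilstm_forward(h, model$params$head)
      head_caches[[s]] <- fw
      v[s, ] <- fw$out
    }
  }
  logits <- v %*% model$params$cls$W +
    rep(model$params$cls$b, each = b)
  probs <- softmax_rows(logits)
  list(probs = probs, v = v, enc = enc, head_caches = head_caches)
}

# Backward pass: mean cross-entropy gradient through classifier, head
# and encoder. labels: 0/1 vector. Returns the nested gradient list.
model_backward <- function(model, fw, labels) {
  b <- length(labels)
  y <- cbind(1 - labels, labels)
  dlogits <- (fw$probs - y) / b
  grads <- list(encoder = NULL, head = NULL,
                cls = list(W = crossprod(fw$v, dlogits),
                           b = colSums(dlogits)))
  dv <- tcrossprod(dlogits, model$params$cls$W)
  n_regions <- model$n_regions
  d <- model$d
  dfeats <- vector("list", b)
  for (s in seq_len(b)) {
    if (model$head == "attention") {
      bk <- attention_backward(matrix(dv[s, ], n_regions, d),
                               model$params$head, fw$head_caches[[s]])
      dfeats[[s]] <- bk$dh
      grads$head <- param_add(grads$head, bk$grads)
    } else if (model$head == "none") {
      dfeats[[s]] <- matrix(dv[s, ], n_regions, d)
    } else if (model$head == "dense") {
      bk <- dense_backward(dv[s, ], model$params$head, fw$head_caches[[s]])
      dfeats[[s]] <- bk$dh
      grads$head <- param_add(grads$head, bk$grads)
    } else {
      bk <- bilstm_backward(dv[s, ], model$params$head, fw$head_caches[[s]])
      dfeats[[s]] <- bk$dh
      grads$head <- param_add(grads$head, bk$grads)
    }
  }
  grads$encoder <- encoder_backward_subjects(
    dfeats, model$encoder_config, model$params$encoder, fw$enc)
  if (model$head == "none") grads$head <- list()
  grads
}

cross_entropy <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Predict class-1 probabilities for a set of subjects
#'
#' @param model a built (typically trained) `sccnn_model`.
#' @param subjects a `cohort` or list of `roi_ts` objects.
#' @param standardize apply per-region z-scoring before encoding
#'   (default TRUE; must match how the model was trained).
#' @param chunk_size number of subjects encoded at a time (memory knob).
#' @return numeric vector of probabilities of class 1.
#' @export
predict_proba <- function(model, subjects, standardize = TRUE,
                          chunk_size = 64L) {
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  mats <- lapply(subjects, function(s) {
    v <- if (inherits(s, "roi_ts")) s else roi_timeseries(s)
    if (standardize) v <- standardize(v)
    v$values
  })
  out <- numeric(length(mats))
  chunks <- split(seq_along(mats), ceiling(seq_along(mats) / chunk_size))
  for (ch in chunks) {
    fw <- model_forward(model, mats[ch])
    out[ch] <- fw$probs[, 2]
  }
  out
}

#' Save / load a full model checkpoint
#'
#' The checkpoint carries configuration, weights, optimizer state, step
#' counter and training history, so training can resume exactly.
#'
#' @param model an `sccnn_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the
#'   model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sccnn_model")) stop("not a model checkpoint: ", path)
  m
}
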