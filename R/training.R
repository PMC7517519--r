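#' Training configuration
#'
#' Optimization settings: class-balanced minibatches (16 cases + 16
#' controls by default, sampled with replacement within class, which
#' keeps the effective class prior at 1/2 regardless of cohort
#' imbalance), Adam with default moment parameters and initial step size
#' 0.01, cross-entropy loss, and an L2 penalty on all multiplicative
#' weights.
#'
#' @param batch_size total subjects per minibatch.
#' @param per_class_per_batch subjects drawn per class; must be half of
#'   `batch_size`.
#' @param learning_rate initial Adam step size.
#' @param l2_coefficient L2 penalty coefficient on weights (not biases).
#' @param max_steps number of minibatch updates.
#' @param seed integer seed governing batch sampling.
#' @param head recorded fusion head name (informational).
#' @param standardize apply per-region z-scoring to every subject before
#'   training/prediction.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, per_class_per_batch = 16L,
                         learning_rate = 0.01, l2_coefficient = 1e-4,
                         max_steps = 200L, seed = 1L,
                         head = "attention", standardize = TRUE) {
  batch_size <- as.integer(batch_size)
  per_class_per_batch <- as.integer(per_class_per_batch)
  if (per_class_per_batch * 2L != batch_size) {
    stop("batch_size must equal 2 * per_class_per_batch")
  }
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (l2_coefficient < 0) stop("l2_coefficient must be nonnegative")
  structure(list(batch_size = batch_size,
                 per_class_per_batch = per_class_per_batch,
                 learning_rate = learning_rate,
                 l2_coefficient = l2_coefficient,
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed), head = head,
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Class-balanced minibatch sampler
#'
#' Returns an iterator function; each call yields the subject indices of
#' one batch containing exactly `per_class_per_batch` members of each
#' class, sampled uniformly with replacement within class. Sampling with
#' replacement lets a 20-subject minority class fill its half of every
#' batch. The stream is reproducible from the seed.
#'
#' @param cohort a `cohort`, or an integer 0/1 label vector.
#' @param config a [train_config()].
#' @param seed integer seed of the sampling stream.
#' @return function() returning an integer vector of subject indices
#'   (cases first).
#' @export
balanced_batches <- function(cohort, config = train_config(), seed = 1L) {
  labels <- if (inherits(cohort, "cohort")) cohort_labels(cohort)
            else as.integer(cohort)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("balanced batching needs both classes present in the training pool")
  }
  m <- config$per_class_per_batch
  # Keep a private RNG stream so the sampler neither disturbs nor is
  # disturbed by other random draws.
  rng <- new.env()
  set.seed(as.integer(seed))
  rng$state <- get(".Random.seed", envir = .GlobalEnv)
  function() {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    assign(".Random.seed", rng$state, envir = .GlobalEnv)
    idx <- c(pos[sample.int(length(pos), m, replace = TRUE)],
             neg[sample.int(length(neg), m, replace = TRUE)])
    rng$state <- get(".Random.seed", envir = .GlobalEnv)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    idx
  }
}

# One Adam update over parallel nested lists; returns updated p/m/v.
adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  if (is.list(p)) {
    if (length(p) == 0L) return(list(p = p, m = m, v = v))
    for (nm in names(p)) {
      res <- adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  if (is.null(dim(p))) numeric(length(p)) # keep plain vectors dimension-free
  else array(0, dim = dim(p))
}

#' Train a model on a cohort
#'
#' Minimizes mean cross-entropy plus `l2_coefficient` times the squared
#' norm of the multiplicative weights over class-balanced minibatches,
#' using Adam. Fully reproducible from the seeds; `max_steps = 0`
#' returns the model unchanged. Aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model an `sccnn_model` from [build_model()].
#' @param cohort a `cohort` containing both classes (the training pool).
#' @param config a [train_config()].
#' @return the trained model, with `history` (step, loss, batch
#'   accuracy) appended.
#' @export
train <- function(model, cohort, config = train_config()) {
  stopifnot(inherits(model, "sccnn_model"), inherits(cohort, "cohort"))
  labels_all <- cohort_labels(cohort)
  if (config$max_steps < 1L) return(model)
  sampler <- balanced_batches(labels_all, config,
                              seed = derive_seed(config$seed, 101L))
  mats <- lapply(cohort$subjects, function(s) {
    if (config$standardize) standardize(s)$values else s$values
  })
  if (is.null(model$opt_state)) {
    model$opt_state <- list(m = zeros_like(model$params),
                            v = zeros_like(model$params))
  }
  hist_step <- integer(config$max_steps)
  hist_loss <- numeric(config$max_steps)
  hist_acc <- numeric(config$max_steps)
  l2 <- config$l2_coefficient
  for (k in seq_len(config$max_steps)) {
    idx <- sampler()
    y <- labels_all[idx]
    fw <- model_forward(model, mats[idx])
    data_loss <- cross_entropy(fw$probs, y)
    loss <- data_loss + l2 * param_sq_norm(model$params)
    if (!is.finite(loss)) {
      stop(sprintf("non-finite loss at step %d (data term %.4g); try a smaller learning rate",
                   model$step + k, data_loss))
    }
    grads <- model_backward(model, fw, y)
    if (l2 > 0) {
      grads <- param_map2(grads, model$params, function(g, p, nm) {
        if (is_weight_name(nm)) g + 2 * l2 * p else g
      })
    }
    model$step <- model$step + 1L
    upd <- adam_update(model$params, grads, model$opt_state$m,
                       model$opt_state$v, config$learning_rate, model$step)
    model$params <- upd$p
    model$opt_state$m <- upd$m
    model$opt_state$v <- upd$v
    hist_step[k] <- model$step
    hist_loss[k] <- loss
    hist_acc[k] <- mean((fw$probs[, 2] > 0.5) == (y == 1L))
  }
  new_hist <- data.frame(step = hist_step, loss = hist_loss,
                         batch_accuracy = hist_acc)
  model$history <- rbind(model$history, new_hist)
  model
}
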