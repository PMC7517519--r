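test_that("balanced batches are always 16/16 even from a 20/200 pool", {
  labels <- c(rep(1L, 20), rep(0L, 200))
  sampler <- balanced_batches(labels, train_config(), seed = 3)
  for (i in 1:200) {
    idx <- sampler()
    expect_length(idx, 32)
    expect_equal(sum(labels[idx] == 1L), 16L)
    expect_equal(sum(labels[idx] == 0L), 16L)
  }
  expect_error(balanced_batches(rep(0L, 10), train_config()), "both classes")
})

test_that("within-class inclusion is uniform across batches", {
  labels <- c(rep(1L, 20), rep(0L, 200))
  sampler <- balanced_batches(labels, train_config(), seed = 17)
  counts <- integer(220)
  n_batches <- 2000
  for (i in seq_len(n_batches)) {
    idx <- sampler()
    tab <- tabulate(idx, 220)
    counts <- counts + tab
  }
  # chi-square uniformity within each class
  p_pos <- chisq.test(counts[1:20])$p.value
  p_neg <- chisq.test(counts[21:220])$p.value
  expect_gt(p_pos, 0.01)
  expect_gt(p_neg, 0.01)
})

test_that("the sampler stream is reproducible and seed-sensitive", {
  labels <- rep(c(0L, 1L), 25)
  s1 <- balanced_batches(labels, train_config(), seed = 5)
  s2 <- balanced_batches(labels, train_config(), seed = 5)
  expect_identical(replicate(10, s1()), replicate(10, s2()))
  s3 <- balanced_batches(labels, train_config(), seed = 6)
  expect_false(identical(replicate(10, s1()), replicate(10, s3())))
})

test_that("built models emit proper softmax probabilities and honor seeds", {
  cfg <- tiny_encoder()
  m1 <- build_model(cfg, head = "attention", n_regions = 8, seed = 4, d_a = 3)
  m2 <- build_model(cfg, head = "attention", n_regions = 8, seed = 4, d_a = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, head = "attention", n_regions = 8, seed = 5, d_a = 3)
  expect_false(identical(m1$params, m3$params))
  expect_error(build_model(cfg, head = "transformer", n_regions = 8),
               "unknown head")

  coh <- tiny_cohort()
  p <- sccnn:::model_forward(m1, lapply(coh$subjects[1:3],
                                        function(s) standardize(s)$values))
  expect_equal(rowSums(p$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p$probs > 0 & p$probs < 1))
})

test_that("head=none and head=dense models differ only by the head parameters", {
  cfg <- tiny_encoder()
  m_none <- build_model(cfg, head = "none", n_regions = 8, seed = 4)
  m_dense <- build_model(cfg, head = "dense", n_regions = 8, seed = 4,
                         dense_width = 10)
  n_none <- sum(unlist(rapply(m_none$params, length, how = "unlist")))
  n_dense <- sum(unlist(rapply(m_dense$params, length, how = "unlist")))
  d <- m_none$d
  head_params <- 10 * (8 * d) + 10          # dense W + b
  cls_diff <- (8 * d) * 2 - 10 * 2          # classifier input width change
  expect_equal(n_dense - n_none, head_params - cls_diff)
})

test_that("training reduces loss on a separable toy cohort and reaches high accuracy", {
  coh <- tiny_cohort(n_regions = 8, effect_size = 2.5, seed = 21,
                     n_per_class = 10)
  cfg <- tiny_encoder()
  tc <- train_config(max_steps = 300L, seed = 2, head = "attention")
  model <- build_model(cfg, head = "attention", n_regions = 8, seed = 2,
                       d_a = 3)
  model <- train(model, coh, tc)
  expect_lt(mean(tail(model$history$loss, 20)),
            mean(head(model$history$loss, 20)))
  scores <- predict_proba(model, coh)
  acc <- accuracy(phenotype(coh)$label, as.integer(scores > 0.5))
  expect_gt(acc, 0.9)
})

test_that("zero steps leave the model untouched and seeds give identical traces", {
  coh <- tiny_cohort()
  cfg <- tiny_encoder()
  model <- build_model(cfg, head = "dense", n_regions = 8, seed = 9,
                       dense_width = 6)
  same <- train(model, coh, train_config(max_steps = 0L, seed = 1))
  expect_identical(same$params, model$params)

  tc <- train_config(max_steps = 25L, seed = 31, head = "dense")
  t1 <- train(model, coh, tc)
  t2 <- train(model, coh, tc)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
})

test_that("strong L2 shrinks weight norms relative to no regularization", {
  coh <- tiny_cohort()
  cfg <- tiny_encoder()
  model <- build_model(cfg, head = "none", n_regions = 8, seed = 3)
  free <- train(model, coh, train_config(max_steps = 60L, seed = 4,
                                         l2_coefficient = 0))
  shrunk <- train(model, coh, train_config(max_steps = 60L, seed = 4,
                                           l2_coefficient = 10))
  norm_w <- function(m) sccnn:::param_sq_norm(m$params)
  expect_lt(norm_w(shrunk), norm_w(free))
})

test_that("end-to-end gradients are exact for every head", {
  set.seed(40)
  cfg <- encoder_config(n_layers = 2, filters = c(2L, 3L), kernel_size = 3,
                        pooling = "max2")
  mats <- list(matrix(rnorm(3 * 12), 3, 12), matrix(rnorm(3 * 15), 3, 15))
  labels <- c(1L, 0L)
  for (head in c("none", "attention", "dense", "lstm")) {
    model <- build_model(cfg, head = head, n_regions = 3, seed = 11,
                         d_a = 2, dense_width = 4, lstm_hidden = 3)
    fw <- sccnn:::model_forward(model, mats)
    grads <- sccnn:::model_backward(model, fw, labels)
    lossfn <- function(params) {
      m2 <- model; m2$params <- params
      sccnn:::cross_entropy(sccnn:::model_forward(m2, mats)$probs, labels)
    }
    if (head == "none") grads$head <- NULL
    params <- model$params
    if (head == "none") params$head <- NULL
    expect_lt(max_rel_grad_err(lossfn, params, grads), 1e-4)
  }
})

test_that("mixed-length batches reproduce single-subject encoding", {
  coh <- tiny_cohort(n_regions = 6)
  cfg <- tiny_encoder()
  params <- encoder_init(cfg, seed = 14)
  mats <- lapply(coh$subjects[1:8], function(s) standardize(s)$values)
  batch <- sccnn:::encode_subjects(mats, cfg, params)
  for (i in seq_along(mats)) {
    solo <- encode(mats[[i]], cfg, params)
    expect_lt(max(abs(batch$features[[i]] - solo)), 1e-6)
  }
})

test_that("balanced batching keeps the predicted positive rate near 1/2 on imbalanced null data", {
  # 90/10 imbalance, zero effect: without balancing the prior would
  # collapse to the majority class; balanced batches must prevent that
  sites <- list(site_spec("A", 20, 180, 40L), site_spec("B", 20, 180, 40L))
  sig <- signal_spec(n_regions = 6, effect_size = 0)
  coh <- generate_cohort(sites, sig, seed = 77)
  cfg <- encoder_config(n_layers = 1, filters = 3L, kernel_size = 5,
                        pooling = "none")
  model <- build_model(cfg, head = "none", n_regions = 6, seed = 1)
  model <- train(model, coh, train_config(max_steps = 60L, seed = 1))
  bal_sites <- list(site_spec("C", 50, 50, 40L))
  test_coh <- generate_cohort(bal_sites, sig, seed = 78)
  rate <- mean(predict_proba(model, test_coh) > 0.5)
  expect_gte(rate, 0.3)
  expect_lte(rate, 0.7)
})

test_that("training aborts with a diagnostic once the loss is non-finite", {
  coh <- tiny_cohort()
  cfg <- tiny_encoder()
  model <- build_model(cfg, head = "none", n_regions = 8, seed = 3)
  model$params$cls$W[1] <- NaN # e.g. a corrupted checkpoint resume
  expect_error(train(model, coh, train_config(max_steps = 5L, seed = 1)),
               "non-finite")
})
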