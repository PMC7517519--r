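test_that("the five-site default layout matches the targeted cohort structure", {
  sites <- default_adhd200_sites()
  expect_length(sites, 5)
  counts <- data.frame(
    site = vapply(sites, `[[`, character(1), "site_id"),
    adhd = vapply(sites, `[[`, integer(1), "n_adhd"),
    hc = vapply(sites, `[[`, integer(1), "n_hc"))
  expect_equal(counts$adhd[match(c("KKI", "NI", "NYU", "OHSU", "Peking"),
                                 counts$site)],
               c(35L, 36L, 151L, 43L, 102L))
  expect_equal(counts$hc[match(c("KKI", "NI", "NYU", "OHSU", "Peking"),
                               counts$site)],
               c(69L, 37L, 111L, 70L, 143L))
  # NYU is the largest and most case-heavy site: 151 + 111 = 262 subjects
  expect_equal(counts$adhd[counts$site == "NYU"] +
                 counts$hc[counts$site == "NYU"], 262L)
  ohsu <- sites[[which(counts$site == "OHSU")]]
  expect_setequal(ohsu$lengths, c(78L, 50L, 73L))
})

test_that("generated cohorts honor site counts, lengths and the seed contract", {
  sites <- list(site_spec("A", 3, 4, c(40L, 52L)),
                site_spec("B", 2, 2, 64L, scale = 2, baseline_shift = 5))
  sig <- signal_spec(n_regions = 6, informative_regions = 1:2,
                     effect_size = 1)
  coh <- generate_cohort(sites, sig, seed = 99)
  ph <- phenotype(coh)
  expect_equal(nrow(ph), 11L)
  expect_equal(as.vector(table(ph$site_id)), c(7L, 4L))
  expect_equal(sum(ph$label), 5L)
  expect_true(all(ph$n_timepoints[ph$site_id == "A"] %in% c(40L, 52L)))
  expect_true(all(ph$n_timepoints[ph$site_id == "B"] == 64L))

  coh2 <- generate_cohort(sites, sig, seed = 99)
  expect_identical(coh$subjects[[5]]$values, coh2$subjects[[5]]$values)
  coh3 <- generate_cohort(sites, sig, seed = 100)
  expect_false(identical(coh$subjects[[5]]$values, coh3$subjects[[5]]$values))
})

test_that("adding a site leaves existing subjects untouched", {
  sites <- list(site_spec("A", 2, 2, 40L))
  sig <- signal_spec(n_regions = 4, effect_size = 1)
  coh_small <- generate_cohort(sites, sig, seed = 7)
  coh_big <- generate_cohort(c(sites, list(site_spec("B", 2, 2, 48L))),
                             sig, seed = 7)
  for (i in seq_len(4)) {
    expect_identical(coh_small$subjects[[i]]$values,
                     coh_big$subjects[[i]]$values)
  }
})

test_that("a zero effect size yields distributionally identical classes", {
  # informative-region sample variance is the statistic the planted signal
  # shifts; under the null its two-class t-test p-values should be roughly
  # uniform -> rejections at 10% should stay near nominal across replicates
  sites <- list(site_spec("A", 8, 8, 60L))
  reject <- 0
  n_rep <- 40
  for (rep in seq_len(n_rep)) {
    sig <- signal_spec(n_regions = 4, informative_regions = 1:2,
                       effect_size = 0)
    coh <- generate_cohort(sites, sig, seed = 1000 + rep)
    v <- vapply(coh$subjects, function(s) var(s$values[1, ]), numeric(1))
    lab <- phenotype(coh)$label
    p <- t.test(v[lab == 1], v[lab == 0])$p.value
    reject <- reject + (p < 0.1)
  }
  # Binomial(40, 0.1): P(X > 10) < 0.001
  expect_lte(reject, 10)
})

test_that("a planted coupling signal shifts informative-region variance in cases", {
  sites <- list(site_spec("A", 20, 20, 80L))
  sig <- signal_spec(n_regions = 6, informative_regions = 1:2,
                     effect_size = 2, mechanism = "coupling")
  coh <- generate_cohort(sites, sig, seed = 5)
  lab <- phenotype(coh)$label
  v_inf <- vapply(coh$subjects, function(s) var(s$values[1, ]), numeric(1))
  v_non <- vapply(coh$subjects, function(s) var(s$values[6, ]), numeric(1))
  expect_lt(t.test(v_inf[lab == 1], v_inf[lab == 0])$p.value, 1e-4)
  expect_gt(t.test(v_non[lab == 1], v_non[lab == 0])$p.value, 0.01)
})

test_that("all three mechanisms degenerate to the null at effect size zero", {
  sites <- list(site_spec("A", 2, 2, 40L))
  for (mech in c("amplitude", "frequency", "coupling")) {
    sig <- signal_spec(n_regions = 3, informative_regions = 1L,
                       effect_size = 0, mechanism = mech)
    coh <- generate_cohort(sites, sig, seed = 3)
    # same seed, zero effect: case and control series generators coincide,
    # so the same per-subject stream gives label-independent values
    sig_amp <- signal_spec(n_regions = 3, informative_regions = 1L,
                           effect_size = 0, mechanism = "amplitude")
    coh2 <- generate_cohort(sites, sig_amp, seed = 3)
    if (mech != "frequency") {
      expect_identical(coh$subjects[[1]]$values, coh2$subjects[[1]]$values)
    }
  }
})

test_that("toy volumes reproduce their recorded truth exactly", {
  toy <- generate_toy_volume(3, shape = c(3, 2, 2), n_t = 5, seed = 21)
  ts <- extract_roi_timeseries(toy$volume, toy$atlas)
  expect_equal(ts$values, toy$truth, tolerance = 1e-14)

  toy2 <- generate_toy_volume(3, shape = c(3, 2, 2), n_t = 5, seed = 21)
  expect_identical(toy$volume, toy2$volume)

  expect_error(generate_toy_volume(117, shape = c(2, 2, 2)), "tile")
})
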