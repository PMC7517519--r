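#' Site specification for the synthetic cohort generator
#'
#' Describes one acquisition site: class counts, the pool of run lengths
#' its scanner produced (each subject draws one), and site-level signal
#' distortions (multiplicative gain, additive baseline) that emulate
#' scanner heterogeneity.
#'
#' @param site_id character site name.
#' @param n_adhd,n_hc nonnegative subject counts (at least one subject in
#'   total).
#' @param lengths nonempty integer vector of admissible series lengths
#'   (each >= 8).
#' @param scale positive site gain applied to every value.
#' @param baseline_shift additive site offset.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_id, n_adhd, n_hc, lengths,
                      scale = 1, baseline_shift = 0) {
  n_adhd <- as.integer(n_adhd); n_hc <- as.integer(n_hc)
  if (n_adhd < 0L || n_hc < 0L || n_adhd + n_hc < 1L) {
    stop("site must have nonnegative counts and at least one subject")
  }
  lengths <- as.integer(lengths)
  if (length(lengths) < 1L || any(lengths < 8L)) {
    stop("lengths must be a nonempty vector of integers >= 8")
  }
  if (scale <= 0) stop("scale must be positive")
  structure(list(site_id = as.character(site_id), n_adhd = n_adhd,
                 n_hc = n_hc, lengths = lengths, scale = scale,
                 baseline_shift = baseline_shift),
            class = "site_spec")
}

#' Class-signal specification for the synthetic cohort generator
#'
#' Defines the planted, recoverable difference between cases and
#' controls. Every region's background is a stationary AR(1) series;
#' the class signal is confined to `informative_regions` and realized by
#' one of three mechanisms:
#'
#' * `amplitude`: cases receive an added sinusoid of amplitude
#'   `effect_size` at `base_frequency` (controls receive nothing);
#' * `frequency`: both classes oscillate with unit amplitude, controls
#'   at `base_frequency` and cases at `base_frequency * (1 +
#'   effect_size)`;
#' * `coupling`: cases receive a slow latent sinusoid (random phase per
#'   subject, shared across the informative regions) with loading
#'   `effect_size`.
#'
#' In all three, `effect_size = 0` makes the two classes
#' distributionally identical. Because the pipeline z-scores each region,
#' a planted signal is recoverable only through the spectral shape it
#' induces, which all three mechanisms provide.
#'
#' @param n_regions number of regions per subject (default 116, the AAL
#'   atlas size).
#' @param informative_regions 1-based indices of signal-carrying regions;
#'   default: 12 indices evenly spread over the regions.
#' @param effect_size nonnegative signal strength (units of the noise
#'   standard deviation).
#' @param mechanism one of `"amplitude"`, `"frequency"`, `"coupling"`.
#' @param ar_coefficient AR(1) coefficient of the background, in (-1, 1).
#' @param noise_sd marginal standard deviation of the background.
#' @param base_frequency oscillation frequency in cycles per sample.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(n_regions = 116L, informative_regions = NULL,
                        effect_size = 1,
                        mechanism = c("coupling", "amplitude", "frequency"),
                        ar_coefficient = 0.3, noise_sd = 1,
                        base_frequency = 0.05) {
  mechanism <- match.arg(mechanism)
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be positive")
  if (is.null(informative_regions)) {
    informative_regions <-
      unique(round(seq(1, n_regions, length.out = min(12L, n_regions))))
  }
  informative_regions <- as.integer(informative_regions)
  if (any(informative_regions < 1L | informative_regions > n_regions)) {
    stop("informative_regions out of range 1..n_regions")
  }
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (abs(ar_coefficient) >= 1) stop("ar_coefficient must lie in (-1, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_regions = n_regions,
                 informative_regions = informative_regions,
                 effect_size = effect_size, mechanism = mechanism,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 base_frequency = base_frequency),
            class = "signal_spec")
}

#' The five-site multi-site cohort layout
#'
#' Site specifications reproducing the structure of the public five-site
#' ADHD release the method targets: per-site case/control counts
#' (35/69, 36/37, 151/111, 43/70, 102/143, i.e. 367 cases and 430
#' controls) and per-site run-length pools. Site gain and baseline
#' values are synthetic stand-ins for scanner heterogeneity.
#'
#' @return list of five [site_spec()] objects (KKI, NI, NYU, OHSU,
#'   Peking).
#' @export
default_adhd200_sites <- function() {
  list(
    site_spec("KKI", 35, 69, c(152L, 119L), scale = 1.00, baseline_shift = 0),
    site_spec("NI", 36, 37, 257L, scale = 1.25, baseline_shift = 20),
    site_spec("NYU", 151, 111, c(176L, 172L), scale = 0.80, baseline_shift = -10),
    site_spec("OHSU", 43, 70, c(78L, 50L, 73L), scale = 1.10, baseline_shift = 5),
    site_spec("Peking", 102, 143, c(236L, 231L), scale = 0.90, baseline_shift = 15)
  )
}

#' @rdname default_adhd200_sites
#' @param fraction scaling factor in (0, 1] applied to every class count
#'   (rounded, minimum 1), keeping the length pools and site effects; used
#'   for desk-scale experiments.
#' @export
scaled_adhd200_sites <- function(fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  lapply(default_adhd200_sites(), function(s) {
    s$n_adhd <- max(1L, as.integer(round(s$n_adhd * fraction)))
    s$n_hc <- max(1L, as.integer(round(s$n_hc * fraction)))
    s
  })
}

# Stationary AR(1) matrix (rows = regions) with marginal sd `sd`;
# a 50-sample burn-in removes the zero-initialization transient.
ar1_matrix <- function(n_regions, n_t, phi, sd) {
  burn <- 50L
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(stats::rnorm(n_regions * (n_t + burn), sd = innov_sd),
              nrow = n_t + burn, ncol = n_regions)
  x <- stats::filter(e, phi, method = "recursive")
  t(x[(burn + 1L):(n_t + burn), , drop = FALSE])
}

#' Generate a multi-site synthetic cohort
#'
#' Each subject's region-by-time matrix is
#' `baseline_shift + scale * (AR(1) background + class term)` with the
#' class term defined by the [signal_spec()] mechanism. One base seed
#' governs the whole cohort through a per-subject derived seed, so adding
#' a site or subject never perturbs the series of the others, and the
#' same seed reproduces the cohort exactly.
#'
#' @param sites list of [site_spec()] objects.
#' @param signal a [signal_spec()].
#' @param seed integer base seed.
#' @return A `cohort` whose `truth` attribute records the signal spec and
#'   seed used.
#' @export
generate_cohort <- function(sites, signal = signal_spec(), seed = 1L) {
  if (inherits(sites, "site_spec")) sites <- list(sites)
  stopifnot(length(sites) >= 1L, inherits(signal, "signal_spec"))
  subjects <- list()
  for (si in seq_along(sites)) {
    s <- sites[[si]]
    n <- s$n_adhd + s$n_hc
    labels <- c(rep(1L, s$n_adhd), rep(0L, s$n_hc))
    for (j in seq_len(n)) {
      sub_seed <- derive_seed(seed, si, j)
      set.seed(sub_seed)
      n_t <- s$lengths[sample.int(length(s$lengths), 1L)]
      bg <- ar1_matrix(signal$n_regions, n_t, signal$ar_coefficient,
                       signal$noise_sd)
      phase <- stats::runif(1, 0, 2 * pi)
      tt <- seq_len(n_t)
      term <- matrix(0, signal$n_regions, n_t)
      inf_idx <- signal$informative_regions
      lab <- labels[j]
      if (signal$mechanism == "amplitude") {
        if (lab == 1L && signal$effect_size > 0) {
          osc <- signal$effect_size *
            sin(2 * pi * signal$base_frequency * tt + phase)
          term[inf_idx, ] <- rep(osc, each = length(inf_idx))
        }
      } else if (signal$mechanism == "frequency") {
        freq <- signal$base_frequency * (1 + signal$effect_size * lab)
        osc <- sin(2 * pi * freq * tt + phase)
        term[inf_idx, ] <- rep(osc, each = length(inf_idx))
      } else { # coupling: shared slow latent, loaded on cases only
        if (lab == 1L && signal$effect_size > 0) {
          latent <- sin(2 * pi * (signal$base_frequency / 2) * tt + phase)
          term[inf_idx, ] <- rep(signal$effect_size * latent,
                                 each = length(inf_idx))
        }
      }
      values <- s$baseline_shift + s$scale * (bg + term)
      subjects[[length(subjects) + 1L]] <- roi_timeseries(
        values, subject_id = sprintf("%s_%03d", s$site_id, j),
        site_id = s$site_id, label = lab)
    }
  }
  out <- cohort(subjects)
  attr(out, "truth") <- list(signal = signal, seed = as.integer(seed))
  out
}

#' Toy 4D volume + atlas fixture with known region means
#'
#' Tiles the voxel grid into `regions` contiguous label blocks (leftover
#' voxels become background 0) and fills every voxel of region r at time
#' t with a recorded value `truth[r, t]`, so the expected region-mean
#' time series is known exactly.
#'
#' @param regions number of regions; must not exceed the voxel count.
#' @param shape integer length-3 spatial shape.
#' @param n_t number of time points.
#' @param seed integer seed for the recorded values.
#' @return list with `volume` (4D array), `atlas` (3D integer array) and
#'   `truth` (regions x n_t matrix).
#' @export
generate_toy_volume <- function(regions, shape = c(4L, 4L, 4L), n_t = 5L,
                                seed = 1L) {
  regions <- as.integer(regions); shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), n_t >= 1L, regions >= 1L)
  nvox <- prod(shape)
  if (nvox < regions) {
    stop(sprintf("cannot tile %d regions into a grid of %d voxels",
                 regions, nvox))
  }
  per_region <- nvox %/% regions
  labels <- c(rep(seq_len(regions), each = per_region),
              rep(0L, nvox - per_region * regions))
  set.seed(as.integer(seed))
  truth <- matrix(stats::rnorm(regions * n_t), nrow = regions, ncol = n_t)
  vox <- matrix(0, nrow = nvox, ncol = n_t)
  nonzero <- labels != 0L
  vox[nonzero, ] <- truth[labels[nonzero], , drop = FALSE]
  list(volume = array(vox, dim = c(shape, n_t)),
       atlas = array(labels, dim = shape),
       truth = truth)
}
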