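#' Per-subject region-by-time series matrix
#'
#' The basic data unit of the package: one subject's region-mean BOLD
#' series, a real matrix with one row per atlas region and one column per
#' time point. Series length `T` may differ between subjects (multi-site
#' acquisitions differ in run length); the region count `R` must match
#' across subjects that enter the same model.
#'
#' @param values numeric matrix, regions x time points; all values finite.
#' @param region_ids integer vector of region labels, one per row
#'   (default `seq_len(nrow(values))`).
#' @param subject_id,site_id character scalars identifying the subject and
#'   the acquisition site.
#' @param label diagnosis label: `1` (case, e.g. ADHD), `0` (control), or
#'   `NA` when unknown.
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(values, region_ids = NULL,
                           subject_id = "subject", site_id = "site",
                           label = NA_integer_) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("time-series matrix must have at least one region and one time point")
  }
  if (!all(is.finite(values))) {
    stop("time-series values must all be finite")
  }
  if (is.null(region_ids)) region_ids <- seq_len(nrow(values))
  region_ids <- as.integer(region_ids)
  if (length(region_ids) != nrow(values)) {
    stop("length of region_ids must equal the number of rows")
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("label must be 0, 1 or NA")
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, region_ids = region_ids,
         subject_id = as.character(subject_id),
         site_id = as.character(site_id),
         label = as.integer(label)),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s | site %s | label %s | %d regions x %d time points\n",
              x$subject_id, x$site_id,
              ifelse(is.na(x$label), "?", x$label),
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$values)

#' Per-region z-scoring of a time series
#'
#' Centers and scales every region's series to mean 0 and unit sample
#' standard deviation. A constant region (zero variance) maps to all
#' zeros rather than dividing by zero. Applied per subject, so it uses no
#' cross-subject statistics and cannot leak information between
#' cross-validation folds; it removes site-level gain and baseline
#' differences before the series enter the encoder.
#'
#' @param ts an `roi_ts` object or a plain regions x time matrix.
#' @return Same type as the input, standardized row-wise.
#' @export
standardize <- function(ts) {
  m <- if (inherits(ts, "roi_ts")) ts$values else as.matrix(ts)
  if (ncol(m) < 2L) {
    stop("standardize needs at least 2 time points per region")
  }
  mu <- rowMeans(m)
  centered <- m - mu
  sdv <- sqrt(rowSums(centered^2) / (ncol(m) - 1L))
  scale_fac <- ifelse(sdv > 0, 1 / sdv, 0)
  out <- centered * scale_fac
  if (inherits(ts, "roi_ts")) {
    ts$values <- out
    ts
  } else {
    out
  }
}

#' Assemble a cohort from per-subject series
#'
#' @param subjects list of [roi_timeseries()] objects with consistent
#'   region counts.
#' @return An object of class `cohort`.
#' @export
cohort <- function(subjects) {
  if (length(subjects) == 0L) stop("cohort needs at least one subject")
  ok <- vapply(subjects, inherits, logical(1), what = "roi_ts")
  if (!all(ok)) stop("all cohort members must be roi_ts objects")
  r <- vapply(subjects, function(s) nrow(s$values), integer(1))
  if (length(unique(r)) != 1L) {
    stop("all subjects must have the same number of regions")
  }
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  structure(list(subjects = subjects), class = "cohort")
}

#' @export
length.cohort <- function(x) length(x$subjects)

#' @export
print.cohort <- function(x, ...) {
  ph <- phenotype(x)
  cat(sprintf("<cohort> %d subjects | %d sites | %d regions\n",
              nrow(ph), length(unique(ph$site_id)),
              nrow(x$subjects[[1]]$values)))
  print(table(site = ph$site_id, label = ph$label))
  invisible(x)
}

#' Phenotype table of a cohort
#'
#' @param x a `cohort`.
#' @return data.frame with columns `subject_id`, `site_id`, `label`,
#'   `n_timepoints`.
#' @export
phenotype <- function(x) {
  stopifnot(inherits(x, "cohort"))
  data.frame(
    subject_id = vapply(x$subjects, function(s) s$subject_id, character(1)),
    site_id = vapply(x$subjects, function(s) s$site_id, character(1)),
    label = vapply(x$subjects, function(s) s$label, integer(1)),
    n_timepoints = vapply(x$subjects, function(s) ncol(s$values), integer(1)),
    stringsAsFactors = FALSE
  )
}

subset_cohort <- function(x, idx) {
  x$subjects <- x$subjects[idx]
  x
}

cohort_labels <- function(x) {
  vapply(x$subjects, function(s) s$label, integer(1))
}

#' Apply per-region z-scoring to every subject of a cohort
#' @param x a `cohort`.
#' @return the standardized `cohort`.
#' @export
standardize_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  x$subjects <- lapply(x$subjects, standardize)
  x
}
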