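#' Extract region-mean time series from a 4D volume and an integer atlas
#'
#' For every atlas region, averages the BOLD value over all voxels
#' carrying that region's label, at every time point, producing one
#' series per region (the AAL-116 use case yields 116 series). Voxels
#' labelled 0 are background and always excluded. The volume and atlas
#' must already share a voxel grid; no resampling or registration is
#' attempted.
#'
#' @param volume 4D numeric array (x, y, z, t), an `RNifti` image, or a
#'   path to a NIfTI file (`.nii` / `.nii.gz`).
#' @param atlas 3D integer array, `RNifti` image, or NIfTI path; spatial
#'   shape must match `volume`.
#' @param region_ids optional integer vector fixing the row order of the
#'   output; defaults to the sorted distinct nonzero atlas labels. Every
#'   requested id must label at least one voxel (an empty region has no
#'   defined mean).
#' @inheritParams roi_timeseries
#' @return An [roi_timeseries()] object, regions x time.
#' @export
extract_roi_timeseries <- function(volume, atlas, region_ids = NULL,
                                   subject_id = "subject", site_id = "site",
                                   label = NA_integer_) {
  if (is.character(volume)) volume <- RNifti::readNifti(volume)
  if (is.character(atlas)) atlas <- RNifti::readNifti(atlas)
  volume <- unclass(volume)
  atlas <- unclass(atlas)
  dv <- dim(volume)
  da <- dim(atlas)
  if (length(dv) != 4L) stop("volume must be 4D (x, y, z, t)")
  if (length(da) != 3L) stop("atlas must be 3D (x, y, z)")
  if (!identical(dv[1:3], da)) {
    stop(sprintf("spatial shape mismatch: volume %s vs atlas %s",
                 paste(dv[1:3], collapse = "x"), paste(da, collapse = "x")))
  }
  if (!all(is.finite(volume))) stop("volume contains non-finite values")
  n_t <- dv[4]
  labels <- as.integer(round(atlas))
  present <- sort(unique(labels[labels != 0L]))
  if (length(present) == 0L) stop("atlas has no nonzero labels")
  if (is.null(region_ids)) {
    region_ids <- present
  } else {
    region_ids <- as.integer(region_ids)
    missing_ids <- setdiff(region_ids, present)
    if (length(missing_ids) > 0L) {
      stop(sprintf("region id(s) %s have no voxels in the atlas; mean undefined",
                   paste(missing_ids, collapse = ", ")))
    }
  }
  vox <- matrix(volume, nrow = prod(dv[1:3]), ncol = n_t)
  keep <- labels %in% region_ids
  sums <- rowsum(vox[keep, , drop = FALSE], group = labels[keep])
  counts <- table(labels[keep])
  ord <- match(as.character(region_ids), rownames(sums))
  means <- sums[ord, , drop = FALSE] / as.numeric(counts[as.character(region_ids)])
  roi_timeseries(means, region_ids = region_ids, subject_id = subject_id,
                 site_id = site_id, label = label)
}

#' Write / read a region-by-time series as tab-delimited text
#'
#' The format is a single header line of tab-separated region ids (in row
#' order), followed by one tab-separated row of values per region.
#'
#' @param ts an `roi_ts`.
#' @param path output file path.
#' @return `write_roi_ts` returns `path` invisibly; `read_roi_ts`
#'   returns an `roi_ts`.
#' @export
write_roi_ts <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(ts$region_ids, collapse = "\t"), con)
  utils::write.table(format(ts$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_ts
#' @inheritParams roi_timeseries
#' @export
read_roi_ts <- function(path, subject_id = "subject", site_id = "site",
                        label = NA_integer_) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed time-series file: ", path)
  ids <- as.integer(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  vals <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  if (nrow(vals) != length(ids)) {
    stop("header region count does not match matrix rows in ", path)
  }
  roi_timeseries(vals, region_ids = ids, subject_id = subject_id,
                 site_id = site_id, label = label)
}

#' Write / read a cohort as a directory of text files
#'
#' One tab-delimited series file per subject (named `<subject_id>.tsv`)
#' plus a `phenotype.tsv` table with columns `subject_id`, `site_id`,
#' `label`. The same readers serve synthetic and real (extracted) data.
#'
#' @param x a `cohort`.
#' @param dir directory to create/fill.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns
#'   a `cohort`.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- phenotype(x)[, c("subject_id", "site_id", "label")]
  utils::write.table(ph, file.path(dir, "phenotype.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (s in x$subjects) {
    write_roi_ts(s, file.path(dir, paste0(s$subject_id, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ph_path <- file.path(dir, "phenotype.tsv")
  if (!file.exists(ph_path)) stop("phenotype table not found: ", ph_path)
  ph <- utils::read.table(ph_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(ph)), function(i) {
    read_roi_ts(file.path(dir, paste0(ph$subject_id[i], ".tsv")),
                subject_id = ph$subject_id[i], site_id = ph$site_id[i],
                label = ph$label[i])
  })
  cohort(subjects)
}
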