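#' Normalize a spectrum to unit total intensity
#'
#' Divides a vector of non-negative spectral intensities by its sum, so that
#' every spectrum carries the same total signal. Total-intensity
#' normalization removes inter-sample dilution and acquisition-gain
#' differences before binning.
#'
#' @param intensity Numeric vector of non-negative intensities with at least
#'   one strictly positive entry.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' normalize_to_total(c(1, 3))
#' @export
normalize_to_total <- function(intensity) {
  if (!is.numeric(intensity) || length(intensity) == 0) {
    abort("`intensity` must be a non-empty numeric vector")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    abort("invalid spectrum: intensities must be finite and non-negative")
  }
  total <- sum(intensity)
  if (total <= 0) {
    abort("invalid spectrum: all intensities are zero")
  }
  intensity / total
}

#' Define a spectral binning scheme
#'
#' Fixed-width coarse-graining of the chemical-shift axis. The default
#' covers 0 to 9.6 ppm in 0.32-ppm bins (30 bins), the resolution at which
#' a ~30-parameter linear coordinate remains identifiable from a cohort of
#' a few hundred spectra. Finer binning (e.g. 0.1 ppm) is supported but
#' inflates the parameter count and is expected to over-fit small cohorts;
#' [loocv()] flags this.
#'
#' @param ppm_min,ppm_max Chemical-shift window in ppm.
#' @param bin_width Bin width in ppm.
#' @param floor_epsilon Intensity floor applied to bin means before the log
#'   transform, on the normalized (unit total) scale. Keeps near-empty
#'   baseline regions finite.
#' @return An object of class `binning_scheme`.
#' @examples
#' binning_scheme()          # 30 bins of 0.32 ppm
#' binning_scheme(bin_width = 0.1)
#' @export
binning_scheme <- function(ppm_min = 0, ppm_max = 9.6, bin_width = 0.32,
                           floor_epsilon = 1e-12) {
  stopifnot(is.numeric(ppm_min), is.numeric(ppm_max), is.numeric(bin_width),
            is.numeric(floor_epsilon))
  if (ppm_max <= ppm_min) abort("`ppm_max` must exceed `ppm_min`")
  if (bin_width <= 0) abort("`bin_width` must be positive")
  if (floor_epsilon <= 0) abort("`floor_epsilon` must be positive")
  n_bins <- as.integer(ceiling((ppm_max - ppm_min) / bin_width - 1e-9))
  if (n_bins < 2) abort("scheme must contain at least 2 bins")
  edges <- ppm_min + bin_width * seq(0, n_bins)
  edges[n_bins + 1] <- max(edges[n_bins + 1], ppm_max)
  structure(
    list(ppm_min = ppm_min, ppm_max = ppm_max, bin_width = bin_width,
         floor_epsilon = floor_epsilon, n_bins = n_bins, edges = edges),
    class = "binning_scheme"
  )
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %g-%g ppm, width %g ppm, %d bins\n",
              x$ppm_min, x$ppm_max, x$bin_width, x$n_bins))
  invisible(x)
}

#' Bin a single spectrum and log-transform the bin means
#'
#' Averages normalized intensity within each chemical-shift bin
#' (half-open `[lo, hi)` bins, last bin closed) and returns the natural log
#' of the bin means, floored at the scheme's `floor_epsilon`. These log bin
#' intensities are the basis functions of the linear reaction coordinate.
#'
#' @param ppm Strictly monotone numeric vector of chemical shifts (ppm).
#' @param intensity Normalized intensities on the same grid.
#' @param scheme A [binning_scheme()].
#' @return Numeric vector of length `scheme$n_bins`.
#' @export
bin_spectrum <- function(ppm, intensity, scheme = binning_scheme()) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (length(ppm) != length(intensity)) {
    abort("`ppm` and `intensity` must have the same length")
  }
  dppm <- diff(ppm)
  if (length(ppm) < 2 || !(all(dppm > 0) || all(dppm < 0))) {
    abort("`ppm` must be strictly monotone")
  }
  idx <- findInterval(ppm, scheme$edges, rightmost.closed = TRUE)
  in_range <- idx >= 1L & idx <= scheme$n_bins
  if (!any(in_range)) {
    abort("spectrum ppm range does not overlap the binning scheme window")
  }
  means <- vapply(seq_len(scheme$n_bins), function(k) {
    sel <- in_range & idx == k
    if (!any(sel)) return(NA_real_)
    mean(intensity[sel])
  }, numeric(1))
  if (anyNA(means)) {
    abort(sprintf(
      "binning-resolution error: %d bin(s) contain no data points",
      sum(is.na(means))))
  }
  log(pmax(means, scheme$floor_epsilon))
}

#' Build per-patient feature trajectories from long-format spectra
#'
#' Normalizes each spectrum to unit total intensity, bins it, log-transforms
#' the bin means, and assembles one row per (patient, day) sorted by day
#' within patient, with clinical class labels attached. The resulting wide
#' table is the multivariate trajectory ensemble that coordinate
#' optimization consumes.
#'
#' Patients with fewer than two time points cannot contribute dynamical
#' steps and are dropped with a warning. Duplicate (patient, day) spectra
#' are an error.
#'
#' @param spectra Tibble with columns `patient_id`, `day`, `ppm`,
#'   `intensity` (one row per spectral point; `day` is relative to the
#'   intervention, pre-op days are non-positive).
#' @param metadata Tibble with columns `patient_id`, `clinical_class`
#'   (one of `"PF"`, `"DGF"`, `"AR"`), optionally `dialysis_day`.
#' @param scheme A [binning_scheme()].
#' @return A tibble with columns `patient_id`, `day`, `clinical_class`, and
#'   feature columns `bin_01` ... `bin_K`; attributes `features` (feature
#'   column names) and `bin_edges` (K+1 ppm values).
#' @export
build_trajectories <- function(spectra, metadata, scheme = binning_scheme()) {
  stopifnot(is.data.frame(spectra), is.data.frame(metadata))
  need <- c("patient_id", "day", "ppm", "intensity")
  if (!all(need %in% names(spectra))) {
    abort(paste("`spectra` must have columns", paste(need, collapse = ", ")))
  }
  if (!all(c("patient_id", "clinical_class") %in% names(metadata))) {
    abort("`metadata` must have columns patient_id, clinical_class")
  }
  unknown <- setdiff(unique(spectra$patient_id), metadata$patient_id)
  if (length(unknown) > 0) {
    abort(paste("metadata error: patients without metadata:",
                paste(unknown, collapse = ", ")))
  }

  feats <- sprintf("bin_%02d", seq_len(scheme$n_bins))
  binned <- spectra |>
    dplyr::group_by(.data$patient_id, .data$day) |>
    dplyr::group_modify(function(d, key) {
      if (anyDuplicated(d$ppm) > 0) {
        abort(sprintf("duplicate spectrum rows for patient %s day %s",
                      key$patient_id, key$day))
      }
      v <- bin_spectrum(d$ppm, normalize_to_total(d$intensity), scheme)
      tibble::as_tibble(as.list(setNames(v, feats)))
    }) |>
    dplyr::ungroup()

  out <- binned |>
    dplyr::left_join(
      dplyr::select(metadata, "patient_id", "clinical_class"),
      by = "patient_id") |>
    dplyr::relocate("patient_id", "day", "clinical_class") |>
    dplyr::arrange(.data$patient_id, .data$day)

  n_pts <- dplyr::count(out, .data$patient_id)
  short <- n_pts$patient_id[n_pts$n < 2]
  if (length(short) > 0) {
    warn(paste("dropping patients with < 2 time points:",
               paste(short, collapse = ", ")))
    out <- dplyr::filter(out, !.data$patient_id %in% short)
  }
  if (dplyr::n_distinct(out$patient_id) < 2) {
    abort("need at least 2 patients with >= 2 time points")
  }
  attr(out, "features") <- feats
  attr(out, "bin_edges") <- scheme$edges
  out
}

#' Read long-format spectra or cohort metadata from delimited files
#'
#' Thin wrappers over [utils::read.csv()]/[utils::read.delim()] returning
#' tibbles in the column layout [build_trajectories()] expects.
#'
#' @param path Path to a CSV (or TSV, by extension) file.
#' @return A tibble.
#' @export
read_spectra <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- tibble::as_tibble(utils::read.delim(path, sep = sep))
  need <- c("patient_id", "day", "ppm", "intensity")
  if (!all(need %in% names(d))) {
    abort(paste("spectra file must have columns",
                paste(need, collapse = ", ")))
  }
  d$patient_id <- as.character(d$patient_id)
  d
}

#' @rdname read_spectra
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- tibble::as_tibble(utils::read.delim(path, sep = sep))
  if (!all(c("patient_id", "clinical_class") %in% names(d))) {
    abort("metadata file must have columns patient_id, clinical_class")
  }
  d$patient_id <- as.character(d$patient_id)
  d$clinical_class <- as.character(d$clinical_class)
  bad <- setdiff(unique(d$clinical_class), c("PF", "DGF", "AR"))
  if (length(bad) > 0) {
    abort(paste("unknown clinical_class value(s):", paste(bad, collapse = ", ")))
  }
  d
}
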