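# Shared fixture builders: small chains, spectra and ensembles, all
# generated in code under fixed seeds.

# Nearest-neighbor birth-death chain on n states with upward probability p
# (ergodic: boundaries reflect with the leftover probability mass).
nn_chain <- function(n = 5, p = 0.5) {
  P <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    P[i, i + 1] <- p
    P[i, i - 1] <- 1 - p
  }
  P[1, 2] <- p
  P[1, 1] <- 1 - p
  P[n, n - 1] <- 1 - p
  P[n, n] <- p
  P
}

# Same chain with absorbing boundaries, for the committor oracle.
nn_chain_absorbing <- function(n = 5, p = 0.5) {
  P <- nn_chain(n, p)
  P[1, ] <- 0
  P[1, 1] <- 1
  P[n, ] <- 0
  P[n, n] <- 1
  P
}

# Four-state chain with fast within-pair mixing and a slow middle link.
barrier_chain <- function(fast = 0.3, slow = 0.02) {
  P <- matrix(0, 4, 4)
  P[1, 2] <- fast
  P[2, 1] <- fast
  P[2, 3] <- slow
  P[3, 2] <- slow
  P[3, 4] <- fast
  P[4, 3] <- fast
  diag(P) <- 1 - rowSums(P)
  P
}

# Tiny two-patient long-format spectra table on a uniform ppm grid, with
# intensities constant within each 0.32-ppm bin.
toy_spectra <- function(values_by_day, ppm_max = 0.96, points_per_bin = 3) {
  n_bins <- round(ppm_max / 0.32)
  ppm <- seq(0.32 / (2 * points_per_bin), ppm_max,
             by = 0.32 / points_per_bin)
  purrr::imap_dfr(values_by_day, function(days, pid) {
    purrr::imap_dfr(days, function(vals, d) {
      stopifnot(length(vals) == n_bins)
      tibble::tibble(patient_id = pid, day = as.integer(d),
                     ppm = ppm,
                     intensity = rep(vals, each = points_per_bin))
    })
  })
}

toy_metadata <- function(ids, classes = "PF") {
  tibble::tibble(patient_id = ids,
                 clinical_class = rep(classes, length.out = length(ids)),
                 dialysis_day = NA_integer_)
}

# Tidy scalar ensemble from a plain list of numeric series.
as_ensemble <- function(series, dt = 1) {
  out <- purrr::imap_dfr(series, function(s, i) {
    tibble::tibble(patient_id = paste0("s", i), day = seq_along(s), x = s)
  })
  attr(out, "dt") <- dt
  out
}

# Central-occupancy average of an estimated profile column.
central_mean <- function(profile, col, lo = 0.1, hi = 0.9) {
  occ <- cumsum(profile$Z_H) / sum(profile$Z_H)
  sel <- occ > lo & occ < hi
  mean(profile[[col]][sel], na.rm = TRUE)
}
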