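# Internal helpers shared across modules.

# Cumulative trapezoidal integral of f over x, starting at 0.
cumtrapz <- function(x, f) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(0, cumsum(diff(x) * (f[-n] + f[-1]) / 2))
}

# Count of v strictly less than each y (v need not be sorted).
count_less <- function(v, y) {
  findInterval(y, sort(v), left.open = TRUE)
}

# Sum of weights w over elements with v < y, for each y.
wsum_less <- function(v, w, y) {
  o <- order(v)
  cw <- c(0, cumsum(w[o]))
  cw[count_less(v, y) + 1L]
}

# Resolve the feature columns of a cohort table: explicit argument, the
# "features" attribute set by the builders, or a naming convention.
feature_cols <- function(data, features = NULL) {
  if (!is.null(features)) return(features)
  feats <- attr(data, "features")
  if (!is.null(feats) && all(feats %in% names(data))) return(feats)
  feats <- grep("^(bin_|state_|feat_)", names(data), value = TRUE)
  if (length(feats) == 0) {
    abort("no feature columns found; pass `features` explicitly")
  }
  feats
}

feature_matrix <- function(data, features = NULL) {
  feats <- feature_cols(data, features)
  as.matrix(data[feats])
}

# Split a tidy projected ensemble into a named list of numeric series,
# ordered by `day` within `patient_id`.
as_series_list <- function(data, value = "x") {
  stopifnot(is.data.frame(data), value %in% names(data))
  if (!"patient_id" %in% names(data)) {
    abort("ensemble data must have a `patient_id` column")
  }
  d <- data
  if ("day" %in% names(d)) d <- dplyr::arrange(d, .data$patient_id, .data$day)
  split(d[[value]], factor(d$patient_id, levels = unique(d$patient_id)))
}

# Minimum-norm least-squares solution via SVD with relative cutoff.
solve_min_norm <- function(A, b, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * max(sv$d)
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  list(x = drop(x),
       condition = max(sv$d) / min(sv$d[sv$d > 0]),
       rank = sum(keep))
}
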