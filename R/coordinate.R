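#' Fit a linear reaction coordinate to a trajectory cohort
#'
#' Learns weights `alpha` so that the scalar projection
#' `R = sum_k alpha_k f_k + alpha_0` of the feature trajectories is an
#' optimal reaction coordinate, in one of three modes:
#'
#' * `"supervised"` — minimizes the summed squared step increments
#'   `sum (R[i+1] - R[i])^2` plus, for every trajectory, one virtual step
#'   from its last point to its terminal label `b` in `{0, 1}`. The
#'   minimizer approximates the committor (probability of ending in the
#'   `b = 1` state before the `b = 0` state); the linear system is solved
#'   by a minimum-norm SVD pseudo-solution.
#' * `"unsupervised"` — minimizes the same step increments subject to unit
#'   variance of the projection over all sampled points, i.e. solves the
#'   generalized eigenvalue problem `A v = lambda B v` with
#'   `A = (1/n_steps) sum df df'` and `B = (1/n_points) sum (f - fbar)(f - fbar)'`.
#'   The smallest nontrivial eigenvalue is the slowest relaxation mode
#'   (`ev = 2`); `ev = 3` selects the next slowest. The constant function
#'   (the trivial zero mode) is removed by centering.
#' * `"pca"` — principal components of the pooled, mean-centered feature
#'   matrix; a static-variance baseline that ignores the temporal order.
#'
#' @param cohort Feature trajectory tibble from [build_trajectories()] (or
#'   [sample_chain()]): columns `patient_id`, `day`, feature columns,
#'   optionally `clinical_class`.
#' @param mode Optimization mode.
#' @param labels Terminal labels for supervised mode: either a tibble with
#'   columns `patient_id`, `b` (0 or 1), or a named numeric vector. If
#'   omitted, labels are derived from `clinical_class` via `label_map`.
#' @param label_map Named vector mapping clinical classes to `{0, 1}`;
#'   the default sends PF to 0 and DGF/AR to 1.
#' @param ev For unsupervised mode, which eigenvector to report: 2 (the
#'   slowest relaxation mode) or 3 (the second slowest).
#' @param features Feature column names; default taken from the cohort.
#' @param remap For supervised mode, remap the `{0, 1}` committor scale to
#'   `{-1, 1}` (an affine display convention).
#' @param boundary_weight Weight of the virtual terminal step in the
#'   supervised objective. The default 1 matches trajectories truncated
#'   before reaching an end state (each contributes one extra, yet-unseen
#'   step). For ensembles *terminated on arrival* in an end state (with the
#'   terminal point stripped, as [sample_chain()] does with
#'   `strip_absorbing = TRUE`), use 2: interior links are sampled in both
#'   directions but boundary links only inward, so doubling the virtual
#'   step restores the equilibrium link counting under which the minimizer
#'   is the committor.
#' @param rcond Relative singular-value cutoff for the minimum-norm solve.
#' @return An object of class `cfep_coordinate`: weights, constant term,
#'   affine map, mode, eigen spectrum (unsupervised), fit diagnostics.
#' @seealso [project_coordinate()], [loocv()], [tidy.cfep_coordinate()]
#' @export
fit_coordinate <- function(cohort,
                           mode = c("unsupervised", "supervised", "pca"),
                           labels = NULL,
                           label_map = c(PF = 0, DGF = 1, AR = 1),
                           ev = 2L, features = NULL, remap = FALSE,
                           boundary_weight = 1, rcond = 1e-10) {
  mode <- match.arg(mode)
  feats <- feature_cols(cohort, features)
  X <- feature_matrix(cohort, feats)
  ids <- cohort$patient_id
  if (dplyr::n_distinct(ids) < 2) abort("need at least 2 trajectories")
  by_id <- split(seq_len(nrow(X)), factor(ids, levels = unique(ids)))

  dX <- do.call(rbind, purrr::map(by_id, function(ix) {
    if (length(ix) < 2) return(NULL)
    diff(X[ix, , drop = FALSE])
  }))
  if (is.null(dX) || nrow(dX) == 0) abort("cohort contains no steps")

  fit <- switch(mode,
    supervised = fit_supervised(X, dX, by_id, cohort, labels, label_map,
                                boundary_weight, rcond),
    unsupervised = fit_unsupervised(X, dX, ev, rcond),
    pca = fit_pca(X))

  model <- structure(
    list(weights = setNames(fit$weights, feats), const = fit$const,
         affine = c(shift = 0, scale = 1), mode = mode,
         ev = if (mode == "unsupervised") as.integer(ev) else NA_integer_,
         eigen = fit$eigen, features = feats,
         bin_edges = attr(cohort, "bin_edges"),
         diagnostics = c(fit$diag, list(n_steps = nrow(dX),
                                        n_points = nrow(X)))),
    class = "cfep_coordinate")

  if (mode == "supervised" && remap) {
    model$affine <- c(shift = -1, scale = 2)
  }
  if (mode != "supervised") {
    model <- orient_coordinate(model, cohort, label_map)
  }
  model
}

fit_supervised <- function(X, dX, by_id, cohort, labels, label_map,
                           boundary_weight, rcond) {
  b <- resolve_labels(cohort, labels, label_map)
  if (length(unique(b)) < 2) {
    abort("supervised fit needs both terminal labels (0 and 1) present")
  }
  K <- ncol(X)
  # step rows: projection increments target 0 (constant term cancels);
  # boundary rows: one virtual step from each trajectory's last point to b
  last_rows <- vapply(by_id, function(ix) ix[length(ix)], integer(1))
  sw <- sqrt(boundary_weight)
  A <- rbind(cbind(dX, 0), sw * cbind(X[last_rows, , drop = FALSE], 1))
  t_vec <- c(rep(0, nrow(dX)), sw * b[names(by_id)])
  sol <- solve_min_norm(A, t_vec, rcond = rcond)
  if (sol$rank < K + 1) {
    inform(sprintf(
      "rank-deficient supervised system (rank %d of %d); minimum-norm solution, condition %.3g",
      sol$rank, K + 1, sol$condition))
  }
  list(weights = sol$x[seq_len(K)], const = sol$x[K + 1], eigen = NULL,
       diag = list(condition = sol$condition, rank = sol$rank,
                   labels = b))
}

resolve_labels <- function(cohort, labels, label_map) {
  pid <- unique(cohort$patient_id)
  if (is.null(labels)) {
    if (!"clinical_class" %in% names(cohort)) {
      abort("supervised mode needs `labels` or a `clinical_class` column")
    }
    cls <- cohort |>
      dplyr::distinct(.data$patient_id, .data$clinical_class)
    if (anyNA(cls$clinical_class) ||
        !all(cls$clinical_class %in% names(label_map))) {
      abort("clinical_class values not covered by `label_map`")
    }
    b <- setNames(unname(label_map[cls$clinical_class]), cls$patient_id)
  } else if (is.data.frame(labels)) {
    b <- setNames(labels$b, labels$patient_id)
  } else {
    b <- labels
  }
  if (!all(pid %in% names(b))) abort("labels missing for some patients")
  b <- b[pid]
  if (!all(b %in% c(0, 1))) abort("labels must be 0 or 1")
  b
}

fit_unsupervised <- function(X, dX, ev, rcond) {
  ev <- as.integer(ev)
  if (!ev %in% c(2L, 3L)) abort("`ev` must be 2 or 3")
  K <- ncol(X)
  if (nrow(dX) < K) abort("pooled steps must be at least the feature count")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  A <- crossprod(dX) / nrow(dX)
  B <- crossprod(Xc) / nrow(X)

  # Whitening restricted to the span of B: null directions of the
  # covariance (the constant function under an indicator basis, unsampled
  # subspaces) drop out of the problem instead of reappearing as spurious
  # zero modes, which a diagonal ridge would cause.
  eb <- eigen(B, symmetric = TRUE)
  keep <- eb$values > rcond * max(eb$values)
  # a basis containing the constant (e.g. state indicators) always has one
  # expected null direction; only deeper deficiencies are worth a warning
  ones <- rep(1, K)
  const_in_span <- max(abs(B %*% ones)) < 1e-10 * max(abs(B))
  expected_rank <- K - as.integer(const_in_span)
  rank_deficient <- sum(keep) < expected_rank
  if (rank_deficient) {
    warn(sprintf(
      "rank-deficient covariance (rank %d of %d); solving on its span",
      sum(keep), K))
  }
  W <- eb$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(eb$values[keep]),
                                                 nrow = sum(keep))
  M <- crossprod(W, A %*% W)
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values)           # ascending: slowest mode first
  values <- em$values[ord]
  vectors <- W %*% em$vectors[, ord, drop = FALSE]
  sel <- ev - 1L                    # mode 1 is the slowest nontrivial one
  if (sel > ncol(vectors)) abort("requested eigenvector beyond spectrum")
  w <- vectors[, sel]
  list(weights = w, const = -sum(colMeans(X) * w),
       eigen = list(values = values, vectors = vectors, selected = sel),
       diag = list(rank_deficient = rank_deficient, rank = sum(keep)))
}

fit_pca <- function(X) {
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  w <- p$rotation[, 1]
  list(weights = unname(w), const = -sum(p$center * w), eigen = NULL,
       diag = list(sdev = p$sdev))
}

# Deterministic sign convention: classes mapping to b = 0 (PF-like) project
# to negative values; without labels, make the largest-|weight| coefficient
# positive.
orient_coordinate <- function(model, cohort, label_map) {
  flip <- FALSE
  if ("clinical_class" %in% names(cohort) &&
      !anyNA(cohort$clinical_class) &&
      all(cohort$clinical_class %in% names(label_map))) {
    proj <- project_coordinate(cohort, model)
    final <- proj |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_tail(n = 1) |>
      dplyr::ungroup()
    b <- label_map[final$clinical_class]
    if (all(c(0, 1) %in% b)) {
      flip <- mean(final$x[b == 0]) > mean(final$x[b == 1])
    }
  } else {
    flip <- model$weights[which.max(abs(model$weights))] < 0
  }
  if (flip) {
    model$weights <- -model$weights
    model$const <- -model$const
  }
  model
}

#' Project a cohort onto a fitted reaction coordinate
#'
#' @param cohort Feature trajectory tibble (same feature columns as used in
#'   the fit).
#' @param model A `cfep_coordinate` from [fit_coordinate()].
#' @return Tibble with `patient_id`, `day` (if present), `clinical_class`
#'   (if present) and the scalar projection `x`, row order preserved.
#' @export
project_coordinate <- function(cohort, model) {
  stopifnot(inherits(model, "cfep_coordinate"))
  if (!all(model$features %in% names(cohort))) {
    abort("cohort lacks the model's feature columns")
  }
  X <- as.matrix(cohort[model$features])
  r <- drop(X %*% model$weights) + model$const
  x <- model$affine[["scale"]] * r + model$affine[["shift"]]
  keep <- intersect(c("patient_id", "day", "clinical_class"), names(cohort))
  out <- dplyr::bind_cols(cohort[keep], tibble::tibble(x = x))
  attr(out, "dt") <- attr(cohort, "dt") %||% 1
  out
}

#' Leave-one-out cross-validation of a reaction-coordinate fit
#'
#' Refits the coordinate with each patient held out and projects the
#' held-out trajectory on the reduced fit. Because both the eigenvector and
#' committor coordinates are defined up to an affine map, agreement is
#' scored as the absolute Pearson correlation between held-out and full-fit
#' projections, per patient. A cohort whose median correlation falls below
#' `threshold` is flagged as over-fitting: the coordinate depends on the
#' very trajectory it is asked to describe.
#'
#' @inheritParams fit_coordinate
#' @param threshold Median |correlation| at or above which the fit is
#'   called `"stable"`.
#' @param ... Passed on to [fit_coordinate()].
#' @return An object of class `cfep_loocv`: per-patient correlations,
#'   held-out and full projections, the median, and a verdict
#'   (`"stable"` or `"over-fitting"`).
#' @export
loocv <- function(cohort, mode = c("unsupervised", "supervised", "pca"),
                  threshold = 0.8, features = NULL, ...) {
  mode <- match.arg(mode)
  feats <- feature_cols(cohort, features)
  ids <- unique(cohort$patient_id)
  if (length(ids) < 3) abort("leave-one-out needs at least 3 trajectories")

  full <- fit_coordinate(cohort, mode = mode, features = feats, ...)
  proj_full <- project_coordinate(cohort, full)

  folds <- purrr::map(ids, function(id) {
    train <- dplyr::filter(cohort, .data$patient_id != id)
    attr(train, "features") <- feats
    test <- dplyr::filter(cohort, .data$patient_id == id)
    fit <- tryCatch(fit_coordinate(train, mode = mode, features = feats, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(list(proj = NULL,
                  row = tibble::tibble(patient_id = id,
                                       correlation = NA_real_,
                                       failed = TRUE)))
    }
    held <- project_coordinate(test, fit)
    xf <- proj_full$x[proj_full$patient_id == id]
    r <- if (length(held$x) >= 3 && sd(held$x) > 0 && sd(xf) > 0) {
      abs(cor(held$x, xf))
    } else {
      NA_real_
    }
    held$x_full <- xf
    list(proj = held,
         row = tibble::tibble(patient_id = id, correlation = r,
                              failed = FALSE))
  })

  per_patient <- purrr::map_dfr(folds, "row")
  med <- stats::median(per_patient$correlation, na.rm = TRUE)
  structure(
    list(per_patient = per_patient,
         projections = purrr::map_dfr(folds, "proj"),
         full_projections = proj_full,
         median_abs_cor = med,
         threshold = threshold,
         verdict = if (is.finite(med) && med >= threshold) "stable"
                   else "over-fitting",
         mode = mode),
    class = "cfep_loocv")
}

#' @export
print.cfep_coordinate <- function(x, ...) {
  cat(sprintf("<cfep_coordinate> mode=%s, %d features\n",
              x$mode, length(x$weights)))
  if (!is.null(x$eigen)) {
    cat(sprintf("  eigenvalue (mode %d): %.4g\n",
                x$ev, x$eigen$values[x$eigen$selected]))
  }
  top <- head(sort(abs(x$weights), decreasing = TRUE), 3)
  cat("  largest |weights|:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cfep_loocv <- function(x, ...) {
  cat(sprintf("<cfep_loocv> mode=%s, %d folds, median |cor| = %.3f -> %s\n",
              x$mode, nrow(x$per_patient), x$median_abs_cor, x$verdict))
  invisible(x)
}

#' Tidy a fitted reaction coordinate
#'
#' @param x A `cfep_coordinate`.
#' @param ... Unused.
#' @return One row per basis function: `term`, `weight`, and (when the fit
#'   came from binned spectra) `ppm_lo`, `ppm_hi`.
#' @export
tidy.cfep_coordinate <- function(x, ...) {
  out <- tibble::tibble(term = names(x$weights), weight = unname(x$weights))
  if (!is.null(x$bin_edges) && length(x$bin_edges) == nrow(out) + 1) {
    out$ppm_lo <- head(x$bin_edges, -1)
    out$ppm_hi <- tail(x$bin_edges, -1)
  }
  out
}

#' @rdname tidy.cfep_coordinate
#' @export
glance.cfep_coordinate <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_features = length(x$weights),
    n_points = x$diagnostics$n_points,
    n_steps = x$diagnostics$n_steps,
    eigenvalue = if (!is.null(x$eigen)) x$eigen$values[x$eigen$selected]
                 else NA_real_,
    condition = x$diagnostics$condition %||% NA_real_)
}

#' @export
tidy.cfep_loocv <- function(x, ...) x$per_patient

#' @export
glance.cfep_loocv <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_folds = nrow(x$per_patient),
                 n_failed = sum(x$per_patient$failed),
                 median_abs_cor = x$median_abs_cor,
                 threshold = x$threshold, verdict = x$verdict)
}

#' @export
autoplot.cfep_coordinate <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "coordinate weight") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.cfep_loocv <- function(object, ...) {
  plot_trajectories(object$projections) +
    ggplot2::labs(y = "held-out projection")
}

#' Plot projected patient trajectories
#'
#' @param projections Output of [project_coordinate()].
#' @return A ggplot object; one line per patient, colored by clinical class
#'   when available.
#' @export
plot_trajectories <- function(projections) {
  aes <- if ("clinical_class" %in% names(projections)) {
    ggplot2::aes(x = .data$day, y = .data$x, group = .data$patient_id,
                 colour = .data$clinical_class)
  } else {
    ggplot2::aes(x = .data$day, y = .data$x, group = .data$patient_id)
  }
  ggplot2::ggplot(projections, aes) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "day relative to surgery", y = "reaction coordinate",
                  colour = "class")
}
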