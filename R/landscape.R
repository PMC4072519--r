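#' Reconstruct the equilibrium free-energy landscape from a trajectory
#' ensemble
#'
#' Patient ensembles are not at equilibrium: trajectories start near the
#' barrier and drain into the outcome basins, so the observed occupancy is
#' a steady-state, not a Boltzmann, distribution. Assuming diffusive
#' dynamics, the 1-D steady state obeys
#' `J(y) = -D(y) e^{-F(y)} d/dy [P_ss(y) e^{F(y)}]`, which integrates to
#' `G(y) = P_ss e^{F} = G(y0) exp(-int J/(D P_ss) dy)`. The equilibrium
#' profile is then `F_eq = ln G - ln P_ss`, anchored at `min F_eq = 0`.
#' When `J = 0` this reduces exactly to `F_eq = -ln P_ss + const`.
#'
#' Occupancy `P_ss`, the diffusion coefficient `D` (from the
#' distance-weighted cut profile) and the net flux `J` (from directional
#' crossing counts) are all taken from a single [cut_profile()]. The
#' working interval is the largest contiguous run of positive occupancy
#' containing the occupancy maximum; anything outside is truncated.
#'
#' @param profile A `cfep_profile` from [cut_profile()] (columns `D` and
#'   `J` are computed on the fly if absent).
#' @param dt,total_time Overrides for the profile attributes.
#' @param D Optional known diffusion coefficient (scalar or vector on the
#'   profile grid) used instead of the estimate.
#' @return An object of class `cfep_landscape` holding a tibble
#'   (`y`, `P_ss`, `D`, `J`, `F_eq`) and basin/barrier locations.
#' @export
reconstruct_landscape <- function(profile, dt = NULL, total_time = NULL,
                                  D = NULL) {
  stopifnot(inherits(profile, "cfep_profile") ||
              all(c("y", "Z_H", "n_up", "n_down") %in% names(profile)))
  if (!"D" %in% names(profile)) {
    profile <- estimate_diffusion(profile, dt = dt)
  }
  if (!"J" %in% names(profile)) {
    profile <- net_flux(profile, total_time = total_time)
  }
  if (!is.null(D)) {
    profile$D <- if (length(D) == 1) rep(D, nrow(profile)) else D
  }

  pos <- profile$Z_H > 0 & is.finite(profile$D) & profile$D > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  imax <- which.max(profile$Z_H)
  run_id <- which(runs$values & starts <= imax & ends >= imax)
  if (length(run_id) == 0) abort("no usable occupancy around the mode")
  sel <- seq(starts[run_id], ends[run_id])
  if (length(sel) < nrow(profile)) {
    warn(sprintf("truncating working interval to %d of %d grid points",
                 length(sel), nrow(profile)))
  }

  y <- profile$y[sel]
  p_ss <- profile$Z_H[sel]
  d_y <- profile$D[sel]
  j_y <- profile$J[sel]

  log_g <- -cumtrapz(y, j_y / (d_y * p_ss))
  f_eq <- log_g - log(p_ss)
  f_eq <- f_eq - min(f_eq)

  tab <- tibble::tibble(y = y, P_ss = p_ss, D = d_y, J = j_y, F_eq = f_eq)
  basins <- find_basins(y, f_eq)
  structure(
    list(table = tab, basins = basins,
         dt = attr(profile, "dt"), rescaled = FALSE),
    class = "cfep_landscape")
}

# Two deepest local minima of F and the barrier top between them.
find_basins <- function(y, f) {
  n <- length(f)
  if (n < 5) return(list(left = y[which.min(f)], right = y[which.min(f)],
                         barrier = NA_real_, barrier_height = NA_real_))
  is_min <- c(FALSE, f[2:(n - 1)] <= f[1:(n - 2)] &
                f[2:(n - 1)] <= f[3:n], FALSE)
  is_min[c(1, n)] <- c(f[1] < f[2], f[n] < f[n - 1])
  cand <- which(is_min)
  if (length(cand) < 2) {
    i <- which.min(f)
    return(list(left = y[i], right = y[i], barrier = NA_real_,
                barrier_height = NA_real_))
  }
  # pick the pair of minima with the most prominent barrier between them,
  # which is robust against shallow noise wiggles inside one basin
  best <- NULL
  best_prom <- -Inf
  for (ii in seq_len(length(cand) - 1)) {
    for (jj in seq(ii + 1, length(cand))) {
      a <- cand[ii]
      b <- cand[jj]
      between <- seq(a, b)
      ib <- between[which.max(f[between])]
      prom <- f[ib] - max(f[a], f[b])
      if (prom > best_prom) {
        best_prom <- prom
        best <- c(a, b, ib)
      }
    }
  }
  list(left = y[best[1]], right = y[best[2]], barrier = y[best[3]],
       barrier_height = f[best[3]] - min(f[best[1:2]]))
}

#' Rescale the coordinate so the diffusion coefficient is unity
#'
#' Applies the monotone change of variable `ytilde(y) = int dy' / sqrt(D(y'))`.
#' Under a coordinate map the diffusion coefficient transforms as
#' `D_tilde = D (dytilde/dy)^2 = 1`, so on the rescaled coordinate the
#' dynamics has unit diffusion everywhere; free-energy values carry over
#' pointwise (the cut profile is invariant under monotone maps).
#'
#' @param landscape A `cfep_landscape`.
#' @return The landscape with a `y_tilde` column, flagged as rescaled.
#' @export
rescale_unit_diffusion <- function(landscape) {
  stopifnot(inherits(landscape, "cfep_landscape"))
  tab <- landscape$table
  if (any(!is.finite(tab$D) | tab$D <= 0)) {
    abort("diffusion coefficient must be positive on the working interval")
  }
  tab$y_tilde <- cumtrapz(tab$y, 1 / sqrt(tab$D))
  landscape$table <- tab
  landscape$rescaled <- TRUE
  map_to_tilde <- stats::approxfun(tab$y, tab$y_tilde, rule = 2)
  landscape$basins_tilde <- list(
    left = map_to_tilde(landscape$basins$left),
    right = map_to_tilde(landscape$basins$right),
    barrier = if (is.finite(landscape$basins$barrier))
      map_to_tilde(landscape$basins$barrier) else NA_real_)
  landscape
}

#' Outcome probability from the free-energy profile
#'
#' The probability of reaching the `left` boundary (e.g. the recovery
#' basin) before the `right` one, starting from `x`, for diffusion on the
#' profile: `q(x) = int_x^right e^{F}/D dy / int_left^right e^{F}/D dy`
#' (the standard 1-D splitting probability). Evaluated by trapezoidal
#' quadrature on a fine grid; `q(left) = 1`, `q(right) = 0`, and values of
#' `x` outside `[left, right]` are clamped.
#'
#' @param landscape A `cfep_landscape`.
#' @param left,right Committor anchors; default to the two basin minima.
#' @param x Evaluation points; default `n_grid` points spanning
#'   `[left, right]`.
#' @param n_grid Quadrature/evaluation grid size.
#' @param unit_D Treat the diffusion coefficient as 1 (appropriate after
#'   [rescale_unit_diffusion()] on the rescaled coordinate, or whenever the
#'   profile is already expressed on a unit-diffusion coordinate).
#' @return Tibble with columns `x`, `q_model`.
#' @export
committor_from_profile <- function(landscape, left = NULL, right = NULL,
                                   x = NULL, n_grid = 201, unit_D = TRUE) {
  stopifnot(inherits(landscape, "cfep_landscape"))
  tab <- landscape$table
  left <- left %||% landscape$basins$left
  right <- right %||% landscape$basins$right
  if (!(left < right)) abort("`left` must be less than `right`")

  g <- seq(left, right, length.out = n_grid)
  f_g <- approx(tab$y, tab$F_eq, xout = g, rule = 2)$y
  d_g <- if (unit_D) rep(1, n_grid) else approx(tab$y, tab$D, xout = g,
                                                rule = 2)$y
  integrand <- exp(f_g - max(f_g)) / d_g
  cum <- cumtrapz(g, integrand)
  total <- cum[n_grid]
  q_grid <- (total - cum) / total

  if (is.null(x)) {
    return(tibble::tibble(x = g, q_model = q_grid))
  }
  q <- approx(g, q_grid, xout = pmin(pmax(x, left), right), rule = 2)$y
  q[x <= left] <- 1
  q[x >= right] <- 0
  tibble::tibble(x = x, q_model = q)
}

#' Agresti-Coull estimate of a binomial proportion
#'
#' The "add two successes and two failures" point estimate and 95% band:
#' `p = (s + 2) / (s + f + 4)`, `p +/- 2 sqrt(p (1 - p) / (s + f + 4))`,
#' clipped to `[0, 1]`. The multiplier is exactly 2.
#'
#' @param successes,failures Non-negative counts (vectorized).
#' @return Tibble with `p_hat`, `ci_low`, `ci_high`.
#' @export
agresti_coull <- function(successes, failures) {
  stopifnot(all(successes >= 0), all(failures >= 0))
  n <- successes + failures + 4
  p <- (successes + 2) / n
  half <- 2 * sqrt(p * (1 - p) / n)
  tibble::tibble(p_hat = p,
                 ci_low = pmax(p - half, 0),
                 ci_high = pmin(p + half, 1))
}

#' Empirical outcome probability along the coordinate
#'
#' For each coordinate bin, counts the trajectories that visit the bin and
#' end on the left versus the right of `split_point` (e.g. the barrier
#' top), and converts the counts to a success probability with an
#' Agresti-Coull 95% interval. This is the trajectory-based counterpart of
#' [committor_from_profile()].
#'
#' @param data Projected ensemble tibble (`patient_id`, `x`, optional
#'   `day`).
#' @param split_point Coordinate value separating the two outcomes.
#' @param breaks Bin edges along the coordinate; default 21 uniform bins
#'   over the data range.
#' @return Tibble with `x` (bin midpoint), `n_left`, `n_right`, `p_hat`,
#'   `ci_low`, `ci_high`, `visited`.
#' @export
empirical_outcome_probability <- function(data, split_point, breaks = NULL) {
  series <- as_series_list(data)
  finals <- purrr::map_dbl(series, ~ tail(.x, 1))
  if (any(!is.finite(finals))) abort("non-finite final points")
  ended_left <- finals < split_point

  if (is.null(breaks)) {
    rng <- range(unlist(series, use.names = FALSE))
    breaks <- seq(rng[1] - 1e-9 * diff(rng), rng[2] + 1e-9 * diff(rng),
                  length.out = 22)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(mids)

  visits <- purrr::map(series, function(s) {
    unique(findInterval(s, breaks, rightmost.closed = TRUE))
  })
  n_left <- integer(nb)
  n_right <- integer(nb)
  for (i in seq_along(series)) {
    v <- visits[[i]]
    v <- v[v >= 1 & v <= nb]
    if (ended_left[[i]]) n_left[v] <- n_left[v] + 1L
    else n_right[v] <- n_right[v] + 1L
  }
  ac <- agresti_coull(n_left, n_right)
  tibble::tibble(x = mids, n_left = n_left, n_right = n_right,
                 p_hat = ac$p_hat, ci_low = ac$ci_low, ci_high = ac$ci_high,
                 visited = n_left + n_right > 0)
}

#' @export
print.cfep_landscape <- function(x, ...) {
  cat(sprintf(
    "<cfep_landscape> %d grid points, basins at %.3g / %.3g, barrier %.3g kT%s\n",
    nrow(x$table), x$basins$left, x$basins$right,
    x$basins$barrier_height,
    if (isTRUE(x$rescaled)) " (unit-diffusion rescaled)" else ""))
  invisible(x)
}

#' Tidy a reconstructed landscape
#'
#' @param x A `cfep_landscape`.
#' @param ... Unused.
#' @return The landscape grid as a tibble (`y`, `P_ss`, `D`, `J`, `F_eq`,
#'   plus `y_tilde` after rescaling).
#' @export
tidy.cfep_landscape <- function(x, ...) x$table

#' @rdname tidy.cfep_landscape
#' @export
glance.cfep_landscape <- function(x, ...) {
  tibble::tibble(n_grid = nrow(x$table),
                 basin_left = x$basins$left,
                 basin_right = x$basins$right,
                 barrier = x$basins$barrier,
                 barrier_height = x$basins$barrier_height,
                 rescaled = isTRUE(x$rescaled))
}

#' @export
autoplot.cfep_landscape <- function(object, committor = NULL, ...) {
  tab <- object$table
  xvar <- if (isTRUE(object$rescaled) && "y_tilde" %in% names(tab))
    "y_tilde" else "y"
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data[[xvar]],
                                         y = .data$F_eq)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate", y = "free energy (kT)")
  if (!is.null(committor)) {
    p <- p +
      ggplot2::geom_line(data = committor,
                         ggplot2::aes(x = .data$x,
                                      y = .data$q_model * max(tab$F_eq)),
                         colour = "red") +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / max(tab$F_eq),
                                     name = "P(success)"))
  }
  p
}
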