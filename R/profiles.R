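#' Decompose the crossings of a scalar series through a point
#'
#' Counts the steps of a time series that cross a coordinate value `y`,
#' split by direction, together with the summed step lengths. A step
#' `x[i] -> x[i+1]` crosses upward iff `x[i] < y <= x[i+1]` and downward iff
#' `x[i+1] < y <= x[i]` (half-open tie rule: a point exactly at `y` belongs
#' to the upper side).
#'
#' @param series Numeric vector, length >= 2.
#' @param y Scalar coordinate value.
#' @return Named list with `n_up`, `n_down` (crossing counts) and `w_up`,
#'   `w_down` (summed `|dx|` over the corresponding crossings).
#' @examples
#' crossing_decomposition(c(0, 1, 0, 1), 0.5)
#' @export
crossing_decomposition <- function(series, y) {
  stopifnot(is.numeric(series), length(series) >= 2, length(y) == 1)
  a <- series[-length(series)]
  b <- series[-1]
  up <- a < y & y <= b
  down <- b < y & y <= a
  list(n_up = sum(up), n_down = sum(down),
       w_up = sum(abs(b - a)[up]), w_down = sum(abs(b - a)[down]))
}

# Directional crossing counts and distance-weighted sums for every grid
# point at once. `a`, `b` are pooled step endpoints. O((n + G) log n).
cut_counts <- function(a, b, grid) {
  d <- abs(b - a)
  res <- function(lo, hi, w) {
    n <- count_less(lo, grid) - count_less(hi, grid)
    ws <- wsum_less(lo, w, grid) - wsum_less(hi, w, grid)
    list(n = n, w = ws)
  }
  is_up <- b > a
  is_dn <- b < a
  up <- res(a[is_up], b[is_up], d[is_up])
  dn <- res(b[is_dn], a[is_dn], d[is_dn])
  list(n_up = up$n, n_down = dn$n, w_up = up$w, w_down = dn$w)
}

#' Cut-based and histogram free-energy profiles of a trajectory ensemble
#'
#' Pools the steps of all trajectories (never forming steps across
#' trajectories) and evaluates, at each grid point `y`:
#' `Z_C(y)` = half the number of steps crossing `y`; `Z_C1(y)` = half the
#' sum of `|dx|` over crossing steps, split into directional parts `Z_plus`
#' and `Z_minus`; and the occupancy density `Z_H(y)` (counts in grid cells
#' divided by total points times cell width). Free-energy profiles are
#' `F_* = -ln Z_*` in units of kT (kT = 1), defined only where the
#' partition function is positive.
#'
#' The cut-based profile is invariant under strictly increasing
#' re-parameterizations of the coordinate, unlike the histogram profile.
#' Raw directional crossing counts `n_up`, `n_down` are retained for flux
#' estimation.
#'
#' @param data Tibble with columns `patient_id`, `x`, and optionally `day`
#'   (used to order points within a patient), e.g. the output of
#'   [project_coordinate()] or [simulate_diffusion()].
#' @param grid Strictly increasing numeric vector of evaluation points;
#'   default `n_grid` uniform points spanning the pooled data range.
#' @param n_grid Number of default grid points.
#' @param dt Sampling interval of the series (days); defaults to the `dt`
#'   attribute of `data`, else 1.
#' @return A tibble (class `cfep_profile`) with columns `y`, `n_up`,
#'   `n_down`, `Z_C`, `Z_C1`, `Z_plus`, `Z_minus`, `Z_H`, `F_C`, `F_C1`,
#'   `F_H`; attributes `n_steps`, `n_points`, `dt`, `total_time`.
#' @examples
#' ens <- tibble::tibble(patient_id = "p1", day = 1:4, x = c(0, 1, 0, 1))
#' cut_profile(ens, grid = c(0.25, 0.5, 0.75))
#' @export
cut_profile <- function(data, grid = NULL, n_grid = 101, dt = NULL) {
  series <- as_series_list(data)
  if (length(series) == 0) abort("empty ensemble")
  dt <- dt %||% attr(data, "dt") %||% 1

  steps <- purrr::map(series, function(s) {
    if (length(s) < 2) return(NULL)
    a <- s[-length(s)]
    b <- s[-1]
    ok <- is.finite(a) & is.finite(b)
    if (!all(ok)) {
      inform(sprintf("skipping %d non-finite step(s)", sum(!ok)))
    }
    cbind(a[ok], b[ok])
  })
  st <- do.call(rbind, steps)
  if (is.null(st) || nrow(st) == 0) abort("ensemble contains no usable steps")
  pts <- unlist(series, use.names = FALSE)
  pts <- pts[is.finite(pts)]

  if (is.null(grid)) {
    rng <- range(pts)
    if (diff(rng) <= 0) abort("degenerate ensemble: constant coordinate")
    eps <- 1e-8 * diff(rng)
    grid <- seq(rng[1] - eps, rng[2] + eps, length.out = n_grid)
  }
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing")

  cc <- cut_counts(st[, 1], st[, 2], grid)
  z_c <- (cc$n_up + cc$n_down) / 2
  z_plus <- cc$w_up / 2
  z_minus <- cc$w_down / 2
  z_c1 <- z_plus + z_minus

  # occupancy density on cells centered at the grid points
  if (length(grid) >= 2) {
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    cell_edges <- c(grid[1] - (mids[1] - grid[1]),
                    mids,
                    grid[length(grid)] +
                      (grid[length(grid)] - mids[length(mids)]))
    widths <- diff(cell_edges)
    counts <- tabulate(findInterval(pts, cell_edges,
                                    rightmost.closed = TRUE),
                       nbins = length(grid))
    z_h <- counts / (length(pts) * widths)
  } else {
    z_h <- NA_real_   # occupancy density undefined on a single-point grid
  }

  neglog <- function(z) ifelse(z > 0, -log(z), NA_real_)
  out <- tibble::tibble(
    y = grid, n_up = cc$n_up, n_down = cc$n_down,
    Z_C = z_c, Z_C1 = z_c1, Z_plus = z_plus, Z_minus = z_minus, Z_H = z_h,
    F_C = neglog(z_c), F_C1 = neglog(z_c1), F_H = neglog(z_h))
  attr(out, "n_steps") <- nrow(st)
  attr(out, "n_points") <- length(pts)
  attr(out, "dt") <- dt
  attr(out, "total_time") <- nrow(st) * dt
  class(out) <- c("cfep_profile", class(out))
  out
}

#' Check invariance of the cut profile under a monotone coordinate map
#'
#' Crossing counts are order statistics, so `Z_C` evaluated at `y` on the
#' original ensemble must equal `Z_C` evaluated at `map(y)` on the mapped
#' ensemble, exactly. This is the defining property that distinguishes
#' cut-based profiles from histogram profiles.
#'
#' @inheritParams cut_profile
#' @param map Strictly increasing function.
#' @return `TRUE` if the counts agree exactly at every grid point.
#' @export
invariance_check <- function(data, map, grid = NULL, n_grid = 101) {
  p0 <- cut_profile(data, grid = grid, n_grid = n_grid)
  g <- p0$y
  gm <- map(g)
  probe <- sort(unique(c(g, as_series_list(data) |> unlist())))
  if (any(diff(map(probe)) <= 0)) {
    abort("`map` must be strictly increasing")
  }
  mapped <- data
  mapped$x <- map(mapped$x)
  p1 <- cut_profile(mapped, grid = gm)
  isTRUE(all.equal(p0$Z_C, p1$Z_C)) && all(p0$n_up == p1$n_up) &&
    all(p0$n_down == p1$n_down)
}

#' Coordinate-dependent diffusion coefficient from cut profiles
#'
#' In the diffusive (memoryless, small-interval) limit the
#' distance-weighted cut partition function per step equals
#' `Z_H(y) * D(y) * dt`, so `D(y) = Z_C1(y) / (n_steps * Z_H(y) * dt)`.
#' Regions with zero occupancy are masked as `NA`.
#'
#' @param profile A `cfep_profile` from [cut_profile()].
#' @param dt Sampling interval; defaults to the profile's `dt` attribute.
#' @return The profile tibble with a `D` column appended.
#' @export
estimate_diffusion <- function(profile, dt = NULL) {
  stopifnot(all(c("Z_C1", "Z_H") %in% names(profile)))
  dt <- dt %||% attr(profile, "dt") %||% 1
  n_steps <- attr(profile, "n_steps")
  if (is.null(n_steps)) abort("profile lacks an `n_steps` attribute")
  profile$D <- ifelse(profile$Z_H > 0,
                      (profile$Z_C1 / n_steps) / (profile$Z_H * dt),
                      NA_real_)
  profile
}

#' Net probability flux along the coordinate
#'
#' `J(y) = (N_up(y) - N_down(y)) / T` from the raw directional crossing
#' counts, where `T` is the total sampled time. For an equilibrium
#' (detailed-balance) ensemble `J` vanishes everywhere; a source/sink
#' steady state has constant positive flux between source and sink.
#'
#' @param profile A `cfep_profile` from [cut_profile()].
#' @param total_time Total trajectory time; defaults to the profile's
#'   `total_time` attribute (`n_steps * dt`).
#' @return The profile tibble with a `J` column appended.
#' @export
net_flux <- function(profile, total_time = NULL) {
  stopifnot(all(c("n_up", "n_down") %in% names(profile)))
  total_time <- total_time %||% attr(profile, "total_time")
  if (is.null(total_time) || total_time <= 0) {
    abort("`total_time` must be positive")
  }
  profile$J <- (profile$n_up - profile$n_down) / total_time
  profile
}

#' Mean squared displacement versus lag
#'
#' Pools squared displacements at each lag over all trajectories. For free
#' diffusion the MSD grows linearly, `MSD(n) = 2 D n dt`; sub-linear growth
#' signals a sub-optimal (memory-bearing) coordinate.
#'
#' @inheritParams cut_profile
#' @param lags Integer vector of lags (in sampling intervals).
#' @return Tibble with columns `lag`, `msd`, `n_pairs`.
#' @export
msd_diagnostic <- function(data, lags = c(1L, 2L, 4L)) {
  series <- as_series_list(data)
  stopifnot(all(lags >= 1))
  if (max(lags) >= max(lengths(series))) {
    abort("max lag must be smaller than the longest series")
  }
  purrr::map_dfr(lags, function(L) {
    sq <- purrr::map(series, function(s) {
      if (length(s) <= L) return(numeric(0))
      (s[-seq_len(L)] - s[seq_len(length(s) - L)])^2
    })
    sq <- unlist(sq, use.names = FALSE)
    tibble::tibble(lag = L,
                   msd = if (length(sq)) mean(sq) else NA_real_,
                   n_pairs = length(sq))
  })
}

#' @export
autoplot.cfep_profile <- function(object, which = c("F_C1", "F_C", "F_H"),
                                  ...) {
  which <- match.arg(which, c("F_C1", "F_C", "F_H"), several.ok = TRUE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("y", which)],
    cols = -"y", names_to = "profile", values_to = "F")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$y, y = .data$F,
                                     colour = .data$profile)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "reaction coordinate", y = "free energy (kT)",
                  colour = NULL)
}
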