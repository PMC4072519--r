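#' Specify a one-dimensional free-energy landscape for simulation
#'
#' The default form is the quartic double well
#' `F(x) = h ((u^2 - 1)^2)` with `u` the coordinate rescaled so the wells
#' sit at `well_positions`; `h` is the barrier height in kT. A custom
#' landscape can be given as a function `F(x)` (its gradient is taken
#' numerically unless `dF` is supplied).
#'
#' @param form `"double_well_quartic"` or `"custom"`.
#' @param barrier_height Barrier height `h` in kT (quartic form).
#' @param well_positions Locations of the two minima.
#' @param D Diffusion coefficient: scalar, or function of position.
#' @param dt_sim Integration time step (days). Must resolve the steepest
#'   curvature: `D * dt_sim * max|F''|` well below 1.
#' @param F_fun,dF_fun For `form = "custom"`, the potential and its
#'   derivative.
#' @return An object of class `landscape_spec` with callable `F` and `dF`.
#' @export
landscape_spec <- function(form = c("double_well_quartic", "custom"),
                           barrier_height = 3, well_positions = c(-1, 1),
                           D = 1, dt_sim = 0.01,
                           F_fun = NULL, dF_fun = NULL) {
  form <- match.arg(form)
  stopifnot(barrier_height >= 0, dt_sim > 0,
            length(well_positions) == 2,
            well_positions[2] > well_positions[1])
  if (form == "double_well_quartic") {
    a <- well_positions[1]
    b <- well_positions[2]
    s <- 2 / (b - a)                       # du/dx
    u <- function(x) (2 * x - (a + b)) / (b - a)
    F_fun <- function(x) barrier_height * (u(x)^2 - 1)^2
    dF_fun <- function(x) barrier_height * 4 * u(x) * (u(x)^2 - 1) * s
  } else {
    if (is.null(F_fun)) abort("custom form needs `F_fun`")
    if (is.null(dF_fun)) {
      h <- 1e-5
      dF_fun <- function(x) (F_fun(x + h) - F_fun(x - h)) / (2 * h)
    }
  }
  D_fun <- if (is.function(D)) D else function(x) rep(D, length(x))
  structure(
    list(form = form, barrier_height = barrier_height,
         well_positions = well_positions, D = D, D_fun = D_fun,
         dt_sim = dt_sim, F = F_fun, dF = dF_fun),
    class = "landscape_spec")
}

#' Simulate overdamped diffusive dynamics on a landscape
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' `x[i+1] = x[i] - D F'(x[i]) dt + sqrt(2 D dt) xi` with standard normal
#' `xi` (position-dependent `D` uses the local value; no spurious-drift
#' correction, adequate for slowly varying `D`).
#'
#' Three sampling modes:
#' * `"equilibrium"` — trajectories start in the wells (alternating) and a
#'   burn-in of `burn_in` steps precedes recording, giving a
#'   detailed-balance ensemble.
#' * `"steady_state"` — every trajectory starts at `source` and is
#'   terminated once it passes `sink` (recording the crossing point),
#'   emulating a constant-flux source/sink ensemble.
#' * `"first_passage"` — trajectories start at `x0` (default the barrier
#'   top) and are absorbed at either `source` (left anchor) or `sink`
#'   (right anchor), defaulting to the two well positions. The fraction of
#'   trajectories absorbed left, among those visiting a point, is exactly
#'   the committor at that point.
#'
#' @param spec A [landscape_spec()].
#' @param n_traj Number of trajectories.
#' @param n_steps Recorded steps per trajectory (cap, for steady state).
#' @param mode Sampling mode.
#' @param x0 Initial position(s); default depends on mode.
#' @param burn_in Discarded initial steps (equilibrium mode).
#' @param subsample Keep every `subsample`-th recorded point (the observed
#'   sampling interval is then `dt_sim * subsample`).
#' @param source,sink Source and absorbing positions (steady-state mode);
#'   default: left well and one well-spacing beyond the right well.
#' @param seed Integer seed; the simulation is reproducible given
#'   (spec, arguments, seed).
#' @return Tidy ensemble tibble (`patient_id`, `day`, `x`) with attribute
#'   `dt = dt_sim * subsample`.
#' @export
simulate_diffusion <- function(spec, n_traj, n_steps,
                               mode = c("equilibrium", "steady_state",
                                        "first_passage"),
                               x0 = NULL, burn_in = 1000L, subsample = 1L,
                               source = NULL, sink = NULL, seed = NULL) {
  stopifnot(inherits(spec, "landscape_spec"), n_traj >= 1, n_steps >= 2)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  dt <- spec$dt_sim
  span <- diff(spec$well_positions)
  # divergence guard: generous envelope of confining wells plus the free
  # diffusive spread over the whole run (flat landscapes diffuse freely)
  probe <- seq(min(spec$well_positions) - 2 * span,
               max(spec$well_positions) + 2 * span, length.out = 101)
  d_max <- max(spec$D_fun(probe))
  bound <- max(abs(spec$well_positions)) + 5 * span +
    10 * sqrt(2 * d_max * n_steps * dt)

  step_all <- function(x) {
    d <- spec$D_fun(x)
    xn <- x - spec$dF(x) * d * dt +
      sqrt(2 * d * dt) * rnorm(length(x))
    if (any(abs(xn) > bound)) {
      abort("divergent trajectory: reduce `dt_sim` (integration unstable)")
    }
    xn
  }

  if (mode == "equilibrium") {
    x <- x0 %||% rep(spec$well_positions, length.out = n_traj)
    x <- rep(x, length.out = n_traj)
    for (i in seq_len(burn_in)) x <- step_all(x)
    keep <- seq(1L, n_steps, by = subsample)
    keep_mask <- logical(n_steps)
    keep_mask[keep] <- TRUE
    rec <- matrix(NA_real_, nrow = length(keep), ncol = n_traj)
    k <- 1L
    for (i in seq_len(n_steps)) {
      if (keep_mask[i]) {
        rec[k, ] <- x
        k <- k + 1L
      }
      if (i < n_steps) x <- step_all(x)
    }
    out <- tibble::tibble(
      patient_id = rep(sprintf("traj_%03d", seq_len(n_traj)),
                       each = length(keep)),
      day = rep((keep - 1L) * dt, times = n_traj),
      x = as.vector(rec))
  } else {
    if (mode == "steady_state") {
      source <- source %||% spec$well_positions[1]
      sink <- sink %||% (spec$well_positions[2] + span / 4)
      lo <- -Inf
      x <- rep(source, n_traj)
    } else {
      lo <- source %||% spec$well_positions[1]
      sink <- sink %||% spec$well_positions[2]
      x0 <- x0 %||% mean(spec$well_positions)
      x <- rep(x0, length.out = n_traj)
    }
    # all trajectories advance together; absorbed ones stop being stepped
    active <- rep(TRUE, n_traj)
    absorbed_at <- rep(n_steps, n_traj)
    chunk_size <- 10000L
    chunks <- list()
    cur <- matrix(NA_real_, min(chunk_size, n_steps), n_traj)
    ci <- 0L
    for (i in seq_len(n_steps)) {
      ci <- ci + 1L
      if (ci > nrow(cur)) {
        chunks[[length(chunks) + 1L]] <- cur
        cur <- matrix(NA_real_, chunk_size, n_traj)
        ci <- 1L
      }
      cur[ci, ] <- x
      newly <- active & (x >= sink | x <= lo)
      absorbed_at[newly] <- i
      active[newly] <- FALSE
      if (!any(active) || i == n_steps) break
      xa <- x[active]
      da <- spec$D_fun(xa)
      xa <- xa - spec$dF(xa) * da * dt + sqrt(2 * da * dt) *
        rnorm(length(xa))
      if (any(abs(xa) > bound)) {
        abort("divergent trajectory: reduce `dt_sim` (integration unstable)")
      }
      x[active] <- xa
    }
    chunks[[length(chunks) + 1L]] <- cur[seq_len(ci), , drop = FALSE]
    rec <- do.call(rbind, chunks)
    paths <- purrr::map(seq_len(n_traj), function(j) {
      rec[seq(1L, min(absorbed_at[j], nrow(rec)), by = subsample), j]
    })
    out <- tibble::tibble(
      patient_id = rep(sprintf("traj_%03d", seq_len(n_traj)),
                       times = lengths(paths)),
      day = unlist(purrr::map(paths, ~ (seq_along(.x) - 1L) * dt *
                                subsample)),
      x = unlist(paths))
  }
  attr(out, "dt") <- dt * subsample
  out
}

# Smooth channel loading and baseline patterns as functions of chemical
# shift, so coarse (30-channel) and fine (~100-channel) embeddings describe
# the same underlying signal. The loading peaks near 4 ppm, mimicking a
# dominant small-molecule resonance, with weaker oscillatory structure
# across the rest of the spectrum.
default_loading <- function(ppm) {
  0.8 * exp(-0.5 * ((ppm - 4) / 0.8)^2) + 0.15 * cos(2 * pi * ppm / 2.9)
}

default_baseline <- function(ppm) {
  0.3 + exp(-0.5 * ((ppm - 3) / 2.5)^2)
}

#' Encode a latent scalar trajectory into spectrum-like channels
#'
#' Channel `k` at time `t` has intensity
#' `baseline_k * exp(loading_k * x(t) + noise)`, with independent Gaussian
#' log-scale channel noise: strictly positive, and exactly log-linear in
#' the latent coordinate at zero noise, so the binning + log preprocessing
#' recovers `x` by a linear coordinate. Each channel is emitted as
#' `points_per_channel` ppm points of constant intensity so that bin means
#' reproduce channel intensities.
#'
#' An optional nuisance component adds a second latent variable `z(t)`,
#' drawn independently at every time point (fast, memoryless), loading on
#' a direction orthogonalized against `loading`: it inflates static
#' variance without carrying slow dynamics.
#'
#' @param latent Tidy ensemble (`patient_id`, `day`, `x`).
#' @param n_channels Number of spectral channels over `ppm_range`.
#' @param loading Channel response to the latent coordinate; default a
#'   smooth pattern with a dominant channel near 4 ppm.
#' @param baseline Positive channel baselines.
#' @param noise_sd Log-scale channel noise standard deviation.
#' @param nuisance_sd Standard deviation of the memoryless nuisance latent
#'   (0 disables it).
#' @param ppm_range Chemical-shift window the channels tile.
#' @param points_per_channel Spectral points emitted per channel.
#' @param seed Integer seed.
#' @return Long spectra tibble (`patient_id`, `day`, `ppm`, `intensity`)
#'   ready for [build_trajectories()].
#' @export
embed_to_spectra <- function(latent, n_channels = 30, loading = NULL,
                             baseline = NULL, noise_sd = 0.1,
                             nuisance_sd = 0, ppm_range = c(0, 9.6),
                             points_per_channel = 4L, seed = NULL) {
  stopifnot(all(c("patient_id", "day", "x") %in% names(latent)))
  if (!is.null(seed)) set.seed(seed)
  edges <- seq(ppm_range[1], ppm_range[2], length.out = n_channels + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  loading <- loading %||% default_loading(centers)
  baseline <- baseline %||% default_baseline(centers)
  stopifnot(length(loading) == n_channels, length(baseline) == n_channels,
            all(baseline > 0), any(loading != 0))

  nuis_dir <- NULL
  if (nuisance_sd > 0) {
    raw <- sin(2 * pi * centers / 1.7) + 0.5
    nuis_dir <- raw - sum(raw * loading) / sum(loading^2) * loading
    nuis_dir <- nuis_dir / sqrt(sum(nuis_dir^2)) * sqrt(n_channels) * 0.3
  }

  n_obs <- nrow(latent)
  noise <- matrix(rnorm(n_obs * n_channels, sd = noise_sd),
                  nrow = n_obs)
  logint <- outer(latent$x, loading) + noise +
    matrix(log(baseline), n_obs, n_channels, byrow = TRUE)
  if (!is.null(nuis_dir)) {
    z <- rnorm(n_obs, sd = nuisance_sd)
    logint <- logint + outer(z, nuis_dir)
  }

  # emit points_per_channel interior ppm points per channel
  width <- diff(edges)[1]
  offs <- (seq_len(points_per_channel) - 0.5) / points_per_channel * width
  ppm_pts <- as.vector(outer(offs, edges[-length(edges)], "+"))
  ord <- order(ppm_pts)

  purrr::map_dfr(seq_len(n_obs), function(i) {
    inten <- rep(exp(logint[i, ]), each = points_per_channel)[ord]
    tibble::tibble(patient_id = latent$patient_id[i],
                   day = latent$day[i],
                   ppm = ppm_pts[ord],
                   intensity = inten)
  })
}

#' Generate a synthetic longitudinal cohort
#'
#' Ground-truth cohorts for validating the full pipeline: a latent scalar
#' coordinate evolves by diffusion on a quartic double well (wells at
#' -1/+1, barrier 3 kT, D = 0.5 per day, integrated at dt = 0.01 day and
#' observed daily), starting near the barrier top as a patient does at
#' surgery, and is encoded into positive spectrum-like channels. Outcome
#' classes are defined by the basin a trajectory relaxes into: PF ends in
#' the left well, DGF in the right; AR trajectories evolve in a shallow
#' trap at the barrier top (a stand-in for dynamics unresolved within the
#' observation window, not a biological model). Trajectories are generated
#' per class by rejection until the class quota is met.
#'
#' Scenarios:
#' * `paper_scale_two_class` — 18 patients, PF:DGF = 9:9, 30 channels.
#' * `paper_scale_three_class` — 18 patients, PF:DGF:AR = 9:5:4.
#' * `pca_blind` — two classes plus a high-variance memoryless nuisance
#'   direction that dominates the static covariance (PCA sees it; the
#'   dynamical coordinate does not).
#' * `overfit_probe` — two classes at ~100 channels (the fine-binning
#'   analogue), for exercising leave-one-out instability.
#'
#' @param scenario Preset name.
#' @param seed Integer seed; output is fully reproducible.
#' @param n_days Maximum time points per patient (days -1 to 7 when 9).
#' @return List with `spectra` (long tibble), `metadata` (patient_id,
#'   clinical_class, dialysis_day), `latent` (the hidden coordinate), and
#'   `spec` (the generating [landscape_spec()]).
#' @export
generate_cohort <- function(scenario = c("paper_scale_two_class",
                                         "paper_scale_three_class",
                                         "pca_blind", "overfit_probe"),
                            seed = 1, n_days = 9) {
  scenario <- tryCatch(match.arg(scenario), error = function(e) {
    abort(paste("unknown scenario; presets:",
                "paper_scale_two_class, paper_scale_three_class,",
                "pca_blind, overfit_probe"))
  })
  set.seed(seed)
  quotas <- switch(scenario,
    paper_scale_three_class = c(PF = 9, DGF = 5, AR = 4),
    c(PF = 9, DGF = 9))
  n_channels <- if (scenario == "overfit_probe") 100L else 30L
  nuisance_sd <- if (scenario == "pca_blind") 2 else 0

  spec <- landscape_spec(barrier_height = 3, well_positions = c(-1, 1),
                         D = 0.5, dt_sim = 0.01)
  trap <- landscape_spec(form = "custom", dt_sim = spec$dt_sim, D = 0.5,
                         F_fun = function(x) spec$F(x) + 3 * x^2,
                         dF_fun = function(x) spec$dF(x) + 6 * x)

  steps_per_day <- round(1 / spec$dt_sim)
  days <- seq(-1, n_days - 2)          # day -1 (pre-op) through day 7
  n_steps <- (length(days) - 1) * steps_per_day + 1

  # class membership is decided at the last *observed* day, so truncated
  # series still end clearly inside their basin
  sample_one <- function(class, n_keep) {
    for (attempt in 1:500) {
      use_spec <- if (class == "AR") trap else spec
      tr <- simulate_diffusion(use_spec, n_traj = 1, n_steps = n_steps,
                               mode = "equilibrium", burn_in = 0,
                               x0 = rnorm(1, 0, 0.1),
                               subsample = steps_per_day)
      xf <- tr$x[n_keep]
      ok <- switch(class,
                   PF = xf < -0.5,
                   DGF = xf > 0.5,
                   AR = abs(xf) < 0.5)
      if (ok) return(tr$x[seq_len(n_keep)])
    }
    abort(sprintf("could not generate a %s trajectory in 500 attempts",
                  class))
  }

  classes <- rep(names(quotas), times = quotas)
  pids <- sprintf("patient_%02d", seq_along(classes))
  latent <- purrr::map2_dfr(pids, classes, function(id, cl) {
    # variable series lengths: drop 0-4 trailing days for a third of cohort
    n_keep <- length(days)
    if (runif(1) < 1 / 3) n_keep <- sample(5:(length(days) - 1), 1)
    x <- sample_one(cl, n_keep)
    tibble::tibble(patient_id = id, day = days[seq_len(n_keep)],
                   x = x, clinical_class = cl)
  })

  spectra <- embed_to_spectra(latent[c("patient_id", "day", "x")],
                              n_channels = n_channels,
                              noise_sd = 0.1, nuisance_sd = nuisance_sd)
  metadata <- latent |>
    dplyr::distinct(.data$patient_id, .data$clinical_class) |>
    dplyr::mutate(dialysis_day = NA_integer_)
  list(spectra = spectra, metadata = metadata, latent = latent, spec = spec)
}

#' Finite-state Markov chain oracles
#'
#' Exact reference quantities for a row-stochastic transition matrix:
#' the committor (probability of reaching state `b` before state `a`) from
#' a dense linear solve, and the eigendecomposition of the transition
#' matrix (eigenvalues sorted by decreasing real part; the second
#' eigenvector is the slowest relaxation mode).
#'
#' @param P Row-stochastic matrix.
#' @param a,b Boundary states (1-based indices): `q[a] = 0`, `q[b] = 1`.
#' @return List with `committor`, `eigenvalues`, `eigenvectors`.
#' @export
chain_oracles <- function(P, a = 1L, b = nrow(P)) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            all(abs(rowSums(P) - 1) < 1e-10), all(P >= 0))
  n <- nrow(P)
  interior <- setdiff(seq_len(n), c(a, b))
  q <- numeric(n)
  q[b] <- 1
  if (length(interior) > 0) {
    M <- diag(length(interior)) - P[interior, interior, drop = FALSE]
    rhs <- P[interior, b]
    q[interior] <- solve(M, rhs)
  }
  e <- eigen(P)
  ord <- order(-Re(e$values))
  list(committor = q,
       eigenvalues = Re(e$values[ord]),
       eigenvectors = Re(e$vectors[, ord, drop = FALSE]))
}

#' Sample trajectories from a finite-state Markov chain
#'
#' Emits a cohort table with one indicator feature per state
#' (`state_1` ... `state_K`), suitable for [fit_coordinate()] with the
#' chain oracles as ground truth. With `absorb`, trajectories stop on
#' first entry to an absorbing state (plus that final point).
#'
#' @param P Row-stochastic transition matrix.
#' @param n_traj,n_steps Trajectories and (maximum) length of each.
#' @param init Initial state distribution (default uniform over
#'   non-absorbing states).
#' @param absorb Integer vector of absorbing states (may be empty).
#' @param strip_absorbing Drop the final (absorbing) point of each
#'   trajectory, leaving the arrival encoded in the `labels` attribute
#'   (`b = 1` when the trajectory reached `max(absorb)`). This is the
#'   construction the supervised boundary term assumes: the end state is
#'   reached on the step *after* the data end.
#' @param segment_at For an ergodic (non-absorbing) chain: sample one long
#'   stationary trajectory per `n_traj` and split it into excursions
#'   between visits to these boundary states. Each excursion keeps only
#'   the interior points, labeled by the boundary it hit next (`labels`
#'   attribute). In stationarity every interior link is then sampled in
#'   both directions while each boundary link appears once as a virtual
#'   terminal step, which is the ensemble under which the supervised
#'   objective (with `boundary_weight = 2`) recovers the chain committor.
#' @param burn_in Discarded initial steps (with `segment_at`).
#' @param seed Integer seed.
#' @return Cohort tibble (`patient_id`, `day`, `state`, indicator
#'   features) with a `features` attribute (and a `labels` attribute when
#'   `strip_absorbing = TRUE`).
#' @export
sample_chain <- function(P, n_traj, n_steps, init = NULL,
                         absorb = integer(), strip_absorbing = FALSE,
                         segment_at = integer(), burn_in = 1000L,
                         seed = NULL) {
  stopifnot(all(abs(rowSums(P) - 1) < 1e-10))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  free <- setdiff(seq_len(n), absorb)
  init <- init %||% {
    p <- numeric(n)
    p[free] <- 1 / length(free)
    p
  }

  sim_one <- function(s0, len_max, stop_at) {
    s <- integer(len_max)
    s[1] <- s0
    len <- 1L
    for (i in 2:len_max) {
      s[i] <- findInterval(runif(1), cum[s[i - 1], ],
                           left.open = TRUE) + 1L
      len <- i
      if (s[i] %in% stop_at) break
    }
    s[seq_len(len)]
  }

  if (length(segment_at) > 0) {
    if (length(absorb) > 0) abort("`segment_at` needs an ergodic chain")
    # one long stationary run per n_traj, split into labeled excursions
    excursions <- list()
    lab_b <- numeric(0)
    for (run in seq_len(n_traj)) {
      s0 <- sample.int(n, 1, prob = init)
      long <- sim_one(s0, burn_in + n_steps, integer())
      long <- long[-seq_len(burn_in)]
      hits <- which(long %in% segment_at)
      if (length(hits) < 2) next
      for (h in seq_len(length(hits) - 1)) {
        i0 <- hits[h]
        i1 <- hits[h + 1]
        if (i1 - i0 < 2) next            # no interior points
        excursions[[length(excursions) + 1L]] <- long[(i0 + 1):(i1 - 1)]
        lab_b <- c(lab_b, as.numeric(long[i1] == max(segment_at)))
      }
    }
    if (length(excursions) == 0) abort("no complete excursions sampled")
    states <- excursions
    ids <- sprintf("traj_%04d", seq_along(states))
    labels <- tibble::tibble(patient_id = ids, b = lab_b)
  } else {
    states <- purrr::map(seq_len(n_traj), function(i) {
      sim_one(sample.int(n, 1, prob = init), n_steps, absorb)
    })
    labels <- NULL
    if (strip_absorbing) {
      if (length(absorb) == 0) {
        abort("`strip_absorbing` needs `absorb` states")
      }
      ended <- purrr::map_int(states, ~ tail(.x, 1))
      absorbed <- ended %in% absorb
      states <- purrr::map(states, function(s) {
        if (tail(s, 1) %in% absorb && length(s) > 1) head(s, -1) else s
      })
      keep <- absorbed & lengths(states) >= 1
      states <- states[keep]
      labels <- tibble::tibble(
        patient_id = sprintf("traj_%04d", which(keep)),
        b = as.numeric(ended[keep] == max(absorb)))
      if (sum(keep) < n_traj) {
        inform(sprintf("dropped %d unabsorbed trajectories",
                       n_traj - sum(keep)))
      }
      ids <- sprintf("traj_%04d", which(keep))
    } else {
      ids <- sprintf("traj_%04d", seq_len(n_traj))
    }
  }
  out <- tibble::tibble(
    patient_id = rep(ids, times = lengths(states)),
    day = unlist(purrr::map(states, seq_along)),
    state = unlist(states))
  feats <- sprintf("state_%d", seq_len(n))
  ind <- matrix(0, nrow(out), n, dimnames = list(NULL, feats))
  ind[cbind(seq_len(nrow(out)), out$state)] <- 1
  out <- dplyr::bind_cols(out, tibble::as_tibble(ind))
  attr(out, "features") <- feats
  attr(out, "dt") <- 1
  attr(out, "labels") <- labels
  out
}
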