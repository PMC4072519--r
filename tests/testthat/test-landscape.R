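test_that("net flux satisfies the crossing identities", {
  p <- net_flux(cut_profile(as_ensemble(list(c(0, 1, 0, 1))), grid = 0.5))
  expect_equal(p$n_up - p$n_down, 1L)
  expect_equal(p$J, 1 / 3)   # one net crossing over three unit steps

  # N trajectories all crossing y once: J = N / T
  ens <- as_ensemble(purrr::map(1:5, ~ c(0, 1)))
  p2 <- net_flux(cut_profile(ens, grid = 0.5))
  expect_equal(p2$J, 5 / 5)

  # equilibrium double-well ensemble: flux ~ 0 everywhere
  dw <- landscape_spec(barrier_height = 1, D = 1, dt_sim = 0.005)
  sim <- simulate_diffusion(dw, n_traj = 10, n_steps = 5000,
                            mode = "equilibrium", seed = 51)
  p3 <- net_flux(cut_profile(sim))
  # net crossings are bounded by one endpoint-difference per trajectory
  expect_lte(max(abs(p3$J)) * attr(p3, "total_time"), 10)
})

test_that("zero-flux reconstruction reduces exactly to the histogram profile", {
  set.seed(52)
  ens <- as_ensemble(purrr::map(1:6, ~ cumsum(rnorm(200, sd = 0.1))))
  pr <- estimate_diffusion(cut_profile(ens, n_grid = 41))
  pr$J <- rep(0, nrow(pr))
  land <- suppressWarnings(reconstruct_landscape(pr))
  resid <- land$table$F_eq + log(land$table$P_ss)
  expect_lt(diff(range(resid)), 1e-10)
})

test_that("rescaling to unit diffusion is the closed-form coordinate change", {
  tab <- tibble::tibble(y = seq(0, 1, by = 0.1),
                        P_ss = rep(1, 11), D = rep(1, 11),
                        J = rep(0, 11), F_eq = rep(0, 11))
  land <- structure(list(table = tab,
                         basins = list(left = 0, right = 1, barrier = 0.5,
                                       barrier_height = 0),
                         rescaled = FALSE),
                    class = "cfep_landscape")
  r1 <- rescale_unit_diffusion(land)
  expect_equal(r1$table$y_tilde, tab$y - tab$y[1])

  land$table$D <- rep(4, 11)
  r4 <- rescale_unit_diffusion(land)
  expect_equal(r4$table$y_tilde, (tab$y - tab$y[1]) / 2)

  land$table$D[3] <- -1
  expect_error(rescale_unit_diffusion(land), "positive")
})

test_that("profile committor obeys boundaries, symmetry, monotonicity and shift invariance", {
  g <- seq(-1, 1, length.out = 101)
  mk_land <- function(f) {
    structure(list(table = tibble::tibble(y = g, P_ss = exp(-f) /
                                            sum(exp(-f)),
                                          D = 1, J = 0, F_eq = f),
                   basins = list(left = -1, right = 1, barrier = 0,
                                 barrier_height = max(f)),
                   rescaled = TRUE),
              class = "cfep_landscape")
  }
  f_sym <- 3 * (g^2 - 1)^2
  land <- mk_land(f_sym)
  q <- committor_from_profile(land, -1, 1)
  expect_equal(q$q_model[1], 1)
  expect_equal(q$q_model[nrow(q)], 0)
  expect_equal(committor_from_profile(land, -1, 1, x = 0)$q_model, 0.5,
               tolerance = 1e-8)
  expect_true(all(diff(q$q_model) <= 1e-12))
  # clamping outside the anchors
  expect_equal(committor_from_profile(land, -1, 1,
                                      x = c(-2, 2))$q_model, c(1, 0))
  # invariance under adding a constant to F
  q_shift <- committor_from_profile(mk_land(f_sym + 5), -1, 1, x = q$x)
  expect_equal(q_shift$q_model, q$q_model, tolerance = 1e-12)
})

test_that("profile committor matches the committor of the matched-rate chain", {
  n <- 201
  g <- seq(-1, 1, length.out = n)
  f <- 3 * (g^2 - 1)^2
  # birth-death chain with detailed-balance rates on the same grid
  r <- 0.2
  P <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    P[i, i + 1] <- r * exp(-(f[i + 1] - f[i]) / 2)
    P[i, i - 1] <- r * exp(-(f[i - 1] - f[i]) / 2)
  }
  P[1, ] <- 0
  P[1, 1] <- 1
  P[n, ] <- 0
  P[n, n] <- 1
  diag(P)[2:(n - 1)] <- 1 - rowSums(P)[2:(n - 1)]
  stopifnot(all(P >= 0))
  q_chain <- chain_oracles(P, 1, n)$committor
  # chain committor runs 0 -> 1 toward state n; the profile committor is
  # the probability of reaching the LEFT anchor first
  land <- structure(list(table = tibble::tibble(y = g,
                                                P_ss = exp(-f) / sum(exp(-f)),
                                                D = 1, J = 0, F_eq = f),
                         basins = list(left = -1, right = 1, barrier = 0,
                                       barrier_height = 3),
                         rescaled = TRUE),
                    class = "cfep_landscape")
  q_prof <- committor_from_profile(land, -1, 1, x = g)$q_model
  expect_lt(max(abs((1 - q_prof) - q_chain)), 0.02)
})

test_that("Agresti-Coull estimates follow the add-two prescription", {
  expect_equal(agresti_coull(0, 0),
               tibble::tibble(p_hat = 0.5, ci_low = 0, ci_high = 1))
  expect_equal(agresti_coull(8, 0)$p_hat, 10 / 12)
  set.seed(53)
  s <- rpois(50, 4)
  f <- rpois(50, 4)
  ac <- agresti_coull(s, f)
  expect_true(all(ac$ci_low >= 0 & ac$ci_low <= ac$p_hat))
  expect_true(all(ac$ci_high <= 1 & ac$ci_high >= ac$p_hat))
})

test_that("empirical outcome counts trajectories once per visited bin", {
  ens <- as_ensemble(list(c(-0.9, -0.1, -0.8),   # ends left, visits middle
                          c(-0.1, 0.6, 0.9),     # ends right
                          c(-0.85, -0.9, -0.7))) # stays left
  out <- empirical_outcome_probability(ens, split_point = 0,
                                       breaks = c(-1, -0.5, 0, 0.5, 1))
  expect_equal(out$n_left, c(2L, 1L, 0L, 0L))
  expect_equal(out$n_right, c(0L, 1L, 0L, 1L))
  expect_equal(out$p_hat, (out$n_left + 2) / (out$n_left + out$n_right + 4))
  expect_equal(out$visited, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("reconstruction closes the loop with equilibrium resimulation", {
  # recover a profile from one ensemble, resimulate on the recovered
  # profile, and check the occupancies agree
  dw <- landscape_spec(barrier_height = 2, D = 1, dt_sim = 0.005)
  sim <- simulate_diffusion(dw, n_traj = 10, n_steps = 20000,
                            mode = "equilibrium", seed = 54)
  pr <- net_flux(estimate_diffusion(cut_profile(sim, n_grid = 61)))
  land <- suppressWarnings(reconstruct_landscape(pr))
  tab <- land$table
  f_fun <- stats::approxfun(tab$y, tab$F_eq, rule = 2)
  spec2 <- landscape_spec(form = "custom", D = 1, dt_sim = 0.005,
                          F_fun = f_fun)
  sim2 <- simulate_diffusion(spec2, n_traj = 10, n_steps = 20000,
                             mode = "equilibrium", x0 = rep(c(-1, 1), 5),
                             burn_in = 2000, seed = 55)
  p2 <- cut_profile(sim2, grid = pr$y)
  sel <- pr$Z_H > 0 & p2$Z_H > 0 & tab$F_eq[match(pr$y, tab$y)] < 3
  sel[is.na(sel)] <- FALSE
  d <- -log(p2$Z_H[sel]) + log(pr$Z_H[sel])
  expect_lt(sd(d), 0.35)
})

test_that("landscape accessors expose the grid and basin summaries", {
  dw <- landscape_spec(barrier_height = 3, D = 1, dt_sim = 0.005)
  sim <- simulate_diffusion(dw, n_traj = 10, n_steps = 20000,
                            mode = "equilibrium", seed = 56)
  land <- suppressWarnings(
    reconstruct_landscape(net_flux(estimate_diffusion(cut_profile(sim)))))
  td <- tidy(land)
  expect_true(all(c("y", "P_ss", "D", "J", "F_eq") %in% names(td)))
  gl <- glance(land)
  expect_lt(gl$basin_left, gl$barrier)
  expect_gt(gl$basin_right, gl$barrier)
  expect_s3_class(autoplot(land), "ggplot")
})
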