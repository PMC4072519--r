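test_that("projection is the affine-mapped linear combination of features", {
  coh <- tibble::tibble(
    patient_id = rep("p1", 3), day = 1:3,
    feat_a = c(0.1, 0.2, 0.3), feat_b = c(5, 4, 3))
  attr(coh, "features") <- c("feat_a", "feat_b")

  sel <- structure(list(weights = c(feat_a = 0, feat_b = 1), const = 0,
                        affine = c(shift = 0, scale = 1),
                        mode = "supervised", features = c("feat_a", "feat_b")),
                   class = "cfep_coordinate")
  expect_equal(project_coordinate(coh, sel)$x, coh$feat_b)

  sel$weights <- c(feat_a = 0, feat_b = 0)
  expect_equal(project_coordinate(coh, sel)$x, rep(0, 3))

  sel$weights <- c(feat_a = 1, feat_b = 0)
  sel$const <- 0.65
  sel$affine <- c(shift = -1, scale = 2)
  expect_equal(project_coordinate(coh, sel)$x[1], 2 * 0.75 - 1)

  sel$features <- c("feat_a", "feat_missing")
  expect_error(project_coordinate(coh, sel), "feature")
})

test_that("supervised optimization recovers the gambler's-ruin committor", {
  P <- nn_chain(5, 0.5)
  coh <- sample_chain(P, n_traj = 2, n_steps = 20000, segment_at = c(1, 5),
                      seed = 31)
  fit <- fit_coordinate(coh, mode = "supervised",
                        labels = attr(coh, "labels"), boundary_weight = 2)
  vals <- fit$weights + fit$const
  expect_lt(max(abs(vals[2:4] - c(0.25, 0.5, 0.75))), 0.05)
})

test_that("supervised fit refuses degenerate label sets", {
  P <- nn_chain(5, 0.5)
  coh <- sample_chain(P, n_traj = 5, n_steps = 50, seed = 2)
  labs <- tibble::tibble(patient_id = unique(coh$patient_id), b = 1)
  expect_error(fit_coordinate(coh, mode = "supervised", labels = labs),
               "both")
})

test_that("a basis containing the exact committor gets all the weight", {
  q <- c(0, 0.25, 0.5, 0.75, 1)
  P <- nn_chain(5, 0.5)
  coh <- sample_chain(P, n_traj = 2, n_steps = 20000, segment_at = c(1, 5),
                      seed = 32)
  set.seed(33)
  coh2 <- dplyr::mutate(coh,
                        f_commit = q[.data$state],
                        f_noise = rnorm(dplyr::n(), sd = 0.5))
  attr(coh2, "features") <- c("f_commit", "f_noise")
  fit <- fit_coordinate(coh2, mode = "supervised",
                        labels = attr(coh, "labels"), boundary_weight = 2)
  expect_lt(abs(fit$weights[["f_commit"]] - 1), 0.05)
  expect_lt(abs(fit$weights[["f_noise"]]), 0.05)
})

test_that("the returned supervised weights minimize the objective", {
  objective <- function(vals, coh, labels) {
    proj <- vals[coh$state]
    steps <- sum(unlist(purrr::map(split(proj, coh$patient_id), ~ diff(.x)^2)))
    lastp <- vapply(split(proj, coh$patient_id), function(v) tail(v, 1),
                    numeric(1))
    b <- setNames(labels$b, labels$patient_id)[names(lastp)]
    steps + 2 * sum((lastp - b)^2)
  }
  P <- nn_chain(5, 0.6)
  coh <- sample_chain(P, n_traj = 2, n_steps = 4000, segment_at = c(1, 5),
                      seed = 34)
  labels <- attr(coh, "labels")
  fit <- fit_coordinate(coh, mode = "supervised", labels = labels,
                        boundary_weight = 2)
  vals <- fit$weights + fit$const
  base <- objective(vals, coh, labels)
  set.seed(35)
  for (i in 1:20) {
    expect_gte(objective(vals + rnorm(5, sd = 0.05), coh, labels) + 1e-10,
               base)
  }
})

test_that("unsupervised mode solves the two-state chain in closed form", {
  p <- 0.3
  P <- matrix(c(1 - p, p, p, 1 - p), 2, byrow = TRUE)
  coh <- sample_chain(P, n_traj = 2, n_steps = 3000, seed = 36)
  fit <- fit_coordinate(coh, mode = "unsupervised")
  # the nontrivial mode is exactly antisymmetric for an indicator basis
  expect_equal(fit$weights[[1]] / fit$weights[[2]], -1, tolerance = 1e-10)
  # eigenvalue = mean squared step of the unit-variance mode = 2 (1 - a1),
  # with a1 the lag-one autocorrelation (= 1 - 2p in expectation)
  sl <- split(coh$state, coh$patient_id)
  flip <- mean(unlist(purrr::map(sl, ~ diff(.x) != 0)))
  expect_equal(fit$eigen$values[fit$eigen$selected], 4 * flip,
               tolerance = 1e-3)
})

test_that("a constant feature yields a null direction that is never selected", {
  P <- barrier_chain()
  coh <- sample_chain(P, n_traj = 2, n_steps = 5000, seed = 37)
  coh2 <- dplyr::mutate(coh, f_const = 1)
  attr(coh2, "features") <- c(attr(coh, "features"), "f_const")
  expect_warning(fit <- fit_coordinate(coh2, mode = "unsupervised"),
                 "rank-deficient")
  proj <- project_coordinate(coh2, fit)
  expect_gt(sd(proj$x), 0.5)   # unit-variance mode, not the constant
  expect_gt(min(fit$eigen$values), 1e-8)
})

test_that("unsupervised solutions are invariant to linear re-parameterization of the basis", {
  P <- barrier_chain()
  coh <- sample_chain(P, n_traj = 2, n_steps = 5000, seed = 38)
  fit0 <- fit_coordinate(coh, mode = "unsupervised")
  x0 <- project_coordinate(coh, fit0)$x

  set.seed(39)
  Tm <- matrix(rnorm(16), 4, 4)
  while (abs(det(Tm)) < 0.1) Tm <- matrix(rnorm(16), 4, 4)
  X <- as.matrix(coh[attr(coh, "features")]) %*% Tm
  coh2 <- coh
  coh2[attr(coh, "features")] <- X
  fit1 <- suppressWarnings(fit_coordinate(coh2, mode = "unsupervised"))
  x1 <- project_coordinate(coh2, fit1)$x
  expect_gt(abs(cor(x0, x1)), 1 - 1e-8)
})

test_that("PCA baseline finds the dominant static direction", {
  set.seed(40)
  t_along <- rnorm(200)
  coh <- tibble::tibble(
    patient_id = rep(c("a", "b"), each = 100),
    day = rep(1:100, 2),
    f_1 = t_along + rnorm(200, sd = 0.01),
    f_2 = t_along + rnorm(200, sd = 0.01))
  attr(coh, "features") <- c("f_1", "f_2")
  fit <- fit_coordinate(coh, mode = "pca")
  w <- unname(fit$weights) / sqrt(sum(fit$weights^2))
  expect_equal(abs(w), rep(1 / sqrt(2), 2), tolerance = 0.01)

  iso <- dplyr::mutate(coh, f_1 = rnorm(200), f_2 = rnorm(200))
  attr(iso, "features") <- c("f_1", "f_2")
  fit_iso <- fit_coordinate(iso, mode = "pca")
  sdev <- fit_iso$diagnostics$sdev
  expect_lt(abs(sdev[1] / sdev[2] - 1), 0.3)
})

test_that("leave-one-out on duplicated trajectories reproduces the full fit", {
  P <- barrier_chain()
  one <- sample_chain(P, n_traj = 1, n_steps = 60, seed = 41)
  coh <- purrr::map_dfr(1:6, function(i) {
    dplyr::mutate(one, patient_id = paste0("copy_", i))
  })
  attr(coh, "features") <- attr(one, "features")
  cv <- loocv(coh, mode = "unsupervised")
  expect_true(all(cv$per_patient$correlation > 1 - 1e-6, na.rm = TRUE))
  expect_identical(cv$verdict, "stable")
  expect_error(loocv(one, mode = "unsupervised"), "at least 3")
})

test_that("tidy and glance summarize fits in the broom layout", {
  P <- barrier_chain()
  coh <- sample_chain(P, n_traj = 2, n_steps = 2000, seed = 42)
  fit <- fit_coordinate(coh, mode = "unsupervised")
  td <- tidy(fit)
  expect_named(td, c("term", "weight"))
  expect_equal(nrow(td), 4L)
  gl <- glance(fit)
  expect_equal(gl$mode, "unsupervised")
  expect_equal(gl$n_features, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})
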