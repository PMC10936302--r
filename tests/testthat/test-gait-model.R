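batch_mle <- function(X) {
  # independent batch oracle: sample mean and divide-by-n covariance
  n <- nrow(X)
  mu <- colMeans(X)
  C <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) C <- C + tcrossprod(X[i, ] - mu)
  list(mu = mu, Sigma = C / n)
}

test_that("recursive cell updates reproduce batch MLE estimates", {
  cell <- update_cell(NULL, c(1, 2))
  expect_equal(cell$n, 1L)
  expect_equal(cell$mu, c(1, 2))
  expect_equal(cell$Sigma, matrix(0, 2, 2))

  # one-dimensional pair: mean 1, MLE variance ((0-1)^2 + (2-1)^2)/2 = 1
  cell <- update_cell(update_cell(NULL, 0), 2)
  expect_equal(cell$mu, 1)
  expect_equal(cell$Sigma, matrix(1, 1, 1))

  set.seed(9)
  X <- matrix(rnorm(50 * 3), 50, 3)
  cell <- NULL
  for (i in 1:50) cell <- update_cell(cell, X[i, ])
  ref <- batch_mle(X)
  expect_equal(cell$mu, ref$mu, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cell$Sigma, ref$Sigma, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(update_cell(cell, c(1, 2)), "length")
})

test_that("model fit counts observations per cell and captures timing", {
  model <- fx_model()
  n_cycles <- model$timing$n_cycles
  for (p in GAIT_PHASES) {
    ns <- vapply(model$cells[[p]], `[[`, integer(1), "n")
    expect_true(all(abs(ns - n_cycles) <= 2))
  }
  expect_equal(model$timing$cycle_sd, 0)
  expect_equal(sum(model$max_k), 103L)   # 1.03 s cycle at 100 Hz
})

test_that("two identical noiseless cycles give zero covariance and timing sd", {
  quiet <- default_gait_template(noise_sd = 1e-12)
  st <- simulate_gait(quiet, 1.4, duration = 3.2, seed = 1)
  model <- fit_gait_model(st)
  sig_max <- max(vapply(GAIT_PHASES, function(p)
    max(vapply(model$cells[[p]], function(cl) max(abs(cl$Sigma)),
               numeric(1))), numeric(1)))
  expect_lt(sig_max, 1e-20)
  for (p in GAIT_PHASES) expect_equal(model$timing[[p]]$sd_k, 0)
})

test_that("squared Mahalanobis distance evaluates the quadratic form", {
  cell <- structure(list(n = 10L, mu = c(0, 0), Sigma = diag(2)),
                    class = "gaussian_cell")
  expect_equal(squared_mahalanobis(cell$mu, cell, ridge = 0), 0)
  expect_equal(squared_mahalanobis(c(3, 4), cell, ridge = 0), 25)
  cell2 <- structure(list(n = 10L, mu = c(1, 2), Sigma = diag(c(2, 8))),
                     class = "gaussian_cell")
  expect_equal(squared_mahalanobis(c(3, 6), cell2, ridge = 0), 4)
  expect_error(squared_mahalanobis(c(1, 2, 3), cell2), "dimension")
  # zero covariance is rescued by the ridge, not by failure
  cell3 <- structure(list(n = 1L, mu = c(0, 0), Sigma = matrix(0, 2, 2)),
                     class = "gaussian_cell")
  expect_equal(squared_mahalanobis(c(1, 0), cell3, ridge = 1e-6), 1e6)
  expect_error(squared_mahalanobis(c(1, 0), cell3, ridge = 0),
               "ill-conditioned")
})

test_that("squared distance is invariant under joint affine transforms", {
  set.seed(17)
  for (rep in 1:20) {
    m <- sample(2:4, 1)
    A <- matrix(rnorm(m * m), m)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(m * m), m)
    b <- rnorm(m)
    mu <- rnorm(m)
    L <- matrix(rnorm(m * m), m)
    Sigma <- crossprod(L) + diag(0.5, m)
    x <- rnorm(m)
    cell <- structure(list(n = 50L, mu = mu, Sigma = Sigma),
                      class = "gaussian_cell")
    cellT <- structure(list(n = 50L, mu = as.vector(A %*% mu + b),
                            Sigma = A %*% Sigma %*% t(A)),
                       class = "gaussian_cell")
    expect_equal(squared_mahalanobis(as.vector(A %*% x + b), cellT, ridge = 0),
                 squared_mahalanobis(x, cell, ridge = 0), tolerance = 1e-8)
  }
})

test_that("squared distances of in-model Gaussian data follow chi-squared", {
  set.seed(23)
  m <- 4
  L <- matrix(rnorm(16), 4)
  Sigma <- crossprod(L) + diag(0.5, 4)
  mu <- rnorm(4)
  X <- MASS::mvrnorm(4000, mu, Sigma)
  cell <- structure(list(n = 4000L, mu = mu, Sigma = Sigma),
                    class = "gaussian_cell")
  d2 <- apply(X, 1, squared_mahalanobis, cell = cell, ridge = 0)
  expect_equal(mean(d2), m, tolerance = 0.05)
  thr <- threshold_for_cdf(0.99, m)
  expect_equal(mean(d2 > thr), 0.01, tolerance = 0.5)
})

test_that("chi-squared CDF matches the even-dof closed form", {
  closed_form <- function(x, dof) {
    # 1 - exp(-x/2) * sum_{i < dof/2} (x/2)^i / i!
    i <- 0:(dof / 2 - 1)
    1 - exp(-x / 2) * sum((x / 2)^i / factorial(i))
  }
  for (dof in c(2L, 4L, 6L))
    for (x in c(0.1, 1, 4, 13.5, 30))
      expect_equal(chi2_cdf(x, dof), closed_form(x, dof), tolerance = 1e-10)
  expect_equal(chi2_cdf(0, 4), 0)
  d2 <- seq(0, 60, by = 0.5)
  expect_true(all(diff(chi2_cdf(d2, 4)) > 0))
  expect_gt(chi2_cdf(60, 4), 1 - 1e-9)
  expect_error(chi2_cdf(13.5, 0), "dof")
  expect_error(chi2_cdf(-1, 4), ">= 0")
})

test_that("threshold inversion round-trips and hits the dof-2 closed form", {
  expect_equal(threshold_for_cdf(chi2_cdf(13.5, 4), 4), 13.5,
               tolerance = 1e-9)
  expect_equal(threshold_for_cdf(0.5, 2), 2 * log(2), tolerance = 1e-12)
  expect_gt(threshold_for_cdf(1 - 1e-12, 4), threshold_for_cdf(0.999, 4))
  expect_error(threshold_for_cdf(1, 4), "between 0 and 1")
  expect_error(threshold_for_cdf(0, 4), "between 0 and 1")
})

test_that("model save/load round-trips and supports continued training", {
  model <- fit_gait_model(simulate_gait(fx_template(), 1.4, duration = 20,
                                        seed = 41))
  path <- withr::local_tempfile(fileext = ".json")
  save_gait_model(model, path)
  back <- load_gait_model(path)
  expect_equal(back$max_k, model$max_k)
  expect_equal(back$timing$cycle_mean, model$timing$cycle_mean,
               tolerance = 1e-12)
  for (p in GAIT_PHASES)
    for (k in seq_len(model$max_k[[p]])) {
      expect_equal(back$cells[[p]][[k]]$mu, model$cells[[p]][[k]]$mu,
                   tolerance = 1e-12)
      expect_equal(back$cells[[p]][[k]]$Sigma, model$cells[[p]][[k]]$Sigma,
                   tolerance = 1e-12)
    }

  # resumption: updating a reloaded cell equals uninterrupted training
  set.seed(6)
  xs <- matrix(rnorm(10 * 4, sd = 2), 10)
  direct <- back$cells$LSS[[5]]
  resumed <- model$cells$LSS[[5]]
  for (i in 1:10) {
    direct <- update_cell(direct, xs[i, ])
    resumed <- update_cell(resumed, xs[i, ])
  }
  expect_equal(resumed$mu, direct$mu, tolerance = 1e-12)
  expect_equal(resumed$Sigma, direct$Sigma, tolerance = 1e-12)

  # corrupted files are refused
  expect_error(load_gait_model(withr::local_tempfile(lines = "{}",
                                                     fileext = ".json")),
               "not a gait model")
  ser <- jsonlite::read_json(path)
  ser$timing <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(ser, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_gait_model(path2), "missing")
})
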