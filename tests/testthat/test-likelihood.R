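test_that("component likelihood is the closed-form Gaussian density", {
  # one cell with mu = 0, sigma = 1 observed at its mean: standard normal peak
  expect_equal(component_log_likelihood(0, counts = 1, mu_col = 0, sigma_col = 1),
               log(1 / sqrt(2 * pi)))

  # symmetry of the Gaussian around sum(N_i mu_ij)
  counts <- c(10, 20, 30)
  mu_col <- c(5, 7, 11); sigma_col <- c(1, 2, 3)
  center <- sum(counts * mu_col)
  for (d in c(0.5, 13, 250)) {
    expect_equal(
      component_log_likelihood(center + d, counts, mu_col, sigma_col),
      component_log_likelihood(center - d, counts, mu_col, sigma_col)
    )
  }

  # independent closed-form oracle on random parameters
  set.seed(411)
  mu_col <- runif(3, 10, 100); sigma_col <- runif(3, 1, 20)
  e <- sum(counts * mu_col) + 37
  expect_equal(
    component_log_likelihood(e, counts, mu_col, sigma_col),
    dnorm(e, mean = sum(counts * mu_col),
          sd = sqrt(sum(counts * sigma_col^2)), log = TRUE)
  )
})

test_that("aggregate likelihood is the sum of component log terms", {
  prof <- grid_profile(3, 3)
  counts <- c(40, 10, 25)
  obs <- aggregate_obs(as.numeric(counts %*% prof$mu_hat) * 1.02,
                       prof$attribute_names)
  # m = 1 reduces to a single component term
  prof1 <- cell_line_profile(prof$cell_line_names, prof$mu_hat[, 1, drop = FALSE],
                             prof$sigma_hat[, 1, drop = FALSE],
                             prof$attribute_names[1])
  obs1 <- aggregate_obs(obs$e_sum[1], prof$attribute_names[1])
  expect_equal(aggregate_log_likelihood(obs1, counts, prof1),
               component_log_likelihood(obs$e_sum[1], counts,
                                        prof$mu_hat[, 1], prof$sigma_hat[, 1]))

  # sum-of-logs equals product of exponentiated component terms
  per_attr <- vapply(1:3, function(j)
    component_log_likelihood(obs$e_sum[j], counts, prof$mu_hat[, j],
                             prof$sigma_hat[, j]), numeric(1))
  expect_equal(aggregate_log_likelihood(obs, counts, prof), sum(per_attr))
  expect_equal(exp(aggregate_log_likelihood(obs, counts, prof) -
                     sum(per_attr)), 1)

  # consistently permuting attribute columns leaves the value unchanged
  perm <- c(3, 1, 2)
  obs_p <- aggregate_obs(obs$e_sum[perm], prof$attribute_names[perm])
  expect_equal(aggregate_log_likelihood(obs_p, counts, prof),
               aggregate_log_likelihood(obs, counts, prof))
})

test_that("attribute mismatches and degenerate variances are flagged", {
  prof <- grid_profile(2, 2)
  obs_bad <- aggregate_obs(c(1, 2), c("a1", "wrong"))
  expect_error(aggregate_log_likelihood(obs_bad, c(1, 1), prof),
               "do not match profile attributes")
  obs <- aggregate_obs(c(100, 100), prof$attribute_names)
  expect_error(aggregate_log_likelihood(obs, c(0, 0), prof, var_floor = 0),
               "degenerate variance")
  # with the default floor, all-zero counts are merely a terrible fit
  expect_lt(aggregate_log_likelihood(obs, c(0, 0), prof), -1e6)
})

test_that("posterior support and prior cancellation behave as specified", {
  prof <- grid_profile(2, 2)
  counts <- c(50, 80)
  obs <- aggregate_obs(as.numeric(counts %*% prof$mu_hat), prof$attribute_names)

  # outside the prior support the log-posterior is exactly log zero
  expect_identical(
    log_unnormalized_posterior(c(-1, 80), obs, prof, prior_config()), -Inf)
  expect_identical(
    log_unnormalized_posterior(c(50, 2e6), obs, prof, prior_config(1e6)), -Inf)

  # inside support it equals the aggregate log-likelihood ...
  expect_equal(log_unnormalized_posterior(counts, obs, prof, prior_config()),
               aggregate_log_likelihood(obs, counts, prof))

  # ... and differences are exactly free of M
  other <- c(55, 75)
  for (M in c(1e4, 1e8)) {
    p <- prior_config(M)
    expect_identical(
      log_unnormalized_posterior(counts, obs, prof, p) -
        log_unnormalized_posterior(other, obs, prof, p),
      log_unnormalized_posterior(counts, obs, prof, prior_config(1e6)) -
        log_unnormalized_posterior(other, obs, prof, prior_config(1e6))
    )
  }
})

test_that("single-line likelihood has a unique maximizer that tracks the data", {
  prof <- unit_profile()  # mu = sigma = 100
  grid <- seq(1, 2000, by = 1)
  argmax_for <- function(e_sumj) {
    obs <- aggregate_obs(c(x = e_sumj))
    ll <- vapply(grid, function(N) aggregate_log_likelihood(obs, N, prof),
                 numeric(1))
    expect_equal(sum(diff(sign(diff(ll))) != 0), 1)  # single interior peak
    grid[which.max(ll)]
  }
  maxima <- vapply(c(20000, 50000, 120000), argmax_for, numeric(1))
  expect_true(all(diff(maxima) > 0))  # larger observed sum, larger count
})

test_that("exponentiated likelihood is integrable on a 2-D grid", {
  prof <- toy_profile()
  obs <- generate_aggregate(prof$mu_hat, 0.1, c(200, 800), seed = 412,
                            attribute_names = prof$attribute_names)
  g1 <- seq(100, 300, by = 2); g2 <- seq(700, 900, by = 2)
  ll <- outer(g1, g2, Vectorize(function(a, b)
    aggregate_log_likelihood(obs, c(a, b), prof)))
  mass <- sum(exp(ll - max(ll))) * 4  # cell area 2 x 2
  expect_true(is.finite(mass) && mass > 0)
})
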