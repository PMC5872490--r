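test_that("the uniform proposal is centered and symmetric", {
  set.seed(421)
  cur <- 250
  # degenerate limit: tiny half-width stays at the current value
  expect_equal(propose_count(cur, 1e-12), cur, tolerance = 1e-9)

  delta <- 40
  props <- replicate(1e5, propose_count(cur, delta))
  # uniform moments: mean within 3 standard errors of the center
  expect_lt(abs(mean(props) - cur), 3 * delta / sqrt(3 * 1e5))
  expect_true(all(props > cur - delta & props < cur + delta))
  # displacement distribution is symmetric: it is uniform(-delta, delta)
  ks <- suppressWarnings(stats::ks.test(props - cur, "punif", -delta, delta))
  expect_gt(ks$p.value, 0.001)
  expect_error(propose_count(cur, 0), "delta must be positive")
})

test_that("acceptance ratio reduces to a posterior ratio independent of M", {
  prof <- toy_profile()
  counts <- c(200, 800)
  obs <- aggregate_obs(as.numeric(counts %*% prof$mu_hat), prof$attribute_names)

  expect_equal(acceptance_ratio(counts, counts, obs, prof), 1)

  prop <- c(210, 800)
  r_small <- acceptance_ratio(prop, counts, obs, prof, prior_config(1e4))
  r_large <- acceptance_ratio(prop, counts, obs, prof, prior_config(1e8))
  expect_identical(r_small, r_large)

  # brute-force likelihood-ratio oracle from the closed-form Gaussian
  direct <- function(N) {
    mean_v <- as.numeric(N %*% prof$mu_hat)
    var_v <- as.numeric(N %*% prof$sigma_hat^2)
    sum(dnorm(obs$e_sum, mean_v, sqrt(var_v), log = TRUE))
  }
  expect_equal(r_small, exp(direct(prop) - direct(counts)))

  # out-of-support proposals are rejected outright ...
  expect_identical(acceptance_ratio(c(-5, 800), counts, obs, prof), 0)
  expect_identical(acceptance_ratio(c(200, 2e6), counts, obs, prof), 0)
  # ... while an out-of-support current state means the chain is corrupt
  expect_error(acceptance_ratio(prop, c(-5, 800), obs, prof), "corrupted")
})

test_that("chains are reproducible and confined to the sampler support", {
  prof <- toy_profile()
  obs <- generate_aggregate(prof$mu_hat, 0.1, c(200, 800), seed = 422,
                            attribute_names = prof$attribute_names)
  cfg <- sampler_config(n_burnin = 200, n_samples = 500, seed = 99)
  ch1 <- run_chain(obs, prof, cfg)
  ch2 <- run_chain(obs, prof, cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(dim(ch1$samples), c(500L, 2L))
  expect_true(all(ch1$samples >= cfg$eps_n & ch1$samples <= cfg$prior$upper_bound))
  expect_true(all(ch1$acceptance_rate >= 0 & ch1$acceptance_rate <= 1))
})

test_that("chain samples match the grid-normalized posterior (n = 1)", {
  prof <- unit_profile()
  obs <- aggregate_obs(c(x = 50000))
  ch <- run_chain(obs, prof,
                  sampler_config(n_burnin = 2000, n_samples = 20000, seed = 11))
  s <- ch$samples[, 1]

  grid <- seq(300, 700, by = 0.5)
  lp <- vapply(grid, function(N) aggregate_log_likelihood(obs, N, prof),
               numeric(1))
  post <- exp(lp - max(lp)); post <- post / sum(post)

  breaks <- seq(300, 700, by = 10)
  p_chain <- as.numeric(table(cut(s, breaks))) / length(s)
  p_grid <- as.numeric(tapply(post, cut(grid, breaks), sum))
  p_grid[is.na(p_grid)] <- 0
  tv <- 0.5 * sum(abs(p_chain - p_grid)) + 0.5 * (1 - sum(p_chain))
  expect_lt(tv, 0.05)
})

test_that("acceptance follows min(r, 1) in the two regimes", {
  # near-flat posterior (huge sigma): r ~ 1, in-support proposals all accepted
  prof_flat <- suppressWarnings(
    cell_line_profile("A", matrix(1), matrix(1e6), "x"))
  obs <- aggregate_obs(c(x = 500))
  cfg <- sampler_config(delta = 1, n_burnin = 100, n_samples = 2000,
                        seed = 7, prior = prior_config(1e6), init = 500)
  ch <- run_chain(obs, prof_flat, cfg)
  expect_gt(ch$acceptance_rate[[1]], 0.95)

  # sharply peaked posterior with a huge proposal width: most moves rejected
  prof_sharp <- cell_line_profile("A", matrix(100), matrix(1), "x")
  obs2 <- aggregate_obs(c(x = 50000))
  cfg2 <- sampler_config(delta = 5000, n_burnin = 100, n_samples = 2000,
                         seed = 8, init = 500)
  ch2 <- run_chain(obs2, prof_sharp, cfg2)
  expect_lt(ch2$acceptance_rate[[1]], 0.05)
})

test_that("adaptive proposal widths land in a healthy acceptance range", {
  # reference 10-line design, shortened chain: per-component acceptance
  # after burn-in adaptation should be neither glacial nor jammed
  mu <- cyclic_mean_matrix(100 * 1:10)
  cbc <- generate_cell_by_cell(mu, 1, 500, seed = 423)
  prof <- estimate_profile(cbc)
  obs <- generate_aggregate(mu, 1, rep(500, 10), seed = 424,
                            attribute_names = prof$attribute_names)
  ch <- run_chain(obs, prof,
                  sampler_config(n_burnin = 1000, n_samples = 1000, seed = 425))
  expect_true(all(ch$acceptance_rate >= 0.1 & ch$acceptance_rate <= 0.7))
})

test_that("chain CSV and JSON sidecar round-trip the essentials", {
  prof <- toy_profile()
  obs <- aggregate_obs(as.numeric(c(200, 800) %*% prof$mu_hat),
                       prof$attribute_names)
  ch <- run_chain(obs, prof, sampler_config(n_burnin = 50, n_samples = 100,
                                            seed = 5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_chain(ch, csv)
  back <- utils::read.csv(csv)
  expect_identical(dim(back), c(100L, 2L))
  meta <- jsonlite::fromJSON(paste0(csv, ".json"))
  expect_identical(meta$seed, 5L)
  expect_identical(meta$n_samples, 100L)
})
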