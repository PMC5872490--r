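#' Sampler configuration
#'
#' Settings for the Metropolis-within-Gibbs chain over the counts
#' vector. Each sweep updates every component once with a symmetric
#' uniform proposal on `(N_i - delta_i, N_i + delta_i)` accepted with
#' probability `min(r, 1)`.
#'
#' Proposal half-widths matter: too small and the chain crawls to
#' stationarity with highly correlated samples; too large and almost
#' every proposal is rejected. The default `delta = "auto"` adapts each
#' component's half-width during burn-in only (doubling/halving toward
#' 30--50% acceptance) and freezes it afterwards, so the retained chain
#' is a valid fixed-kernel Metropolis chain.
#'
#' @param delta Proposal half-width in cells: `"auto"` (default) for
#'   burn-in adaptation, or a positive numeric (recycled per component)
#'   used unchanged.
#' @param n_burnin Number of initial sweeps discarded (default 5000).
#' @param n_samples Number of retained sweeps `k` (default 10000).
#' @param thin Keep every `thin`-th sweep after burn-in (default 1).
#' @param seed Optional integer RNG seed; a seeded run is exactly
#'   reproducible.
#' @param prior A [prior_config]; default upper bound `M = 1e6` cells.
#' @param init Initialization: `"nnls"` (default) solves the mean
#'   equations `e_sum ~ t(mu_hat) N` by nonnegative least squares so
#'   the chain starts near the posterior mass; `"flat"` starts every
#'   component at `sum(e_sum) / sum(mu_hat)`; or a numeric vector of
#'   starting counts.
#' @param eps_n Positivity floor (cells): counts are confined to
#'   `[eps_n, M]` inside the sampler so the model variance stays
#'   positive. Default `1e-3`.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(delta = "auto", n_burnin = 5000L, n_samples = 10000L,
                           thin = 1L, seed = NULL, prior = prior_config(),
                           init = "nnls", eps_n = 1e-3) {
  if (is.numeric(delta)) {
    if (any(delta <= 0)) stop("delta must be positive", call. = FALSE)
  } else if (!identical(delta, "auto")) {
    stop("delta must be \"auto\" or a positive numeric", call. = FALSE)
  }
  stopifnot(n_burnin >= 0, n_samples >= 2, thin >= 1,
            inherits(prior, "prior_config"), eps_n > 0)
  structure(list(delta = delta, n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples), thin = as.integer(thin),
                 seed = seed, prior = prior, init = init, eps_n = eps_n),
            class = "sampler_config")
}

#' Symmetric uniform proposal
#'
#' Draws a proposal uniformly on `(current - delta, current + delta)`.
#' The proposal density is symmetric in its arguments, which is what
#' lets the Metropolis acceptance ratio reduce to a posterior ratio.
#'
#' @param current Current value(s).
#' @param delta Positive half-width(s), recycled against `current`.
#' @return Numeric vector of proposals, one per element of `current`.
#' @export
propose_count <- function(current, delta) {
  if (any(delta <= 0)) stop("delta must be positive", call. = FALSE)
  stats::runif(length(current), current - delta, current + delta)
}

#' Metropolis acceptance ratio for a single-component move
#'
#' `r = P(proposal | E_sum, ...) / P(current | E_sum, ...)`, computed
#' from the unnormalized log-posterior -- the uniform-prior constant
#' `1/M` cancels exactly, so `r` does not depend on `M`. Proposals
#' outside the sampler support `[eps_n, M]` get `r = 0` (rejected); a
#' current state outside support indicates chain corruption and is an
#' error.
#'
#' @param proposal,current Full counts vectors differing in one
#'   component.
#' @param obs An [aggregate_obs].
#' @param profile A [cell_line_profile].
#' @param prior A [prior_config].
#' @param eps_n Positivity floor (cells), as in [sampler_config()].
#' @return The acceptance ratio `r >= 0`.
#' @export
acceptance_ratio <- function(proposal, current, obs, profile,
                             prior = prior_config(), eps_n = 1e-3) {
  if (any(current < eps_n | current > prior$upper_bound))
    stop("current state lies outside the sampler support [eps_n, M]; ",
         "the chain is corrupted", call. = FALSE)
  if (any(proposal < eps_n | proposal > prior$upper_bound)) return(0)
  log_r <- log_unnormalized_posterior(proposal, obs, profile, prior) -
    log_unnormalized_posterior(current, obs, profile, prior)
  exp(log_r)
}

# NNLS-or-flat starting point, clipped to the sampler support.
initial_counts <- function(init, e_sum, mu, eps_n, upper) {
  n <- nrow(mu)
  x <- if (is.numeric(init)) {
    rep_len(as.numeric(init), n)
  } else if (identical(init, "nnls")) {
    fit <- tryCatch(pracma::lsqnonneg(t(mu), e_sum)$x, error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit))) rep(sum(e_sum) / sum(mu), n) else fit
  } else {
    rep(sum(e_sum) / sum(mu), n)
  }
  pmin(pmax(x, eps_n), upper)
}

#' Run the Metropolis-within-Gibbs chain
#'
#' Simulates the posterior of the counts vector `N` given one aggregate
#' observation and a cell-line profile. Each sweep visits the
#' components in order `1..n`; component `i` receives a uniform
#' proposal on `(N_i - delta_i, N_i + delta_i)` and is accepted with
#' probability `min(r, 1)` where `r` is the posterior ratio (the
#' uniform-prior bound `M` cancels). The first `n_burnin` sweeps are
#' discarded, then every `thin`-th sweep is retained until `n_samples`
#' rows are collected. Runs are exactly reproducible given
#' `config$seed`.
#'
#' @param obs An [aggregate_obs].
#' @param profile A [cell_line_profile].
#' @param config A [sampler_config()].
#' @return An object of class `posterior_chain`: list with `samples`
#'   (`n_samples x n` matrix, columns named by cell line),
#'   `acceptance_rate` (per component, over the retained phase),
#'   `delta` (final per-component half-widths), `init`, `config` and
#'   `seed`.
#' @export
run_chain <- function(obs, profile, config = sampler_config()) {
  stopifnot(inherits(config, "sampler_config"))
  e_sum <- align_obs(obs, profile)
  mu <- unname(profile$mu_hat)
  s2 <- unname(profile$sigma_hat^2)
  n <- nrow(mu); m <- ncol(mu)
  eps_n <- config$eps_n
  upper <- config$prior$upper_bound
  if (!is.null(config$seed)) set.seed(config$seed)

  if (any(colSums(s2) <= 0))
    warning("attribute(s) ",
            paste(profile$attribute_names[colSums(s2) <= 0], collapse = ", "),
            " have zero variance in every cell line; a variance floor is applied",
            call. = FALSE)
  floor_vec <- variance_floor(e_sum)

  cur <- initial_counts(config$init, e_sum, mu, eps_n, upper)
  adapt <- identical(config$delta, "auto")
  delta <- if (adapt) pmax(0.1 * cur, 1) else rep_len(config$delta, n)

  loglik <- function(mean_vec, var_vec) {
    vv <- pmax(var_vec, floor_vec)
    sum(stats::dnorm(e_sum, mean_vec, sqrt(vv), log = TRUE))
  }
  mean_vec <- as.numeric(cur %*% mu)
  var_vec <- as.numeric(cur %*% s2)
  cur_ll <- loglik(mean_vec, var_vec)

  n_burnin <- config$n_burnin
  n_keep <- config$n_samples
  thin <- config$thin
  total <- n_burnin + n_keep * thin
  samples <- matrix(NA_real_, n_keep, n,
                    dimnames = list(NULL, profile$cell_line_names))
  acc_sampling <- integer(n)
  acc_window <- integer(n)
  window <- 50L  # sweeps per burn-in adaptation step
  kept <- 0L

  for (sweep in seq_len(total)) {
    for (i in seq_len(n)) {
      prop_i <- stats::runif(1L, cur[i] - delta[i], cur[i] + delta[i])
      if (prop_i < eps_n || prop_i > upper) next
      d <- prop_i - cur[i]
      new_mean <- mean_vec + d * mu[i, ]
      new_var <- var_vec + d * s2[i, ]
      new_ll <- loglik(new_mean, new_var)
      if (log(stats::runif(1L)) < new_ll - cur_ll) {
        cur[i] <- prop_i
        mean_vec <- new_mean
        var_vec <- new_var
        cur_ll <- new_ll
        if (sweep > n_burnin) acc_sampling[i] <- acc_sampling[i] + 1L
        else acc_window[i] <- acc_window[i] + 1L
      }
    }
    if (sweep <= n_burnin && adapt && sweep %% window == 0L) {
      rate <- acc_window / window
      delta <- ifelse(rate > 0.5, delta * 2,
                      ifelse(rate < 0.3, delta / 2, delta))
      delta <- pmin(pmax(delta, 1e-6), upper)
      acc_window <- integer(n)
    }
    if (sweep %% 500L == 0L) {  # guard against incremental drift
      mean_vec <- as.numeric(cur %*% mu)
      var_vec <- as.numeric(cur %*% s2)
      cur_ll <- loglik(mean_vec, var_vec)
    }
    if (sweep > n_burnin && (sweep - n_burnin) %% thin == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- cur
    }
  }

  structure(
    list(samples = samples,
         acceptance_rate = stats::setNames(acc_sampling / (n_keep * thin),
                                           profile$cell_line_names),
         delta = stats::setNames(delta, profile$cell_line_names),
         init = stats::setNames(initial_counts(config$init, e_sum, mu, eps_n, upper),
                                profile$cell_line_names),
         config = config, seed = config$seed),
    class = "posterior_chain"
  )
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("Posterior chain: ", nrow(x$samples), " retained sweeps x ",
      ncol(x$samples), " cell lines\n", sep = "")
  cat("Acceptance rate (retained phase):\n")
  print(round(x$acceptance_rate, 3))
  invisible(x)
}

#' Write a chain to CSV with a JSON sidecar
#'
#' One row per retained sweep, one column per cell line; the sidecar
#' records the seed, configuration and acceptance rates.
#'
#' @param chain A `posterior_chain` from [run_chain()].
#' @param csv_path,json_path Output paths (the sidecar defaults to the
#'   CSV path with `.json` appended).
#' @return `csv_path`, invisibly.
#' @export
write_chain <- function(chain, csv_path, json_path = paste0(csv_path, ".json")) {
  stopifnot(inherits(chain, "posterior_chain"))
  utils::write.csv(as.data.frame(chain$samples), csv_path, row.names = FALSE)
  meta <- list(
    seed = chain$seed,
    acceptance_rate = as.list(chain$acceptance_rate),
    delta = as.list(chain$delta),
    n_burnin = chain$config$n_burnin,
    n_samples = chain$config$n_samples,
    thin = chain$config$thin,
    prior_upper_bound = chain$config$prior$upper_bound
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             json_path)
  invisible(csv_path)
}
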