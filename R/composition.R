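#' Composition ratio
#'
#' Normalizes a counts vector to the simplex: `pi = N / sum(N)`, the
#' fraction of the mixture contributed by each cell line.
#'
#' @param counts Numeric vector of non-negative counts with a positive
#'   sum.
#' @return Numeric vector summing to 1 (names preserved).
#' @export
#' @examples
#' composition_ratio(c(3314, 3710, 2070))
composition_ratio <- function(counts) {
  counts <- if (is.list(counts)) as.numeric(counts) else counts
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  s <- sum(counts)
  if (s <= 0)
    stop("composition ratio is undefined for an all-zero counts vector",
         call. = FALSE)
  counts / s
}

#' Root square error between composition vectors
#'
#' The Euclidean distance
#' \deqn{e = \sqrt{\sum_i (\pi_i - \hat\pi_i)^2}}
#' between a reference and an estimated composition. Unlike a root
#' *mean* square error it does not shrink automatically as the number
#' of cell lines grows (the ratios are constrained to sum to 1).
#'
#' @param pi_true,pi_est Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
#' @examples
#' root_square_error(c(0.364, 0.408, 0.228), c(0.490, 0.508, 0.002))
root_square_error <- function(pi_true, pi_est) {
  if (length(pi_true) != length(pi_est))
    stop("pi_true and pi_est must have the same length", call. = FALSE)
  sqrt(sum((pi_true - pi_est)^2))
}

#' Estimate the composition of a heterogeneous mixture
#'
#' The end-to-end estimator: runs the Metropolis-within-Gibbs chain
#' ([run_chain()]) on the aggregate observation, extracts each
#' component's marginal posterior density and MAP by Gaussian KDE with
#' the plug-in bandwidth ([map_estimate()]), and normalizes the MAP
#' counts into composition ratios. Fully deterministic given
#' `config$seed`.
#'
#' The reported count vector is the vector of per-component *marginal*
#' MAPs; the joint posterior mode is not computed.
#'
#' @param obs An [aggregate_obs].
#' @param profile A [cell_line_profile].
#' @param config A [sampler_config()].
#' @param n_grid KDE grid size per component (default 2048).
#' @return An object of class `composition_estimate` with elements
#'   `n_hat` (named MAP counts), `pi_hat` (composition ratios),
#'   `densities` (list of `marginal_density`), `chain` (the
#'   [run_chain()] result) and `call`. Methods: `print`, `summary`,
#'   `coef`, `plot`, `as.data.frame`.
#' @export
estimate_composition <- function(obs, profile, config = sampler_config(),
                                 n_grid = 2048L) {
  chain <- run_chain(obs, profile, config)
  maps <- lapply(seq_len(ncol(chain$samples)),
                 function(i) map_estimate(chain$samples[, i], n_grid = n_grid))
  n_hat <- stats::setNames(vapply(maps, `[[`, numeric(1L), "map"),
                           profile$cell_line_names)
  structure(
    list(n_hat = n_hat,
         pi_hat = composition_ratio(n_hat),
         densities = stats::setNames(lapply(maps, `[[`, "density"),
                                     profile$cell_line_names),
         chain = chain,
         call = match.call()),
    class = "composition_estimate"
  )
}

#' @export
print.composition_estimate <- function(x, digits = 3L, ...) {
  cat("Composition estimate (", length(x$n_hat), " cell lines, ",
      nrow(x$chain$samples), " posterior samples)\n\n", sep = "")
  tab <- data.frame(
    cell_line = names(x$n_hat),
    n_hat = round(unname(x$n_hat)),
    pi_hat = round(unname(x$pi_hat), digits),
    row.names = NULL
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.composition_estimate <- function(object, type = c("counts", "ratio"), ...) {
  type <- match.arg(type)
  if (type == "counts") object$n_hat else object$pi_hat
}

#' Summarize a composition estimate
#'
#' Adds per-component empirical chain quantiles (a convenience interval
#' taken directly from the retained samples, not a density-based
#' credible interval), KDE bandwidths and sampler acceptance rates to
#' the MAP table.
#'
#' @param object A `composition_estimate`.
#' @param level Central interval coverage for the chain quantiles
#'   (default 0.95).
#' @param ... Unused.
#' @export
summary.composition_estimate <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  qs <- t(apply(object$chain$samples, 2L, stats::quantile, probs = c(a, 1 - a)))
  tab <- data.frame(
    cell_line = names(object$n_hat),
    n_hat = unname(object$n_hat),
    pi_hat = unname(object$pi_hat),
    ci_low = qs[, 1L],
    ci_high = qs[, 2L],
    bandwidth = vapply(object$densities, `[[`, numeric(1L), "bandwidth"),
    acceptance = unname(object$chain$acceptance_rate),
    row.names = NULL
  )
  structure(list(table = tab, level = level,
                 n_samples = nrow(object$chain$samples)),
            class = "summary.composition_estimate")
}

#' @export
print.summary.composition_estimate <- function(x, digits = 3L, ...) {
  cat("Composition estimate from ", x$n_samples, " posterior samples\n",
      "(intervals are empirical chain quantiles, central ",
      format(100 * x$level), "%)\n\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, digits = digits + 2L)
  tab$pi_hat <- round(x$table$pi_hat, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.composition_estimate <- function(x, ...) {
  summary(x)$table
}

#' Plot marginal posterior densities
#'
#' One panel per cell line showing the KDE of the marginal posterior of
#' its count, with the MAP marked.
#'
#' @param x A `composition_estimate`.
#' @param components Which cell lines to plot (names or indices);
#'   default all.
#' @param ... Passed to [plot.marginal_density()].
#' @export
plot.composition_estimate <- function(x, components = NULL, ...) {
  dens <- x$densities
  if (!is.null(components)) dens <- dens[components]
  nc <- ceiling(sqrt(length(dens)))
  nr <- ceiling(length(dens) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(dens)) {
    plot(dens[[nm]], main = nm, ...)
    graphics::abline(v = x$n_hat[[nm]], lty = 2)
  }
  invisible(x)
}

#' Write a composition estimate to JSON
#'
#' Per cell line: MAP count, composition ratio and the chain-quantile
#' interval from [summary.composition_estimate()].
#'
#' @param estimate A `composition_estimate`.
#' @param path Optional output path; if `NULL` the JSON string is
#'   returned.
#' @param level Interval coverage (default 0.95).
#' @return The JSON string (invisibly when written to `path`).
#' @export
estimate_to_json <- function(estimate, path = NULL, level = 0.95) {
  tab <- summary(estimate, level = level)$table
  obj <- stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
    list(n_hat = tab$n_hat[i], pi_hat = tab$pi_hat[i],
         ci_low = tab$ci_low[i], ci_high = tab$ci_high[i])
  }), tab$cell_line)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
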