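#' Aggregate attribute observation
#'
#' The low-cost measurement of a mixture: for each attribute, the sum
#' of that attribute's value over every cell in the tissue (e.g. total
#' red fluorescence). One such length-`m` vector is all the mixture
#' data the estimator needs.
#'
#' @param values Numeric vector of summed attribute values.
#' @param attribute_names Character vector of attribute names; defaults
#'   to `names(values)`.
#' @return An object of class `aggregate_obs`.
#' @export
#' @examples
#' aggregate_obs(c(red = 5e6, green = 4e6, blue = 9e6))
aggregate_obs <- function(values, attribute_names = names(values)) {
  force(attribute_names)
  values <- as.numeric(values)
  if (!all(is.finite(values)))
    stop("aggregate observation contains non-finite values", call. = FALSE)
  if (is.null(attribute_names))
    attribute_names <- paste0("attr", seq_along(values))
  attribute_names <- as.character(attribute_names)
  if (length(attribute_names) != length(values))
    stop("attribute_names length does not match values", call. = FALSE)
  names(values) <- attribute_names
  structure(list(e_sum = values, attribute_names = attribute_names),
            class = "aggregate_obs")
}

#' @export
print.aggregate_obs <- function(x, ...) {
  cat("Aggregate observation (", length(x$e_sum), " attributes):\n", sep = "")
  print(x$e_sum, ...)
  invisible(x)
}

#' Read an aggregate observation from CSV or JSON
#'
#' CSV files need columns `attribute` and `value`; JSON files an object
#' mapping attribute names to values (or `attribute_names` / `values`
#' fields).
#'
#' @param path File path (`.json` is detected by extension).
#' @return An [aggregate_obs].
#' @export
read_aggregate <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (all(c("attribute_names", "values") %in% names(obj)))
      return(aggregate_obs(obj$values, obj$attribute_names))
    return(aggregate_obs(unlist(obj)))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("attribute", "value") %in% names(df)))
    stop("aggregate file '", path, "' must have columns 'attribute' and 'value'",
         call. = FALSE)
  aggregate_obs(as.numeric(df$value), as.character(df$attribute))
}

#' Uniform prior configuration for cell counts
#'
#' Each count is given an independent uniform prior on `[0, M]` with
#' `M` arbitrarily large; `M` cancels in the Metropolis acceptance
#' ratio, so its exact value does not influence the posterior samples
#' as long as it comfortably exceeds any plausible count.
#'
#' @param upper_bound Positive upper bound `M` (cells). Default `1e6`.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(upper_bound = 1e6) {
  stopifnot(is.numeric(upper_bound), length(upper_bound) == 1L,
            is.finite(upper_bound), upper_bound > 0)
  structure(list(upper_bound = upper_bound), class = "prior_config")
}

# Per-attribute variance floor used when Sum_i N_i sigma_ij^2 is not
# positive (degenerate profile column or all-zero counts): relative to
# the observation scale so it is negligible whenever real variance exists.
variance_floor <- function(e_sumj) pmax(1e-12 * e_sumj^2, 1e-300)

#' Log-likelihood of one aggregate attribute component
#'
#' By the central limit theorem the summed attribute `j` of a mixture
#' with counts `N` is approximately Gaussian with mean
#' \eqn{\sum_i N_i \mu_{ij}} and variance \eqn{\sum_i N_i \sigma_{ij}^2}.
#' This evaluates the log of that Gaussian density at the observed sum.
#'
#' @param e_sumj Observed summed value of attribute `j`.
#' @param counts Numeric vector of `n` non-negative cell counts.
#' @param mu_col,sigma_col Length-`n` mean and SD of attribute `j`
#'   across the cell lines.
#' @param var_floor Variance floor substituted when the model variance
#'   is not positive; `NULL` (default) uses a floor relative to
#'   `e_sumj`, `0` disables flooring and makes a degenerate variance an
#'   error.
#' @return The log density (a single number).
#' @export
#' @examples
#' component_log_likelihood(0, counts = 1, mu_col = 0, sigma_col = 1)
component_log_likelihood <- function(e_sumj, counts, mu_col, sigma_col,
                                     var_floor = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mean_j <- sum(counts * mu_col)
  var_j <- sum(counts * sigma_col^2)
  if (var_j <= 0) {
    if (!is.null(var_floor) && identical(var_floor, 0))
      stop("degenerate variance: sum(N_i * sigma_ij^2) is not positive ",
           "and the variance floor is disabled", call. = FALSE)
    var_j <- if (is.null(var_floor)) variance_floor(e_sumj) else var_floor
  }
  unname(stats::dnorm(e_sumj, mean = mean_j, sd = sqrt(var_j), log = TRUE))
}

# Align an aggregate observation's attributes with a profile's; errors
# on mismatch, reorders on a consistent permutation.
align_obs <- function(obs, profile) {
  stopifnot(inherits(obs, "aggregate_obs"), inherits(profile, "cell_line_profile"))
  if (identical(obs$attribute_names, profile$attribute_names)) return(obs$e_sum)
  idx <- match(profile$attribute_names, obs$attribute_names)
  if (anyNA(idx) || length(obs$attribute_names) != length(profile$attribute_names))
    stop("aggregate observation attributes (",
         paste(obs$attribute_names, collapse = ", "),
         ") do not match profile attributes (",
         paste(profile$attribute_names, collapse = ", "), ")", call. = FALSE)
  obs$e_sum[idx]
}

#' Log-likelihood of a full aggregate observation
#'
#' The attributes are modelled as independent, so the log-likelihood of
#' the length-`m` aggregate vector is the sum over attributes of
#' [component_log_likelihood()]. All likelihood arithmetic is done in
#' log space: with many attributes and thousands of cells the raw
#' densities underflow double precision.
#'
#' @param obs An [aggregate_obs]; its attributes must match the
#'   profile's (a consistent reordering is accepted).
#' @param counts Numeric vector of `n` non-negative cell counts.
#' @param profile A [cell_line_profile].
#' @inheritParams component_log_likelihood
#' @return The total log-likelihood (a single number).
#' @export
aggregate_log_likelihood <- function(obs, counts, profile, var_floor = NULL) {
  e_sum <- align_obs(obs, profile)
  counts <- as.numeric(counts)
  if (length(counts) != length(profile$cell_line_names))
    stop("counts length does not match the number of cell lines", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mean_vec <- as.numeric(counts %*% profile$mu_hat)
  var_vec <- as.numeric(counts %*% (profile$sigma_hat^2))
  bad <- var_vec <= 0
  if (any(bad)) {
    if (!is.null(var_floor) && identical(var_floor, 0))
      stop("degenerate variance on attribute(s) ",
           paste(profile$attribute_names[bad], collapse = ", "), call. = FALSE)
    fl <- if (is.null(var_floor)) variance_floor(e_sum) else rep_len(var_floor, length(e_sum))
    var_vec[bad] <- fl[bad]
  }
  sum(stats::dnorm(e_sum, mean = mean_vec, sd = sqrt(var_vec), log = TRUE))
}

#' Unnormalized log-posterior of the counts
#'
#' With independent uniform priors on `[0, M]` the full conditional of
#' each count is proportional to the aggregate likelihood times `1/M`;
#' the constant cancels in any posterior ratio, so this returns the
#' aggregate log-likelihood inside the prior support and `-Inf`
#' (log-zero) outside it. Out-of-support is a value, not an error.
#'
#' @inheritParams aggregate_log_likelihood
#' @param prior A [prior_config].
#' @return Log of the unnormalized posterior density; `-Inf` when any
#'   count lies outside `[0, M]`.
#' @export
log_unnormalized_posterior <- function(counts, obs, profile,
                                       prior = prior_config(), var_floor = NULL) {
  stopifnot(inherits(prior, "prior_config"))
  counts <- as.numeric(counts)
  if (any(counts < 0 | counts > prior$upper_bound)) return(-Inf)
  aggregate_log_likelihood(obs, counts, profile, var_floor = var_floor)
}
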