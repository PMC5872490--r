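#' Cyclic mean matrix
#'
#' Builds the square attribute-mean matrix used in the simulation
#' study: row 1 is `first_row`, and each subsequent row is the previous
#' one rotated left by one position (so with first row
#' `[100 200 ... 1000]`, row 2 begins 200). Every cell line therefore
#' contributes to every attribute while keeping distinct profiles.
#'
#' @param first_row Numeric vector of positive attribute means; the
#'   construction requires `n = m` (as many cell lines as attributes).
#' @return An `m x m` matrix.
#' @export
#' @examples
#' cyclic_mean_matrix(c(1, 2, 3))
cyclic_mean_matrix <- function(first_row) {
  first_row <- as.numeric(first_row)
  m <- length(first_row)
  if (m < 1L) stop("first_row must be non-empty", call. = FALSE)
  t(vapply(seq_len(m), function(i) {
    if (i == 1L) first_row else first_row[c(i:m, seq_len(i - 1L))]
  }, numeric(m)))
}

#' Similarity-controlled first row
#'
#' Attribute means equally spaced from `top * k` up to `top`. The
#' similarity parameter `k` in `[0, 1)` compresses the spread of means
#' across cell lines: larger `k` makes the lines look more alike, and
#' at `k = 1` all profiles would coincide and the lines would be
#' indistinguishable, so `k >= 1` is rejected.
#'
#' @param k Similarity in `[0, 1)`.
#' @param m Number of attributes (>= 2).
#' @param top Largest mean (default 1000).
#' @return Numeric vector of length `m`.
#' @export
#' @examples
#' similarity_first_row(0.55, 10)  # 550, 600, ..., 1000
similarity_first_row <- function(k, m, top = 1000) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k >= 1)
    stop("similarity k must lie in [0, 1): at k = 1 all cell lines have ",
         "identical profiles and cannot be distinguished", call. = FALSE)
  if (m < 2L) stop("m must be at least 2", call. = FALSE)
  seq(top * k, top, length.out = m)
}

#' Generate cell-by-cell profiling data
#'
#' Draws `p` independent cells per line, each attribute from
#' `Normal(mu[i, j], (cv * mu[i, j])^2)` -- a constant coefficient of
#' variation across all attributes. Draws are used as-is (no truncation
#' at 0): the estimator only consumes means and variances.
#'
#' @param mu `n x m` matrix of attribute means.
#' @param cv Positive coefficient of variation `sigma / mu`.
#' @param p Number of cells per line (>= 2).
#' @param seed Optional integer seed.
#' @param cell_line_names,attribute_names Optional names; defaults
#'   `line01..` / `attr1..`.
#' @return List of [cell_data()] objects, one per row of `mu`.
#' @export
generate_cell_by_cell <- function(mu, cv, p, seed = NULL,
                                  cell_line_names = NULL,
                                  attribute_names = NULL) {
  mu <- as.matrix(mu)
  if (!is.numeric(cv) || length(cv) != 1L || cv <= 0)
    stop("cv must be a single positive number", call. = FALSE)
  if (p < 2L) stop("p must be at least 2", call. = FALSE)
  n <- nrow(mu); m <- ncol(mu)
  if (is.null(cell_line_names)) cell_line_names <- sprintf("line%02d", seq_len(n))
  if (is.null(attribute_names)) attribute_names <- paste0("attr", seq_len(m))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    samples <- matrix(
      stats::rnorm(p * m, mean = rep(mu[i, ], each = p),
                   sd = rep(cv * abs(mu[i, ]), each = p)),
      nrow = p, dimnames = list(NULL, attribute_names))
    cell_data(cell_line_names[i], samples)
  })
}

#' Generate an aggregate observation from a known mixture
#'
#' For each cell line `i`, draws `N_i` cells (each attribute from
#' `Normal(mu[i, j], (cv * mu[i, j])^2)`) and sums every attribute over
#' all cells of all lines -- the measurement an aggregate instrument
#' would report for a mixture with true counts `n_true`.
#'
#' @inheritParams generate_cell_by_cell
#' @param n_true Numeric vector of true cell counts (whole cells;
#'   non-integers are rounded with a warning).
#' @return An [aggregate_obs].
#' @export
generate_aggregate <- function(mu, cv, n_true, seed = NULL,
                               attribute_names = NULL) {
  mu <- as.matrix(mu)
  if (!is.numeric(cv) || length(cv) != 1L || cv <= 0)
    stop("cv must be a single positive number", call. = FALSE)
  n_true <- as.numeric(n_true)
  if (length(n_true) != nrow(mu))
    stop("n_true length must match the number of cell lines", call. = FALSE)
  if (any(n_true < 0)) stop("n_true must be non-negative", call. = FALSE)
  if (any(n_true != round(n_true))) {
    warning("non-integer true counts rounded to whole cells", call. = FALSE)
    n_true <- round(n_true)
  }
  m <- ncol(mu)
  if (is.null(attribute_names)) attribute_names <- paste0("attr", seq_len(m))
  if (!is.null(seed)) set.seed(seed)
  e_sum <- numeric(m)
  for (i in seq_len(nrow(mu))) {
    if (n_true[i] == 0) next
    draws <- matrix(
      stats::rnorm(n_true[i] * m, mean = rep(mu[i, ], each = n_true[i]),
                   sd = rep(cv * abs(mu[i, ]), each = n_true[i])),
      nrow = n_true[i])
    e_sum <- e_sum + colSums(draws)
  }
  aggregate_obs(e_sum, attribute_names)
}

#' Simulation configuration
#'
#' Describes one synthetic study condition: the attribute-mean design
#' (an explicit cyclic first row, or a similarity parameter `k`), the
#' coefficient of variation, the number of profiling cells per line,
#' and the true mixture counts. Defaults reproduce the reference
#' 10-line / 10-attribute design: cyclic means with first row
#' `[100 200 ... 1000]`, CV = 1 and 2000 profiling cells per line.
#'
#' @param n_lines,n_attrs Numbers of cell lines and attributes (the
#'   cyclic design requires them equal; both default to 10).
#' @param first_row Optional explicit first row of the cyclic mean
#'   matrix; default `100 * (1:n_attrs)`.
#' @param similarity Optional similarity `k` in `[0, 1)`; overrides
#'   `first_row` via [similarity_first_row()].
#' @param top Largest mean when `similarity` is used (default 1000).
#' @param cv Coefficient of variation (default 1).
#' @param p_profile Profiling cells per line (default 2000).
#' @param n_true True counts vector (default 500 cells of every line).
#' @param seed Master seed; profiling data, aggregate data and the
#'   sampler get separate streams derived from it.
#' @param label Optional label used by [run_sweep()] (defaults to the
#'   similarity or CV value).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 10L, n_attrs = 10L, first_row = NULL,
                       similarity = NULL, top = 1000, cv = 1,
                       p_profile = 2000L, n_true = rep(500, n_lines),
                       seed = 1L, label = NULL) {
  if (!is.null(similarity)) {
    first_row <- similarity_first_row(similarity, n_attrs, top)
  } else if (is.null(first_row)) {
    first_row <- 100 * seq_len(n_attrs)
  }
  if (length(first_row) != n_attrs)
    stop("first_row length must equal n_attrs", call. = FALSE)
  if (any(first_row < 0) || all(first_row == 0))
    stop("first_row entries must be non-negative with at least one positive",
         call. = FALSE)
  if (n_lines != n_attrs)
    stop("the cyclic design requires n_lines == n_attrs", call. = FALSE)
  if (!is.numeric(cv) || cv <= 0) stop("cv must be positive", call. = FALSE)
  if (length(n_true) != n_lines)
    stop("n_true length must equal n_lines", call. = FALSE)
  if (is.null(label))
    label <- if (!is.null(similarity)) paste0("k=", similarity) else paste0("cv=", cv)
  structure(list(n_lines = as.integer(n_lines), n_attrs = as.integer(n_attrs),
                 first_row = as.numeric(first_row), similarity = similarity,
                 cv = cv, p_profile = as.integer(p_profile),
                 n_true = as.numeric(n_true), seed = seed, label = label),
            class = "sim_config")
}

#' Run one simulated estimation end-to-end
#'
#' Generates profiling data and an aggregate observation under a
#' [sim_config()], estimates the profile, runs the full composition
#' estimator, and scores it with [root_square_error()] against the
#' known truth. The master seed spawns separate streams for profiling
#' data, aggregate data and the sampler, so each source of randomness
#' can be varied independently.
#'
#' @param config A [sim_config()].
#' @param sampler A [sampler_config()]; its `seed` (if `NULL`) is
#'   filled from the config's derived stream.
#' @param n_grid KDE grid size (default 2048).
#' @return List with `estimate` (a `composition_estimate`), `profile`,
#'   `obs`, `n_true`, `pi_true` and `e` (the root square error).
#' @export
run_simulation <- function(config, sampler = sampler_config(), n_grid = 2048L) {
  stopifnot(inherits(config, "sim_config"))
  mu <- cyclic_mean_matrix(config$first_row)
  set.seed(config$seed)
  streams <- sample.int(2147483646L, 3L)
  cbc <- generate_cell_by_cell(mu, config$cv, config$p_profile, seed = streams[1L])
  profile <- estimate_profile(cbc, min_cells = 2L)
  obs <- generate_aggregate(mu, config$cv, config$n_true, seed = streams[2L],
                            attribute_names = profile$attribute_names)
  if (is.null(sampler$seed)) sampler$seed <- streams[3L]
  est <- estimate_composition(obs, profile, sampler, n_grid = n_grid)
  pi_true <- composition_ratio(config$n_true)
  list(estimate = est, profile = profile, obs = obs,
       n_true = config$n_true, pi_true = pi_true,
       e = root_square_error(pi_true, est$pi_hat))
}

#' Parameter sweep over simulation conditions
#'
#' Repeats [run_simulation()] for each configuration with `replicates`
#' different seeds and tabulates the root square error: the tool used
#' to study how estimation accuracy degrades as cell-line profiles
#' become more similar (the `k` sweep) or noisier (the CV sweep). A
#' failing replicate is recorded as `NA` and the sweep continues.
#'
#' @param configs List of [sim_config()] objects.
#' @param replicates Replicates per configuration (>= 1); replicate `r`
#'   of a config uses seed `config$seed + r - 1`.
#' @param sampler A [sampler_config()] shared by all runs.
#' @param n_grid KDE grid size (default 2048).
#' @return Data frame with one row per configuration: `parameter`
#'   (label), `mean_e`, `sd_e` (`NA` with a single replicate) and
#'   `n_ok`. The per-replicate errors are attached as attribute
#'   `"details"` (columns `parameter`, `replicate`, `e`).
#' @export
run_sweep <- function(configs, replicates = 10L, sampler = sampler_config(),
                      n_grid = 2048L) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(replicates >= 1L)
  details <- do.call(rbind, lapply(configs, function(cfg) {
    e <- vapply(seq_len(replicates), function(r) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r - 1L
      s <- sampler
      s$seed <- NULL  # derived from the replicate's master seed
      tryCatch(run_simulation(cfg_r, s, n_grid = n_grid)$e,
               error = function(err) {
                 warning("replicate ", r, " of ", cfg$label, " failed: ",
                         conditionMessage(err), call. = FALSE)
                 NA_real_
               })
    }, numeric(1L))
    data.frame(parameter = cfg$label, replicate = seq_len(replicates), e = e,
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(split(details, details$parameter)[
    unique(details$parameter)], function(d) {
      ok <- d$e[!is.na(d$e)]
      data.frame(parameter = d$parameter[1L],
                 mean_e = mean(ok),
                 sd_e = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
                 n_ok = length(ok),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  attr(summary, "details") <- details
  summary
}
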