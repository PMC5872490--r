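#' Cell-by-cell attribute data for one cell line
#'
#' Container for the high-cost single-cell measurements of one cell
#' line: a `p x m` matrix with one row per imaged cell and one column
#' per attribute (e.g. red, green and blue fluorescence).
#'
#' @param cell_line_id Single string naming the cell line.
#' @param samples Numeric matrix (or data frame) with `p >= 2` rows
#'   (cells) and `m` columns (attributes). All values must be finite.
#' @param attribute_names Character vector of `m` attribute names;
#'   defaults to the column names of `samples`.
#'
#' @return An object of class `cell_by_cell_data` with elements
#'   `cell_line_id`, `samples` and `attribute_names`.
#' @seealso [estimate_profile()], [read_cell_data()]
#' @export
#' @examples
#' cd <- cell_data("HCT116", cbind(red = c(10, 12, 9), blue = c(5, 6, 7)))
#' cd$attribute_names
cell_data <- function(cell_line_id, samples, attribute_names = colnames(samples)) {
  stopifnot(is.character(cell_line_id), length(cell_line_id) == 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L)
    stop("cell line '", cell_line_id,
         "' has fewer than 2 cells; at least 2 are required to estimate a standard deviation",
         call. = FALSE)
  if (!all(is.finite(samples)))
    stop("cell line '", cell_line_id, "' contains non-finite attribute values", call. = FALSE)
  if (is.null(attribute_names))
    attribute_names <- paste0("attr", seq_len(ncol(samples)))
  attribute_names <- as.character(attribute_names)
  if (length(attribute_names) != ncol(samples))
    stop("attribute_names length does not match the number of columns", call. = FALSE)
  colnames(samples) <- attribute_names
  structure(
    list(cell_line_id = cell_line_id, samples = samples,
         attribute_names = attribute_names),
    class = "cell_by_cell_data"
  )
}

#' @export
print.cell_by_cell_data <- function(x, ...) {
  cat("Cell-by-cell data: ", x$cell_line_id, "\n",
      "  cells:      ", nrow(x$samples), "\n",
      "  attributes: ", paste(x$attribute_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a cell-line profile
#'
#' Low-level constructor for the profile "database": per-cell-line,
#' per-attribute means and standard deviations. Most users should call
#' [estimate_profile()] instead.
#'
#' @param cell_line_names Character vector of `n` cell-line names.
#' @param mu_hat,sigma_hat Numeric `n x m` matrices of estimated means
#'   and standard deviations (attribute units); `sigma_hat` must be
#'   non-negative.
#' @param attribute_names Character vector of `m` attribute names.
#'
#' @return An object of class `cell_line_profile`.
#' @export
cell_line_profile <- function(cell_line_names, mu_hat, sigma_hat, attribute_names) {
  mu_hat <- as.matrix(mu_hat)
  sigma_hat <- as.matrix(sigma_hat)
  cell_line_names <- as.character(cell_line_names)
  attribute_names <- as.character(attribute_names)
  if (!identical(dim(mu_hat), dim(sigma_hat)))
    stop("mu_hat and sigma_hat must have identical dimensions", call. = FALSE)
  if (nrow(mu_hat) != length(cell_line_names) || ncol(mu_hat) != length(attribute_names))
    stop("profile dimensions do not match cell_line_names / attribute_names", call. = FALSE)
  if (!all(is.finite(mu_hat)) || !all(is.finite(sigma_hat)))
    stop("profile matrices must be finite", call. = FALSE)
  if (any(sigma_hat < 0))
    stop("sigma_hat must be non-negative", call. = FALSE)
  if (any(sigma_hat == 0))
    warning("profile contains zero-variance entries; a variance floor will be applied ",
            "in the likelihood if a whole attribute is degenerate", call. = FALSE)
  dimnames(mu_hat) <- dimnames(sigma_hat) <- list(cell_line_names, attribute_names)
  structure(
    list(cell_line_names = cell_line_names, mu_hat = mu_hat,
         sigma_hat = sigma_hat, attribute_names = attribute_names),
    class = "cell_line_profile"
  )
}

#' @export
print.cell_line_profile <- function(x, ...) {
  cat("Cell-line profile: ", length(x$cell_line_names), " cell lines, ",
      length(x$attribute_names), " attributes\n", sep = "")
  cat("Means (mu_hat):\n")
  print(x$mu_hat, ...)
  cat("Standard deviations (sigma_hat):\n")
  print(x$sigma_hat, ...)
  invisible(x)
}

#' Estimate cell-line attribute profiles
#'
#' The one-time, high-cost profiling step: for each cell line the
#' sample mean and Bessel-corrected sample standard deviation of every
#' attribute are estimated from its cell-by-cell data,
#' \deqn{\hat\mu_{ij} = \frac{1}{p}\sum_k e_{ijk}, \qquad
#'       \hat\sigma_{ij} = \sqrt{\frac{\sum_k (e_{ijk}-\hat\mu_{ij})^2}{p-1}}.}
#' Profiles are assumed stable across mixtures measured under the same
#' experimental setup, so this database is built once and reused.
#'
#' @param data A `cell_by_cell_data` object or a list of them, one per
#'   cell line. All must share identical attribute names (in the same
#'   order).
#' @param min_cells Profiling with fewer cells than this per line
#'   triggers a warning (the estimate is still produced). Default 100.
#'
#' @return A [cell_line_profile] with one row per cell line.
#' @export
#' @examples
#' cd <- cell_data("A", matrix(c(1, 2, 3, 4), ncol = 2,
#'                             dimnames = list(NULL, c("x", "y"))))
#' estimate_profile(cd)
estimate_profile <- function(data, min_cells = 100L) {
  if (inherits(data, "cell_by_cell_data")) data <- list(data)
  if (!length(data) || !all(vapply(data, inherits, TRUE, "cell_by_cell_data")))
    stop("data must be a cell_by_cell_data object or a list of them", call. = FALSE)
  attrs <- data[[1L]]$attribute_names
  for (d in data) {
    if (!identical(d$attribute_names, attrs))
      stop("attribute names of cell line '", d$cell_line_id,
           "' do not match those of '", data[[1L]]$cell_line_id, "'", call. = FALSE)
    if (nrow(d$samples) < min_cells)
      warning("cell line '", d$cell_line_id, "' profiled from only ",
              nrow(d$samples), " cells (< ", min_cells,
              "); estimates may be noisy", call. = FALSE)
  }
  mu_hat <- t(vapply(data, function(d) colMeans(d$samples), numeric(length(attrs))))
  sigma_hat <- t(vapply(data, function(d) apply(d$samples, 2L, stats::sd),
                        numeric(length(attrs))))
  cell_line_profile(
    cell_line_names = vapply(data, `[[`, character(1L), "cell_line_id"),
    mu_hat = mu_hat, sigma_hat = sigma_hat, attribute_names = attrs
  )
}

#' Read cell-by-cell data from CSV
#'
#' Reads a delimited table with one row per cell and one column per
#' attribute. If a `cell_line` column is present the file is treated as
#' a long table covering several cell lines and a list is returned;
#' otherwise the whole file is one cell line.
#'
#' @param path Path to a CSV file with a header row naming attributes.
#' @param cell_line_id Cell-line name used when the file has no
#'   `cell_line` column; defaults to the file name without extension.
#' @return A `cell_by_cell_data` object, or a list of them for a long
#'   file.
#' @export
read_cell_data <- function(path, cell_line_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("cell_line" %in% names(df)) {
    ids <- unique(as.character(df$cell_line))
    lapply(ids, function(id) {
      sub <- df[df$cell_line == id, setdiff(names(df), "cell_line"), drop = FALSE]
      cell_data(id, as.matrix(sub))
    })
  } else {
    if (is.null(cell_line_id))
      cell_line_id <- sub("\\.[^.]*$", "", basename(path))
    cell_data(cell_line_id, as.matrix(df))
  }
}

#' Write / read a profile database
#'
#' The profile is persisted as a long-format CSV with columns
#' `cell_line`, `attribute`, `mu`, `sigma` -- a diffable, versionable
#' "database". Numbers are written with 17 significant digits so the
#' round trip preserves full double precision. Cell-line and attribute
#' order is taken from first appearance in the file and must match the
#' order used later for the aggregate measurement.
#'
#' @param profile A [cell_line_profile].
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a [cell_line_profile].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cell_line_profile"))
  n <- length(profile$cell_line_names)
  m <- length(profile$attribute_names)
  df <- data.frame(
    cell_line = rep(profile$cell_line_names, each = m),
    attribute = rep(profile$attribute_names, times = n),
    mu = sprintf("%.17g", t(profile$mu_hat)),
    sigma = sprintf("%.17g", t(profile$sigma_hat)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- tryCatch(utils::read.csv(path, colClasses = "character", check.names = FALSE),
                 error = function(e) stop("cannot parse profile file '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  required <- c("cell_line", "attribute", "mu", "sigma")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("profile file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mu <- suppressWarnings(as.numeric(df$mu))
  sigma <- suppressWarnings(as.numeric(df$sigma))
  bad <- which(is.na(mu) | is.na(sigma))
  if (length(bad))
    stop("profile file '", path, "': non-numeric mu/sigma at data line ",
         bad[1L] + 1L, " ('", df$mu[bad[1L]], "', '", df$sigma[bad[1L]], "')",
         call. = FALSE)
  lines <- unique(df$cell_line)
  attrs <- unique(df$attribute)
  n <- length(lines); m <- length(attrs)
  if (nrow(df) != n * m)
    stop("profile file '", path, "': expected ", n * m,
         " rows (", n, " cell lines x ", m, " attributes), found ", nrow(df),
         call. = FALSE)
  mu_hat <- matrix(NA_real_, n, m, dimnames = list(lines, attrs))
  sigma_hat <- mu_hat
  idx <- cbind(match(df$cell_line, lines), match(df$attribute, attrs))
  if (anyDuplicated(idx))
    stop("profile file '", path, "': duplicated (cell_line, attribute) pair",
         call. = FALSE)
  mu_hat[idx] <- mu
  sigma_hat[idx] <- sigma
  suppressWarnings(cell_line_profile(lines, mu_hat, sigma_hat, attrs))
}

#' Export a profile as JSON
#'
#' @param profile A [cell_line_profile].
#' @param path Optional file path; if `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
profile_to_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "cell_line_profile"))
  obj <- list(
    cell_line_names = profile$cell_line_names,
    attribute_names = profile$attribute_names,
    mu_hat = unname(profile$mu_hat),
    sigma_hat = unname(profile$sigma_hat)
  )
  json <- jsonlite::toJSON(obj, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
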