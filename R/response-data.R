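#' Binary item-response data with a missingness mask
#'
#' Container for an `N x J` matrix of 0/1 item responses together with an
#' indicator mask of which cells were actually observed.  Missing cells carry
#' `NA` in `$y` and `0` in `$mask`; observed cells are guaranteed to be 0 or 1.
#' For every item `j`, the rows with `mask == 0` are the observation set
#' complement (the respondents whose answer to item `j` is missing).
#'
#' @param y matrix (or data frame) with entries in `{0, 1, NA}`.
#' @param mask optional `N x J` 0/1 matrix, 1 = observed.  Defaults to
#'   `!is.na(y)`.  Cells with `mask == 0` are treated as missing regardless of
#'   the value stored in `y`.
#' @return an object of class `response_data`: a list with elements `y`
#'   (integer matrix, `NA` where missing), `mask` (integer matrix), `N`, `J`,
#'   and `items` (column names).
#' @examples
#' y <- matrix(c(1, 0, NA, 1), 2, 2)
#' d <- response_data(y)
#' d$mask
#' @export
response_data <- function(y, mask = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (is.null(mask)) {
    mask <- !is.na(y)
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(y)))
      stop("mask dimensions do not match y")
    if (!all(mask %in% c(0L, 1L)))
      stop("mask entries must be 0 (missing) or 1 (observed)")
  }
  storage.mode(mask) <- "integer"
  y[mask == 0L] <- NA_integer_
  obs <- y[mask == 1L]
  if (anyNA(obs))
    stop("cells flagged observed in the mask must not be NA")
  if (!all(obs %in% c(0L, 1L)))
    stop("observed responses must be coded 0/1")
  items <- colnames(y) %||% paste0("Y", seq_len(ncol(y)))
  colnames(y) <- colnames(mask) <- items
  structure(
    list(y = y, mask = mask, N = nrow(y), J = ncol(y), items = items),
    class = "response_data"
  )
}

#' @export
print.response_data <- function(x, ...) {
  miss <- mean(x$mask == 0L)
  cat("response_data: ", x$N, " respondents x ", x$J, " items, ",
      sprintf("%.1f%%", 100 * miss), " missing\n", sep = "")
  invisible(x)
}

# logical index of rows with no missing cell
complete_rows <- function(data) {
  rowSums(data$mask == 0L) == 0L
}

# extract the response matrix, requiring that no cell is missing
complete_matrix <- function(y) {
  if (inherits(y, "response_data")) {
    if (any(y$mask == 0L))
      stop("data contain missing cells; impute them first")
    y <- y$y
  }
  y <- as.matrix(y)
  if (anyNA(y)) stop("data contain missing cells; impute them first")
  if (!all(y %in% c(0L, 1L))) stop("responses must be coded 0/1")
  storage.mode(y) <- "integer"
  y
}

#' Read item responses from CSV
#'
#' Expects a header row of item names and one row per respondent, with values
#' in `{0, 1}` or a missing token.  Survey exports that code skipped questions
#' as e.g. `"Unknown"` can be read by listing that token in `missing`.
#'
#' @param file path to a CSV file.
#' @param missing character vector of tokens read as missing (default `"NA"`).
#' @return a [response_data] object.
#' @export
read_responses <- function(file, missing = "NA") {
  df <- read.csv(file, na.strings = missing, check.names = FALSE)
  response_data(as.matrix(df))
}

#' Write item responses to CSV
#'
#' @param data a [response_data] object.
#' @param file output path.
#' @param missing token written for missing cells (default `"NA"`).
#' @export
write_responses <- function(data, file, missing = "NA") {
  out <- data$y
  out[data$mask == 0L] <- NA
  out <- as.data.frame(out)
  if (!identical(missing, "NA")) {
    out[] <- lapply(out, function(v) {
      v <- as.character(v)
      v[is.na(v)] <- missing
      v
    })
  }
  write.csv(out, file, row.names = FALSE, na = "NA")
  invisible(file)
}

#' Read an Ising parameter matrix from CSV
#'
#' The file must be square with a header row.  Symmetry is validated to
#' `tol`; small asymmetries (e.g. from printing precision) are repaired by
#' averaging `S` with its transpose, larger ones are an error.
#'
#' @param file path to a CSV file.
#' @param tol symmetry tolerance (default `1e-8`).
#' @return symmetric numeric matrix.
#' @export
read_ising_matrix <- function(file, tol = 1e-8) {
  S <- as.matrix(read.csv(file, check.names = FALSE))
  storage.mode(S) <- "double"
  validate_ising_matrix(S, tol = tol)
}

#' Write an Ising parameter matrix to CSV
#'
#' @param S symmetric numeric matrix.
#' @param file output path.
#' @export
write_ising_matrix <- function(S, file) {
  S <- validate_ising_matrix(S)
  colnames(S) <- colnames(S) %||% paste0("Y", seq_len(ncol(S)))
  write.csv(as.data.frame(S), file, row.names = FALSE)
  invisible(file)
}
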