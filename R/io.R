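# Plain-CSV interchange for monotherapy and checkerboard tables.
# Long format, header required, "." decimal separator, doses in user
# units.

#' Read a monotherapy dose-effect table
#'
#' Expects columns `drug`, `dose`, `effect` and optionally `replicate`
#' (filled with 1 when absent).
#'
#' @param path CSV file path.
#' @return Data frame with columns `drug`, `dose`, `effect`,
#'   `replicate`.
#' @export
read_monotherapy_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "dose", "effect")
  if (!all(need %in% names(tab))) {
    stop("monotherapy CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  validate_monotherapy(tab)
  tab[c("drug", "dose", "effect", "replicate")]
}

#' Write a monotherapy dose-effect table
#'
#' @param table Data frame with columns `drug`, `dose`, `effect`,
#'   `replicate` (a table without `drug` gets the placeholder `"drug"`).
#' @param path Output CSV path.
#' @export
write_monotherapy_csv <- function(table, path) {
  if (!"drug" %in% names(table)) table$drug <- "drug"
  if (!"replicate" %in% names(table)) table$replicate <- 1L
  utils::write.csv(table[c("drug", "dose", "effect", "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a combination checkerboard table
#'
#' Expects columns `drug_a`, `drug_b`, `dose_a`, `dose_b`, `effect` and
#' optionally `replicate`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `drug_a`, `drug_b`, `dose_a`,
#'   `dose_b`, `effect`, `replicate`.
#' @export
read_checkerboard_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_a", "drug_b", "dose_a", "dose_b", "effect")
  if (!all(need %in% names(tab))) {
    stop("checkerboard CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  if (any(!is.finite(tab$dose_a)) || any(tab$dose_a < 0) ||
      any(!is.finite(tab$dose_b)) || any(tab$dose_b < 0)) {
    stop("doses must be finite and non-negative")
  }
  tab[c("drug_a", "drug_b", "dose_a", "dose_b", "effect", "replicate")]
}

#' Write a combination checkerboard table
#'
#' @param table Data frame with columns `dose_a`, `dose_b`, `effect`
#'   and optionally `drug_a`, `drug_b`, `replicate` (placeholders are
#'   supplied).
#' @param path Output CSV path.
#' @export
write_checkerboard_csv <- function(table, path) {
  if (!"drug_a" %in% names(table)) table$drug_a <- "A"
  if (!"drug_b" %in% names(table)) table$drug_b <- "B"
  if (!"replicate" %in% names(table)) table$replicate <- 1L
  utils::write.csv(
    table[c("drug_a", "drug_b", "dose_a", "dose_b", "effect", "replicate")],
    path, row.names = FALSE
  )
  invisible(path)
}
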