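#' Construct a taxa-by-sample count table
#'
#' The basic data container of the package: a non-negative integer matrix
#' with taxa as rows and samples as columns, both uniquely named. Per-sample
#' totals \eqn{n_A} (individuals) and richness \eqn{N_A} (taxa with
#' \eqn{n_{Ai} > 0}) are derived from it by [sample_totals()] and
#' [sample_richness()].
#'
#' @param counts numeric matrix of non-negative integers; rows are taxa,
#'   columns are samples. Dimnames are required (unique taxon and sample IDs).
#' @param allow_empty_samples keep samples whose total count is zero instead
#'   of raising an error. Used internally by simulators before filtering.
#' @return a matrix of class `"count_table"`.
#' @examples
#' m <- matrix(c(5, 3, 0, 0, 2, 4), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("A", "B")))
#' ct <- count_table(m)
#' sample_totals(ct)    # n_A
#' sample_richness(ct)  # N_A
#' @export
count_table <- function(counts, allow_empty_samples = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have taxon row names and sample column names")
  }
  dup_t <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_t)) {
    stop("duplicate taxon ID(s): ", paste(dup_t, collapse = ", "))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(counts)) stop("`counts` contains missing values")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  counts <- round(counts)
  if (!allow_empty_samples) {
    empty <- colnames(counts)[colSums(counts) == 0]
    if (length(empty)) {
      stop("sample(s) with zero total count: ", paste(empty, collapse = ", "))
    }
  }
  structure(counts, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("Count table: %d taxa x %d samples, %s individuals\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`
#' @export
taxa_ids <- function(x) rownames(x)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x)

#' @rdname count_table
#' @export
sample_totals <- function(x) colSums(unclass(x))

#' @rdname count_table
#' @export
sample_richness <- function(x) colSums(unclass(x) > 0)

#' Per-sample relative abundances
#'
#' Divides each sample (column) by its total, so columns sum to 1:
#' \eqn{p_{Ai} = n_{Ai} / n_A}.
#'
#' @param x a [count_table()]
#' @return numeric matrix of the same shape with unit column sums.
#' @export
relative_abundances <- function(x) {
  m <- unclass(x)
  sweep(m, 2, colSums(m), "/")
}
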