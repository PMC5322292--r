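#' Read a count table from TSV
#'
#' Expects a tab-separated file with a header row and an ID column first.
#' By default rows are taxa and columns are samples; `orientation =
#' "samples"` transposes on read for tables stored the other way around.
#'
#' @param path file path
#' @param orientation `"taxa"` if rows are taxa (default), `"samples"` if
#'   rows are samples.
#' @return a [count_table()]
#' @export
read_count_table <- function(path, orientation = c("taxa", "samples")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs an ID column plus data: ", path)
  ids <- as.character(raw[[1]])
  body <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(body)) stop("non-numeric entries in count table: ", path)
  rownames(body) <- ids
  if (orientation == "samples") body <- t(body)
  count_table(body)
}

#' Write a count table to TSV
#'
#' @param x a [count_table()]
#' @param path output file path
#' @param id_header name of the leading ID column
#' @export
write_count_table <- function(x, path, id_header = "taxon_id") {
  write_square_body(unclass(x), path, id_header)
}

#' Read a phylogenetic tree from a Newick file
#'
#' Reads a single Newick tree, validates leaf labels and branch lengths,
#' and midpoint-roots unrooted input so that root-to-leaf path lengths
#' \eqn{\phi_i} are defined for every taxon.
#'
#' @param path Newick file with one tree
#' @return an [ape::phylo] object, rooted
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("cannot parse Newick file ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("cannot parse Newick file ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected exactly one tree in ", path)
    tr <- tr[[1]]
  }
  validate_tree(tr)
}

## Shared tree validation + midpoint rooting, also applied to trees passed
## in directly as phylo objects.
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("tree must be a 'phylo' object")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
  tr
}

#' Root-to-leaf path lengths
#'
#' \eqn{\phi_i}: the summed branch length from the root to leaf i.
#'
#' @param tree a rooted [ape::phylo]
#' @return named numeric vector over leaves
#' @export
root_to_leaf_lengths <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::node.depth.edgelength(tree)
  stats::setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Restrict a count table, tree and interaction matrix to shared taxa
#'
#' Subsets all provided objects to the intersection of their taxon ID sets
#' (in the count table's order), pruning the tree and sub-setting matrices
#' to match. IDs that get dropped are reported via `message()`.
#'
#' @param table a [count_table()]
#' @param tree optional [ape::phylo] whose tip labels are taxon IDs
#' @param interactions optional square matrix with taxon IDs as dimnames
#'   (raw interaction or association matrix)
#' @return list with elements `table`, `tree`, `interactions` (the latter
#'   two `NULL` when not supplied) and `dropped`, the IDs removed from any
#'   input.
#' @export
harmonise <- function(table, tree = NULL, interactions = NULL) {
  stopifnot(inherits(table, "count_table"))
  sets <- list(taxa_ids(table))
  if (!is.null(tree)) {
    tree <- validate_tree(tree)
    sets <- c(sets, list(tree$tip.label))
  }
  if (!is.null(interactions)) {
    if (!is_symmetric(unclass(interactions), tol = 1e-6)) {
      stop("`interactions` must be a symmetric square matrix")
    }
    if (is.null(rownames(interactions))) stop("`interactions` needs taxon IDs as dimnames")
    sets <- c(sets, list(rownames(interactions)))
  }
  shared <- Reduce(intersect, sets)
  if (!length(shared)) stop("no taxa shared between the provided objects")
  dropped <- setdiff(unique(unlist(sets)), shared)
  if (length(dropped)) {
    message("harmonise: dropping ", length(dropped), " taxa not shared by all inputs: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  keep <- taxa_ids(table)[taxa_ids(table) %in% shared]
  tab <- count_table(unclass(table)[keep, , drop = FALSE],
                     allow_empty_samples = TRUE)
  empty <- sample_ids(tab)[sample_totals(tab) == 0]
  if (length(empty)) {
    stop("harmonise left sample(s) empty: ", paste(empty, collapse = ", "))
  }
  tab <- count_table(unclass(tab))
  if (!is.null(tree)) {
    tree <- ape::keep.tip(tree, keep)
  }
  if (!is.null(interactions)) {
    cls <- class(interactions)
    at <- attributes(interactions)
    interactions <- unclass(interactions)[keep, keep, drop = FALSE]
    for (nm in setdiff(names(at), c("dim", "dimnames", "class"))) {
      attr(interactions, nm) <- at[[nm]]
    }
    class(interactions) <- cls
  }
  list(table = tab, tree = tree, interactions = interactions, dropped = dropped)
}

## --- square-matrix TSV plumbing -------------------------------------------

## 10 significant digits: enough for lossless round trips at test tolerance.
write_square_body <- function(m, path, id_header) {
  txt <- matrix(formatC(m, digits = 10, format = "g"), nrow = nrow(m))
  df <- data.frame(rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_header, colnames(m))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

read_square_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in matrix file: ", path)
  rownames(m) <- ids
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("matrix file is not square with matching IDs: ", path)
  }
  m
}

#' Write / read a sample distance matrix as TSV
#'
#' The file is a square tab-separated matrix with sample IDs as both the
#' header and the first column, at 10 significant digits.
#'
#' @param d a symmetric zero-diagonal distance matrix (class `"community_dist"`
#'   or plain matrix)
#' @param path file path
#' @return `write_distance_matrix` returns `path` invisibly;
#'   `read_distance_matrix` returns a `"community_dist"` matrix.
#' @export
write_distance_matrix <- function(d, path) {
  d <- as_community_dist(d)
  write_square_body(unclass(d), path, "sample_id")
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  as_community_dist(read_square_matrix(path))
}

#' Write / read a square taxa association or interaction matrix as TSV
#'
#' @param m square matrix with taxon IDs as dimnames
#' @param path file path
#' @export
write_association_matrix <- function(m, path) {
  write_square_body(unclass(m), path, "taxon_id")
}

#' @rdname write_association_matrix
#' @export
read_association_matrix <- function(path) {
  m <- read_square_matrix(path)
  if (!is_symmetric(m, tol = 1e-6)) stop("matrix in ", path, " is not symmetric")
  m
}

#' Read a sample metadata table from TSV
#'
#' First column is the sample ID; remaining columns are group labels or
#' numeric covariates.
#'
#' @param path file path
#' @return data.frame with sample IDs as row names
#' @export
read_metadata <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in metadata: ", path)
  df <- raw[, -1, drop = FALSE]
  rownames(df) <- ids
  df
}

## Coerce to a validated community_dist matrix.
as_community_dist <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!is_symmetric(d, tol = 1e-8)) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-12) stop("distance matrix must have a zero diagonal")
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(d, class = c("community_dist", "matrix", "array"))
}

#' @export
print.community_dist <- function(x, ...) {
  cat(sprintf("Community distance matrix: %d samples, range [%.3g, %.3g]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}
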