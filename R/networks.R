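#' Infer a raw taxa co-occurrence interaction matrix
#'
#' Associates every pair of taxa by their abundance profiles across samples,
#' yielding the raw interaction matrix that [transform_association()]
#' converts to the common association scale. Four inference methods are
#' supported:
#' \describe{
#'   \item{`sparcc`}{compositionally robust basis correlations
#'     (see [sparcc_correlations()]); scale \[-1, 1\].}
#'   \item{`spearman`}{Spearman rank correlation of taxa across samples;
#'     scale \[-1, 1\].}
#'   \item{`braycurtis`}{taxa-wise Bray-Curtis similarity
#'     (1 - dissimilarity) of count profiles; scale \[0, 1\].}
#'   \item{`wjaccard`}{taxa-wise weighted Jaccard similarity: the mean
#'     fraction of a taxon's counts falling in samples where the partner
#'     taxon is also present; scale \[0, 1\].}
#' }
#' Taxa with all-zero counts are removed with a warning (their association
#' is undefined). The diagonal is each method's self-association, 1.
#'
#' @param table a [count_table()] with at least 3 samples and 2 taxa
#' @param method association metric, see Details
#' @param seed RNG seed (only `sparcc` is stochastic)
#' @param ... further arguments passed to [sparcc_correlations()]
#' @return symmetric numeric matrix of class `"interaction_matrix"` with
#'   attribute `method`.
#' @export
infer_cooccurrence <- function(table,
                               method = c("sparcc", "spearman", "braycurtis",
                                          "wjaccard"),
                               seed = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(table, "count_table"))
  if (ncol(table) < 3) stop("need at least 3 samples for co-occurrence inference")
  table <- drop_empty_taxa(table)
  if (nrow(table) < 2) stop("need at least 2 taxa with non-zero counts")
  m <- unclass(table)
  raw <- switch(method,
    spearman = {
      r <- suppressWarnings(stats::cor(t(m), method = "spearman"))
      if (anyNA(r)) {
        warning("constant taxa profiles produced undefined correlations; set to 0")
        r[is.na(r)] <- 0
      }
      diag(r) <- 1
      r
    },
    braycurtis = {
      s <- 1 - as.matrix(vegan::vegdist(m, method = "bray"))
      diag(s) <- 1
      s
    },
    wjaccard = {
      p <- m / rowSums(m)              # per-taxon profile across samples
      b <- (m > 0) * 1
      w <- p %*% t(b)                  # fraction of taxon i's counts where j present
      s <- (w + t(w)) / 2
      diag(s) <- 1
      s
    },
    sparcc = return(sparcc_correlations(table, seed = seed, ...))
  )
  new_interaction_matrix(raw, method)
}

new_interaction_matrix <- function(m, method) {
  stopifnot(is_symmetric(m, tol = 1e-8))
  m <- (m + t(m)) / 2
  structure(m, method = method,
            class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("Raw interaction matrix: %d taxa, method '%s', range [%.3g, %.3g]\n",
              nrow(x), attr(x, "method") %||% "?", min(x), max(x)))
  invisible(x)
}

drop_empty_taxa <- function(table) {
  zero <- rowSums(unclass(table)) == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " all-zero taxa: ",
            paste(utils::head(taxa_ids(table)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
    table <- count_table(unclass(table)[!zero, , drop = FALSE])
  }
  table
}

#' Transform a raw interaction matrix to the canonical association scale
#'
#' Taxa are correlated by their full association profiles (rows of the raw
#' matrix) and the Pearson correlation is rescaled to \[0, 1\]:
#' \deqn{C_{ij} = (1 + r(I_{i*}, I_{j*})) / 2.}
#' The resulting matrix scales from 0 (avoidance) through 0.5 (neutral
#' association) to 1 (complete association), has unit diagonal, and is
#' positive semi-definite (it equals (J + R) / 2 with R a correlation
#' matrix). Taxa whose profile has zero variance are uninformative: their
#' correlations are set to 0, i.e. the neutral association 0.5, with a
#' warning.
#'
#' @param raw symmetric square matrix (an `"interaction_matrix"` or plain
#'   matrix) with at least 3 taxa
#' @param exclude_focal correlate profiles after removing the two focal
#'   columns i and j for each pair (default `FALSE`: full rows are used)
#' @return matrix of class `"association_matrix"` with attribute `source`.
#' @export
transform_association <- function(raw, exclude_focal = FALSE) {
  src <- if (identical(attr(raw, "method"), "cophenetic")) "phylogeny" else "cooccurrence"
  m <- unclass(raw)
  if (!is_symmetric(m, tol = 1e-6)) stop("raw interaction matrix must be symmetric")
  if (nrow(m) < 3) stop("need at least 3 taxa to correlate association profiles")
  m <- (m + t(m)) / 2
  n <- nrow(m)
  if (!exclude_focal) {
    r <- suppressWarnings(stats::cor(m))    # columns = rows by symmetry
    if (anyNA(r)) {
      warning("zero-variance association profile(s); set to neutral 0.5")
      r[is.na(r)] <- 0
    }
  } else {
    r <- diag(1, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        keep <- setdiff(seq_len(n), c(i, j))
        rij <- suppressWarnings(stats::cor(m[i, keep], m[j, keep]))
        if (is.na(rij)) rij <- 0
        r[i, j] <- r[j, i] <- rij
      }
    }
  }
  diag(r) <- 1
  cmat <- (1 + r) / 2
  cmat <- pmin(pmax(cmat, 0), 1)
  dimnames(cmat) <- dimnames(m)
  structure(cmat, source = src,
            class = c("association_matrix", "matrix", "array"))
}

#' @export
print.association_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf(
    "Association matrix (%s): %d taxa, off-diagonal range [%.3g, %.3g]\n",
    attr(x, "source") %||% "?", nrow(x),
    if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
  invisible(x)
}

#' Cophenetic phylogenetic similarity matrix
#'
#' Converts cophenetic (leaf-to-leaf path length) distances on a tree into
#' a similarity on \[0, 1\] by complementing against the largest observed
#' distance: \eqn{I_{\phi,ij} = 1 - d_{coph}(i,j) / \max_{kl} d_{coph}(k,l)}.
#' The result plays the role of a phylogenetic association network,
#' analogous to a co-occurrence interaction matrix.
#'
#' @param tree a rooted [ape::phylo] with at least 3 leaves
#' @return `"interaction_matrix"` with method `"cophenetic"`.
#' @export
cophenetic_similarity <- function(tree) {
  tree <- validate_tree(tree)
  if (length(tree$tip.label) < 3) stop("need at least 3 leaves")
  d <- ape::cophenetic.phylo(tree)
  dmax <- max(d)
  if (dmax <= 0) stop("all cophenetic distances are zero (zero branch lengths)")
  new_interaction_matrix(1 - d / dmax, "cophenetic")
}

#' Phylogenetic association matrix
#'
#' The two-step construction of the phylogenetic association matrix
#' \eqn{\Phi}: cophenetic similarity ([cophenetic_similarity()]) followed by
#' the canonical association transform ([transform_association()]).
#'
#' @inheritParams cophenetic_similarity
#' @param ... passed to [transform_association()]
#' @return `"association_matrix"` with source `"phylogeny"`.
#' @export
phylo_association <- function(tree, ...) {
  transform_association(cophenetic_similarity(tree), ...)
}
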