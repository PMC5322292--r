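#' Pairwise community similarity indices
#'
#' Scalar similarities between two samples, each on \[0, 1\] and returned
#' as similarity S (the matching dissimilarity is D = 1 - S, see
#' [distance_matrix()]). `a` and `b` are count vectors over the same taxa,
#' in the same order (use named vectors or rely on position).
#'
#' The count-based indices are:
#' \describe{
#'   \item{[jaccard_classical()] (JCI)}{shared taxa / union of observed
#'     taxa (incidence only).}
#'   \item{[jaccard_weighted()] (JCW)}{mean fraction of individuals in
#'     shared taxa across both samples.}
#'   \item{[jaccard_chao()] (JCC)}{abundance-based Jaccard corrected for
#'     unseen shared taxa via the Chao et al. (2004) formula-9 estimators.}
#'   \item{[bray_curtis()] (BC)}{2 * sum of per-taxon minima over the summed
#'     totals.}
#'   \item{[morisita_horn()] (MH)}{cross-product overlap of relative
#'     abundances adjusted by per-sample concentration indices.}
#' }
#'
#' @param a,b non-negative count vectors over the same taxa
#' @return similarity in \[0, 1\]
#' @name count_indices
NULL

check_pair <- function(a, b) {
  if (length(a) != length(b)) stop("count vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("negative counts")
  if (sum(a) <= 0 || sum(b) <= 0) stop("both samples must be non-empty")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    stop("taxon names of the two samples disagree")
  }
  invisible(TRUE)
}

#' @rdname count_indices
#' @export
jaccard_classical <- function(a, b) {
  check_pair(a, b)
  oa <- a > 0; ob <- b > 0
  sum(oa & ob) / sum(oa | ob)
}

#' @rdname count_indices
#' @export
jaccard_weighted <- function(a, b) {
  check_pair(a, b)
  sh <- a > 0 & b > 0
  (sum(a[sh]) / sum(a) + sum(b[sh]) / sum(b)) / 2
}

#' @rdname count_indices
#' @export
bray_curtis <- function(a, b) {
  check_pair(a, b)
  2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

#' @rdname count_indices
#' @export
morisita_horn <- function(a, b) {
  check_pair(a, b)
  pa <- a / sum(a); pb <- b / sum(b)
  2 * sum(pa * pb) / (sum(pa^2) + sum(pb^2))
}

#' @rdname count_indices
#' @export
jaccard_chao <- function(a, b) {
  check_pair(a, b)
  u <- chao_shared_estimator(a, b)
  v <- chao_shared_estimator(b, a)
  if (u == 0 || v == 0) return(0)
  (u * v) / (u + v - u * v)
}

## Chao et al. (2004) formula 9: estimated fraction of sample `a`'s
## individuals belonging to taxa shared with sample `b`, extrapolated from
## shared taxa that are rare (singletons/doubletons) in `b`. f_{+2} = 0 is
## replaced by 1 (continuity correction) and the estimate capped at 1.
chao_shared_estimator <- function(a, b) {
  sh <- a > 0 & b > 0
  if (!any(sh)) return(0)
  na <- sum(a); nb <- sum(b)
  observed <- sum(a[sh]) / na
  f1 <- sum(sh & b == 1)                 # shared, singleton in partner
  f2 <- sum(sh & b == 2)                 # shared, doubleton in partner
  f2c <- if (f2 == 0) 1 else f2
  corr <- ((nb - 1) / nb) * (f1 / (2 * f2c)) * sum(a[sh & b == 1]) / na
  min(1, observed + corr)
}

## --- UniFrac ---------------------------------------------------------------

## Per-edge tip incidence: rows = edges of `tree`, columns = tips, TRUE when
## the tip lies below the edge. Shared across UniFrac calls via
## precompute_branches().
precompute_branches <- function(tree) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    below[par, ] <- below[par, ] | below[ch, ]
  }
  list(tree = tree,
       lengths = tree$edge.length,
       tip_below = below[tree$edge[, 2], , drop = FALSE],
       tips = tree$tip.label,
       phi = root_to_leaf_lengths(tree))
}

match_tree_counts <- function(x, br) {
  if (is.null(names(x))) {
    if (length(x) != length(br$tips)) stop("unnamed counts must match tip count")
    return(x)
  }
  miss <- setdiff(names(x)[x > 0], br$tips)
  if (length(miss)) {
    stop("taxa missing from tree: ", paste(utils::head(miss, 5), collapse = ", "),
         " (harmonise first)")
  }
  out <- stats::setNames(numeric(length(br$tips)), br$tips)
  keep <- intersect(names(x), br$tips)
  out[keep] <- x[keep]
  out
}

#' UniFrac similarity between two samples
#'
#' `unifrac_unweighted` is the fraction of tree branch length leading to
#' taxa observed in both samples among branch length leading to taxa
#' observed in either (similarity form; D = 1 - S). `unifrac_weighted` is
#' the normalised abundance-weighted variant: the branch-wise abundance
#' flow difference \eqn{\sum_b L_b |p_A(b) - p_B(b)|} divided by its
#' abundance-weighted maximum \eqn{\sum_i \phi_i (p_{Ai} + p_{Bi})},
#' returned as similarity 1 - D so that both variants live on \[0, 1\].
#'
#' @param a,b count vectors named by taxon (tree tips)
#' @param tree rooted [ape::phylo]; all observed taxa must be tips
#' @return similarity in \[0, 1\]
#' @export
unifrac_unweighted <- function(a, b, tree) {
  check_pair(a, b)
  br <- if (is.list(tree) && !inherits(tree, "phylo")) tree else precompute_branches(tree)
  a <- match_tree_counts(a, br); b <- match_tree_counts(b, br)
  in_a <- br$tip_below %*% (a > 0) > 0
  in_b <- br$tip_below %*% (b > 0) > 0
  union <- sum(br$lengths[in_a | in_b])
  if (union == 0) stop("no branch length leads to observed taxa")
  sum(br$lengths[in_a & in_b]) / union
}

#' @rdname unifrac_unweighted
#' @export
unifrac_weighted <- function(a, b, tree) {
  check_pair(a, b)
  br <- if (is.list(tree) && !inherits(tree, "phylo")) tree else precompute_branches(tree)
  a <- match_tree_counts(a, br); b <- match_tree_counts(b, br)
  pa <- a / sum(a); pb <- b / sum(b)
  flow <- sum(br$lengths * abs(br$tip_below %*% pa - br$tip_below %*% pb))
  denom <- sum(br$phi * (pa + pb))
  if (denom == 0) stop("zero root-to-leaf length for all observed taxa")
  1 - flow / denom
}

## --- TINA / PINA -----------------------------------------------------------

check_assoc <- function(x, assoc) {
  if (is.null(rownames(assoc))) stop("association matrix needs taxon IDs")
  if (!is.null(names(x))) {
    miss <- setdiff(names(x)[x > 0], rownames(assoc))
    if (length(miss)) {
      stop("taxa absent from association matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
  } else if (length(x) != nrow(assoc)) {
    stop("unnamed counts must match association matrix dimension")
  }
  invisible(TRUE)
}

align_assoc <- function(x, assoc) {
  if (is.null(names(x))) return(x)
  out <- stats::setNames(numeric(nrow(assoc)), rownames(assoc))
  keep <- intersect(names(x), rownames(assoc))
  out[keep] <- x[keep]
  out
}

#' Interaction-adjusted community similarity (TINA / PINA)
#'
#' Similarity between two communities as the average pairwise association
#' strength between their taxa, given an association matrix on \[0, 1\]
#' with neutral midpoint 0.5 (a co-occurrence matrix C for TINA, a
#' phylogenetic matrix \eqn{\Phi} for PINA; see
#' [transform_association()] / [phylo_association()]).
#'
#' The unweighted (incidence) form averages associations between every
#' taxon observed in A and every taxon observed in B:
#' \deqn{TU(A,B) = \frac{1}{N_A N_B} \sum_{i \in A} \sum_{j \in B} C_{ij}.}
#' The weighted form is the abundance-weighted average association, scaled
#' by the geometric mean of the two within-sample weighted associations:
#' \deqn{TW(A,B) = \frac{\sum_{ij} p_{Ai} p_{Bj} C_{ij}}{
#'   \sqrt{(\sum_{ij} p_{Ai} p_{Aj} C_{ij})(\sum_{ij} p_{Bi} p_{Bj} C_{ij})}}.}
#' TW of a sample with itself is exactly 1; both forms tend to 0.5 when
#' associations are neutral, to 0 under a strong avoidance signal and up
#' to 1 when all taxa are completely associated, including for sample
#' pairs sharing no taxa at all. The unweighted form carries no
#' self-normalisation, so TU(A, A) is generally below 1.
#'
#' @param a,b count vectors over taxa (named, or positionally matching
#'   `assoc`)
#' @param assoc association matrix on \[0, 1\] (class
#'   `"association_matrix"` or plain symmetric matrix)
#' @return similarity in \[0, 1\]
#' @export
tina_unweighted <- function(a, b, assoc) {
  check_pair(a, b)
  check_assoc(a, assoc); check_assoc(b, assoc)
  a <- align_assoc(a, assoc); b <- align_assoc(b, assoc)
  ia <- which(a > 0); ib <- which(b > 0)
  mean(unclass(assoc)[ia, ib, drop = FALSE])
}

#' @rdname tina_unweighted
#' @export
tina_weighted <- function(a, b, assoc) {
  check_pair(a, b)
  check_assoc(a, assoc); check_assoc(b, assoc)
  a <- align_assoc(a, assoc); b <- align_assoc(b, assoc)
  m <- unclass(assoc)
  pa <- a / sum(a); pb <- b / sum(b)
  waa <- drop(pa %*% m %*% pa)
  wbb <- drop(pb %*% m %*% pb)
  if (waa <= 0 || wbb <= 0) stop("zero within-sample weighted association")
  drop(pa %*% m %*% pb) / sqrt(waa * wbb)
}

#' @rdname tina_unweighted
#' @export
pina_unweighted <- function(a, b, assoc) tina_unweighted(a, b, assoc)

#' @rdname tina_unweighted
#' @export
pina_weighted <- function(a, b, assoc) tina_weighted(a, b, assoc)

## --- all-pairs distance matrices ------------------------------------------

#' Index registry
#'
#' The 11 supported index codes and the auxiliary data each requires:
#' `"jci"`, `"jcw"`, `"jcc"`, `"bc"`, `"mh"` (counts only), `"ufu"`,
#' `"ufw"` (tree), `"tu"`, `"tw"` (co-occurrence association matrix),
#' `"pu"`, `"pw"` (phylogenetic association matrix).
#'
#' @return data.frame with columns `code` and `requires`.
#' @export
index_registry <- function() {
  data.frame(
    code = c("jci", "jcw", "jcc", "bc", "mh", "ufu", "ufw", "tu", "tw", "pu", "pw"),
    requires = c(rep("none", 5), "tree", "tree", "assoc", "assoc",
                 "phylo_assoc", "phylo_assoc"),
    stringsAsFactors = FALSE
  )
}

index_fun <- function(code) {
  switch(code,
    jci = jaccard_classical, jcw = jaccard_weighted, jcc = jaccard_chao,
    bc = bray_curtis, mh = morisita_horn,
    ufu = unifrac_unweighted, ufw = unifrac_weighted,
    tu = tina_unweighted, tw = tina_weighted,
    pu = pina_unweighted, pw = pina_weighted,
    stop("unknown index code: ", code))
}

#' All-pairs community distance matrix
#'
#' Computes a full sample-by-sample dissimilarity matrix for one index,
#' as D = max(0, 1 - S) with zero diagonal. Vectorised computations are
#' used where the index admits them and agree with the scalar per-pair
#' functions to numerical precision.
#'
#' @param table a [count_table()]
#' @param index one of the codes in [index_registry()]
#' @param tree rooted [ape::phylo], required for `ufu`, `ufw` (and used to
#'   derive `assoc` for `pu`/`pw` when `assoc` is not supplied)
#' @param assoc association matrix on \[0, 1\], required for `tu`, `tw`
#'   (co-occurrence) and `pu`, `pw` (phylogenetic; derived from `tree`
#'   via [phylo_association()] when missing)
#' @return matrix of class `"community_dist"`.
#' @export
distance_matrix <- function(table, index, tree = NULL, assoc = NULL) {
  stopifnot(inherits(table, "count_table"))
  index <- match.arg(tolower(index), index_registry()$code)
  req <- index_registry()$requires[index_registry()$code == index]
  if (req %in% c("tree") && is.null(tree)) stop("index '", index, "' requires a tree")
  if (req == "assoc" && is.null(assoc)) {
    stop("index '", index, "' requires an association matrix")
  }
  if (req == "phylo_assoc" && is.null(assoc)) {
    if (is.null(tree)) stop("index '", index, "' requires a tree or association matrix")
    assoc <- phylo_association(tree)
  }
  m <- unclass(table)
  n <- ncol(m)
  p <- relative_abundances(table)
  bmat <- (m > 0) * 1

  s <- switch(index,
    jci = {
      shared <- t(bmat) %*% bmat
      nt <- colSums(bmat)
      shared / (outer(nt, nt, "+") - shared)
    },
    jcw = {
      w <- t(p) %*% bmat      # W[A,B] = sum_{i present in B} p_Ai
      ## restrict to taxa present in BOTH: subtract p mass where partner absent
      ## t(p) %*% bmat already sums over partner-present taxa; taxa absent in A
      ## contribute 0, so W[A,B] = sum_{i in shared} p_Ai. Symmetrise:
      (w + t(w)) / 2
    },
    jcc = pairwise_apply(m, jaccard_chao),
    bc = {
      1 - as.matrix(vegan::vegdist(t(m), method = "bray"))
    },
    mh = {
      cross <- t(p) %*% p
      conc <- colSums(p^2)
      2 * cross / outer(conc, conc, "+")
    },
    ufu = {
      br <- precompute_branches(tree)
      check_all_tips(m, br)
      v <- (br$tip_below %*% bmat[br$tips, , drop = FALSE]) > 0
      lv <- br$lengths * v
      shared <- t(lv) %*% v
      tot <- colSums(lv)
      shared / (outer(tot, tot, "+") - shared)
    },
    ufw = {
      br <- precompute_branches(tree)
      check_all_tips(m, br)
      u <- br$tip_below %*% p[br$tips, , drop = FALSE]
      flow <- as.matrix(stats::dist(t(br$lengths * u), method = "manhattan"))
      c1 <- colSums(br$phi * p[br$tips, , drop = FALSE])
      1 - flow / outer(c1, c1, "+")
    },
    tu = tina_unweighted_all(bmat, assoc),
    pu = tina_unweighted_all(bmat, assoc),
    tw = tina_weighted_all(p, assoc),
    pw = tina_weighted_all(p, assoc)
  )
  dimnames(s) <- list(colnames(m), colnames(m))
  d <- 1 - s
  d[d < 0] <- 0       # clamp: D = max(0, 1 - S)
  diag(d) <- 0
  as_community_dist(d)
}

check_all_tips <- function(m, br) {
  miss <- setdiff(rownames(m), br$tips)
  if (length(miss)) {
    stop("taxa missing from tree: ", paste(utils::head(miss, 5), collapse = ", "),
         " (harmonise first)")
  }
}

align_assoc_matrix <- function(m, assoc) {
  miss <- setdiff(rownames(m), rownames(assoc))
  if (length(miss)) {
    stop("taxa absent from association matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  unclass(assoc)[rownames(m), rownames(m), drop = FALSE]
}

tina_unweighted_all <- function(bmat, assoc) {
  cmat <- align_assoc_matrix(bmat, assoc)
  cross <- t(bmat) %*% cmat %*% bmat
  nt <- colSums(bmat)
  cross / outer(nt, nt)
}

tina_weighted_all <- function(p, assoc) {
  cmat <- align_assoc_matrix(p, assoc)
  cross <- t(p) %*% cmat %*% p
  w <- diag(cross)
  if (any(w <= 0)) stop("zero within-sample weighted association")
  cross / sqrt(outer(w, w))
}

pairwise_apply <- function(m, f, ...) {
  n <- ncol(m)
  s <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s[i, j] <- s[j, i] <- f(m[, i], m[, j], ...)
      }
    }
  }
  s
}
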