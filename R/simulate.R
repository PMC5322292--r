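#' Habitat-structured signed interaction matrix
#'
#' Builds the ground-truth interaction matrix used by the interaction-driven
#' simulation scenarios: taxa are split into two groups; within each group
#' interactions live on the edges of a scale-free Barabasi-Albert graph
#' with magnitudes and signs drawn uniformly, while every between-group
#' interaction is competitive (strictly negative) with uniform noise. The
#' matrix is symmetric with zero diagonal (self-limitation is carried by
#' the logistic term of [glv_simulate()]).
#'
#' @param n_taxa number of taxa
#' @param groups group membership vector of length `n_taxa` with exactly
#'   two levels; default an even split
#' @param ba_edges_per_node edges added per node in the Barabasi-Albert
#'   graph (default 2); each group must have more taxa than this
#' @param strength_max within-group interaction magnitudes are
#'   Uniform(0, `strength_max`) (default 0.5)
#' @param competition between-group interactions are
#'   Uniform(`competition[1]`, `competition[2]`) (default c(-0.5, -0.1))
#' @param noise_sd half-width of the uniform noise added to between-group
#'   interactions (default 0.05)
#' @param taxa_ids taxon names (default `t1..tn`)
#' @param seed RNG seed
#' @return symmetric numeric matrix with attribute `groups`.
#' @export
make_interaction_matrix <- function(n_taxa, groups = NULL,
                                    ba_edges_per_node = 2,
                                    strength_max = 0.5,
                                    competition = c(-0.5, -0.1),
                                    noise_sd = 0.05,
                                    taxa_ids = NULL, seed = NULL) {
  if (is.null(groups)) {
    groups <- c(rep(1L, ceiling(n_taxa / 2)), rep(2L, floor(n_taxa / 2)))
  }
  if (length(groups) != n_taxa) stop("`groups` must have length n_taxa")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("`groups` must have exactly two levels")
  sizes <- table(groups)
  if (any(sizes < ba_edges_per_node + 1)) {
    stop("each group needs more than ba_edges_per_node taxa")
  }
  taxa_ids <- taxa_ids %||% paste0("t", seq_len(n_taxa))
  a <- matrix(0, n_taxa, n_taxa, dimnames = list(taxa_ids, taxa_ids))
  with_seed(seed, {
    for (lev in levels(groups)) {
      idx <- which(groups == lev)
      gr <- igraph::sample_pa(length(idx), m = ba_edges_per_node,
                              directed = FALSE)
      el <- igraph::as_edgelist(gr, names = FALSE)
      if (nrow(el)) {
        w <- stats::runif(nrow(el), 0, strength_max) *
          sample(c(-1, 1), nrow(el), replace = TRUE)
        a[cbind(idx[el[, 1]], idx[el[, 2]])] <- w
        a[cbind(idx[el[, 2]], idx[el[, 1]])] <- w
      }
    }
    between <- outer(as.integer(groups), as.integer(groups), "!=")
    ut <- between & upper.tri(a)
    nb <- sum(ut)
    w <- stats::runif(nb, competition[1], competition[2]) +
      stats::runif(nb, -noise_sd, noise_sd)
    a[ut] <- w
    a <- t(a); a[ut] <- w; a <- t(a)  # mirror into the lower triangle
  })
  if (any(a[outer(as.integer(groups), as.integer(groups), "!=")] >= 0)) {
    stop("internal error: non-negative between-group interaction")
  }
  attr(a, "groups") <- stats::setNames(as.character(groups), taxa_ids)
  a
}

#' Shuffle counts across samples
#'
#' Permutes each taxon's counts across samples, globally (destroying both
#' habitat-preference and co-abundance structure) or within habitat groups
#' (preserving habitat preference while destroying co-abundance). Per-taxon
#' totals are preserved exactly within the shuffling scope.
#'
#' @param table a [count_table()]
#' @param scope `"global"` or `"within_group"`
#' @param groups sample group labels (named or positional), required for
#'   `"within_group"`
#' @param seed RNG seed
#' @return a [count_table()]
#' @export
shuffle_counts <- function(table, scope = c("global", "within_group"),
                           groups = NULL, seed = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "count_table"))
  m <- unclass(table)
  with_seed(seed, {
    if (scope == "global") {
      for (i in seq_len(nrow(m))) m[i, ] <- m[i, sample.int(ncol(m))]
    } else {
      if (is.null(groups)) stop("`groups` required for within_group shuffling")
      groups <- align_labels(groups, colnames(m), "groups")
      for (lev in unique(groups)) {
        idx <- which(groups == lev)
        if (length(idx) > 1) {
          for (i in seq_len(nrow(m))) m[i, idx] <- m[i, idx[sample.int(length(idx))]]
        }
      }
    }
  })
  count_table(m, allow_empty_samples = TRUE)
}

#' Poisson starting counts
#'
#' i.i.d. Poisson(lambda) count table, the habitat-naive starting condition
#' of the interaction-driven simulation scenario.
#'
#' @param n_taxa,n_samples table dimensions
#' @param lambda Poisson mean (default 5)
#' @param seed RNG seed
#' @return a [count_table()]
#' @export
poisson_counts <- function(n_taxa, n_samples, lambda = 5, seed = NULL) {
  if (lambda < 0) stop("lambda must be non-negative")
  m <- with_seed(seed,
    matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
           dimnames = list(paste0("t", seq_len(n_taxa)),
                           paste0("s", seq_len(n_samples)))))
  count_table(m, allow_empty_samples = TRUE)
}

#' Assign mock habitat labels from taxa-group abundance
#'
#' Labels each sample by the taxa group holding the larger summed count;
#' exact ties go to the first group with a warning.
#'
#' @param table a [count_table()]
#' @param taxa_groups group membership vector over taxa (named or aligned
#'   to table rows) with two levels
#' @return named character vector sample -> group label
#' @export
assign_mock_habitats <- function(table, taxa_groups) {
  stopifnot(inherits(table, "count_table"))
  taxa_groups <- align_labels(taxa_groups, taxa_ids(table), "taxa_groups")
  taxa_groups <- as.factor(taxa_groups)
  if (nlevels(taxa_groups) != 2) stop("`taxa_groups` must have two levels")
  m <- unclass(table)
  sums <- rowsum(m, taxa_groups)         # 2 x samples
  ties <- sums[1, ] == sums[2, ]
  if (any(ties)) warning(sum(ties), " tied sample(s) assigned to group ",
                         levels(taxa_groups)[1])
  lab <- levels(taxa_groups)[ifelse(sums[1, ] >= sums[2, ], 1L, 2L)]
  stats::setNames(lab, colnames(m))
}

#' Sample count tables from a Dirichlet-multinomial mixture
#'
#' For each sample, a mixture component is drawn from `weights`, taxon
#' probabilities from Dirichlet(alpha) of that component, and counts from
#' Multinomial(depth, p). Only sampling is provided (no model fitting).
#'
#' @param component_weights mixture weights summing to 1
#' @param component_alphas list of positive alpha vectors, one per
#'   component, equal lengths (taxa)
#' @param depth sequencing depth per sample (> 0)
#' @param n_samples number of samples
#' @param taxa_ids,sample_ids identifiers (defaults `t*`, `s*`)
#' @param seed RNG seed
#' @return a [count_table()] with attribute `component`, the per-sample
#'   component index.
#' @export
sample_dirichlet_multinomial <- function(component_weights, component_alphas,
                                         depth, n_samples,
                                         taxa_ids = NULL, sample_ids = NULL,
                                         seed = NULL) {
  if (abs(sum(component_weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (depth <= 0) stop("depth must be positive")
  if (!is.list(component_alphas) ||
      length(component_alphas) != length(component_weights)) {
    stop("need one alpha vector per component")
  }
  n_taxa <- length(component_alphas[[1]])
  if (any(vapply(component_alphas, length, 1L) != n_taxa)) {
    stop("alpha vectors must have equal length")
  }
  if (any(unlist(component_alphas) <= 0)) stop("alphas must be positive")
  taxa_ids <- taxa_ids %||% paste0("t", seq_len(n_taxa))
  sample_ids <- sample_ids %||% paste0("s", seq_len(n_samples))
  with_seed(seed, {
    comp <- sample.int(length(component_weights), n_samples, replace = TRUE,
                       prob = component_weights)
    m <- matrix(0L, n_taxa, n_samples, dimnames = list(taxa_ids, sample_ids))
    for (s in seq_len(n_samples)) {
      alpha <- component_alphas[[comp[s]]]
      p <- stats::rgamma(n_taxa, shape = alpha, rate = 1)
      p <- p / sum(p)
      m[, s] <- stats::rmultinom(1, depth, p)
    }
  })
  out <- count_table(m, allow_empty_samples = TRUE)
  attr(out, "component") <- stats::setNames(comp, sample_ids)
  out
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's individuals without replacement to exactly
#' `depth`. Samples with fewer than `depth` individuals are dropped with a
#' warning; taxa left with all-zero counts are removed.
#'
#' @param table a [count_table()]
#' @param depth target depth (>= 1)
#' @param seed RNG seed
#' @return a [count_table()] whose sample totals all equal `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (depth < 1) stop("depth must be >= 1")
  m <- unclass(table)
  tot <- colSums(m)
  keep <- tot >= depth
  if (!any(keep)) stop("every sample is below the rarefaction depth")
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(utils::head(colnames(m)[!keep], 5), collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  with_seed(seed, {
    for (s in seq_len(ncol(m))) {
      if (sum(m[, s]) == depth) next
      pool <- rep.int(seq_len(nrow(m)), m[, s])
      draw <- sample(pool, depth, replace = FALSE)
      m[, s] <- tabulate(draw, nbins = nrow(m))
    }
  })
  m <- m[rowSums(m) > 0, , drop = FALSE]
  count_table(m)
}
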