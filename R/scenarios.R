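#' Benchmark simulation scenarios
#'
#' Composes the simulation engines into the four benchmark setups used to
#' probe what signal an index responds to. Each scenario returns a count
#' table, per-sample habitat labels, the per-taxon habitat-preference
#' groups and (when interactions are non-neutral) the ground-truth
#' interaction matrix:
#' \describe{
#'   \item{`negative_control`}{taxon counts shuffled globally across
#'     samples (destroying habitat preference and co-abundance), then
#'     interaction-neutral GLV dynamics; no index should separate the
#'     groups.}
#'   \item{`habitat_only`}{counts shuffled within habitat groups
#'     (preserving habitat preference, destroying co-abundance), then
#'     interaction-neutral GLV dynamics.}
#'   \item{`interaction_only`}{habitat-naive Poisson(5) starting counts,
#'     invariant growth rates, and a two-group competitive interaction
#'     matrix ([make_interaction_matrix()]); samples are labelled post hoc
#'     by dominant taxa group ([assign_mock_habitats()]).}
#'   \item{`habitat_plus_interaction`}{within-group shuffled counts
#'     (habitat preference kept) combined with the structured interaction
#'     matrix.}
#' }
#' When `base` is not supplied, a habitat-structured base table is drawn
#' from a two-component Dirichlet-multinomial mixture in which each
#' component favours one half of the taxa (see [dmm_base_table()]).
#'
#' @param name scenario name, see Details
#' @param base optional list with elements `counts` (a [count_table()]),
#'   `labels` (sample -> habitat) and `taxa_groups` (taxon -> preferred
#'   habitat); default generated by [dmm_base_table()]
#' @param n_taxa,n_samples dimensions of the default base table
#'   (default 200 taxa, 50 samples)
#' @param seed master RNG seed; stage seeds are derived deterministically
#' @return list with `counts`, `labels`, `taxa_groups`, `interactions`
#'   (ground-truth matrix or `NULL`) and `name`.
#' @export
make_benchmark_scenario <- function(name = c("negative_control", "habitat_only",
                                             "interaction_only",
                                             "habitat_plus_interaction"),
                                    base = NULL, n_taxa = 200, n_samples = 50,
                                    seed = NULL) {
  name <- match.arg(name)
  if (name != "interaction_only" && is.null(base)) {
    base <- dmm_base_table(n_taxa, n_samples, seed = stage_seed(seed, 1))
  }
  out <- switch(name,
    negative_control = {
      sh <- shuffle_counts(base$counts, "global", seed = stage_seed(seed, 2))
      counts <- neutral_glv(sh, stage_seed(seed, 3))
      list(counts = counts, labels = base$labels,
           taxa_groups = base$taxa_groups, interactions = NULL)
    },
    habitat_only = {
      sh <- shuffle_counts(base$counts, "within_group", groups = base$labels,
                           seed = stage_seed(seed, 2))
      counts <- neutral_glv(sh, stage_seed(seed, 3))
      list(counts = counts, labels = base$labels,
           taxa_groups = base$taxa_groups, interactions = NULL)
    },
    interaction_only = {
      start <- poisson_counts(n_taxa, n_samples, lambda = 5,
                              seed = stage_seed(seed, 2))
      groups <- c(rep("g1", ceiling(n_taxa / 2)), rep("g2", floor(n_taxa / 2)))
      names(groups) <- taxa_ids(start)
      a <- make_interaction_matrix(n_taxa, groups = groups,
                                   taxa_ids = taxa_ids(start),
                                   seed = stage_seed(seed, 3))
      counts <- glv_simulate(start, interactions = a,
                             growth_rates = rep(0.5, n_taxa),
                             carrying_capacity = 10 * sample_totals(start),
                             seed = stage_seed(seed, 4))
      counts <- drop_empty_samples(counts)
      labels <- assign_mock_habitats(counts, groups[taxa_ids(counts)])
      list(counts = counts, labels = labels, taxa_groups = groups,
           interactions = a)
    },
    habitat_plus_interaction = {
      sh <- shuffle_counts(base$counts, "within_group", groups = base$labels,
                           seed = stage_seed(seed, 2))
      a <- make_interaction_matrix(nrow(sh), groups = base$taxa_groups,
                                   taxa_ids = taxa_ids(sh),
                                   seed = stage_seed(seed, 3))
      start <- scale_to_fraction(sh, 0.1, stage_seed(seed, 4))
      counts <- glv_simulate(start, interactions = a,
                             carrying_capacity = sample_totals(sh),
                             seed = stage_seed(seed, 5))
      counts <- drop_empty_samples(counts)
      list(counts = counts, labels = base$labels[sample_ids(counts)],
           taxa_groups = base$taxa_groups, interactions = a)
    }
  )
  out$name <- name
  out
}

## Interaction-neutral GLV pass: downscale to 10% of capacity, grow back.
neutral_glv <- function(counts, seed) {
  keep <- sample_totals(counts) > 0
  counts <- count_table(unclass(counts)[, keep, drop = FALSE])
  start <- scale_to_fraction(counts, 0.1, stage_seed(seed, 1))
  out <- glv_simulate(start, interactions = NULL,
                      carrying_capacity = sample_totals(counts),
                      seed = stage_seed(seed, 2))
  drop_empty_samples(out)
}

scale_to_fraction <- function(counts, fraction, seed) {
  m <- unclass(counts)
  out <- with_seed(seed, stochastic_round(m * fraction))
  count_table(out, allow_empty_samples = TRUE)
}

drop_empty_samples <- function(counts) {
  keep <- sample_totals(counts) > 0
  count_table(unclass(counts)[, keep, drop = FALSE])
}

#' Habitat-structured Dirichlet-multinomial base table
#'
#' The synthetic stand-in for a two-habitat microbiome count table: a
#' two-component Dirichlet-multinomial mixture over `n_taxa` taxa split
#' into two preference groups. Component k uses a lognormal(0, 1) alpha
#' template with off-habitat taxa down-weighted by `off_scale`, so samples
#' from different components are dominated by different taxa groups while
#' still overlapping. Emulates habitat preference and sampling noise; it
#' carries no taxa interaction signal.
#'
#' @param n_taxa,n_samples table dimensions (samples split evenly between
#'   the two habitats)
#' @param depth per-sample sequencing depth (default 5000)
#' @param off_scale down-weighting of off-habitat alphas (default 0.02)
#' @param seed RNG seed
#' @return list with `counts`, `labels` (sample -> "h1"/"h2") and
#'   `taxa_groups` (taxon -> "h1"/"h2").
#' @export
dmm_base_table <- function(n_taxa = 200, n_samples = 50, depth = 5000,
                           off_scale = 0.02, seed = NULL) {
  g1 <- ceiling(n_taxa / 2)
  taxa_groups <- c(rep("h1", g1), rep("h2", n_taxa - g1))
  tab <- with_seed(seed, {
    template <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1)
    alpha1 <- template * ifelse(taxa_groups == "h1", 1, off_scale)
    alpha2 <- template * ifelse(taxa_groups == "h2", 1, off_scale)
    ## fixed half/half design: first half of samples from habitat 1
    n1 <- ceiling(n_samples / 2)
    comp <- c(rep(1L, n1), rep(2L, n_samples - n1))
    m <- matrix(0L, n_taxa, n_samples,
                dimnames = list(paste0("t", seq_len(n_taxa)),
                                paste0("s", seq_len(n_samples))))
    for (s in seq_len(n_samples)) {
      alpha <- if (comp[s] == 1L) alpha1 else alpha2
      p <- stats::rgamma(n_taxa, shape = alpha, rate = 1)
      p <- p / sum(p)
      m[, s] <- stats::rmultinom(1, depth, p)
    }
    structure(count_table(m, allow_empty_samples = TRUE),
              component = comp)
  })
  comp <- attr(tab, "component")
  labels <- stats::setNames(paste0("h", comp), sample_ids(tab))
  names(taxa_groups) <- taxa_ids(tab)
  list(counts = tab, labels = labels, taxa_groups = taxa_groups)
}
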