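#' Benchmark community similarity indices on one dataset
#'
#' Runs the full per-index pipeline on a labelled count table: infer the
#' taxa co-occurrence network from the same samples under analysis, apply
#' the association transform, build each index's distance matrix, and test
#' group separation by PERMANOVA. Returns one row per index with the
#' pseudo-F, R-squared and permutation p-value.
#'
#' @param counts a [count_table()]
#' @param labels sample group labels (named or positional)
#' @param indices index codes (see [index_registry()]); defaults to every
#'   index whose auxiliaries are available
#' @param tree optional rooted [ape::phylo] enabling `ufu`, `ufw`, `pu`,
#'   `pw`
#' @param network_method co-occurrence inference method for `tu`/`tw`
#'   (default `"sparcc"`)
#' @param interactions optional raw interaction matrix used for `tu`/`tw`
#'   instead of inferring one from counts (e.g. a known ground-truth
#'   matrix); passed through [transform_association()]
#' @param n_perm PERMANOVA permutations (default 999)
#' @param seed master seed; stage seeds are derived deterministically
#' @return data.frame with columns `index`, `network`, `F`, `R2`, `p`.
#' @export
run_benchmark <- function(counts, labels, indices = NULL, tree = NULL,
                          network_method = "sparcc", interactions = NULL,
                          n_perm = 999, seed = NULL) {
  stopifnot(inherits(counts, "count_table"))
  labels <- align_labels(labels, sample_ids(counts), "labels")
  names(labels) <- sample_ids(counts)
  ## taxa never observed carry no information and have no defined association
  zero <- rowSums(unclass(counts)) == 0
  if (any(zero)) {
    counts <- count_table(unclass(counts)[!zero, , drop = FALSE])
  }
  if (!is.null(tree)) {
    h <- harmonise(counts, tree = tree)
    counts <- h$table; tree <- h$tree
  }
  reg <- index_registry()
  if (is.null(indices)) {
    indices <- reg$code[reg$requires == "none" | !is.null(tree) |
                          reg$requires == "assoc"]
  }
  indices <- match.arg(tolower(indices), reg$code, several.ok = TRUE)
  bad <- indices[reg$requires[match(indices, reg$code)] %in%
                   c("tree", "phylo_assoc") & is.null(tree)]
  if (length(bad)) {
    stop("index(es) require a tree: ", paste(bad, collapse = ", "))
  }

  assoc <- NULL
  if (any(indices %in% c("tu", "tw"))) {
    net_tag <- if (!is.null(interactions)) "known" else network_method
    raw <- if (!is.null(interactions)) {
      interactions
    } else {
      infer_cooccurrence(counts, method = network_method,
                         seed = stage_seed(seed, 11))
    }
    assoc <- transform_association(raw)
  } else {
    net_tag <- NA_character_
  }
  phi <- if (any(indices %in% c("pu", "pw"))) phylo_association(tree) else NULL

  rows <- lapply(seq_along(indices), function(k) {
    code <- indices[k]
    aux <- switch(reg$requires[match(code, reg$code)],
                  none = list(), tree = list(tree = tree),
                  assoc = list(assoc = assoc),
                  phylo_assoc = list(assoc = phi))
    d <- do.call(distance_matrix, c(list(table = counts, index = code), aux))
    pr <- permanova(d, labels, n_perm = n_perm, seed = stage_seed(seed, 20 + k))
    data.frame(index = code,
               network = if (code %in% c("tu", "tw")) net_tag else NA_character_,
               F = pr$terms$F[1], R2 = pr$terms$R2[1], p = pr$terms$p[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Downsampling robustness benchmark
#'
#' Repeats [run_benchmark()] over random subsets of samples (per-group
#' subset sizes) and/or rarefaction depths, re-inferring the co-occurrence
#' network for every subset, and returns a long-format table of per-regime
#' per-iteration results.
#'
#' @inheritParams run_benchmark
#' @param samples_per_group vector of per-group sample counts to test
#'   (`NULL` to skip)
#' @param depths vector of rarefaction depths to test (`NULL` to skip)
#' @param n_iter iterations per regime (default 10)
#' @return data.frame with columns `regime_type`, `regime`, `iteration`,
#'   `n_samples`, `index`, `network`, `F`, `R2`, `p`. Infeasible regimes
#'   are skipped with a warning.
#' @export
run_downsampling <- function(counts, labels, samples_per_group = NULL,
                             depths = NULL, n_iter = 10, indices = NULL,
                             tree = NULL, network_method = "sparcc",
                             n_perm = 999, seed = NULL) {
  stopifnot(inherits(counts, "count_table"))
  labels <- align_labels(labels, sample_ids(counts), "labels")
  out <- list()
  step <- 0L
  for (g in samples_per_group %||% numeric(0)) {
    if (any(table(labels) < g)) {
      warning("regime ", g, " samples/group infeasible; skipped")
      next
    }
    for (it in seq_len(n_iter)) {
      step <- step + 1L
      sub <- with_seed(stage_seed(seed, 100 + step), {
        unlist(lapply(split(seq_along(labels), labels),
                      function(ix) sample(ix, g)))
      })
      tab <- count_table(unclass(counts)[, sub, drop = FALSE],
                         allow_empty_samples = TRUE)
      tab <- count_table(unclass(tab)[rowSums(tab) > 0, , drop = FALSE])
      res <- run_benchmark(tab, labels[sub], indices = indices, tree = tree,
                           network_method = network_method, n_perm = n_perm,
                           seed = stage_seed(seed, 200 + step))
      out[[length(out) + 1L]] <- data.frame(
        regime_type = "samples_per_group", regime = g, iteration = it,
        n_samples = ncol(tab), res, stringsAsFactors = FALSE)
    }
  }
  for (dp in depths %||% numeric(0)) {
    if (all(sample_totals(counts) < dp)) {
      warning("depth ", dp, " infeasible; skipped")
      next
    }
    for (it in seq_len(n_iter)) {
      step <- step + 1L
      tab <- rarefy(counts, dp, seed = stage_seed(seed, 300 + step))
      res <- run_benchmark(tab, labels[sample_ids(tab)], indices = indices,
                           tree = tree, network_method = network_method,
                           n_perm = n_perm, seed = stage_seed(seed, 400 + step))
      out[[length(out) + 1L]] <- data.frame(
        regime_type = "depth", regime = dp, iteration = it,
        n_samples = ncol(tab), res, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no feasible regimes")
  do.call(rbind, out)
}
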