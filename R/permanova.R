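#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sum of squares of a community distance matrix by a
#' grouping factor (Anderson 2001; McArdle & Anderson 2001) and tests the
#' pseudo-F statistic by free permutation of sample labels. With a groups
#' and n samples,
#' \deqn{F = \frac{SS_{between}/(a-1)}{SS_{within}/(n-a)}, \qquad
#'       R^2 = SS_{between}/SS_{total},}
#' with sums of squares computed from squared distances
#' (\eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g}). The
#' permutation p-value uses the +1 correction,
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}, so it is
#' never exactly zero.
#'
#' @param d a `"community_dist"` matrix (or symmetric matrix / `dist`)
#' @param groups group labels, either named by sample ID or aligned
#'   positionally with the rows of `d`; at least 2 groups with at least 2
#'   samples each
#' @param n_perm number of label permutations (default 999)
#' @param seed RNG seed for the permutations
#' @return object of class `"permanova"`: a list with a per-term results
#'   data.frame (`terms`: df, SS, F, R2, p) and `n_perm`.
#' @references Anderson MJ (2001) A new method for non-parametric
#'   multivariate analysis of variance. Austral Ecology 26:32-46.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as_community_dist(d)
  groups <- align_labels(groups, rownames(d), "groups")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) {
    stop("singleton group(s): ",
         paste(names(which(table(groups) < 2)), collapse = ", "))
  }
  if (any(!is.finite(d))) stop("non-finite distances")
  df <- data.frame(group = groups)
  res <- permanova_engine(d, df, "group", n_perm, seed)
  res$terms$term[1] <- "groups"
  res
}

#' PERMANOVA with sequential multi-term models
#'
#' Sequential (Type I) partition of the distance-matrix sum of squares
#' across an ordered list of terms, including interaction terms written as
#' `"a:b"`, in the adonis convention. Each term's F is tested against the
#' residual mean square under free permutation of samples.
#'
#' @inheritParams permanova
#' @param data data.frame of factors/covariates, rows aligned to (or named
#'   by) the samples of `d`
#' @param terms character vector of term labels in model order, e.g.
#'   `c("region", "depth", "region:depth")`
#' @return `"permanova"` object with one row per term.
#' @export
permanova_formula <- function(d, data, terms, n_perm = 999, seed = NULL) {
  d <- as_community_dist(d)
  if (!is.null(rownames(data)) &&
      !all(rownames(data) == as.character(seq_len(nrow(data)))) &&
      !is.null(rownames(d))) {
    miss <- setdiff(rownames(d), rownames(data))
    if (length(miss)) stop("samples missing from metadata: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    data <- data[rownames(d), , drop = FALSE]
  }
  if (nrow(data) != nrow(d)) stop("metadata rows must match samples")
  permanova_engine(d, data, terms, n_perm, seed)
}

## Shared engine: Gower-centred inner-product matrix G, hat matrices per
## cumulative model, traces give the sequential SS partition.
permanova_engine <- function(d, data, terms, n_perm, seed) {
  n <- nrow(d)
  a2 <- -0.5 * unclass(d)^2
  g <- a2 - rowMeans(a2)[row(a2)] - colMeans(a2)[col(a2)] + mean(a2)
  ss_total <- sum(diag(g))

  hats <- list()
  dfs <- numeric(0)
  x_prev <- matrix(1, n, 1)
  q_prev <- qr(x_prev)
  for (k in seq_along(terms)) {
    tm <- terms[k]
    fml <- stats::as.formula(paste("~", paste(c("1", terms[seq_len(k)]),
                                              collapse = "+")))
    x <- stats::model.matrix(fml, data)
    q <- qr(x)
    df_t <- q$rank - q_prev$rank
    if (df_t <= 0) stop("term '", tm, "' is aliased with preceding terms")
    h_cum <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    h_prev <- tcrossprod(qr.Q(q_prev)[, seq_len(q_prev$rank), drop = FALSE])
    hats[[tm]] <- h_cum - h_prev
    dfs[tm] <- df_t
    q_prev <- q
  }
  df_res <- n - q_prev$rank
  if (df_res <= 0) stop("no residual degrees of freedom")

  ss_obs <- vapply(hats, function(h) sum(h * g), numeric(1))
  ss_res <- ss_total - sum(ss_obs)
  f_obs <- (ss_obs / dfs) / (ss_res / df_res)

  exceed <- numeric(length(terms))
  if (n_perm >= 1) {
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        gp <- g[idx, idx]
        ssp <- vapply(hats, function(h) sum(h * gp), numeric(1))
        ssr <- ss_total - sum(ssp)
        fp <- (ssp / dfs) / (ssr / df_res)
        exceed <- exceed + (fp >= f_obs - 1e-12)
      }
    })
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss_obs, ss_res, ss_total),
    F = c(f_obs, NA, NA),
    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
    p = c(pvals, NA, NA),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(terms = tab, n_perm = n_perm), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_perm, " free permutations)\n", sep = "")
  tab <- x$terms
  tab$SS <- signif(tab$SS, 5); tab$F <- signif(tab$F, 5)
  tab$R2 <- signif(tab$R2, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

align_labels <- function(lab, ids, what) {
  if (!is.null(names(lab)) && !is.null(ids)) {
    miss <- setdiff(ids, names(lab))
    if (length(miss)) stop(what, " missing for sample(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    lab <- lab[ids]
  }
  if (length(lab) != length(ids)) stop(what, " must cover every sample")
  lab
}

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a distance matrix by eigendecomposition of the double-centred
#' squared-distance matrix. Axes are ordered by decreasing eigenvalue;
#' negative eigenvalues are reported but coordinates are returned only for
#' positive axes (no Cailliez/Lingoes correction).
#'
#' @param d a `"community_dist"` matrix (or `dist`)
#' @param n_axes number of axes requested (default 2)
#' @return list of class `"pcoa"` with `points` (samples x axes),
#'   `eigenvalues` (all, descending) and `rel_eig` (relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as_community_dist(d)
  n <- nrow(d)
  res <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = max(1, n - 1), eig = TRUE))
  eig <- res$eig
  npos <- sum(eig > max(abs(eig)) * 1e-10)
  if (n_axes > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning ", npos, " axes")
    n_axes <- npos
  }
  pts <- res$points[, seq_len(n_axes), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(n_axes))
  structure(list(points = pts, eigenvalues = eig,
                 rel_eig = pmax(eig, 0) / sum(pmax(eig, 0))),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes returned; first axes explain %s\n",
              nrow(x$points), ncol(x$points),
              paste(sprintf("%.1f%%", 100 * x$rel_eig[seq_len(ncol(x$points))]),
                    collapse = ", ")))
  invisible(x)
}

#' Rank correlation of community distance with a sample gradient
#'
#' Spearman correlation between the upper triangle of a distance matrix
#' and the pairwise absolute differences of a numeric covariate (e.g.
#' latitude), the standard test for a distance-gradient trend.
#'
#' @param d a `"community_dist"` matrix
#' @param covariate numeric covariate, named by sample or positionally
#'   aligned
#' @param transform pairwise transform of the covariate; only `"absdiff"`
#' @return Spearman's rho (scalar)
#' @export
gradient_correlation <- function(d, covariate, transform = c("absdiff")) {
  transform <- match.arg(transform)
  d <- as_community_dist(d)
  covariate <- align_labels(covariate, rownames(d), "covariate")
  if (!is.numeric(covariate)) stop("covariate must be numeric")
  if (length(unique(covariate)) < 2) stop("covariate is constant; correlation undefined")
  ut <- upper.tri(d)
  delta <- abs(outer(covariate, covariate, "-"))
  stats::cor(d[ut], delta[ut], method = "spearman")
}
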