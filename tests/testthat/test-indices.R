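# Independent scalar oracles, written directly from the index formulas.
oracle_chao_u <- function(a, b) {
  sh <- a > 0 & b > 0
  if (!any(sh)) return(0)
  f1 <- sum(sh & b == 1); f2 <- sum(sh & b == 2)
  u <- sum(a[sh]) / sum(a) +
    ((sum(b) - 1) / sum(b)) * (f1 / (2 * max(f2, 1))) * sum(a[sh & b == 1]) / sum(a)
  min(1, u)
}
oracle_jcc <- function(a, b) {
  u <- oracle_chao_u(a, b); v <- oracle_chao_u(b, a)
  if (u == 0 || v == 0) 0 else u * v / (u + v - u * v)
}

test_that("count-based indices reproduce hand-computed values", {
  t3 <- c(t1 = 1, t2 = 1, t3 = 1, t4 = 0)
  t3b <- c(t1 = 0, t2 = 1, t3 = 1, t4 = 1)
  expect_equal(jaccard_classical(t3, t3b), 0.5)        # 2 shared / 4 union

  a <- c(t1 = 8, t2 = 2, t3 = 0); b <- c(t1 = 0, t2 = 5, t3 = 5)
  expect_equal(jaccard_weighted(a, b), 0.35)           # (2/10 + 5/10)/2

  a2 <- c(2, 2, 0); b2 <- c(0, 2, 2)
  expect_equal(bray_curtis(a2, b2), 0.5)               # 2*2/8
  expect_equal(morisita_horn(a2, b2), 0.5)             # 2*.25/(.5+.5)
})

test_that("identical and disjoint samples hit the index endpoints", {
  set.seed(77)
  x <- rpois(12, 4) + 1
  names(x) <- paste0("t", 1:12)
  y <- c(rep(0, 6), x[7:12] + 3); z <- c(x[1:6], rep(0, 6))
  names(y) <- names(z) <- names(x)
  for (f in list(jaccard_classical, jaccard_weighted, jaccard_chao,
                 bray_curtis, morisita_horn)) {
    expect_equal(f(x, x), 1)
    expect_equal(f(y, z), 0)
  }
})

test_that("chao-corrected jaccard matches an independent formula-9 oracle", {
  a <- c(t1 = 4, t2 = 1, t3 = 3, t4 = 0, t5 = 2, t6 = 0)
  b <- c(t1 = 1, t2 = 0, t3 = 2, t4 = 5, t5 = 1, t6 = 3)
  expect_equal(jaccard_chao(a, b), oracle_jcc(a, b), tolerance = 1e-12)
  # shared taxa present, one a singleton in the partner sample
  set.seed(31)
  for (k in 1:20) {
    x <- rpois(8, 2); y <- rpois(8, 2)
    if (sum(x) == 0 || sum(y) == 0 || !any(x > 0 & y > 0)) next
    names(x) <- names(y) <- paste0("t", 1:8)
    expect_equal(jaccard_chao(x, y), oracle_jcc(x, y), tolerance = 1e-12)
  }
})

test_that("unweighted unifrac equals an explicit edge-set oracle", {
  tr <- balanced_tree()
  a <- c(A = 1, B = 0, C = 0, D = 0); c_ <- c(A = 0, B = 0, C = 1, D = 0)
  expect_equal(unifrac_unweighted(a, c_, tr), 0)    # no shared branches
  ab <- c(A = 2, B = 1, C = 0, D = 0); ac <- c(A = 1, B = 0, C = 3, D = 0)
  # shared: tip edge A plus the inner edge above the (A,B) cherry (a leaf
  # below it is observed in both) = 2; union: tips A, B, C + both inner = 5
  expect_equal(unifrac_unweighted(ab, ac, tr), 2 / 5)
  expect_equal(unifrac_unweighted(ab, ab, tr), 1)
  expect_error(unifrac_unweighted(c(A = 1, X = 1), c(A = 1, X = 0), tr),
               "missing from tree")
})

test_that("weighted unifrac equals a per-branch oracle and matches phyloseq", {
  tr <- balanced_tree()
  pa <- c(A = .5, B = .5, C = 0, D = 0); pb <- c(A = 0, B = .25, C = .5, D = .25)
  # per-branch flow difference over branches (A,B,C,D, two inner edges)
  flow <- 1 * abs(.5 - 0) + 1 * abs(.5 - .25) + 1 * abs(0 - .5) +
    1 * abs(0 - .25) + 1 * abs(1 - .25) + 1 * abs(0 - .75)
  denom <- sum(2 * (pa + pb))   # every leaf at depth 2
  expect_equal(unifrac_weighted(pa * 4, pb * 4, tr), 1 - flow / denom,
               tolerance = 1e-12)
  expect_equal(unifrac_weighted(pa * 4, pa * 8, tr), 1)

  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unifrac_weighted(c(A = 3, B = 0), c(A = 0, B = 2), two), 0)

  skip_if_not_installed("phyloseq")
  ct <- random_counts(8, 6, seed = 5)
  set.seed(6); rtr <- ape::rtree(8, tip.label = taxa_ids(ct))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(unclass(ct), taxa_are_rows = TRUE),
    phyloseq::phy_tree(rtr))
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  ids <- sample_ids(ct)
  expect_equal(unclass(distance_matrix(ct, "ufw", tree = rtr)),
               ref_w[ids, ids], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(distance_matrix(ct, "ufu", tree = rtr)),
               ref_u[ids, ids], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("unweighted TINA averages cross-community associations", {
  ids <- paste0("t", 1:3)
  cm <- matrix(c(1, .4, .6, .4, 1, .2, .6, .2, 1), 3, 3,
               dimnames = list(ids, ids))
  a <- c(t1 = 2, t2 = 1, t3 = 0); b <- c(t1 = 0, t2 = 3, t3 = 1)
  # observed A = {t1,t2}, B = {t2,t3}: mean of C[1,2],C[1,3],C[2,2],C[2,3]
  expect_equal(tina_unweighted(a, b, cm), mean(c(.4, .6, 1, .2)))

  # disjoint samples under constant association regimes
  ids2 <- paste0("t", 1:12)
  a2 <- c(rep(1, 5), rep(0, 7)); b2 <- c(rep(0, 5), rep(1, 7))
  names(a2) <- names(b2) <- ids2
  expect_equal(tina_unweighted(a2, b2, uniform_assoc(ids2, 0.5)), 0.5)
  expect_equal(tina_unweighted(a2, b2, uniform_assoc(ids2, 0)), 0)
  expect_equal(tina_unweighted(a2, b2, uniform_assoc(ids2, 1)), 1)
})

test_that("weighted TINA is a normalised bilinear form", {
  ids <- paste0("t", 1:3)
  cm <- matrix(c(1, .4, .6, .4, 1, .2, .6, .2, 1), 3, 3,
               dimnames = list(ids, ids))
  a <- c(t1 = 6, t2 = 3, t3 = 1); b <- c(t1 = 1, t2 = 0, t3 = 4)
  pa <- a / sum(a); pb <- b / sum(b)
  oracle <- (pa %*% cm %*% pb) /
    sqrt((pa %*% cm %*% pa) * (pb %*% cm %*% pb))
  expect_equal(tina_weighted(a, b, cm), drop(oracle), tolerance = 1e-12)
  expect_equal(tina_weighted(a, a * 3, cm), 1)   # self-similarity, any scale

  # disjoint communities, zero cross association, arbitrary within
  ids4 <- paste0("t", 1:4)
  cz <- matrix(0, 4, 4, dimnames = list(ids4, ids4))
  cz[1, 2] <- cz[2, 1] <- .8; cz[3, 4] <- cz[4, 3] <- .3
  diag(cz) <- 1
  expect_equal(tina_weighted(c(2, 1, 0, 0), c(0, 0, 1, 5), cz), 0)
})

test_that("PINA wrappers share the TINA contracts", {
  phi <- random_assoc(6, seed = 41)
  a <- c(3, 1, 0, 2, 0, 0); b <- c(0, 0, 2, 1, 4, 0)
  names(a) <- names(b) <- rownames(phi)
  expect_equal(pina_unweighted(a, b, phi), tina_unweighted(a, b, phi))
  expect_equal(pina_weighted(a, a, phi), 1)
})

test_that("all-pairs distance matrices equal per-pair scalar computation", {
  ct <- random_counts(12, 10, seed = 8)
  set.seed(9); tr <- ape::rtree(12, tip.label = taxa_ids(ct))
  cm <- random_assoc(12, seed = 10)
  rownames(cm) <- colnames(cm) <- taxa_ids(ct)
  phi <- phylo_association(tr)
  m <- unclass(ct)
  aux <- list(jci = list(), jcw = list(), jcc = list(), bc = list(),
              mh = list(),
              ufu = list(tree = tr), ufw = list(tree = tr),
              tu = list(assoc = cm), tw = list(assoc = cm),
              pu = list(assoc = phi), pw = list(assoc = phi))
  funs <- list(jci = jaccard_classical, jcw = jaccard_weighted,
               jcc = jaccard_chao, bc = bray_curtis, mh = morisita_horn,
               ufu = unifrac_unweighted, ufw = unifrac_weighted,
               tu = tina_unweighted, tw = tina_weighted,
               pu = pina_unweighted, pw = pina_weighted)
  for (code in names(funs)) {
    d <- distance_matrix(ct, code, tree = tr,
                         assoc = aux[[code]]$assoc)
    expect_equal(unname(diag(unclass(d))), rep(0, 10))
    for (i in c(1, 4)) for (j in c(7, 10)) {
      extra <- aux[[code]]
      s <- do.call(funs[[code]], c(list(m[, i], m[, j]), extra))
      expect_equal(unclass(d)[i, j], max(0, 1 - s), tolerance = 1e-12,
                   label = paste("index", code))
    }
  }
})

test_that("similarities are symmetric, bounded, and incidence-invariant", {
  ct <- random_counts(10, 6, seed = 12)
  set.seed(13); tr <- ape::rtree(10, tip.label = taxa_ids(ct))
  cm <- random_assoc(10, seed = 14)
  rownames(cm) <- colnames(cm) <- taxa_ids(ct)
  m <- unclass(ct)
  for (code in index_registry()$code) {
    d <- unclass(distance_matrix(ct, code, tree = tr, assoc = cm))
    expect_symmetric_01(d)
  }
  # incidence-only indices unaffected by abundance rescaling
  m2 <- m * 7L
  ct2 <- count_table(m2)
  for (code in c("jci", "ufu", "tu", "pu")) {
    expect_equal(unclass(distance_matrix(ct, code, tree = tr, assoc = cm)),
                 unclass(distance_matrix(ct2, code, tree = tr, assoc = cm)),
                 tolerance = 1e-12)
  }
})

test_that("taxon order does not affect shared-taxon sums", {
  ct <- random_counts(9, 4, seed = 15)
  perm <- sample(9)
  ct2 <- count_table(unclass(ct)[perm, , drop = FALSE])
  for (code in c("jci", "jcw", "jcc", "bc", "mh")) {
    expect_equal(unclass(distance_matrix(ct, code)),
                 unclass(distance_matrix(ct2, code)), tolerance = 1e-12)
  }
})

test_that("auxiliary requirements are enforced before computation", {
  ct <- random_counts(5, 4, seed = 16)
  expect_error(distance_matrix(ct, "ufu"), "tree")
  expect_error(distance_matrix(ct, "tw"), "association")
  expect_error(tina_unweighted(c(x = 1, y = 2), c(x = 2, y = 0),
                               uniform_assoc(c("x"), 0.5)),
               "absent from association")
})
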