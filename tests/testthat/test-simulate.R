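test_that("glv with zero interactions approaches carrying capacity", {
  start <- poisson_counts(30, 8, lambda = 5, seed = 1)
  k <- 10 * sample_totals(start)
  out <- glv_simulate(start, growth_rates = runif(30, 0.5, 1),
                      carrying_capacity = k, n_steps = 600, seed = 2)
  expect_true(all(abs(sample_totals(out) - k) / k < 0.01))
})

test_that("glv fixed point: zero growth and interactions leave counts unchanged", {
  start <- poisson_counts(10, 5, lambda = 4, seed = 3)
  out <- glv_simulate(start, growth_rates = rep(0, 10),
                      carrying_capacity = sample_totals(start) * 10, seed = 4)
  expect_equal(unclass(out), unclass(start))
})

test_that("glv is deterministic given a seed and errors on divergence", {
  start <- poisson_counts(12, 4, lambda = 5, seed = 5)
  a <- make_interaction_matrix(12, ba_edges_per_node = 1, seed = 6)
  o1 <- glv_simulate(start, interactions = a, growth_rates = rep(.5, 12),
                     carrying_capacity = 10 * sample_totals(start), seed = 7)
  o2 <- glv_simulate(start, interactions = a, growth_rates = rep(.5, 12),
                     carrying_capacity = 10 * sample_totals(start), seed = 7)
  expect_identical(unclass(o1), unclass(o2))

  pos <- matrix(2, 12, 12, dimnames = dimnames(a))  # runaway mutualism
  diag(pos) <- 0
  expect_error(
    glv_simulate(start, interactions = pos, growth_rates = rep(.5, 12),
                 carrying_capacity = 10 * sample_totals(start),
                 n_steps = 2000, seed = 8),
    "divergence|non-finite")
  neg_diag <- a; diag(neg_diag) <- 0.5
  expect_error(glv_simulate(start, interactions = neg_diag), "diagonal")
})

test_that("strong between-group competition produces dominance", {
  n_taxa <- 40
  start <- poisson_counts(n_taxa, 20, lambda = 5, seed = 9)
  groups <- rep(c(1, 2), each = 20)
  a <- matrix(0, n_taxa, n_taxa, dimnames = dimnames(make_interaction_matrix(n_taxa, seed = 1)))
  a[groups == 1, groups == 2] <- -2
  a[groups == 2, groups == 1] <- -2
  out <- glv_simulate(start, interactions = a, growth_rates = rep(.5, n_taxa),
                      carrying_capacity = 10 * sample_totals(start),
                      n_steps = 500, seed = 10)
  m <- unclass(out)
  frac_minority <- apply(m, 2, function(x) {
    s1 <- sum(x[groups == 1]); s2 <- sum(x[groups == 2])
    min(s1, s2) / max(1, s1 + s2)
  })
  expect_gte(mean(frac_minority < 0.10), 0.8)
})

test_that("interaction matrices are competitive between groups and scale-free within", {
  a <- make_interaction_matrix(120, ba_edges_per_node = 2, seed = 11)
  groups <- attr(a, "groups")
  between <- outer(groups, groups, "!=")
  expect_true(all(a[between] < 0))
  expect_true(isSymmetric(unname(a)))
  expect_true(all(diag(a) <= 0))
  # hub property within groups
  within1 <- a[groups == "1", groups == "1"]
  deg <- colSums(within1 != 0)
  expect_gte(max(deg), 3 * median(deg))
  # determinism
  b <- make_interaction_matrix(120, ba_edges_per_node = 2, seed = 11)
  expect_identical(a, b)
  expect_error(make_interaction_matrix(6, groups = rep(1:2, c(2, 4)),
                                       ba_edges_per_node = 2), "ba_edges_per_node")
})

test_that("shuffling preserves per-taxon totals within scope", {
  ct <- random_counts(15, 12, seed = 13)
  g <- rep(c("a", "b"), each = 6)
  names(g) <- sample_ids(ct)
  sh_g <- shuffle_counts(ct, "global", seed = 14)
  expect_equal(rowSums(sh_g), rowSums(ct))
  expect_equal(unname(sort(unclass(sh_g)[3, ])), unname(sort(unclass(ct)[3, ])))

  sh_w <- shuffle_counts(ct, "within_group", groups = g, seed = 15)
  for (lev in c("a", "b")) {
    expect_equal(rowSums(unclass(sh_w)[, g == lev]),
                 rowSums(unclass(ct)[, g == lev]))
  }
  # single-sample group is left untouched
  g2 <- c(rep("a", 11), "solo"); names(g2) <- sample_ids(ct)
  sh_s <- shuffle_counts(ct, "within_group", groups = g2, seed = 16)
  expect_equal(unclass(sh_s)[, 12], unclass(ct)[, 12])
  expect_error(shuffle_counts(ct, "within_group"), "required")
})

test_that("poisson starting counts have the right mean and are reproducible", {
  p1 <- poisson_counts(200, 500, lambda = 5, seed = 17)
  expect_lt(abs(mean(unclass(p1)) - 5) / 5, 0.02)
  p2 <- poisson_counts(200, 500, lambda = 5, seed = 17)
  expect_identical(unclass(p1), unclass(p2))
  p0 <- poisson_counts(5, 5, lambda = 1e-12, seed = 18)
  expect_equal(sum(p0), 0)
})

test_that("mock habitats follow the dominant taxa group", {
  ct <- random_counts(10, 8, seed = 19)
  groups <- rep(c("g1", "g2"), each = 5); names(groups) <- taxa_ids(ct)
  labs <- suppressWarnings(assign_mock_habitats(ct, groups))
  m <- unclass(ct)
  oracle <- ifelse(colSums(m[1:5, ]) >= colSums(m[6:10, ]), "g1", "g2")
  expect_equal(unname(labs), unname(oracle))

  tied <- count_table(matrix(c(1, 1, 0, 2), 2, 2,
                             dimnames = list(c("t1", "t2"), c("A", "B"))))
  expect_warning(lt <- assign_mock_habitats(tied, c(t1 = "g1", t2 = "g2")),
                 "tied")
  expect_equal(unname(lt), c("g1", "g2"))
})

test_that("dirichlet-multinomial sampling conserves depth and concentrates", {
  tab <- sample_dirichlet_multinomial(1, list(c(1000, rep(0.01, 9))),
                                      depth = 500, n_samples = 40, seed = 20)
  expect_true(all(sample_totals(tab) == 500))
  expect_gt(mean(unclass(tab)[1, ] / 500), 0.95)
  t2 <- sample_dirichlet_multinomial(1, list(c(1000, rep(0.01, 9))),
                                     depth = 500, n_samples = 40, seed = 20)
  expect_identical(unclass(tab), unclass(t2))
  expect_error(sample_dirichlet_multinomial(1, list(rep(1, 4)), depth = 0,
                                            n_samples = 2), "positive")
  expect_error(sample_dirichlet_multinomial(c(.5, .6), list(rep(1, 4), rep(1, 4)),
                                            depth = 10, n_samples = 2), "sum to 1")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  ct <- random_counts(20, 10, seed = 21, lambda = 20)
  r <- rarefy(ct, depth = 50, seed = 22)
  expect_true(all(sample_totals(r) == 50))
  expect_true(all(unclass(r)[taxa_ids(r), ] <= unclass(ct)[taxa_ids(r), sample_ids(r)]))

  # depth equal to a sample's total leaves it unchanged
  tot1 <- sample_totals(ct)[1]
  r2 <- suppressWarnings(rarefy(ct, depth = tot1, seed = 23))
  if ("s1" %in% sample_ids(r2)) {
    expect_equal(unclass(r2)[taxa_ids(r2), "s1"],
                 unclass(ct)[taxa_ids(r2), "s1"])
  }
  expect_error(rarefy(ct, depth = 10000, seed = 1), "below")

  # expectation matches the hypergeometric mean n_i * depth / n_total
  small <- count_table(matrix(c(30, 10, 20, 40, 25, 25), 3, 2,
                              dimnames = list(paste0("t", 1:3), c("A", "B"))))
  acc <- matrix(0, 3, 2)
  for (s in 1:200) acc <- acc + unclass(rarefy(small, 20, seed = s))
  expected <- unclass(small) %*% diag(20 / sample_totals(small))
  expect_lt(max(abs(acc / 200 - expected) / expected), 0.05)
})

test_that("benchmark scenarios compose the engines reproducibly", {
  sc1 <- make_benchmark_scenario("habitat_only", n_taxa = 40, n_samples = 16,
                                 seed = 24)
  sc2 <- make_benchmark_scenario("habitat_only", n_taxa = 40, n_samples = 16,
                                 seed = 24)
  expect_identical(unclass(sc1$counts), unclass(sc2$counts))
  expect_identical(sc1$labels, sc2$labels)
  expect_equal(length(sc1$labels), ncol(sc1$counts))
  expect_null(sc1$interactions)

  sci <- make_benchmark_scenario("interaction_only", n_taxa = 40,
                                 n_samples = 16, seed = 25)
  expect_true(all(diag(sci$interactions) <= 0))
  expect_setequal(names(sci$labels), sample_ids(sci$counts))

  schi <- make_benchmark_scenario("habitat_plus_interaction", n_taxa = 40,
                                  n_samples = 16, seed = 26)
  expect_false(is.null(schi$interactions))
  expect_equal(rownames(schi$interactions), taxa_ids(schi$counts))
})

test_that("habitat-preference shuffling leaves co-abundance only between habitats", {
  # same-habitat taxa pairs end up more associated than cross-habitat pairs
  sc <- make_benchmark_scenario("habitat_only", n_taxa = 60, n_samples = 30,
                                seed = 27)
  suppressWarnings({
    raw <- infer_cooccurrence(sc$counts, "spearman")
  })
  cm <- suppressWarnings(transform_association(raw))
  tg <- sc$taxa_groups[rownames(cm)]
  same <- outer(tg, tg, "==") & upper.tri(cm)
  cross <- outer(tg, tg, "!=") & upper.tri(cm)
  expect_gt(mean(cm[same]) - mean(cm[cross]), 0)
})
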