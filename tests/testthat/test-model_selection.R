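# model selection: LRT, per-partition AICc/BIC, RELL, bootstrap, congruence,
# heterogeneity summaries

test_that("likelihood ratio test matches the chi-square oracle", {
  t0 <- likelihood_ratio_test(-100, -100, df = 1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # chi-square oracle: stat 3.841, df 1 -> p ~= 0.0500
  t1 <- likelihood_ratio_test(-100, -100 + 3.841 / 2, df = 1)
  expect_equal(t1$p_value, 0.05, tolerance = 1e-3)
  expect_equal(t1$p_value,
               stats::pchisq(3.841, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(likelihood_ratio_test(-100, -110, df = 1), "nesting")
  expect_error(likelihood_ratio_test(-100, -99, df = 0), "df")
})

test_that("per-partition AICc and BIC follow their formulas", {
  expect_equal(aicc_partitioned(-500, 2, 100), 1000 + 4 + 12 / 97,
               tolerance = 1e-10)
  expect_equal(bic_partitioned(-500, 2, 100), 1000 + 2 * log(100),
               tolerance = 1e-10)
  # K = 0 -> -2*loglik
  expect_equal(aicc_partitioned(-500, c(0, 0), c(50, 60)), 1000)
  expect_equal(bic_partitioned(-500, c(0, 0), c(50, 60)), 1000)
  # penalty additivity over partitions
  pen2 <- aicc_partitioned(-500, c(2, 3), c(100, 200)) + 2 * -(-500) - 1000
  pen_a <- aicc_partitioned(-250, 2, 100) - 500
  pen_b <- aicc_partitioned(-250, 3, 200) - 500
  expect_equal(aicc_partitioned(-500, c(2, 3), c(100, 200)),
               1000 + (pen_a + pen_b), tolerance = 1e-10)
  expect_equal(bic_partitioned(-500, c(2, 3), c(100, 200)),
               1000 + 2 * log(100) + 3 * log(200), tolerance = 1e-10)
  # small-sample breakdown names the offending partition
  expect_error(aicc_partitioned(-10, c(2, 50), c(100, 51)), "2")
  expect_error(bic_partitioned(-10, 2, 0), "n < 1")
})

test_that("RELL supports form a probability distribution with sane limits", {
  # single candidate tree
  one <- rell_bootstrap(matrix(rnorm(20), 1, 20), 50, seed = 1)
  expect_equal(one$tree_support, 1)
  # strictly dominant tree wins every replicate
  m <- rbind(rep(-1, 30), rep(-2, 30), rep(-3, 30))
  r <- rell_bootstrap(m, 100, seed = 2)
  expect_equal(r$tree_support, c(1, 0, 0))
  expect_equal(sum(r$tree_support), 1, tolerance = 1e-12)
  # ties split equally
  tie <- rell_bootstrap(rbind(rep(-1, 10), rep(-1, 10)), 40, seed = 3)
  expect_equal(tie$tree_support, c(0.5, 0.5))
  # determinism
  set.seed(99)
  m2 <- matrix(rnorm(3 * 50, sd = 0.2), 3, 50)
  expect_identical(rell_bootstrap(m2, 200, seed = 7)$tree_support,
                   rell_bootstrap(m2, 200, seed = 7)$tree_support)
  # stratified resampling keeps per-stratum counts
  rs <- rell_bootstrap(m2, 100, seed = 8, strata = rep(1:2, each = 25))
  expect_equal(sum(rs$tree_support), 1, tolerance = 1e-12)
  expect_error(rell_bootstrap(matrix(0, 0, 5)), "non-empty")
  # bipartition support: trees containing a split accumulate its support
  trees <- list(read_newick(text = "((A,B),(C,D),E);"),
                read_newick(text = "((A,C),(B,D),E);"))
  class(trees) <- "multiPhylo"
  m3 <- rbind(rep(-1, 40), rep(-5, 40))
  rb <- rell_bootstrap(m3, 100, seed = 9, trees = trees)
  # splits are keyed on the side not containing the first taxon: the winning
  # tree's {A,B}|{C,D,E} and {C,D}|{A,B,E} splits get full support
  expect_equal(unname(rb$bipartition_support[["C|D|E"]]), 1)
  expect_equal(unname(rb$bipartition_support[["C|D"]]), 1)
})

test_that("hierarchical LRT chain selects the right member on clear data", {
  set.seed(501)
  tr <- random_blen_tree(5, 0.1, 0.4)
  # strongly REV data
  m <- rev_model(c(.4, .1, .15, .35), c(0.2, 6, 0.3, 4, 8, 1))
  pa <- compress_patterns(simulate_alignment(tr, m, discretize_gamma(.7, 6),
                                             2000, seed = 1))
  sel <- hierarchical_gene_model_test(pa, tr, control = quick_ctl)
  expect_equal(sel$best, "REV")
  expect_lt(sel$p_hky_rev, 0.001)
  # site order invariance
  perm <- sample(pa$total_length)
  sel2 <- hierarchical_gene_model_test(subset_sites(pa, perm), tr,
                                       control = quick_ctl)
  expect_equal(sel2$best, sel$best)
  expect_equal(sel2$p_hky_rev, sel$p_hky_rev, tolerance = 1e-4)
})

test_that("congruence summary counts topologies and scores the null", {
  taxa <- paste0("t", 1:8)
  t1 <- random_topology(taxa, seed = 1)
  same <- list(t1, t1, t1)
  cs <- congruence_summary(same, n_sims = 50, seed = 2)
  expect_equal(cs$n_distinct, 1L)
  expect_equal(cs$mean_rf, 0)
  expect_equal(cs$p_value, 0)  # random trees never tie a mean of 0
  # hand-enumerated: two identical + one maximally distant
  a <- read_newick(text = "((A,B),(C,(D,E)));")
  b <- read_newick(text = "((A,D),(C,(B,E)));")  # RF 1 from a
  cs2 <- congruence_summary(list(a, a, b), n_sims = 20, seed = 3)
  expect_equal(cs2$mean_rf, 2 / 3, tolerance = 1e-12)
  expect_equal(cs2$n_distinct, 2L)
  # order invariance
  cs3 <- congruence_summary(list(b, a, a), n_sims = 20, seed = 3)
  expect_equal(cs3$n_distinct, cs2$n_distinct)
  expect_equal(cs3$mean_rf, cs2$mean_rf)
  expect_error(congruence_summary(list(a)), "at least 2")
})

test_that("heterogeneity summary reports R, alpha, GC with percentiles", {
  set.seed(502)
  tr <- random_blen_tree(4, 0.05, 0.2)
  gs <- simulate_heterogeneous_gene_set(
    tr, heterogeneity_profile(n_genes = 3, gene_length_range = c(60, 80)),
    seed = 4)
  fits <- lapply(gs$alignments, function(a)
    optimize_fit(tr, a, "REV", gamma = TRUE, control = quick_ctl))
  hs <- parameter_heterogeneity_summary(fits, gs$alignments)
  expect_equal(nrow(hs$table), 3L)
  expect_true(all(c("R", "alpha", "gc") %in% names(hs$table)))
  expect_true(all(hs$summary[, "min"] <= hs$summary[, "max"]))
  # all-G/C alignment has GC = 1
  gcmat <- matrix(sample(c("G", "C"), 4 * 30, TRUE), 4, 30,
                  dimnames = list(tr$tip.label, NULL))
  expect_equal(gc_content(compress_patterns(gcmat)), 1)
  expect_error(parameter_heterogeneity_summary(list(), list()), "no fits")
})

test_that("model comparison tables have one zero delta and valid columns", {
  rows <- list(
    list(label = "M1", mode = "concatenated", ml_tree = 1, loglik = -1000,
         K_i = c(all = 10), n_i = c(all = 500)),
    list(label = "M2", mode = "concatenated", ml_tree = 1, loglik = -980,
         K_i = c(all = 14), n_i = c(all = 500), lrt_vs = "M1"))
  tab <- model_comparison_table(rows)
  expect_equal(sum(tab$delta_AICc == 0), 1L)
  expect_true(all(tab$delta_AICc >= 0))
  expect_true(all(is.na(tab$lrt_p) | (tab$lrt_p >= 0 & tab$lrt_p <= 1)))
})
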