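# treespace: Newick I/O, resolution enumeration, RF distance, random
# topologies, NNI search

test_that("Newick reading and writing round-trip", {
  set.seed(301)
  for (i in 1:25) {
    tr <- random_blen_tree(sample(4:10, 1))
    s <- write_newick(tr)
    tr2 <- read_newick(text = s)
    expect_equal(robinson_foulds_normalized(tr, tr2), 0)
    expect_equal(sort(tr2$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
    expect_identical(write_newick(tr2), s)  # canonical form is stable
  }
  tr <- read_newick(text = "(A,B,(C,D));")
  expect_equal(ape::Ntip(tr), 4L)
  expect_error(read_newick(text = "((A,B);"), "unbalanced")
  expect_error(read_newick(text = "(A,B,(C,A));"), "duplicate")
})

test_that("resolution counting and enumeration agree with (2k-3)!!", {
  bin <- read_newick(text = "((A,B),(C,D));")
  expect_equal(count_resolutions(bin), 1)
  e <- enumerate_resolutions(bin)
  expect_length(e, 1L)
  expect_equal(robinson_foulds_normalized(e[[1]], bin), 0)

  p4 <- read_newick(text = "(A,B,C,D);")
  e4 <- enumerate_resolutions(p4)
  expect_length(e4, 15L)
  # enumeration is over rooted local arrangements: distinct as rooted trees
  expect_length(unique(vapply(e4, write_newick, "")), 15L)

  # one 3-polytomy nested in one 4-polytomy: 3 x 15 = 45
  mixed <- read_newick(text = "((A,B,C),D,E,F);")
  expect_equal(count_resolutions(mixed), 45)
  e45 <- enumerate_resolutions(mixed)
  expect_length(e45, 45L)
  expect_length(unique(vapply(e45, write_newick, "")), 45L)
  # every output is binary and respects the backbone clade {A,B,C}
  for (tr in e45) {
    expect_true(ape::is.binary(tr))
    expect_true(has_clade(tr, c("A", "B", "C")))
  }
  expect_error(enumerate_resolutions(read_newick(
    text = paste0("(", paste(LETTERS[1:12], collapse = ","), ");")), cap = 1e4),
    "cap")
})

test_that("the yeast backbone yields 4725 resolutions and 3150 candidates", {
  bb <- yeast_backbone()
  expect_equal(ape::Ntip(bb), 18L)
  expect_equal(count_resolutions(bb), 4725)
})

test_that("normalized RF distance behaves as a metric with known values", {
  t1 <- read_newick(text = "((A,B),(C,(D,E)));")
  expect_equal(robinson_foulds_normalized(t1, t1), 0)
  # one NNI away on 5 taxa: 2 of the 4 split slots differ -> 0.5
  t2 <- read_newick(text = "((A,C),(B,(D,E)));")
  expect_equal(robinson_foulds_normalized(t1, t2), 0.5)
  expect_equal(robinson_foulds_normalized(t2, t1), 0.5)
  # no shared internal bipartition -> 1
  t3 <- read_newick(text = "((A,D),(C,(B,E)));")
  expect_equal(robinson_foulds_normalized(t1, t3), 1)
  expect_error(robinson_foulds_normalized(t1, read_newick(
    text = "((A,B),(C,(D,F)));")), "leaf set")
  # metric properties + cross-check against phangorn on random triples
  set.seed(302)
  for (i in 1:10) {
    trs <- lapply(1:3, function(j) random_topology(paste0("t", 1:8)))
    d12 <- robinson_foulds_normalized(trs[[1]], trs[[2]])
    d13 <- robinson_foulds_normalized(trs[[1]], trs[[3]])
    d23 <- robinson_foulds_normalized(trs[[2]], trs[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
    if (requireNamespace("phangorn", quietly = TRUE)) {
      expect_equal(d12 * 2 * (8 - 3),
                   as.numeric(phangorn::RF.dist(trs[[1]], trs[[2]])))
    }
  }
})

test_that("random topologies are seed-deterministic and valid", {
  taxa <- paste0("s", 1:9)
  t1 <- random_topology(taxa, seed = 7)
  t2 <- random_topology(taxa, seed = 7)
  expect_equal(robinson_foulds_normalized(t1, t2), 0)
  expect_true(ape::is.binary(t1))
  expect_error(random_topology(c("a", "b")), "at least 3")
  # 3 taxa: the single unrooted topology
  expect_equal(ape::Ntip(random_topology(c("a", "b", "c"), seed = 1)), 3L)
})

test_that("the RF null distribution is deterministic and near 1 for many taxa", {
  n1 <- rf_null_distribution(18, 6, n_sims = 30, seed = 5)
  n2 <- rf_null_distribution(18, 6, n_sims = 30, seed = 5)
  expect_identical(n1$samples, n2$samples)
  expect_gt(mean(n1$samples), 0.9)
  expect_equal(n1$p_value(0), 0)   # identical trees never arise at random
  expect_equal(n1$p_value(1), 1)
  expect_error(rf_null_distribution(10, 1, 10), "at least 2")
  expect_error(rf_null_distribution(10, 3, 0), "at least 1")
})

test_that("NNI hill climbing matches exhaustive search on 4 taxa", {
  set.seed(303)
  tr <- random_blen_tree(4, 0.1, 0.4)
  mat <- simulate_alignment(tr, hky_model(c(.3, .2, .2, .3), 3),
                            NULL, 500, seed = 2)
  pa <- compress_patterns(mat)
  topos <- enumerate_resolutions(read_newick(
    text = paste0("(", paste(tr$tip.label, collapse = ","), ");")))
  scores <- vapply(topos, function(t2)
    optimize_fit(t2, pa, "HKY", gamma = FALSE,
                 control = quick_ctl)$loglik, 0)
  hc <- nni_hill_climb(pa, "HKY", gamma = FALSE,
                       start = topos[[which.min(scores)]],
                       control = quick_ctl)
  expect_equal(hc$loglik, max(scores), tolerance = 1e-2)
  expect_equal(robinson_foulds_normalized(hc$tree,
                                          topos[[which.max(scores)]]), 0)
  # starting at the optimum leaves the topology unchanged
  hc2 <- nni_hill_climb(pa, "HKY", gamma = FALSE,
                        start = topos[[which.max(scores)]],
                        control = quick_ctl)
  expect_equal(robinson_foulds_normalized(hc2$tree, hc$tree), 0)
})

test_that("has_clade tests unrooted bipartitions", {
  tr <- read_newick(text = "((A,B),(C,(D,E)));")
  expect_true(has_clade(tr, c("A", "B")))
  expect_true(has_clade(tr, c("D", "E")))
  expect_true(has_clade(tr, c("C", "D", "E")))  # complement of {A,B}... rest
  expect_false(has_clade(tr, c("A", "C")))
})
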