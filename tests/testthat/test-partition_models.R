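# partition models: codon splitting, sharing policies, free-parameter
# accounting, partitioned fitting

test_that("codon-position splitting follows the frame", {
  taxa <- c("a", "b", "c", "d")
  pa <- compress_patterns(random_alignment(taxa, 9))
  sp <- split_codon_positions(pa)
  expect_equal(sp[[1]], c(1L, 4L, 7L))
  expect_equal(sp[[2]], c(2L, 5L, 8L))
  expect_equal(sp[[3]], c(3L, 6L, 9L))
  pa10 <- compress_patterns(random_alignment(taxa, 10))
  expect_error(split_codon_positions(pa10), "divisible")
})

test_that("partition schemes are disjoint, covering and nonempty", {
  set.seed(401)
  taxa <- paste0("t", 1:4)
  genes <- list(g1 = compress_patterns(random_alignment(taxa, 12)),
                g2 = compress_patterns(random_alignment(taxa, 9)))
  super <- concatenate_alignments(genes)
  for (mode in c("concatenated", "by_codon_position", "by_gene",
                 "by_gene_and_codon_position")) {
    sc <- partition_scheme(super, mode)
    sites <- unname(unlist(sc$partitions))
    expect_equal(sort(sites), seq_len(21))
    expect_true(all(lengths(sc$partitions) > 0))
  }
  expect_equal(length(partition_scheme(super, "by_gene")$partitions), 2L)
  expect_equal(
    length(partition_scheme(super, "by_gene_and_codon_position")$partitions),
    6L)
})

test_that("free-parameter accounting matches block arithmetic", {
  expect_equal(count_free_parameters("JC", FALSE, 18)$K, 33)
  expect_equal(count_free_parameters("REV", TRUE, 18)$K, 42)
  # 10 fully independent REV+G genes: 420, 42 each
  taxa <- paste0("t", 1:18)
  lab <- rep(paste0("g", 1:10), each = 30)
  pa <- compress_patterns(random_alignment(taxa, 300), gene = lab)
  sc <- partition_scheme(pa, "by_gene")
  k <- count_free_parameters("REV", TRUE, 18, sc)
  expect_equal(k$K, 420)
  expect_equal(unname(k$K_i), rep(42, 10))
  # codon ladder at 18 taxa: G0 = 33+2+3+5+1 = 44; G3 = 33+2+3*8+1 = 60;
  # G4 = 3*42 = 126
  expect_equal(count_free_parameters("REV", TRUE, 18,
    partition_scheme(pa, "by_codon_position"), sharing_policy())$K, 44)
  expect_equal(count_free_parameters("REV", TRUE, 18,
    partition_scheme(pa, "by_codon_position"),
    sharing_policy(separate_frequencies = TRUE,
                   separate_exchangeabilities = TRUE))$K, 60)
  expect_equal(count_free_parameters("REV", TRUE, 18,
    partition_scheme(pa, "by_codon_position"),
    sharing_policy(separate_branch_lengths = TRUE))$K, 126)
  expect_error(count_free_parameters("JC", FALSE, 2), "at least 3")
})

test_that("policy labels and constraints are consistent", {
  expect_equal(policy_label(sharing_policy()), "G0")
  expect_equal(policy_label(sharing_policy(separate_frequencies = TRUE)),
               "G1")
  expect_equal(policy_label(sharing_policy(
    separate_exchangeabilities = TRUE)), "G2")
  expect_equal(policy_label(sharing_policy(
    separate_frequencies = TRUE, separate_exchangeabilities = TRUE)), "G3")
  p4 <- sharing_policy(separate_branch_lengths = TRUE)
  expect_equal(policy_label(p4), "G4")
  expect_false(p4$proportional_rates)  # superseded
  expect_true(p4$per_position_alpha)
  expect_equal(policy_label(sharing_policy(proportional_rates = FALSE)),
               "shared")
})

# one shared simulated dataset for the fitting contracts
part_world <- local({
  set.seed(402)
  tr <- random_blen_tree(5, 0.05, 0.3)
  m <- rev_model(c(.35, .15, .2, .3), c(1, 2.5, 0.8, 1.2, 3, 1))
  mat <- simulate_alignment(tr, m, discretize_gamma(0.5, 6), 900,
                            position_multipliers = c(1, 0.5, 3), seed = 3)
  list(tree = tr, data = compress_patterns(mat))
})

test_that("fully-shared codon policy collapses to the concatenated fit", {
  w <- part_world
  base <- optimize_fit(w$tree, w$data, "HKY", gamma = TRUE,
                       control = quick_ctl)
  shared <- fit_codon_partitioned(w$tree, w$data, "HKY", gamma = TRUE,
                                  policy = sharing_policy(
                                    proportional_rates = FALSE),
                                  control = quick_ctl)
  expect_equal(shared$loglik, base$loglik, tolerance = 2e-2)
  expect_equal(shared$n_free_params, base$n_free_params)
})

test_that("nesting holds along the codon ladder and G4 separates", {
  w <- part_world
  ll <- c(
    shared = optimize_fit(w$tree, w$data, "HKY", TRUE,
                          control = quick_ctl)$loglik,
    G0 = fit_codon_partitioned(w$tree, w$data, "HKY", TRUE,
                               policy = sharing_policy(),
                               control = quick_ctl)$loglik,
    G3 = fit_codon_partitioned(w$tree, w$data, "HKY", TRUE,
                               policy = sharing_policy(
                                 separate_frequencies = TRUE,
                                 separate_exchangeabilities = TRUE),
                               control = quick_ctl)$loglik,
    G4 = fit_codon_partitioned(w$tree, w$data, "HKY", TRUE,
                               policy = sharing_policy(
                                 separate_branch_lengths = TRUE),
                               control = quick_ctl)$loglik)
  expect_true(all(diff(ll) > -1e-3))
  # G4 equals the sum of three independent per-position fits
  pos <- split_codon_positions(w$data)
  indep <- sum(vapply(pos, function(idx)
    optimize_fit(w$tree, subset_sites(w$data, idx), "HKY", TRUE,
                 control = quick_ctl)$loglik, 0))
  expect_equal(ll["G4"], c(G4 = indep), tolerance = 1e-2)
})

test_that("policy requiring positions is rejected on one-position data", {
  taxa <- c("a", "b", "c", "d")
  pa <- compress_patterns(random_alignment(taxa, 30),
                          codon_position = rep(1L, 30))
  tr <- read_newick(text = "(a:0.1,b:0.1,(c:0.1,d:0.1):0.1);")
  expect_error(fit_codon_partitioned(tr, pa, "HKY", TRUE,
                                     policy = sharing_policy()),
               "one position")
})

test_that("gene-partitioned totals are per-gene sums, order-independent", {
  set.seed(403)
  tr <- random_blen_tree(5, 0.05, 0.3)
  genes <- list(
    a = compress_patterns(simulate_alignment(tr, hky_model(rep(.25, 4), 2),
                                             NULL, 240, seed = 4),
                          gene = "a"),
    b = compress_patterns(simulate_alignment(tr, hky_model(rep(.25, 4), 5),
                                             NULL, 300, seed = 5),
                          gene = "b"))
  cand <- list(ape::unroot(tr), random_topology(tr$tip.label, seed = 9))
  class(cand) <- "multiPhylo"
  gf <- fit_gene_partitioned(cand, genes, "HKY", gamma = FALSE,
                             control = quick_ctl)
  # one gene, one tree: total equals the plain fit
  single <- fit_gene_partitioned(cand[[1]], genes["a"], "HKY",
                                 gamma = FALSE, control = quick_ctl)
  plain <- optimize_fit(cand[[1]], genes$a, "HKY", gamma = FALSE,
                        control = quick_ctl)
  expect_equal(unname(single$total_loglik), plain$loglik, tolerance = 1e-2)
  # totals are sums of the per-gene rows
  expect_equal(colSums(gf$gene_loglik), unname(gf$total_loglik),
               tolerance = 1e-10)
  # permuting gene order changes nothing
  gf2 <- fit_gene_partitioned(cand, genes[c("b", "a")], "HKY",
                              gamma = FALSE, control = quick_ctl)
  expect_equal(unname(gf2$total_loglik), unname(gf$total_loglik),
               tolerance = 1e-8)
  # partitioned >= concatenated under the same model
  super <- concatenate_alignments(genes)
  cc <- optimize_fit(cand[[gf$best_tree]], super, "HKY", gamma = FALSE,
                     control = quick_ctl)
  expect_gte(gf$total_loglik[gf$best_tree], cc$loglik - 1e-3)
  # the RELL matrix rows sum to the per-tree totals
  expect_equal(unname(rowSums(gf$site_loglik)), unname(gf$total_loglik),
               tolerance = 1e-6)
  expect_error(fit_gene_partitioned(list(), genes, "HKY"), "empty")
  bad <- genes
  bad$b$taxa[1] <- "zzz"
  expect_error(fit_gene_partitioned(cand, bad, "HKY"), "taxon")
})
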