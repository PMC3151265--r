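# likelihood engine: pattern compression, pruning, optimization, per-site
# log-likelihoods

test_that("pattern compression conserves and inverts", {
  set.seed(201)
  taxa <- paste0("t", 1:6)
  m <- random_alignment(taxa, 200, ambig = 0.05)
  pa <- compress_patterns(m)
  expect_equal(sum(pa$weights), 200)
  expect_equal(pa$total_length, 200L)
  # gaps and N share the fully-ambiguous code and decode as N
  m_norm <- m
  m_norm[m_norm == "-"] <- "N"
  expect_identical(alignment_matrix(pa), m_norm)
  # 4 identical columns -> one pattern of weight 4
  m4 <- matrix(rep(c("A", "C"), 4), 2, 4,
               dimnames = list(c("a", "b"), NULL))
  pa4 <- compress_patterns(m4)
  expect_equal(ncol(pa4$patterns), 1L)
  expect_equal(pa4$weights, 4)
  expect_error(compress_patterns(m[, 0, drop = FALSE]), "length 0")
  expect_error(compress_patterns(rbind(a = "A", a = "C")), "duplicate")
})

test_that("pruning equals exhaustive enumeration on small instances", {
  set.seed(202)
  for (i in 1:18) {
    kind <- sample(c("JC", "HKY", "REV"), 1)
    gm <- if (runif(1) < 0.5) discretize_gamma(runif(1, 0.3, 2),
                                               sample(2:4, 1)) else NULL
    n <- sample(4:5, 1)
    tr <- random_blen_tree(n)
    mat <- random_alignment(tr$tip.label, sample(3:8, 1), ambig = 0.1)
    m <- random_model(kind)
    ll <- log_likelihood(tr, compress_patterns(mat), m, gm)
    expect_equal(ll, brute_force_loglik(tr, mat, m, gm), tolerance = 1e-8)
  }
})

test_that("two-taxon single-site stationary case is exact", {
  tr <- read_newick(text = "(A:0,B:0);")
  pa <- compress_patterns(matrix(c("A", "A"), 2, 1,
                                 dimnames = list(c("A", "B"), NULL)))
  expect_equal(log_likelihood(tr, pa, jc_model()), log(0.25),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to rerooting and taxon order", {
  set.seed(203)
  tr <- random_blen_tree(6)
  mat <- random_alignment(tr$tip.label, 40)
  m <- random_model("REV")
  gm <- discretize_gamma(0.8, 4)
  pa <- compress_patterns(mat)
  ll <- log_likelihood(tr, pa, m, gm)
  for (node in c(2L, 5L)) {
    rerooted <- ape::root(tr, outgroup = tr$tip.label[node],
                          resolve.root = TRUE)
    expect_equal(log_likelihood(rerooted, pa, m, gm), ll,
                 tolerance = 1e-10)
  }
  perm <- sample(nrow(mat))
  expect_equal(log_likelihood(tr, compress_patterns(mat[perm, ]), m, gm),
               ll, tolerance = 1e-10)
})

test_that("engine rejects invalid input", {
  tr <- random_blen_tree(4)
  pa <- compress_patterns(random_alignment(paste0("x", 1:4), 10))
  expect_error(log_likelihood(tr, pa, jc_model()), "leaf set")
  tr2 <- random_blen_tree(4)
  pa2 <- compress_patterns(random_alignment(tr2$tip.label, 10))
  tr2$edge.length[1] <- -0.1
  expect_error(log_likelihood(tr2, pa2, jc_model()), "negative")
})

test_that("two-sequence JC fit reproduces the closed-form distance", {
  p <- 0.15
  s1 <- rep("A", 200)
  s2 <- s1
  s2[seq_len(200 * p)] <- "G"
  pa <- compress_patterns(rbind(A = s1, B = s2))
  fit <- optimize_fit(read_newick(text = "(A:0.1,B:0.1);"), pa, "JC",
                      gamma = FALSE)
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  s <- rep(c("A", "C", "G", "T"), 25)
  mat <- rbind(a = s, b = s, c = s, d = s)
  tr <- read_newick(text = "(a:0.1,b:0.1,(c:0.1,d:0.1):0.1);")
  fit <- optimize_fit(tr, compress_patterns(mat), "JC", gamma = FALSE)
  expect_lt(max(fit$tree$edge.length), 1e-6)
})

test_that("monotone nesting of maximized likelihoods", {
  set.seed(204)
  tr <- random_blen_tree(6, 0.05, 0.3)
  m <- rev_model(c(.35, .15, .2, .3), c(1, 3, 0.7, 1.2, 2.5, 1))
  mat <- simulate_alignment(tr, m, discretize_gamma(0.5, 6), 600, seed = 1)
  pa <- compress_patterns(mat)
  lls <- sapply(c("JC", "HKY", "REV"), function(k)
    optimize_fit(tr, pa, k, gamma = FALSE, control = quick_ctl)$loglik)
  expect_true(lls["HKY"] >= lls["JC"] - 1e-4)
  expect_true(lls["REV"] >= lls["HKY"] - 1e-4)
  llg <- optimize_fit(tr, pa, "REV", gamma = TRUE,
                      control = quick_ctl)$loglik
  expect_true(llg >= lls["REV"] - 1e-4)
})

test_that("per-site log-likelihoods conserve the total and the patterns", {
  set.seed(205)
  tr <- random_blen_tree(5)
  mat <- random_alignment(tr$tip.label, 60)
  mat[, 10] <- mat[, 3]  # force a repeated pattern
  pa <- compress_patterns(mat)
  fit <- optimize_fit(tr, pa, "HKY", gamma = TRUE, control = quick_ctl)
  psl <- per_site_log_likelihoods(fit, pa)
  expect_length(psl, 60)
  expect_equal(sum(psl), fit$loglik, tolerance = 1e-6)
  expect_equal(psl[10], psl[3], tolerance = 1e-12)
  # single-pattern alignment -> constant vector
  pa1 <- compress_patterns(matrix("A", 4, 7,
                                  dimnames = list(c("w", "x", "y", "z"),
                                                  NULL)))
  tr1 <- read_newick(text = "(w:0.1,x:0.1,(y:0.1,z:0.1):0.1);")
  fit1 <- optimize_fit(tr1, pa1, "JC", gamma = FALSE)
  expect_equal(diff(range(per_site_log_likelihoods(fit1, pa1))), 0)
  expect_error(per_site_log_likelihoods(fit, pa1), "taxa|length")
})

test_that("unconverged fits are flagged, not hidden", {
  set.seed(206)
  tr <- random_blen_tree(5)
  pa <- compress_patterns(random_alignment(tr$tip.label, 80))
  fit <- optimize_fit(tr, pa, "REV", gamma = TRUE,
                      control = list(max_sweeps = 1L))
  expect_false(fit$converged)
  expect_true(is.finite(fit$loglik))
})
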