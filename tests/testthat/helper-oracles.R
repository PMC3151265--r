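# Independent oracles, deliberately naive: exhaustive enumeration over
# internal-node states for the likelihood, numeric quadrature for the
# discrete-gamma category means. These never touch the pruning engine.

# log-likelihood by brute-force summation over all internal-node state
# assignments, per site, per rate category
brute_force_loglik <- function(tree, mat, model, gamma = NULL) {
  if (ape::Ntip(tree) > 2L && ape::is.rooted(tree))
    tree <- ape::unroot(tree)
  nt <- ape::Ntip(tree)
  nint <- tree$Nnode
  E <- tree$edge
  Q <- build_generator(model)
  pi <- model$frequencies
  rates <- if (is.null(gamma)) 1 else gamma$category_rates
  probs <- if (is.null(gamma)) 1 else gamma$category_probs
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L)
  allowed <- lapply(1:15, function(m) which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0))
  A <- as.matrix(expand.grid(rep(list(1:4), nint)))
  total <- 0
  mat <- mat[tree$tip.label, , drop = FALSE]
  for (site in seq_len(ncol(mat))) {
    site_lik <- 0
    for (ci in seq_along(rates)) {
      P <- lapply(seq_len(nrow(E)), function(e)
        transition_probabilities(Q, tree$edge.length[e] * rates[ci],
                                 model$frequencies))
      lik <- pi[A[, 1L]]  # root = nt+1 is column 1 of A
      for (e in seq_len(nrow(E))) {
        par_state <- A[, E[e, 1L] - nt]
        child <- E[e, 2L]
        if (child <= nt) {
          st <- allowed[[code[[toupper(mat[child, site])]]]]
          lik <- lik * rowSums(matrix(P[[e]][par_state, st],
                                      ncol = length(st)))
        } else {
          lik <- lik * P[[e]][cbind(par_state, A[, child - nt])]
        }
      }
      site_lik <- site_lik + probs[ci] * sum(lik)
    }
    total <- total + log(site_lik)
  }
  total
}

# conditional means of gamma(alpha, alpha) on its K equal-probability
# quantile bins, by adaptive quadrature (independent of the incomplete-
# gamma identity used by the implementation)
gamma_bin_means_quadrature <- function(alpha, K) {
  qs <- c(0, stats::qgamma(seq_len(K - 1) / K, alpha, rate = alpha), Inf)
  sapply(seq_len(K), function(k) {
    m <- stats::integrate(function(x) x * stats::dgamma(x, alpha,
                                                        rate = alpha),
                          qs[k], qs[k + 1], rel.tol = 1e-10)$value
    m * K  # divide by bin probability 1/K
  })
}

# random nucleotide alignment matrix (uniform; optional ambiguity)
random_alignment <- function(taxa, n_sites, ambig = 0) {
  alphabet <- c("A", "C", "G", "T")
  m <- matrix(sample(alphabet, length(taxa) * n_sites, replace = TRUE),
              length(taxa), n_sites, dimnames = list(taxa, NULL))
  if (ambig > 0) {
    k <- ceiling(ambig * length(m))
    m[sample(length(m), k)] <- sample(c("N", "-"), k, replace = TRUE)
  }
  m
}

# random valid substitution model of a given kind
random_model <- function(kind) {
  f <- as.numeric(stats::runif(4, 0.15, 0.35))
  f <- f / sum(f)
  switch(kind,
         JC = jc_model(),
         HKY = hky_model(f, kappa = stats::runif(1, 0.5, 5)),
         REV = rev_model(f, c(stats::runif(5, 0.3, 4), 1)))
}

random_blen_tree <- function(n, lo = 0.05, hi = 0.5) {
  tr <- random_topology(paste0("t", seq_len(n)))
  tr$edge.length <- stats::runif(nrow(tr$edge), lo, hi)
  tr
}

# loose optimizer control for bulk test fits (differences at this tolerance
# are far below every statistic asserted on)
quick_ctl <- list(tol = 1e-3)
tight_ctl <- list(tol = 1e-6)
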