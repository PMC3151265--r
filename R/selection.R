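#' Likelihood ratio test between nested models
#'
#' Statistic \eqn{2(\ell_{general} - \ell_{nested})} (clipped at 0 for
#' optimizer noise), compared to the chi-square upper tail with \code{df}
#' degrees of freedom.
#'
#' @param ll_nested,ll_general maximized log-likelihoods.
#' @param df degrees of freedom (difference in free parameters), >= 1.
#' @param slack tolerated optimizer slack when the general model scores
#'   below the nested one.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
likelihood_ratio_test <- function(ll_nested, ll_general, df, slack = 1e-6) {
  if (df < 1L) stop("df must be >= 1")
  if (ll_general < ll_nested - slack)
    stop(sprintf(paste0("general model scored %.6f below the nested model:",
                        " broken nesting (optimization failure)"),
                 ll_nested - ll_general))
  stat <- max(0, 2 * (ll_general - ll_nested))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Per-partition AICc
#'
#' Small-sample AIC with the penalty computed partition by partition:
#' \deqn{AICc = -2\ell + \sum_i \left[ 2K_i +
#'   \frac{2K_i(K_i+1)}{n_i - K_i - 1} \right]}
#' where \eqn{\ell} is the total maximized log-likelihood, \eqn{K_i} the
#' number of parameters estimated for partition \eqn{i} and \eqn{n_i} its
#' number of alignment positions. Reduces to standard AICc for one
#' partition.
#'
#' @param loglik total maximized log-likelihood.
#' @param K per-partition free-parameter counts.
#' @param n per-partition site counts; requires \eqn{n_i > K_i + 1}.
#' @return AICc score.
#' @export
aicc_partitioned <- function(loglik, K, n) {
  if (length(K) != length(n)) stop("K and n must have equal length")
  bad <- which(n <= K + 1)
  if (length(bad) > 0L) {
    nm <- if (!is.null(names(K))) names(K)[bad[1L]] else bad[1L]
    stop("partition ", nm, " has n = ", n[bad[1L]], " <= K + 1 = ",
         K[bad[1L]] + 1, ": AICc small-sample penalty breaks down")
  }
  -2 * loglik + sum(2 * K + 2 * K * (K + 1) / (n - K - 1))
}

#' Per-partition BIC
#'
#' \eqn{BIC = -2\ell + \sum_i K_i \log n_i}, the per-partition analogue of
#' the AICc construction.
#'
#' @inheritParams aicc_partitioned
#' @return BIC score.
#' @export
bic_partitioned <- function(loglik, K, n) {
  if (length(K) != length(n)) stop("K and n must have equal length")
  if (any(n < 1)) stop("partition with n < 1")
  -2 * loglik + sum(K * log(n))
}

#' RELL bootstrap over a candidate tree set
#'
#' Resampling of estimated log-likelihoods: each replicate draws sites with
#' replacement, re-sums every candidate tree's per-site log-likelihoods and
#' awards the replicate to the best tree (ties split equally). No
#' re-optimization is performed. Per-tree supports form a probability
#' distribution; bipartition supports sum the supports of the trees
#' containing each split.
#'
#' @param site_loglik matrix, trees x sites, of per-site log-likelihoods at
#'   each tree's ML fit.
#' @param n_samples number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param trees optional \code{multiPhylo} matching the rows, for
#'   bipartition supports.
#' @param strata optional per-site stratum labels (e.g. gene ids) for
#'   stratified resampling; default unstratified.
#' @return list with \code{tree_support} (per-tree, sums to 1) and, when
#'   trees are given, \code{bipartition_support} (named vector).
#' @export
rell_bootstrap <- function(site_loglik, n_samples = 1000, seed = NULL,
                           trees = NULL, strata = NULL) {
  if (!is.matrix(site_loglik) || nrow(site_loglik) < 1L ||
      ncol(site_loglik) < 1L)
    stop("site_loglik must be a non-empty trees x sites matrix")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  nT <- nrow(site_loglik)
  n <- ncol(site_loglik)
  support <- numeric(nT)
  if (!is.null(strata)) strata_idx <- split(seq_len(n), strata)
  for (b in seq_len(n_samples)) {
    idx <- if (is.null(strata)) {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(lapply(strata_idx, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]))
    }
    tot <- site_loglik[, idx, drop = FALSE] %*% rep(1, n)
    winners <- which(tot == max(tot))
    support[winners] <- support[winners] + 1 / length(winners)
  }
  support <- support / n_samples
  out <- list(tree_support = support)
  if (!is.null(trees)) {
    bips <- lapply(trees, bipartitions)
    all_b <- unique(unlist(bips))
    bs <- vapply(all_b, function(b)
      sum(support[vapply(bips, function(x) b %in% x, TRUE)]), 0)
    out$bipartition_support <- stats::setNames(bs, all_b)
  }
  out
}

#' Nonparametric bootstrap support
#'
#' Each replicate resamples alignment columns with replacement and reruns
#' the NNI tree search; the support of each bipartition of the reference
#' (ML) tree is the fraction of replicate trees containing it. By default
#' the substitution-model parameters are held at the full-data estimates in
#' replicates and only branch lengths and topology are re-optimized
#' (\code{refit_model = TRUE} re-estimates everything).
#'
#' @param data a \code{pattern_alignment}.
#' @param kind,gamma,k_categories model specification.
#' @param ml_fit optional \code{pp_fit} on the full data (computed if
#'   missing, by NNI search).
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param refit_model re-estimate substitution parameters per replicate.
#' @param control optimizer control for replicate fits.
#' @return list with \code{ml_tree}, \code{support} (named by canonical
#'   bipartition string) and \code{replicate_trees}.
#' @export
nonparametric_bootstrap <- function(data, kind = "REV", gamma = TRUE,
                                    k_categories = 6L, ml_fit = NULL,
                                    n_reps = 100, seed = NULL,
                                    refit_model = FALSE, control = list()) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  if (is.null(ml_fit))
    ml_fit <- nni_hill_climb(data, kind, gamma, k_categories,
                             control = control)
  fixed <- if (refit_model) NULL else list(model = ml_fit$model,
                                           gamma = ml_fit$gamma)
  ref_bips <- bipartitions(ml_fit$tree)
  counts <- stats::setNames(numeric(length(ref_bips)), ref_bips)
  reps <- vector("list", n_reps)
  n <- data$total_length
  for (b in seq_len(n_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- subset_sites(data, idx)
    fit <- nni_hill_climb(boot, kind, gamma, k_categories,
                          start = ml_fit$tree, fixed_model = fixed,
                          control = control)
    reps[[b]] <- fit$tree
    bb <- bipartitions(fit$tree)
    hit <- ref_bips %in% bb
    counts[hit] <- counts[hit] + 1
  }
  list(ml_tree = ml_fit$tree, support = counts / n_reps,
       replicate_trees = reps)
}

#' Hierarchical likelihood-ratio model choice for one gene
#'
#' The LRT chain JC+G vs HKY+G (4 df: kappa and three frequencies), then
#' HKY+G vs REV+G (4 df: the remaining exchangeabilities), each at level
#' \code{alpha}. Returns the selected model and both p-values.
#'
#' @param data a \code{pattern_alignment}.
#' @param tree \code{phylo} topology to fit on (fixed across models).
#' @param alpha test level (default 0.05).
#' @param k_categories gamma categories.
#' @param control optimizer control.
#' @return list with \code{best} (\code{"JC"}, \code{"HKY"} or
#'   \code{"REV"}), \code{p_jc_hky}, \code{p_hky_rev} and the three fits.
#' @export
hierarchical_gene_model_test <- function(data, tree, alpha = 0.05,
                                         k_categories = 6L,
                                         control = list()) {
  fits <- list(JC = optimize_fit(tree, data, "JC", TRUE, k_categories,
                                 control = control),
               HKY = optimize_fit(tree, data, "HKY", TRUE, k_categories,
                                  control = control),
               REV = optimize_fit(tree, data, "REV", TRUE, k_categories,
                                  control = control))
  # guard against optimizer slack breaking nesting
  ll <- cummax(c(fits$JC$loglik, fits$HKY$loglik, fits$REV$loglik))
  t1 <- likelihood_ratio_test(ll[1L], ll[2L], df = 4)
  t2 <- likelihood_ratio_test(ll[2L], ll[3L], df = 4)
  best <- if (t1$p_value >= alpha) "JC"
          else if (t2$p_value >= alpha) "HKY" else "REV"
  list(best = best, p_jc_hky = t1$p_value, p_hky_rev = t2$p_value,
       fits = fits)
}

#' Gene-tree congruence summary
#'
#' Counts distinct unrooted topologies (canonical-string equality), the
#' mean pairwise normalized RF distance, and an empirical p-value from the
#' random-tree null distribution of the mean pairwise RF.
#'
#' @param gene_trees list (or \code{multiPhylo}) of trees over a shared
#'   leaf set.
#' @param n_sims simulations for the null (default 1000).
#' @param seed integer seed for the null.
#' @return list with \code{n_trees}, \code{n_distinct},
#'   \code{mean_rf}, \code{null_mean}, \code{null_sd}, \code{p_value}.
#' @export
congruence_summary <- function(gene_trees, n_sims = 1000, seed = NULL) {
  if (length(gene_trees) < 2L) stop("need at least 2 gene trees")
  taxa <- gene_trees[[1L]]$tip.label
  for (tr in gene_trees)
    if (!setequal(tr$tip.label, taxa)) stop("gene trees differ in leaf set")
  canon <- vapply(gene_trees, canonical_topology, "")
  mean_rf <- mean_pairwise_rf(gene_trees)
  null <- rf_null_distribution(length(taxa), length(gene_trees),
                               n_sims = n_sims, seed = seed)
  list(n_trees = length(gene_trees), n_distinct = length(unique(canon)),
       mean_rf = mean_rf, null_mean = mean(null$samples),
       null_sd = stats::sd(null$samples),
       p_value = null$p_value(mean_rf))
}

#' Between-gene parameter heterogeneity summary
#'
#' Tabulates, per gene, the average transition/transversion ratio R (from
#' the fitted exchangeabilities and frequencies), the gamma shape
#' \eqn{\alpha} and the empirical GC content, with 2.5/97.5 percentiles
#' (linear interpolation) and full ranges.
#'
#' @param fits named list of per-gene \code{pp_fit}s (REV+G recommended).
#' @param alignments matching named list of \code{pattern_alignment}s.
#' @return list with \code{table} (data.frame gene, R, alpha, gc) and
#'   \code{summary} (2.5\%, 97.5\%, min, max per quantity).
#' @export
parameter_heterogeneity_summary <- function(fits, alignments) {
  if (length(fits) < 1L) stop("no fits")
  if (length(fits) != length(alignments))
    stop("fits and alignments differ in length")
  tab <- data.frame(
    gene = if (!is.null(names(fits))) names(fits) else seq_along(fits),
    R = vapply(fits, function(f) average_ts_tv_ratio(f$model), 0),
    alpha = vapply(fits, function(f)
      if (is.null(f$gamma)) NA_real_ else f$gamma$alpha, 0),
    gc = vapply(alignments, gc_content, 0),
    stringsAsFactors = FALSE)
  qs <- function(x) {
    x <- x[!is.na(x)]
    c(lower95 = unname(stats::quantile(x, 0.025, type = 7)),
      upper95 = unname(stats::quantile(x, 0.975, type = 7)),
      min = min(x), max = max(x))
  }
  list(table = tab,
       summary = rbind(R = qs(tab$R), alpha = qs(tab$alpha),
                       gc = qs(tab$gc)))
}

#' Model-comparison table (supermatrix ladder)
#'
#' Assembles rows (model label, mode, ML tree id, log-likelihood, K, AICc,
#' BIC, delta columns and LRT p against the stated nested predecessor) in
#' the conventional layout. The best model by AICc has delta 0.
#'
#' @param rows list of lists with fields \code{label}, \code{mode},
#'   \code{ml_tree}, \code{loglik}, \code{K_i}, \code{n_i}, optional
#'   \code{lrt_vs} (label of nested predecessor) and \code{df}.
#' @return data.frame with one row per model.
#' @export
model_comparison_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(model = r$label, mode = r$mode, ml_tree = r$ml_tree,
               loglik = r$loglik, K = sum(r$K_i),
               AICc = aicc_partitioned(r$loglik, r$K_i, r$n_i),
               BIC = bic_partitioned(r$loglik, r$K_i, r$n_i),
               stringsAsFactors = FALSE)
  }))
  df$delta_AICc <- df$AICc - min(df$AICc)
  df$delta_BIC <- df$BIC - min(df$BIC)
  df$lrt_p <- NA_real_
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (!is.null(r$lrt_vs)) {
      j <- match(r$lrt_vs, df$model[df$mode == r$mode])
      jj <- which(df$mode == r$mode)[j]
      if (!is.na(jj)) {
        df$lrt_p[i] <- likelihood_ratio_test(
          min(df$loglik[jj], df$loglik[i]), df$loglik[i],
          df = max(1L, df$K[i] - df$K[jj]))$p_value
      }
    }
  }
  df
}
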