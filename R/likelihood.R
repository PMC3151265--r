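#' @useDynLib phylopart, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# engine group: eigen system + rate mixture + branch-length multiplier
make_group <- function(model, gamma = NULL, scale = 1) {
  Q <- build_generator(model)
  d <- decompose_generator(Q, model$frequencies)
  if (is.null(gamma)) {
    rates <- 1
    probs <- 1
  } else {
    rates <- gamma$category_rates
    probs <- gamma$category_probs
  }
  list(freq = as.numeric(model$frequencies), values = d$values,
       V = d$V, Vinv = d$Vinv, rates = as.numeric(rates),
       probs = as.numeric(probs), scale = scale)
}

# unroot (reversible models make the root arbitrary), keep 2-tip trees as-is
as_engine_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) > 2L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree
}

check_tree_data <- function(tree, data) {
  if (!setequal(tree$tip.label, data$taxa))
    stop("tree leaf set does not match alignment taxa")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  invisible(TRUE)
}

# pattern matrix with rows in tree tip-id order
patterns_for_tree <- function(tree, data) {
  data$patterns[match(tree$tip.label, data$taxa), , drop = FALSE]
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Computes \eqn{\ell = \sum_{patterns} w \log \sum_c p_c L_c} under a
#' reversible nucleotide model with optional discrete-gamma rate mixing,
#' using Felsenstein pruning with per-node scaling. Gaps and ambiguity codes
#' are marginalized. The value is invariant to the root placement.
#'
#' @param tree \code{phylo} with branch lengths; leaf set must equal the
#'   alignment's taxa.
#' @param data a \code{pattern_alignment}.
#' @param model a \code{nucleotide_model}.
#' @param gamma optional \code{gamma_rates}.
#' @return log-likelihood in nats.
#' @export
log_likelihood <- function(tree, data, model, gamma = NULL) {
  tree <- as_engine_tree(tree)
  check_tree_data(tree, data)
  pm <- patterns_for_tree(tree, data)
  res <- .pp_siteloglik(tree$edge, ape::Ntip(tree), tree$edge.length,
                        list(make_group(model, gamma)),
                        rep(1L, ncol(pm)), pm, data$weights)
  res$loglik
}

# ---- parameter packing ------------------------------------------------------

softmax4 <- function(x3) {
  z <- exp(c(x3, 0))
  z / sum(z)
}

freq_logits <- function(f) log(f[1:3] / f[4])

# substitution-parameter packing (alpha is optimized separately; the
# exchangeability and frequency blocks are optimized as separate nlminb
# blocks -- smaller finite-difference gradients, same optimum)
pack_par <- function(kind, model) {
  par <- numeric(0)
  lo <- numeric(0)
  hi <- numeric(0)
  if (kind == "HKY") {
    par <- c(log(model$kappa), freq_logits(model$frequencies))
    lo <- c(log(1e-4), rep(-20, 3))
    hi <- c(log(1e4), rep(20, 3))
  } else if (kind == "REV") {
    par <- c(log(model$exchangeabilities[1:5]),
             freq_logits(model$frequencies))
    lo <- c(rep(log(1e-4), 5), rep(-20, 3))
    hi <- c(rep(log(1e4), 5), rep(20, 3))
  }
  nex <- if (kind == "REV") 5L else if (kind == "HKY") 1L else 0L
  list(par = par, lower = lo, upper = hi, nex = nex)
}

unpack_par <- function(par, kind) {
  switch(kind,
         JC = jc_model(),
         HKY = hky_model(softmax4(par[2:4]), exp(par[1L])),
         REV = rev_model(softmax4(par[6:8]), c(exp(par[1:5]), 1)))
}

# blockwise coordinate refinement of the substitution parameters at fixed
# branch lengths; returns updated par and the achieved loglik
optimize_par_blocks <- function(pk, kind, neg_loglik, iter_max) {
  nex <- pk$nex
  npar <- length(pk$par)
  blocks <- list(seq_len(nex), (nex + 1L):npar)
  best <- -neg_loglik(pk$par)
  for (bi in blocks) {
    obj <- function(p) {
      full <- pk$par
      full[bi] <- p
      neg_loglik(full)
    }
    opt <- stats::nlminb(pk$par[bi], obj, lower = pk$lower[bi],
                         upper = pk$upper[bi],
                         control = list(iter.max = iter_max,
                                        rel.tol = 1e-8))
    if (-opt$objective >= best) {
      pk$par[bi] <- opt$par
      best <- -opt$objective
    }
  }
  list(pk = pk, loglik = best)
}

# free parameters of a single unpartitioned fit
k_free_single <- function(kind, with_gamma, n_taxa) {
  (2L * n_taxa - 3L) +
    switch(kind, JC = 0L, HKY = 4L, REV = 8L) +
    (if (with_gamma) 1L else 0L)
}

# ---- maximum-likelihood fitting --------------------------------------------

default_fit_control <- function(control = list()) {
  utils::modifyList(
    list(tol = 1e-6, max_sweeps = 200L, blen_passes = 10L,
         blen_min = 0, blen_max = 50, init_blen = 0.1, use_start = FALSE,
         param_iter = 30L, init = NULL),
    control)
}

#' Maximum-likelihood fit of a substitution model on a fixed topology
#'
#' Coordinate-ascent optimization: fast per-edge branch-length sweeps
#' (Brent bracketing on cached partials) alternate with bounded
#' quasi-Newton refinement of the substitution parameters (exchangeabilities
#' / \eqn{\kappa}, frequencies, gamma shape \eqn{\alpha}), until the
#' improvement per sweep falls below \code{control$tol} nats or
#' \code{control$max_sweeps} is hit (the fit is then flagged unconverged).
#' Deterministic: branch lengths start at 0.1, \eqn{\alpha} at 0.5,
#' exchangeabilities at 1, frequencies at their empirical values.
#'
#' @param tree \code{phylo} topology (branch lengths, if any, are ignored
#'   unless \code{control$use_start = TRUE}).
#' @param data a \code{pattern_alignment}.
#' @param kind \code{"JC"}, \code{"HKY"} or \code{"REV"}.
#' @param gamma logical: add discrete-gamma rate heterogeneity.
#' @param k_categories number of gamma categories (default 6).
#' @param fixed_model optional list \code{(model, gamma)}: hold substitution
#'   parameters fixed and optimize branch lengths only.
#' @param control list of optimizer settings, see
#'   \code{phylopart:::default_fit_control}.
#' @return object of class \code{pp_fit}: \code{tree} (with ML branch
#'   lengths), \code{model}, \code{gamma}, \code{loglik},
#'   \code{n_free_params}, \code{converged}, \code{sweeps}, \code{kind},
#'   \code{n_sites}.
#' @export
optimize_fit <- function(tree, data, kind = c("REV", "HKY", "JC"),
                         gamma = TRUE, k_categories = 6L,
                         fixed_model = NULL, control = list()) {
  kind <- match.arg(kind)
  ctl <- default_fit_control(control)
  tree <- as_engine_tree(tree)
  if (!setequal(tree$tip.label, data$taxa))
    stop("tree leaf set does not match alignment taxa")
  nE <- nrow(tree$edge)
  bl <- if (!is.null(ctl$init) && !is.null(ctl$init$blen)) {
    pmax(ctl$init$blen, 0)
  } else if (ctl$use_start && !is.null(tree$edge.length)) {
    pmax(tree$edge.length, 1e-8)
  } else rep(ctl$init_blen, nE)
  pm <- patterns_for_tree(tree, data)
  pg <- rep(1L, ncol(pm))
  w <- data$weights
  nTip <- ape::Ntip(tree)

  if (!is.null(fixed_model)) {
    model <- fixed_model$model
    gm <- fixed_model$gamma
    eng <- .pp_engine_new(tree$edge, nTip, list(make_group(model, gm)),
                          pg, pm, w)
    res <- .pp_engine_optimize(eng, bl, ctl$blen_min, ctl$blen_max,
                               ctl$tol, ctl$blen_passes)
    tree$edge.length <- res$blen
    return(structure(list(tree = tree, model = model, gamma = gm,
                          loglik = res$loglik,
                          n_free_params = 2L * nTip - 3L,
                          converged = TRUE, sweeps = res$passes,
                          kind = model$kind, n_sites = data$total_length),
                     class = "pp_fit"))
  }

  # deterministic initialization (warm start overrides via `init`)
  init <- ctl$init
  if (!is.null(init)) {
    model <- init$model
    gm <- init$gamma
    if (gamma && is.null(gm)) gm <- discretize_gamma(0.5, k_categories)
  } else {
    model <- switch(kind, JC = jc_model(),
                    HKY = hky_model(base_frequencies(data), kappa = 1),
                    REV = rev_model(base_frequencies(data)))
    gm <- if (gamma) discretize_gamma(0.5, k_categories) else NULL
  }
  pk <- pack_par(kind, model)
  have_par <- length(pk$par) > 0L

  eng <- .pp_engine_new(tree$edge, nTip, list(make_group(model, gm)),
                        pg, pm, w)
  ll <- -Inf
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(ctl$max_sweeps)) {
    sweeps <- s
    # inner loops need not fully converge per outer sweep; the outer
    # improvement criterion governs convergence
    inner_tol <- if (have_par || gamma) max(ctl$tol * 10, 1e-4) else
      ctl$tol / 10
    .pp_engine_set(eng, list(make_group(model, gm)))
    res <- .pp_engine_optimize(eng, bl, ctl$blen_min, ctl$blen_max,
                               inner_tol, ctl$blen_passes)
    bl <- res$blen
    new_ll <- res$loglik
    if (gamma) {
      # joint 2-D refinement of the gamma shape and a global branch-length
      # scale (strongly correlated directions; joint moves avoid the
      # coordinate-ascent zigzag)
      obj2 <- function(p) {
        .pp_engine_set(eng, list(make_group(model,
          discretize_gamma(exp(p[1L]), k_categories))))
        -.pp_engine_loglik(eng, pmin(bl * exp(p[2L]), ctl$blen_max),
                           FALSE)$loglik
      }
      opt2 <- stats::nlminb(c(log(gm$alpha), 0), obj2,
                            lower = c(log(0.01), -3),
                            upper = c(log(100), 3),
                            control = list(iter.max = 40,
                                           rel.tol = 1e-9))
      if (-opt2$objective >= new_ll) {
        gm <- discretize_gamma(exp(opt2$par[1L]), k_categories)
        bl <- pmin(bl * exp(opt2$par[2L]), ctl$blen_max)
        new_ll <- -opt2$objective
      }
      .pp_engine_set(eng, list(make_group(model, gm)))
    }
    if (have_par) {
      neg <- function(p) {
        .pp_engine_set(eng, list(make_group(unpack_par(p, kind), gm)))
        -.pp_engine_loglik(eng, bl, FALSE)$loglik
      }
      ob <- optimize_par_blocks(pk, kind, neg, ctl$param_iter)
      if (ob$loglik >= new_ll) {
        pk <- ob$pk
        model <- unpack_par(pk$par, kind)
        new_ll <- ob$loglik
      }
    }
    if (new_ll - ll < ctl$tol) {
      ll <- max(ll, new_ll)
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  tree$edge.length <- bl
  structure(list(tree = tree, model = model, gamma = gm, loglik = ll,
                 n_free_params = k_free_single(kind, gamma, nTip),
                 converged = converged, sweeps = sweeps, kind = kind,
                 n_sites = data$total_length),
            class = "pp_fit")
}

#' @export
print.pp_fit <- function(x, ...) {
  cat(sprintf("ML fit: %s%s, %d taxa, %d sites\n", x$kind,
              if (!is.null(x$gamma)) "+G" else "", ape::Ntip(x$tree),
              x$n_sites))
  cat(sprintf("  log-likelihood: %.4f   free parameters: %d   %s\n",
              x$loglik, x$n_free_params,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (!is.null(x$gamma)) cat(sprintf("  alpha: %.4f\n", x$gamma$alpha))
  invisible(x)
}

#' Per-site log-likelihoods of a fitted model
#'
#' Maps pattern log-likelihoods back onto the original site order; the sum
#' equals the fit's total log-likelihood. Required input of RELL
#' bootstrapping.
#'
#' @param fit a \code{pp_fit}.
#' @param data the \code{pattern_alignment} the fit was computed on.
#' @return numeric vector, one value per original site (nats).
#' @export
per_site_log_likelihoods <- function(fit, data) {
  stopifnot(inherits(fit, "pp_fit"))
  if (!setequal(fit$tree$tip.label, data$taxa))
    stop("fit and data disagree on taxa")
  if (fit$n_sites != data$total_length)
    stop("fit and data disagree on alignment length")
  pm <- patterns_for_tree(fit$tree, data)
  res <- .pp_siteloglik(fit$tree$edge, ape::Ntip(fit$tree),
                        fit$tree$edge.length,
                        list(make_group(fit$model, fit$gamma)),
                        rep(1L, ncol(pm)), pm, data$weights)
  res$pattern_loglik[data$site_pattern]
}
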