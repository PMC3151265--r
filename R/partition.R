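#' Partition schemes
#'
#' A partition scheme divides the sites of an alignment into disjoint,
#' covering, nonempty partitions derived from its gene and codon-position
#' labels.
#'
#' @param data a \code{pattern_alignment}.
#' @param mode how to partition: all sites together, by codon position, by
#'   gene, or by gene crossed with codon position.
#' @return object of class \code{partition_scheme}: list with \code{mode}
#'   and \code{partitions} (named list of site-index vectors).
#' @export
partition_scheme <- function(data,
                             mode = c("concatenated", "by_codon_position",
                                      "by_gene",
                                      "by_gene_and_codon_position")) {
  mode <- match.arg(mode)
  lab <- data$site_labels
  key <- switch(mode,
    concatenated = rep("all", data$total_length),
    by_codon_position = paste0("pos", lab$codon_position),
    by_gene = lab$gene,
    by_gene_and_codon_position = paste0(lab$gene, "_pos",
                                        lab$codon_position))
  parts <- split(seq_len(data$total_length), factor(key, unique(key)))
  if (any(lengths(parts) == 0L)) stop("empty partition")
  structure(list(mode = mode, partitions = parts),
            class = "partition_scheme")
}

#' Codon-position site partitions of a gene
#'
#' Site \eqn{i} (1-based) is assigned to codon position
#' \eqn{((i-1) \bmod 3) + 1}; the gene length must be divisible by 3 (frame
#' assumed to start at site 1).
#'
#' @param gene a \code{pattern_alignment} holding one gene.
#' @return list of three equal-sized integer site-index vectors.
#' @export
split_codon_positions <- function(gene) {
  n <- gene$total_length
  if (n %% 3L != 0L)
    stop("gene length ", n, " not divisible by 3")
  pos <- ((seq_len(n) - 1L) %% 3L) + 1L
  split(seq_len(n), pos)
}

#' Codon-position parameter sharing policies
#'
#' Encodes the ladder of codon-position models: the simplest adds
#' proportional branch-length scaling factors \eqn{c_k} per codon position
#' (reference position 1 fixed at \eqn{c_1 = 1}); successive options
#' estimate separate base frequencies and/or exchangeabilities per position;
#' the most general estimates fully separate (non-proportional) branch
#' lengths, which supersedes the scaling factors and implies separate
#' frequencies, exchangeabilities and gamma shapes per position. The
#' conventional labels are:
#' \describe{
#'   \item{G0}{proportional rates only}
#'   \item{G1}{+ separate frequencies}
#'   \item{G2}{+ separate exchangeabilities}
#'   \item{G3}{+ both}
#'   \item{G4}{fully separate branch lengths and parameters}
#' }
#' With every flag FALSE the policy collapses to the concatenated model.
#'
#' @param proportional_rates estimate per-position branch-length scaling
#'   factors.
#' @param separate_frequencies per-position base frequencies.
#' @param separate_exchangeabilities per-position exchangeabilities (or
#'   \eqn{\kappa}).
#' @param separate_branch_lengths fully separate branch lengths per
#'   position (supersedes \code{proportional_rates}).
#' @param per_position_alpha one gamma shape per position (always TRUE under
#'   \code{separate_branch_lengths}).
#' @return object of class \code{sharing_policy}.
#' @export
sharing_policy <- function(proportional_rates = TRUE,
                           separate_frequencies = FALSE,
                           separate_exchangeabilities = FALSE,
                           separate_branch_lengths = FALSE,
                           per_position_alpha = FALSE) {
  if (separate_branch_lengths) {
    proportional_rates <- FALSE  # superseded
    separate_frequencies <- TRUE
    separate_exchangeabilities <- TRUE
    per_position_alpha <- TRUE
  }
  structure(list(proportional_rates = proportional_rates,
                 separate_frequencies = separate_frequencies,
                 separate_exchangeabilities = separate_exchangeabilities,
                 separate_branch_lengths = separate_branch_lengths,
                 per_position_alpha = per_position_alpha),
            class = "sharing_policy")
}

#' @rdname sharing_policy
#' @param policy a \code{sharing_policy}.
#' @export
policy_label <- function(policy) {
  if (policy$separate_branch_lengths) return("G4")
  if (!policy$proportional_rates && !policy$separate_frequencies &&
      !policy$separate_exchangeabilities) return("shared")
  if (policy$separate_frequencies && policy$separate_exchangeabilities)
    return("G3")
  if (policy$separate_frequencies) return("G1")
  if (policy$separate_exchangeabilities) return("G2")
  "G0"
}

#' @export
print.sharing_policy <- function(x, ...) {
  cat("codon-position sharing policy", policy_label(x), "\n")
  str <- vapply(names(x), function(k) sprintf("%s=%s", k, x[[k]]), "")
  cat(" ", paste(str, collapse = " "), "\n")
  invisible(x)
}

#' Free-parameter accounting
#'
#' Counts the free parameters of a (possibly partitioned) model fit:
#' \eqn{2n-3} branch lengths per independent branch-length set, 3
#' frequencies per independent set (0 for JC), 5 exchangeabilities per REV
#' set (1 \eqn{\kappa} per HKY set), 1 gamma shape per independent gamma,
#' and one scaling factor per non-reference codon position under
#' proportional rates. Totals are additive over gene partitions.
#'
#' @param kind \code{"JC"}, \code{"HKY"} or \code{"REV"}.
#' @param gamma logical.
#' @param n_taxa number of taxa (>= 3).
#' @param scheme a \code{partition_scheme} (or NULL for a single
#'   unpartitioned fit).
#' @param policy a \code{sharing_policy} for modes involving codon
#'   positions.
#' @return list with \code{K} (total) and \code{K_i} (named per-partition
#'   counts; for codon-position sharing the shared blocks are reported in a
#'   single cell).
#' @export
count_free_parameters <- function(kind, gamma, n_taxa, scheme = NULL,
                                  policy = NULL) {
  if (n_taxa < 3L) stop("need at least 3 taxa")
  kind <- match.arg(kind, c("JC", "HKY", "REV"))
  bl <- 2L * n_taxa - 3L
  kf <- switch(kind, JC = 0L, HKY = 3L, REV = 3L)   # frequencies
  ke <- switch(kind, JC = 0L, HKY = 1L, REV = 5L)   # exch / kappa
  ka <- if (gamma) 1L else 0L
  per_cell <- function(pol) {
    # one gene's worth of parameters under a codon policy (or none)
    if (is.null(pol) || policy_label(pol) == "shared")
      return(bl + kf + ke + ka)
    if (pol$separate_branch_lengths)
      return(3L * (bl + kf + ke + ka))
    nf <- if (pol$separate_frequencies) 3L else 1L
    ne <- if (pol$separate_exchangeabilities) 3L else 1L
    na <- if (pol$per_position_alpha) 3L else 1L
    bl + (if (pol$proportional_rates) 2L else 0L) +
      nf * kf + ne * ke + na * ka
  }
  if (is.null(scheme) || scheme$mode == "concatenated") {
    K <- per_cell(if (is.null(scheme)) NULL else policy)
    parts <- if (is.null(scheme)) "all" else names(scheme$partitions)
    Ki <- stats::setNames(rep(K, 1L), parts[1L])
    return(list(K = K, K_i = Ki))
  }
  if (scheme$mode == "by_codon_position") {
    K <- per_cell(policy)
    return(list(K = K,
                K_i = stats::setNames(K, "codon_positions")))
  }
  # gene modes: each gene fully independent
  pol <- if (scheme$mode == "by_gene_and_codon_position") policy else NULL
  genes <- if (scheme$mode == "by_gene") {
    names(scheme$partitions)
  } else {
    unique(sub("_pos[123]$", "", names(scheme$partitions)))
  }
  Kg <- per_cell(pol)
  Ki <- stats::setNames(rep(Kg, length(genes)), genes)
  list(K = sum(Ki), K_i = Ki)
}

# ---- codon-partitioned fitting ---------------------------------------------

# engine groups for the codon positions of one gene under a policy
codon_groups <- function(models, gammas, scales) {
  lapply(1:3, function(k)
    make_group(models[[k]], gammas[[k]], scales[k]))
}

#' Joint ML fit with codon-position sharing
#'
#' Fits one gene (or any in-frame alignment) under a codon-position sharing
#' policy: branch lengths are shared across the three positions (scaled by
#' \eqn{c_k} under proportional rates), while frequencies, exchangeabilities
#' and the gamma shape are shared or separate per the policy. Under
#' \code{separate_branch_lengths} the model separates completely and is fit
#' as three independent per-position optimizations.
#'
#' @param tree \code{phylo} topology.
#' @param data \code{pattern_alignment}; sites must carry codon-position
#'   labels (1, 2, 3), all three present.
#' @param kind,gamma,k_categories model specification as in
#'   \code{\link{optimize_fit}}.
#' @param policy a \code{sharing_policy}.
#' @param control optimizer control.
#' @return object of class \code{pp_partfit}: \code{loglik},
#'   \code{n_free_params}, \code{models} (per position), \code{gammas},
#'   \code{scales} (\eqn{c_k}), \code{tree}(s), \code{policy},
#'   \code{converged}, and \code{position_fits} when fully separate.
#' @export
fit_codon_partitioned <- function(tree, data, kind = c("REV", "HKY", "JC"),
                                  gamma = TRUE, k_categories = 6L,
                                  policy = sharing_policy(),
                                  control = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(policy, "sharing_policy"))
  ctl <- default_fit_control(control)
  cpos <- data$site_labels$codon_position
  if (length(unique(cpos)) == 1L && policy_label(policy) != "shared")
    stop("per-position parameters requested but data has one position only")
  pos_sites <- split(seq_len(data$total_length), cpos)

  if (policy$separate_branch_lengths) {
    fits <- lapply(pos_sites, function(idx)
      optimize_fit(tree, subset_sites(data, idx), kind, gamma, k_categories,
                   control = control))
    ll <- sum(vapply(fits, `[[`, 0, "loglik"))
    K <- count_free_parameters(kind, gamma, length(data$taxa),
                               policy = policy,
                               scheme = structure(list(
                                 mode = "by_codon_position",
                                 partitions = pos_sites),
                                 class = "partition_scheme"))$K
    return(structure(list(loglik = ll, n_free_params = K,
                          models = lapply(fits, `[[`, "model"),
                          gammas = lapply(fits, `[[`, "gamma"),
                          scales = c(1, 1, 1),
                          tree = fits[[1L]]$tree,
                          trees = lapply(fits, `[[`, "tree"),
                          policy = policy, kind = kind,
                          position_fits = fits,
                          converged = all(vapply(fits, `[[`, TRUE,
                                                 "converged")),
                          n_sites = data$total_length),
                     class = "pp_partfit"))
  }

  tree <- as_engine_tree(tree)
  if (!setequal(tree$tip.label, data$taxa))
    stop("tree leaf set does not match alignment taxa")
  nTip <- ape::Ntip(tree)
  pm <- patterns_for_tree(tree, data)
  # engine patterns must be distinct per position group: patterns are shared
  # columns; assign each pattern to the position of its sites -- a pattern
  # occurring at several positions must be duplicated per group
  pat_of_site <- data$site_pattern
  combo <- paste(pat_of_site, cpos)
  first <- !duplicated(combo)
  eng_pat <- pm[, pat_of_site[first], drop = FALSE]
  eng_group <- cpos[first]
  eng_w <- as.numeric(tapply(rep(1, length(combo)),
                             factor(combo, combo[first]), sum))

  shared_empirical <- base_frequencies(data)
  init_model <- function() switch(kind, JC = jc_model(),
                                  HKY = hky_model(shared_empirical, 1),
                                  REV = rev_model(shared_empirical))
  models <- list(init_model(), init_model(), init_model())
  gm0 <- if (gamma) discretize_gamma(0.5, k_categories) else NULL
  gammas <- list(gm0, gm0, gm0)
  scales <- c(1, 1, 1)
  bl <- rep(ctl$init_blen, nrow(tree$edge))

  eng <- .pp_engine_new(tree$edge, nTip, codon_groups(models, gammas,
                                                      scales),
                        as.integer(eng_group), eng_pat, eng_w)
  cur_ll <- function() .pp_engine_loglik(eng, bl, FALSE)$loglik
  set_eng <- function() .pp_engine_set(eng, codon_groups(models, gammas,
                                                         scales))

  ll <- -Inf
  converged <- FALSE
  have_par <- kind != "JC"
  for (s in seq_len(ctl$max_sweeps)) {
    set_eng()
    res <- .pp_engine_optimize(eng, bl, ctl$blen_min, ctl$blen_max,
                               max(ctl$tol * 10, 1e-4), ctl$blen_passes)
    bl <- res$blen
    new_ll <- res$loglik
    # per-position branch-length scaling factors (reference c_1 = 1)
    if (policy$proportional_rates) {
      for (k in 2:3) {
        sopt <- stats::optimize(function(lc) {
          scales[k] <<- exp(lc)
          set_eng()
          cur_ll()
        }, lower = log(1e-3), upper = log(1e3), maximum = TRUE, tol = 1e-4)
        scales[k] <- exp(sopt$maximum)
        if (sopt$objective >= new_ll) new_ll <- sopt$objective
      }
      set_eng()
    }
    # gamma shape(s)
    if (gamma) {
      ks <- if (policy$per_position_alpha) 1:3 else 1L
      for (k in ks) {
        aopt <- stats::optimize(function(la) {
          g <- discretize_gamma(exp(la), k_categories)
          if (policy$per_position_alpha) gammas[[k]] <<- g
          else gammas <<- list(g, g, g)
          set_eng()
          cur_ll()
        }, lower = log(0.01), upper = log(100), maximum = TRUE, tol = 1e-4)
        g <- discretize_gamma(exp(aopt$maximum), k_categories)
        if (policy$per_position_alpha) gammas[[k]] <- g
        else gammas <- list(g, g, g)
        if (aopt$objective >= new_ll) new_ll <- aopt$objective
      }
      set_eng()
    }
    # substitution parameters: separate per position or shared
    if (have_par) {
      if (policy$separate_frequencies || policy$separate_exchangeabilities) {
        for (k in 1:3) {
          pk <- pack_par(kind, models[[k]])
          obj <- function(p) {
            m <- unpack_par(p, kind)
            # respect sharing: non-separated blocks stay at position-1 values
            models[[k]] <<- constrain_model(m, models[[1L]], policy, kind)
            set_eng()
            -cur_ll()
          }
          opt <- stats::nlminb(pk$par, obj, lower = pk$lower,
                               upper = pk$upper,
                               control = list(iter.max = ctl$param_iter))
          models[[k]] <- constrain_model(unpack_par(opt$par, kind),
                                         models[[1L]], policy, kind)
          if (-opt$objective >= new_ll) new_ll <- -opt$objective
        }
        set_eng()
      } else {
        pk <- pack_par(kind, models[[1L]])
        obj <- function(p) {
          m <- unpack_par(p, kind)
          models <<- list(m, m, m)
          set_eng()
          -cur_ll()
        }
        opt <- stats::nlminb(pk$par, obj, lower = pk$lower, upper = pk$upper,
                             control = list(iter.max = ctl$param_iter))
        m <- unpack_par(opt$par, kind)
        models <- list(m, m, m)
        set_eng()
        if (-opt$objective >= new_ll) new_ll <- -opt$objective
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
  K <- count_free_parameters(kind, gamma, nTip, policy = policy,
                             scheme = structure(list(
                               mode = "by_codon_position",
                               partitions = pos_sites),
                               class = "partition_scheme"))$K
  structure(list(loglik = ll, n_free_params = K, models = models,
                 gammas = gammas, scales = scales, tree = tree,
                 policy = policy, kind = kind, converged = converged,
                 n_sites = data$total_length),
            class = "pp_partfit")
}

# apply sharing constraints: blocks not separated by the policy are copied
# from the reference (position 1) model
constrain_model <- function(m, ref, policy, kind) {
  f <- if (policy$separate_frequencies) m$frequencies else ref$frequencies
  if (kind == "HKY") {
    kap <- if (policy$separate_exchangeabilities) m$kappa else ref$kappa
    return(hky_model(f, kap))
  }
  ex <- if (policy$separate_exchangeabilities) m$exchangeabilities
        else ref$exchangeabilities
  rev_model(f, ex)
}

#' @export
print.pp_partfit <- function(x, ...) {
  cat(sprintf("codon-partitioned ML fit (%s, policy %s): ll = %.4f, K = %d%s\n",
              x$kind, policy_label(x$policy), x$loglik, x$n_free_params,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$scales) && x$policy$proportional_rates)
    cat("  scaling factors c:", sprintf("%.4f", x$scales), "\n")
  invisible(x)
}

# ---- gene-partitioned fitting over a candidate tree set --------------------

#' Per-gene partitioned scoring of a candidate tree set
#'
#' For each candidate tree the total partitioned log-likelihood is the sum
#' over genes of that gene's own maximum likelihood (independent branch
#' lengths, frequencies, exchangeabilities and gamma shape per gene;
#' optionally crossed with a codon-position sharing policy). The best tree
#' is the argmax of the total. Per-site log-likelihoods are retained for
#' RELL bootstrapping. Successive trees are warm-started from the previous
#' tree's parameter estimates per gene (deterministic: candidate order is
#' fixed).
#'
#' @param candidate_trees \code{multiPhylo} (or list of \code{phylo}) over
#'   the genes' taxon set.
#' @param genes named list of \code{pattern_alignment}s with identical
#'   taxa.
#' @param kind,gamma,k_categories model specification.
#' @param codon_policy optional \code{sharing_policy} applied within each
#'   gene.
#' @param control optimizer control.
#' @param site_loglik keep the trees x sites per-site log-likelihood matrix
#'   (needed for RELL).
#' @return object of class \code{pp_genefit}: \code{total_loglik} (per
#'   tree), \code{best_tree} (index), \code{gene_loglik} (genes x trees),
#'   \code{fits} (per-gene fits on the best tree), \code{site_loglik}
#'   (trees x sites or NULL), \code{trees}, \code{K} and \code{K_i}.
#' @export
fit_gene_partitioned <- function(candidate_trees, genes,
                                 kind = c("REV", "HKY", "JC"), gamma = TRUE,
                                 k_categories = 6L, codon_policy = NULL,
                                 control = list(), site_loglik = TRUE) {
  kind <- match.arg(kind)
  if (inherits(candidate_trees, "phylo"))
    candidate_trees <- list(candidate_trees)
  nT <- length(candidate_trees)
  if (nT < 1L) stop("empty candidate tree set")
  if (length(genes) < 1L) stop("no genes")
  taxa <- genes[[1L]]$taxa
  for (g in genes)
    if (!setequal(g$taxa, taxa)) stop("taxon sets differ between genes")
  for (tr in candidate_trees)
    if (!setequal(tr$tip.label, taxa))
      stop("candidate tree does not span the genes' taxon set")
  nm <- names(genes)
  if (is.null(nm)) nm <- paste0("g", seq_along(genes))
  nsites <- vapply(genes, `[[`, 0L, "total_length")
  gll <- matrix(NA_real_, length(genes), nT,
                dimnames = list(nm, NULL))
  sll <- if (site_loglik) matrix(NA_real_, nT, sum(nsites)) else NULL
  offs <- c(0L, cumsum(nsites))
  fits_best <- vector("list", length(genes))
  all_fits_tree <- vector("list", nT)
  for (gi in seq_along(genes)) {
    warm <- NULL
    gene_fits <- vector("list", nT)
    for (ti in seq_len(nT)) {
      ctl <- control
      if (!is.null(warm) && is.null(codon_policy))
        ctl$init <- list(model = warm$model, gamma = warm$gamma)
      fit <- if (is.null(codon_policy)) {
        optimize_fit(candidate_trees[[ti]], genes[[gi]], kind, gamma,
                     k_categories, control = ctl)
      } else {
        fit_codon_partitioned(candidate_trees[[ti]], genes[[gi]], kind,
                              gamma, k_categories, policy = codon_policy,
                              control = ctl)
      }
      if (is.null(codon_policy)) warm <- fit
      gll[gi, ti] <- fit$loglik
      gene_fits[[ti]] <- fit
      if (site_loglik) {
        psl <- if (is.null(codon_policy)) {
          per_site_log_likelihoods(fit, genes[[gi]])
        } else {
          per_site_log_likelihoods_part(fit, genes[[gi]])
        }
        sll[ti, (offs[gi] + 1L):offs[gi + 1L]] <- psl
      }
    }
    best_for_gene <- gene_fits  # keep per-tree fits until best tree known
    fits_best[[gi]] <- best_for_gene
  }
  total <- colSums(gll)
  best <- which.max(total)
  fits <- lapply(fits_best, `[[`, best)
  names(fits) <- nm
  n_taxa <- length(taxa)
  Kg <- vapply(fits, `[[`, 0L, "n_free_params")
  structure(list(total_loglik = total, best_tree = best,
                 gene_loglik = gll, fits = fits,
                 site_loglik = sll, trees = candidate_trees,
                 K = sum(Kg), K_i = stats::setNames(Kg, nm),
                 n_i = stats::setNames(as.numeric(nsites), nm),
                 kind = kind, gamma = gamma),
            class = "pp_genefit")
}

# per-site log-likelihoods of a codon-partitioned fit
per_site_log_likelihoods_part <- function(fit, data) {
  stopifnot(inherits(fit, "pp_partfit"))
  cpos <- data$site_labels$codon_position
  if (fit$policy$separate_branch_lengths) {
    out <- numeric(data$total_length)
    pos_sites <- split(seq_len(data$total_length), cpos)
    for (k in 1:3)
      out[pos_sites[[k]]] <-
        per_site_log_likelihoods(fit$position_fits[[k]],
                                 subset_sites(data, pos_sites[[k]]))
    return(out)
  }
  tree <- fit$tree
  pm <- patterns_for_tree(tree, data)
  pat_of_site <- data$site_pattern
  combo <- paste(pat_of_site, cpos)
  first <- !duplicated(combo)
  eng_pat <- pm[, pat_of_site[first], drop = FALSE]
  eng_group <- cpos[first]
  eng_w <- as.numeric(tapply(rep(1, length(combo)),
                             factor(combo, combo[first]), sum))
  res <- .pp_siteloglik(tree$edge, ape::Ntip(tree), tree$edge.length,
                        codon_groups(fit$models, fit$gammas, fit$scales),
                        as.integer(eng_group), eng_pat, eng_w)
  res$pattern_loglik[match(combo, combo[first])]
}

#' @export
print.pp_genefit <- function(x, ...) {
  cat(sprintf("gene-partitioned fit: %d genes, %d candidate trees (%s%s)\n",
              nrow(x$gene_loglik), length(x$total_loglik), x$kind,
              if (x$gamma) "+G" else ""))
  cat(sprintf("  best tree: #%d, total ll = %.4f, K = %d\n", x$best_tree,
              x$total_loglik[x$best_tree], x$K))
  invisible(x)
}
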