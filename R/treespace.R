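#' Tree input/output
#'
#' Newick reading and writing backed by \code{ape}, with stricter error
#' reporting (unbalanced parentheses and duplicate labels are rejected with
#' position information) and deterministic output: children are rotated so
#' that each clade lists the lexicographically smallest descendant leaf
#' first.
#'
#' @param text Newick string (alternative to \code{path}).
#' @param path file path; files may hold one tree per line.
#' @return a \code{phylo}, or \code{multiPhylo} when the source holds
#'   several trees.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) && is.null(path)) stop("supply text or path")
  if (is.null(text)) {
    text <- readLines(path)
    text <- text[nzchar(trimws(text))]
  }
  trees <- lapply(text, read_newick_one)
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  trees
}

read_newick_one <- function(s) {
  s <- trimws(s)
  depth <- 0L
  for (i in seq_len(nchar(s))) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at offset ", i, " in Newick string")
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick string (", depth, " unclosed)")
  tr <- ape::read.tree(text = s)
  if (is.null(tr)) stop("failed to parse Newick string")
  if (anyDuplicated(tr$tip.label)) {
    dup <- tr$tip.label[duplicated(tr$tip.label)][1L]
    stop("duplicate leaf label '", dup, "' at offset ",
         regexpr(dup, s, fixed = TRUE)[1L])
  }
  tr
}

#' @rdname read_newick
#' @param tree \code{phylo} (or \code{multiPhylo}).
#' @param digits significant digits for branch lengths.
#' @return Newick string(s); written to \code{path} when given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  trees <- if (inherits(tree, "multiPhylo")) tree else list(tree)
  out <- vapply(trees, function(tr) {
    tr <- ape::rotateConstr(tr, sort(tr$tip.label))
    ape::write.tree(tr, digits = digits)
  }, "")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(path))
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Canonical topology string of an unrooted tree
#'
#' Branch lengths are dropped, the tree is rerooted on the leaf with the
#' smallest label and children are sorted recursively by smallest descendant
#' leaf, so two trees share the same canonical string iff they have the same
#' unrooted topology.
#'
#' @param tree \code{phylo}.
#' @return character scalar.
#' @export
canonical_topology <- function(tree) {
  tree$edge.length <- NULL
  tree$node.label <- NULL
  if (ape::Ntip(tree) > 2L) {
    tree <- ape::unroot(tree)
    og <- sort(tree$tip.label)[1L]
    tree <- ape::root(tree, outgroup = og, resolve.root = FALSE)
  }
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  ape::write.tree(tree)
}

# ---- bipartitions and Robinson-Foulds ---------------------------------------

# internal bipartitions as canonical strings (side not containing the
# alphabetically first taxon)
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  ref <- sort(tree$tip.label)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Normalized Robinson-Foulds distance
#'
#' The number of internal bipartitions present in exactly one of the two
#' trees, divided by the maximum possible \eqn{2(n-3)} for binary unrooted
#' trees on \eqn{n} leaves. 0 iff the unrooted topologies are identical.
#'
#' @param t1,t2 \code{phylo} objects over the same leaf set.
#' @return value in \code{[0, 1]}.
#' @export
robinson_foulds_normalized <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  n <- ape::Ntip(t1)
  if (n < 4L) return(0)
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  d <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  d / (2 * (n - 3))
}

# ---- polytomy resolution enumeration ---------------------------------------

double_factorial_odd <- function(k) {
  # (2k-3)!! rooted binary arrangements of k subtrees
  if (k <= 2) return(1)
  prod(seq(1, 2 * k - 3, by = 2))
}

# nested-list representation: leaf = label string, internal = list of children
phylo_to_nested <- function(tree) {
  n <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    lapply(kids[[as.character(node)]], rec)
  }
  rec(n + 1L)
}

nested_to_newick <- function(x) {
  rec <- function(y) {
    if (is.character(y)) return(y)
    paste0("(", paste(vapply(y, rec, ""), collapse = ","), ")")
  }
  paste0(rec(x), ";")
}

# all rooted binary arrangements of k atomic items (labeled 1..k), built by
# sequential insertion: item i+1 attaches to any of the 2i-1 edges (counting
# the root edge), giving (2k-3)!! trees; items are atomic -- arrangements
# never descend into the subtrees they will later stand for
rooted_arrangements_atomic <- function(k) {
  if (k == 1L) return(list(1L))
  trees <- list(1L)
  for (i in 2L:k) {
    out <- list()
    insert_all <- function(t) {
      res <- list(list(t, i))
      if (is.list(t)) {
        for (a in insert_all(t[[1L]])) res <- c(res, list(list(a, t[[2L]])))
        for (b in insert_all(t[[2L]])) res <- c(res, list(list(t[[1L]], b)))
      }
      res
    }
    for (t in trees) out <- c(out, insert_all(t))
    trees <- out
  }
  trees
}

# substitute atomic item indices by their subtrees
fill_arrangement <- function(t, subtrees) {
  if (is.integer(t) || is.numeric(t)) return(subtrees[[t]])
  list(fill_arrangement(t[[1L]], subtrees),
       fill_arrangement(t[[2L]], subtrees))
}

#' Count and enumerate binary resolutions of a backbone tree
#'
#' A backbone (constraint) tree may contain polytomies; each polytomy with
#' \eqn{k} children contributes \eqn{(2k-3)!!} rooted local arrangements, and
#' the full candidate set is the product over polytomies. The tree is
#' treated as rooted (root an unrooted backbone on its outgroup first).
#'
#' @param backbone \code{phylo}, possibly multifurcating.
#' @param cap refuse to enumerate more than this many trees (the count is
#'   still reported in the error).
#' @return \code{count_resolutions}: the number of binary resolutions.
#'   \code{enumerate_resolutions}: a \code{multiPhylo} of all distinct binary
#'   resolutions, in deterministic order.
#' @export
count_resolutions <- function(backbone) {
  n <- ape::Ntip(backbone)
  kids <- table(backbone$edge[, 1])
  root <- n + 1L
  counts <- vapply(names(kids), function(nd) {
    double_factorial_odd(as.integer(kids[[nd]]))
  }, 0)
  prod(counts)
}

#' @rdname count_resolutions
#' @export
enumerate_resolutions <- function(backbone, cap = 1e6) {
  if (ape::Ntip(backbone) < 3L) stop("backbone needs at least 3 leaves")
  cnt <- count_resolutions(backbone)
  if (cnt > cap)
    stop("backbone has ", format(cnt, big.mark = ","),
         " binary resolutions, exceeding the cap (", format(cap), ")")
  nested <- phylo_to_nested(backbone)
  arr_cache <- list()
  resolve <- function(x) {
    if (is.character(x)) return(list(x))
    k <- length(x)
    key <- as.character(k)
    if (is.null(arr_cache[[key]]))
      arr_cache[[key]] <<- rooted_arrangements_atomic(k)
    arrs <- arr_cache[[key]]
    childsets <- lapply(x, resolve)
    combos <- expand.grid(lapply(childsets, seq_along))
    out <- list()
    for (i in seq_len(nrow(combos))) {
      subtrees <- lapply(seq_along(childsets),
                         function(j) childsets[[j]][[combos[i, j]]])
      out <- c(out, lapply(arrs, fill_arrangement, subtrees = subtrees))
    }
    out
  }
  res <- resolve(nested)
  trees <- lapply(res, function(x) read_newick_one(nested_to_newick(x)))
  class(trees) <- "multiPhylo"
  trees
}

#' Does a tree contain a given clade?
#'
#' Tested on the unrooted topology: TRUE when the taxa form one side of some
#' bipartition (or a clade of the rooted tree).
#' @param tree \code{phylo}.
#' @param taxa character vector of leaf labels.
#' @export
has_clade <- function(tree, taxa) {
  n <- ape::Ntip(tree)
  if (length(taxa) <= 1L) return(all(taxa %in% tree$tip.label))
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  target <- sort(taxa)
  for (i in seq_along(pp)) {
    side <- sort(labs[pp[[i]]])
    if (identical(side, target)) return(TRUE)
    if (identical(sort(setdiff(labs, side)), target)) return(TRUE)
  }
  FALSE
}

# ---- random topologies and the RF null -------------------------------------

#' Uniform random unrooted binary topology
#'
#' Sequential addition: each new taxon attaches to an edge chosen uniformly
#' among the \eqn{2m-3} existing edges, which makes every unrooted binary
#' labeled topology equally likely (probability \eqn{1/(2n-5)!!}).
#'
#' @param taxa character vector of at least 3 leaf labels.
#' @param seed optional integer seed (uses the session RNG when NULL).
#' @return unrooted binary \code{phylo} without branch lengths.
#' @export
random_topology <- function(taxa, seed = NULL) {
  if (length(taxa) < 3L) stop("need at least 3 taxa")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  # top-level: three subtrees around the central unrooted node
  tops <- as.list(taxa[1:3])
  sizes <- c(1L, 1L, 1L)
  npos <- function(t) if (is.character(t)) 1L else attr(t, "pos")
  wrap <- function(a, b) {
    t <- list(a, b)
    attr(t, "pos") <- npos(a) + npos(b) + 1L
    t
  }
  insert_at <- function(t, x, k) {
    # k in 1..npos(t); position 1 = above t's root
    if (k == 1L) return(wrap(t, x))
    k <- k - 1L
    la <- npos(t[[1L]])
    if (k <= la) return(wrap(insert_at(t[[1L]], x, k), t[[2L]]))
    wrap(t[[1L]], insert_at(t[[2L]], x, k - la))
  }
  for (x in taxa[-(1:3)]) {
    w <- vapply(tops, npos, 0L)
    j <- sample.int(3L, 1L, prob = w)
    k <- sample.int(w[j], 1L)
    tops[[j]] <- insert_at(tops[[j]], x, k)
  }
  s <- paste0("(", paste(vapply(tops, function(t) {
    rec <- function(y) {
      if (is.character(y)) return(y)
      paste0("(", rec(y[[1L]]), ",", rec(y[[2L]]), ")")
    }
    rec(t)
  }, ""), collapse = ","), ");")
  read_newick_one(s)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Null distribution of mean pairwise RF distance among random trees
#'
#' Each simulation draws \code{n_trees} uniform random topologies on
#' \code{n_taxa} leaves and records the mean pairwise normalized RF
#' distance. The returned p-value function gives the fraction of simulations
#' with mean \eqn{\le} the observed value (the \code{count/n_sims}
#' convention).
#'
#' @param n_taxa,n_trees,n_sims problem size.
#' @param seed integer seed.
#' @return list with \code{samples} (length \code{n_sims}) and
#'   \code{p_value(observed)}.
#' @export
rf_null_distribution <- function(n_taxa, n_trees, n_sims = 1000,
                                 seed = NULL) {
  if (n_trees < 2L) stop("n_trees must be at least 2")
  if (n_sims < 1L) stop("n_sims must be at least 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  taxa <- paste0("t", seq_len(n_taxa))
  samples <- vapply(seq_len(n_sims), function(i) {
    trees <- lapply(seq_len(n_trees), function(j) random_topology(taxa))
    mean_pairwise_rf(trees)
  }, 0)
  list(samples = samples,
       p_value = function(observed) mean(samples <= observed))
}

mean_pairwise_rf <- function(trees) {
  m <- length(trees)
  bips <- lapply(trees, bipartitions)
  n <- ape::Ntip(trees[[1L]])
  denom <- 2 * (n - 3)
  tot <- 0
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    d <- length(setdiff(bips[[i]], bips[[j]])) +
      length(setdiff(bips[[j]], bips[[i]]))
    tot <- tot + d / denom
  }
  tot / (m * (m - 1) / 2)
}

# ---- NNI search -------------------------------------------------------------

# the two NNI rearrangements across each internal edge of a binary unrooted
# tree, realized by edge surgery on the rooted representation
nni_neighbors <- function(tree) {
  tree <- ape::reorder.phylo(as_engine_tree(tree), "postorder")
  n <- ape::Ntip(tree)
  E <- tree$edge
  internal <- which(E[, 2] > n)
  out <- list()
  for (e in internal) {
    u <- E[e, 1]
    v <- E[e, 2]
    vkids <- which(E[, 1] == v)
    sib <- setdiff(which(E[, 1] == u), e)[1L]
    if (is.na(sib)) next
    for (ck in vkids) {
      E2 <- E
      E2[sib, 2] <- E[ck, 2]
      E2[ck, 2] <- E[sib, 2]
      t2 <- tree
      t2$edge <- E2
      t2$edge.length <- NULL
      t2 <- ape::read.tree(text = ape::write.tree(t2))
      out <- c(out, list(t2))
    }
  }
  out
}

#' Hill-climbing tree search over nearest-neighbor interchanges
#'
#' Starting from \code{start} (default: a random topology per restart), the
#' search evaluates the maximum likelihood of every NNI neighbor and moves
#' while improvement exceeds \code{eps}; the result is a local optimum with
#' respect to NNI. Deterministic for a given seed.
#'
#' @param data a \code{pattern_alignment}.
#' @param kind,gamma,k_categories model specification as in
#'   \code{\link{optimize_fit}}.
#' @param start starting \code{phylo} topology; default is the
#'   neighbor-joining tree on pairwise JC distances (deterministic).
#' @param restarts additional random restarts (best result kept).
#' @param seed integer seed for restarts.
#' @param fixed_model optional \code{(model, gamma)} list: score topologies
#'   by optimizing branch lengths only (much faster; used by bootstraps).
#' @param control optimizer control for the per-topology fits.
#' @param eps minimum improvement to accept a move (nats).
#' @return the best \code{pp_fit} found (with \code{$tree} the ML topology).
#' @export
nni_hill_climb <- function(data, kind = "REV", gamma = TRUE,
                           k_categories = 6L, start = NULL, restarts = 0L,
                           seed = NULL, fixed_model = NULL,
                           control = list(), eps = 1e-4) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  full_fit <- function(tr, init = NULL) {
    ctl <- control
    if (!is.null(init)) ctl$init <- list(model = init$model,
                                         gamma = init$gamma)
    optimize_fit(tr, data, kind, gamma, k_categories,
                 fixed_model = fixed_model, control = ctl)
  }
  climb <- function(tr) {
    cur <- full_fit(tr)
    repeat {
      nb <- nni_neighbors(cur$tree)
      if (length(nb) == 0L) return(cur)
      # neighbors scored with substitution parameters frozen at the current
      # optimum (branch lengths re-optimized); accepted moves are refit
      frozen <- if (is.null(fixed_model))
        list(model = cur$model, gamma = cur$gamma) else fixed_model
      lls <- vapply(nb, function(t2)
        optimize_fit(t2, data, fixed_model = frozen,
                     control = control)$loglik, 0)
      if (max(lls) <= cur$loglik + eps) return(cur)
      nxt <- full_fit(nb[[which.max(lls)]], init = cur)
      if (nxt$loglik <= cur$loglik + eps) return(cur)
      cur <- nxt
    }
  }
  starts <- list(if (is.null(start)) nj_start(data) else start)
  if (restarts > 0L)
    starts <- c(starts, lapply(seq_len(restarts),
                               function(i) random_topology(data$taxa)))
  best <- NULL
  for (tr in starts) {
    fit <- climb(tr)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

# neighbor-joining start tree on pairwise JC-corrected distances
nj_start <- function(data) {
  n <- length(data$taxa)
  if (n == 3L) return(random_topology(data$taxa, seed = 1L))
  D <- matrix(0, n, n, dimnames = list(data$taxa, data$taxa))
  pm <- data$patterns
  w <- data$weights
  pure <- pm %in% c(1L, 2L, 4L, 8L)
  dim(pure) <- dim(pm)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- pure[i, ] & pure[j, ]
    tot <- sum(w[ok])
    if (tot == 0) { D[i, j] <- D[j, i] <- 0.5; next }
    p <- sum(w[ok & (pm[i, ] != pm[j, ])]) / tot
    d <- if (p >= 0.745) 3 else -0.75 * log(1 - 4 * p / 3)
    D[i, j] <- D[j, i] <- d
  }
  tr <- ape::nj(stats::as.dist(D))
  ape::unroot(tr)
}
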