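#' Forward simulation of sequence alignments
#'
#' Simulates nucleotide alignments along a tree under a reversible model
#' with optional discrete-gamma among-site rate variation and per-codon-
#' position rate multipliers. Root states are drawn from the stationary
#' frequencies; each child state is drawn from \eqn{P(Q, r t)} where the
#' per-site rate \eqn{r} is the product of the site's gamma-category rate
#' and its codon-position multiplier. No indels are simulated.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param model a \code{nucleotide_model}.
#' @param gamma optional \code{gamma_rates}.
#' @param length number of sites (>= 1).
#' @param position_multipliers optional length-3 rate multipliers for codon
#'   positions 1..3 (site i has position ((i-1) mod 3)+1).
#' @param seed integer seed; the simulation is byte-identical per seed.
#' @return character matrix taxa x sites.
#' @export
simulate_alignment <- function(tree, model, gamma = NULL, length,
                               position_multipliers = NULL, seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (length < 1L) stop("length must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- ape::Ntip(tree)
  nnode <- n + tree$Nnode
  Q <- build_generator(model)
  pi <- model$frequencies
  # per-site rate classes
  rates <- if (is.null(gamma)) 1 else gamma$category_rates
  cat_of_site <- if (is.null(gamma)) rep(1L, length) else
    sample.int(length(rates), length, replace = TRUE)
  mult <- if (is.null(position_multipliers)) rep(1, 3) else {
    stopifnot(length(position_multipliers) == 3L)
    as.numeric(position_multipliers)
  }
  pos_of_site <- ((seq_len(length) - 1L) %% 3L) + 1L
  rate_of_site <- rates[cat_of_site] * mult[pos_of_site]
  classes <- interaction(cat_of_site, pos_of_site, drop = TRUE)
  class_idx <- split(seq_len(length), classes)
  class_rate <- vapply(class_idx, function(ii) rate_of_site[ii[1L]], 0)

  states <- matrix(NA_integer_, nnode, length)
  root <- n + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE, prob = pi)
  d <- decompose_generator(Q, pi)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    for (ci in seq_along(class_idx)) {
      P <- d$V %*% diag(exp(d$values * t * class_rate[ci])) %*% d$Vinv
      P[P < 0] <- 0
      P <- P / rowSums(P)
      ii <- class_idx[[ci]]
      ps <- states[par, ii]
      for (s in 1:4) {
        js <- ii[ps == s]
        if (length(js) > 0L)
          states[ch, js] <- sample.int(4L, length(js), replace = TRUE,
                                       prob = P[s, ])
      }
    }
  }
  out <- matrix(NUC_STATES[states[seq_len(n), , drop = FALSE]], n, length)
  rownames(out) <- tree$tip.label
  out
}

#' Between-gene heterogeneity profile
#'
#' The stated world of the multigene simulator: per-gene parameter ranges
#' matching the heterogeneity reported across real yeast single-gene
#' analyses -- average ts/tv ratio R in [1.30, 4.22], gamma shape
#' \eqn{\alpha} in [0.25, 1.03], average GC content in [0.38, 0.47] -- plus
#' gene lengths in whole codons and per-codon-position rate multipliers
#' (third positions fastest, second slowest).
#'
#' @param R_range,alpha_range,gc_range,gene_length_range numeric intervals
#'   (gene lengths in codons).
#' @param codon_rate_multipliers per-position rate factors.
#' @param n_genes number of genes to simulate.
#' @return object of class \code{heterogeneity_profile}.
#' @export
heterogeneity_profile <- function(R_range = c(1.30, 4.22),
                                  alpha_range = c(0.25, 1.03),
                                  gc_range = c(0.38, 0.47),
                                  gene_length_range = c(100, 800),
                                  codon_rate_multipliers = c(1, 0.5, 3),
                                  n_genes = 20L) {
  chk <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x)) || x[1L] <= 0 ||
        x[2L] < x[1L])
      stop(nm, " must be a positive ordered interval")
  }
  chk(R_range, "R_range")
  chk(alpha_range, "alpha_range")
  chk(gc_range, "gc_range")
  chk(gene_length_range, "gene_length_range")
  if (length(codon_rate_multipliers) != 3L ||
      any(codon_rate_multipliers <= 0))
    stop("codon_rate_multipliers must be 3 positive values")
  structure(list(R_range = R_range, alpha_range = alpha_range,
                 gc_range = gc_range,
                 gene_length_range = gene_length_range,
                 codon_rate_multipliers = codon_rate_multipliers,
                 n_genes = as.integer(n_genes)),
            class = "heterogeneity_profile")
}

# REV model with strand-symmetric frequencies hitting a target GC, and
# transition exchangeabilities scaled so the average ts/tv ratio R equals
# the target. With transversion rates held fixed, R is linear in the joint
# transition scale s, so the root-find has a closed-form solution; the
# resample path guards infeasible jitter draws.
model_for_gene <- function(R_target, gc_target, jitter_sd = 0.2,
                           max_attempts = 100L) {
  f <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  for (attempt in seq_len(max_attempts)) {
    tv <- exp(stats::rnorm(3, 0, jitter_sd))  # AC, AT, CG jitter; GT = 1
    jt <- exp(stats::rnorm(2, 0, jitter_sd))  # AG, CT jitter
    den <- f["A"] * f["C"] * tv[1] + f["A"] * f["T"] * tv[2] +
      f["C"] * f["G"] * tv[3] + f["G"] * f["T"] * 1
    num1 <- f["A"] * f["G"] * jt[1] + f["C"] * f["T"] * jt[2]
    s <- unname(R_target * den / num1)
    if (s >= 1e-3 && s <= 1e3) {
      ex <- c(AC = tv[1], AG = s * jt[1], AT = tv[2], CG = tv[3],
              CT = s * jt[2], GT = 1)
      return(rev_model(f, ex))
    }
    warning("resampling exchangeability jitter for unattainable R")
  }
  stop("could not attain R = ", R_target, " after ", max_attempts,
       " attempts")
}

#' Simulate a heterogeneous multigene dataset with known truth
#'
#' Per gene: draws \eqn{\alpha}, target GC and target R uniformly from the
#' profile's ranges and a length (whole codons) from its length range;
#' builds a REV model with strand-symmetric frequencies (A=T, C=G) matching
#' the GC target and exchangeabilities matched to the R target; and
#' simulates the alignment on the given tree with the profile's
#' codon-position rate multipliers. All generating parameters are recorded.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param profile a \code{heterogeneity_profile}.
#' @param seed integer master seed.
#' @return object of class \code{simulated_gene_set}: \code{alignments}
#'   (named list of \code{pattern_alignment}), \code{truth} (data.frame),
#'   \code{models}, \code{gammas}, \code{tree}, \code{profile},
#'   \code{seed}.
#' @export
simulate_heterogeneous_gene_set <- function(tree, profile, seed = NULL) {
  stopifnot(inherits(profile, "heterogeneity_profile"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  ng <- profile$n_genes
  alignments <- list()
  models <- list()
  gammas <- list()
  truth <- NULL
  if (ng > 0L) {
    for (i in seq_len(ng)) {
      R <- stats::runif(1, profile$R_range[1], profile$R_range[2])
      a <- stats::runif(1, profile$alpha_range[1], profile$alpha_range[2])
      gc <- stats::runif(1, profile$gc_range[1], profile$gc_range[2])
      len <- 3L * as.integer(round(stats::runif(
        1, profile$gene_length_range[1], profile$gene_length_range[2])))
      m <- model_for_gene(R, gc)
      g <- discretize_gamma(a, 6)
      mat <- simulate_alignment(tree, m, g, len,
                                profile$codon_rate_multipliers)
      nmg <- sprintf("gene%03d", i)
      alignments[[nmg]] <- compress_patterns(mat, gene = nmg)
      models[[nmg]] <- m
      gammas[[nmg]] <- g
      truth <- rbind(truth, data.frame(
        gene = nmg, R = R, alpha = a, gc = gc, length = len,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(alignments = alignments, truth = truth, models = models,
                 gammas = gammas, tree = tree, profile = profile,
                 seed = seed),
            class = "simulated_gene_set")
}

#' @export
print.simulated_gene_set <- function(x, ...) {
  cat(sprintf("simulated gene set: %d genes, %d taxa, %d sites total\n",
              length(x$alignments),
              if (length(x$alignments)) length(x$alignments[[1]]$taxa)
              else 0L,
              sum(vapply(x$alignments, `[[`, 0L, "total_length"))))
  invisible(x)
}

#' Default 18-taxon simulation fixture
#'
#' A deterministic test world mimicking the shape of the yeast problem: an
#' 18-taxon true tree with an outgroup and clades of 7, 4 and 6 species; a
#' backbone with one polytomy inside the pre-WGD clade and one inside the
#' CTG clade (3 x 3 = 9 candidate topologies, containing the true tree);
#' and a heterogeneous gene set simulated on the true tree. Taxon names
#' follow the yeast species for readability; the data are synthetic.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (default 4).
#' @param gene_length_codons gene length in codons (default 1667, i.e.
#'   5001 nt).
#' @param profile optional \code{heterogeneity_profile} overriding the
#'   defaults (its \code{n_genes}/length range are replaced by the above).
#' @return list with \code{true_tree}, \code{backbone},
#'   \code{candidate_trees} (\code{multiPhylo}), \code{true_tree_index},
#'   \code{genes} (a \code{simulated_gene_set}).
#' @export
make_default_fixture <- function(seed = 1L, n_genes = 4L,
                                 gene_length_codons = 1667L,
                                 profile = NULL) {
  backbone <- read_newick_one(paste0(
    "(Yarrowia_lipolytica,",
    "(((((((Saccharomyces_cerevisiae,Saccharomyces_paradoxus),",
    "Saccharomyces_mikatae),Saccharomyces_kudriavzevii),",
    "Saccharomyces_bayanus),(Candida_glabrata,Saccharomyces_castellii)),",
    "((Saccharomyces_kluyveri,Kluyveromyces_waltii),Kluyveromyces_lactis,",
    "Ashbya_gossypii)),",
    "(Pichia_stipitis,((Candida_albicans,Candida_tropicalis),",
    "Lodderomyces_elongisporus),",
    "(Debaryomyces_hansenii,Pichia_guilliermondii))));"))
  cand <- enumerate_resolutions(backbone)
  true_nwk <- paste0(
    "(Yarrowia_lipolytica,",
    "(((((((Saccharomyces_cerevisiae,Saccharomyces_paradoxus),",
    "Saccharomyces_mikatae),Saccharomyces_kudriavzevii),",
    "Saccharomyces_bayanus),(Candida_glabrata,Saccharomyces_castellii)),",
    "(((Saccharomyces_kluyveri,Kluyveromyces_waltii),Kluyveromyces_lactis),",
    "Ashbya_gossypii)),",
    "(Pichia_stipitis,(((Candida_albicans,Candida_tropicalis),",
    "Lodderomyces_elongisporus),",
    "(Debaryomyces_hansenii,Pichia_guilliermondii)))));")
  true_tree <- read_newick_one(true_nwk)
  idx <- which(vapply(cand, function(tr)
    robinson_foulds_normalized(tr, true_tree) == 0, TRUE))
  stopifnot(length(idx) == 1L)  # candidate set contains the true tree once
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  # realistic branch lengths: internal edges shorter, outgroup stem longer
  n <- ape::Ntip(true_tree)
  tt <- true_tree
  nb <- nrow(tt$edge)
  tip_edge <- tt$edge[, 2] <= n
  tt$edge.length <- numeric(nb)
  tt$edge.length[tip_edge] <- stats::runif(sum(tip_edge), 0.08, 0.35)
  tt$edge.length[!tip_edge] <- stats::runif(sum(!tip_edge), 0.02, 0.12)
  og <- which(tt$edge[, 2] == match("Yarrowia_lipolytica", tt$tip.label))
  tt$edge.length[og] <- 0.6
  if (is.null(profile)) profile <- heterogeneity_profile()
  profile$n_genes <- as.integer(n_genes)
  profile$gene_length_range <- c(gene_length_codons, gene_length_codons)
  genes <- simulate_heterogeneous_gene_set(tt, profile,
                                           seed = seed + 1000L)
  list(true_tree = tt, backbone = backbone, candidate_trees = cand,
       true_tree_index = idx, genes = genes)
}

#' Write a simulated gene set to disk
#'
#' Emits per-gene FASTA files, a concatenated PHYLIP supermatrix, a RAxML
#' style partition file, the true tree as Newick and the per-gene truth
#' table as TSV.
#'
#' @param gs a \code{simulated_gene_set}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest (named list of paths).
#' @export
write_gene_set <- function(gs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  mats <- lapply(gs$alignments, alignment_matrix)
  for (nm in names(mats))
    paths[[paste0("fasta_", nm)]] <-
      write_fasta(mats[[nm]], file.path(dir, paste0(nm, ".fasta")))
  super <- do.call(cbind, mats)
  paths$supermatrix <- write_phylip(super, file.path(dir,
                                                     "supermatrix.phy"))
  lens <- vapply(gs$alignments, `[[`, 0L, "total_length")
  ends <- cumsum(lens)
  genes <- data.frame(gene = names(lens), start = ends - lens + 1L,
                      end = ends)
  paths$partitions <- write_partition_file(genes,
                                           file.path(dir,
                                                     "partitions.txt"))
  paths$tree <- write_newick(gs$tree, file.path(dir, "true_tree.nwk"))
  utils::write.table(gs$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  invisible(paths)
}
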