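#' Run configuration files
#'
#' Flat \code{key = value} text files (\code{#} comments allowed). Keys are
#' documented per command; paths are resolved relative to the config file's
#' directory.
#'
#' @param path config file path.
#' @return named list of character values (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  out <- lapply(kv, function(x) trimws(paste(x[-1L], collapse = "=")))
  names(out) <- vapply(kv, function(x) trimws(x[[1L]]), "")
  out$`.dir` <- dirname(normalizePath(path))
  structure(out, class = "run_config")
}

cfg_get <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

cfg_path <- function(config, key, default = NULL, must_exist = TRUE) {
  v <- cfg_get(config, key, default)
  if (is.null(v)) return(NULL)
  if (!startsWith(v, "/") && !is.null(config$`.dir`))
    v <- file.path(config$`.dir`, v)
  if (must_exist && !file.exists(v)) stop("path does not exist: ", v)
  v
}

# "REV", "REV+G", "REV+G+G0".."G4", likewise JC/HKY -> spec list
parse_model_token <- function(tok) {
  parts <- strsplit(toupper(trimws(tok)), "+", fixed = TRUE)[[1L]]
  kind <- match.arg(parts[1L], c("JC", "HKY", "REV"))
  gamma <- "G" %in% parts[-1L]
  gopt <- grep("^G[0-4]$", parts[-1L], value = TRUE)
  policy <- NULL
  if (length(gopt) == 1L) {
    policy <- switch(gopt,
      G0 = sharing_policy(),
      G1 = sharing_policy(separate_frequencies = TRUE),
      G2 = sharing_policy(separate_exchangeabilities = TRUE),
      G3 = sharing_policy(separate_frequencies = TRUE,
                          separate_exchangeabilities = TRUE),
      G4 = sharing_policy(separate_branch_lengths = TRUE))
  } else if (length(gopt) > 1L) stop("at most one Mgene option per model")
  list(label = tok, kind = kind, gamma = gamma, policy = policy)
}

load_genes <- function(config) {
  adir <- cfg_path(config, "alignments_dir", must_exist = FALSE)
  if (!is.null(adir) && dir.exists(adir)) {
    files <- sort(list.files(adir, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no alignments in ", adir)
    genes <- lapply(files, function(f)
      compress_patterns(read_alignment(f),
                        gene = tools::file_path_sans_ext(basename(f))))
    names(genes) <- vapply(files, function(f)
      tools::file_path_sans_ext(basename(f)), "")
    return(genes)
  }
  sm <- cfg_path(config, "supermatrix")
  pf <- cfg_path(config, "partition_file")
  if (is.null(sm) || is.null(pf))
    stop("config must give alignments_dir or supermatrix + partition_file")
  mat <- read_alignment(sm)
  parts <- read_partition_file(pf)
  gene <- character(ncol(mat))
  for (i in seq_len(nrow(parts))) gene[parts$sites[[i]]] <- parts$name[i]
  if (any(gene == "")) stop("partition file does not cover all sites")
  split_genes(compress_patterns(mat, gene = gene))
}

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Pipeline commands
#'
#' The four pipeline stages behind the command-line interface.
#' \code{cmd_simulate} writes a synthetic multigene fixture;
#' \code{cmd_genetrees} runs per-gene analyses (NNI tree search,
#' hierarchical model choice, nonparametric bootstrap, congruence and
#' heterogeneity summaries); \code{cmd_supermatrix} scores a candidate tree
#' set under a ladder of concatenated and gene-partitioned models and
#' annotates the best tree with RELL supports; \code{cmd_report} renders a
#' run directory into a markdown summary.
#'
#' @param config a \code{run_config} (or path to one).
#' @return the output directory, invisibly (a named result list for
#'   \code{cmd_supermatrix}).
#' @name pipeline
NULL

as_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(config) {
  config <- as_config(config)
  out <- cfg_get(config, "out_dir", "sim_out")
  if (!startsWith(out, "/") && !is.null(config$`.dir`))
    out <- file.path(config$`.dir`, out)
  seed <- as.integer(cfg_get(config, "seed", "1"))
  n_genes <- as.integer(cfg_get(config, "n_genes", "4"))
  if (is.na(n_genes) || n_genes < 1L) stop("n_genes must be >= 1")
  glc <- as.integer(cfg_get(config, "gene_length_codons", "1667"))
  fx <- make_default_fixture(seed = seed, n_genes = n_genes,
                             gene_length_codons = glc)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- write_gene_set(fx$genes, out)
  write_newick(fx$backbone, file.path(out, "backbone.nwk"))
  write_newick(fx$candidate_trees, file.path(out, "candidate_trees.nwk"))
  write_manifest(out, list(command = "simulate", seed = seed,
                           n_genes = n_genes,
                           gene_length_codons = glc,
                           true_tree_index = fx$true_tree_index,
                           files = paths))
  invisible(out)
}

#' @rdname pipeline
#' @export
cmd_genetrees <- function(config) {
  config <- as_config(config)
  out <- cfg_get(config, "out_dir", "genetrees_out")
  if (!startsWith(out, "/") && !is.null(config$`.dir`))
    out <- file.path(config$`.dir`, out)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(config, "seed", "1"))
  n_boot <- as.integer(cfg_get(config, "bootstrap_reps", "100"))
  # batch runs default to a looser sweep tolerance (1e-3 nats); per-fit
  # differences at this tolerance are far below any test statistic used
  ctl <- list(tol = as.numeric(cfg_get(config, "tol", "1e-3")))
  genes <- load_genes(config)
  if (length(genes) < 1L) stop("no genes")
  log <- character(0)
  rows <- NULL
  trees <- list()
  fits <- list()
  for (nm in names(genes)) {
    g <- genes[[nm]]
    fit <- nni_hill_climb(g, "REV", gamma = TRUE, seed = seed,
                          control = ctl)
    sel <- hierarchical_gene_model_test(g, fit$tree, control = ctl)
    if (!fit$converged) {
      log <- c(log, sprintf("gene %s: unconverged fit, excluded", nm))
      next
    }
    bs <- nonparametric_bootstrap(g, "REV", TRUE, ml_fit = fit,
                                  n_reps = n_boot, seed = seed,
                                  control = ctl)
    tr <- annotate_supports(fit$tree, bs$support)
    write_newick(tr, file.path(out, paste0(nm, ".nwk")))
    trees[[nm]] <- fit$tree
    fits[[nm]] <- fit
    rows <- rbind(rows, data.frame(
      gene = nm, best_model = sel$best, loglik = fit$loglik,
      R = average_ts_tv_ratio(fit$model), alpha = fit$gamma$alpha,
      gc = gc_content(g), p_jc_hky = sel$p_jc_hky,
      p_hky_rev = sel$p_hky_rev, stringsAsFactors = FALSE))
  }
  utils::write.table(rows, file.path(out, "gene_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cong <- if (length(trees) >= 2L) {
    congruence_summary(trees, n_sims = as.integer(
      cfg_get(config, "null_sims", "1000")), seed = seed)
  } else NULL
  het <- parameter_heterogeneity_summary(fits, genes[names(fits)])
  utils::write.table(cbind(stat = rownames(het$summary), het$summary),
                     file.path(out, "heterogeneity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(log) > 0L) writeLines(log, file.path(out, "excluded.log"))
  write_manifest(out, list(command = "genetrees", seed = seed,
                           bootstrap_reps = n_boot,
                           n_genes = length(genes),
                           n_excluded = length(log),
                           congruence = cong))
  invisible(out)
}

#' @rdname pipeline
#' @export
cmd_supermatrix <- function(config) {
  config <- as_config(config)
  out <- cfg_get(config, "out_dir", "supermatrix_out")
  if (!startsWith(out, "/") && !is.null(config$`.dir`))
    out <- file.path(config$`.dir`, out)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg_get(config, "seed", "1"))
  genes <- load_genes(config)
  ctf <- cfg_path(config, "candidate_trees", must_exist = FALSE)
  if (!is.null(ctf) && file.exists(ctf)) {
    cand <- read_newick(path = ctf)
    if (inherits(cand, "phylo")) cand <- structure(list(cand),
                                                   class = "multiPhylo")
  } else {
    bbf <- cfg_path(config, "backbone")
    cap <- as.numeric(cfg_get(config, "candidate_cap", "1e4"))
    cand <- tryCatch(enumerate_resolutions(read_newick(path = bbf),
                                           cap = cap),
                     error = function(e)
                       stop("candidate set too large (", conditionMessage(e),
                            "); constrain the backbone further"))
  }
  models <- strsplit(cfg_get(config, "models", "REV,REV+G,REV+G+G0"),
                     ",")[[1L]]
  modes <- strsplit(cfg_get(config, "modes", "concat,by-gene"), ",")[[1L]]
  n_rell <- as.integer(cfg_get(config, "rell_samples", "1000"))
  ctl <- list(tol = as.numeric(cfg_get(config, "tol", "1e-3")))
  res <- supermatrix_ladder(cand, genes, models = models, modes = modes,
                            rell_samples = n_rell, seed = seed,
                            control = ctl)
  utils::write.table(res$table, file.path(out, "model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(res$best_tree_annotated, file.path(out, "ml_tree.nwk"))
  write_manifest(out, list(command = "supermatrix", seed = seed,
                           n_candidates = length(cand),
                           models = models, modes = modes,
                           best_model = res$best_label,
                           best_tree_index = res$best_tree_index))
  invisible(res)
}

#' Score a candidate tree set under a ladder of supermatrix models
#'
#' Every (model, mode) cell is scored exhaustively over the candidate set:
#' concatenated cells fit one parameter set to all sites; by-gene cells sum
#' independent per-gene maxima. The best cell by per-partition AICc is
#' bootstrapped by RELL.
#'
#' @param cand \code{multiPhylo} candidate set.
#' @param genes named list of \code{pattern_alignment}s.
#' @param models character vector of model tokens (e.g. \code{"REV+G"},
#'   \code{"REV+G+G0"}).
#' @param modes subset of \code{c("concat", "by-gene")}.
#' @param rell_samples RELL replicates for the winning cell.
#' @param seed integer seed (RELL).
#' @param control optimizer control.
#' @return list with \code{table} (model-comparison data.frame),
#'   \code{best_label}, \code{best_tree_index}, \code{best_tree_annotated},
#'   \code{rell}, \code{cells} (per-cell fit summaries).
#' @export
supermatrix_ladder <- function(cand, genes, models = c("REV", "REV+G"),
                               modes = c("concat", "by-gene"),
                               rell_samples = 1000, seed = 1L,
                               control = list()) {
  if (inherits(cand, "phylo")) cand <- structure(list(cand),
                                                 class = "multiPhylo")
  super <- concatenate_alignments(genes)
  n_taxa <- length(super$taxa)
  nsites <- vapply(genes, `[[`, 0L, "total_length")
  rows <- list()
  cells <- list()
  for (mode in modes) {
    for (tok in models) {
      sp <- parse_model_token(tok)
      if (mode == "concat") {
        lls <- numeric(length(cand))
        sll <- matrix(NA_real_, length(cand), super$total_length)
        warm <- NULL
        for (ti in seq_along(cand)) {
          ctl <- control
          if (!is.null(warm) && is.null(sp$policy))
            ctl$init <- list(model = warm$model, gamma = warm$gamma)
          fit <- if (is.null(sp$policy)) {
            optimize_fit(cand[[ti]], super, sp$kind, sp$gamma,
                         control = ctl)
          } else {
            fit_codon_partitioned(cand[[ti]], super, sp$kind, sp$gamma,
                                  policy = sp$policy, control = ctl)
          }
          if (is.null(sp$policy)) warm <- fit
          lls[ti] <- fit$loglik
          sll[ti, ] <- if (is.null(sp$policy))
            per_site_log_likelihoods(fit, super)
          else per_site_log_likelihoods_part(fit, super)
        }
        best <- which.max(lls)
        K <- if (is.null(sp$policy)) {
          count_free_parameters(sp$kind, sp$gamma, n_taxa)$K
        } else {
          count_free_parameters(sp$kind, sp$gamma, n_taxa,
            scheme = structure(list(mode = "by_codon_position",
                                    partitions = list()),
                               class = "partition_scheme"),
            policy = sp$policy)$K
        }
        cell <- list(label = tok, mode = "concatenated", ml_tree = best,
                     loglik = lls[best],
                     K_i = stats::setNames(K, "all"),
                     n_i = stats::setNames(super$total_length, "all"),
                     site_loglik = sll, total_loglik = lls)
      } else {
        gf <- fit_gene_partitioned(cand, genes, sp$kind, sp$gamma,
                                   codon_policy = sp$policy,
                                   control = control)
        cell <- list(label = tok, mode = "partitioned",
                     ml_tree = gf$best_tree,
                     loglik = gf$total_loglik[gf$best_tree],
                     K_i = gf$K_i, n_i = gf$n_i,
                     site_loglik = gf$site_loglik,
                     total_loglik = gf$total_loglik)
      }
      # LRT against the previous (nested) ladder entry within this mode
      prev <- Filter(function(r) r$mode == cell$mode, cells)
      if (length(prev) > 0L) cell$lrt_vs <- prev[[length(prev)]]$label
      cells[[paste(mode, tok)]] <- cell
      rows[[paste(mode, tok)]] <- cell
    }
  }
  tab <- model_comparison_table(rows)
  besti <- which.min(tab$AICc)
  best_cell <- cells[[besti]]
  rell <- rell_bootstrap(best_cell$site_loglik, n_samples = rell_samples,
                         seed = seed, trees = cand)
  best_tree <- cand[[best_cell$ml_tree]]
  annotated <- annotate_supports(best_tree, rell$bipartition_support)
  list(table = tab, best_label = paste(best_cell$mode, best_cell$label),
       best_tree_index = best_cell$ml_tree,
       best_tree_annotated = annotated, rell = rell, cells = cells)
}

#' Annotate bootstrap supports onto a tree
#'
#' Sets \code{node.label} to the support (percent, rounded to 1 decimal) of
#' each internal node's bipartition, matched by canonical bipartition
#' string.
#'
#' @param tree \code{phylo}.
#' @param support named numeric vector (names are canonical bipartition
#'   strings as produced internally, values in \code{[0, 1]}).
#' @return \code{phylo} with node labels.
#' @export
annotate_supports <- function(tree, support) {
  n <- ape::Ntip(tree)
  labs <- character(tree$Nnode)
  all_labs <- tree$tip.label
  ref <- sort(all_labs)[1L]
  for (nd in seq_len(tree$Nnode)) {
    node <- n + nd
    tips <- tip_set(tree, node)
    if (length(tips) <= 1L || length(tips) >= n - 1L) {
      labs[nd] <- ""
      next
    }
    side <- if (ref %in% tips) setdiff(all_labs, tips) else tips
    key <- paste(sort(side), collapse = "|")
    labs[nd] <- if (!is.null(support) && key %in% names(support))
      sprintf("%.1f", 100 * support[[key]]) else ""
  }
  tree$node.label <- labs
  tree
}

tip_set <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_set, tree = tree))
}

#' @rdname pipeline
#' @param run_dir directory written by a pipeline command (must contain
#'   \code{manifest.json}).
#' @export
cmd_report <- function(run_dir) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  manifest <- jsonlite::read_json(mf)
  lines <- c(sprintf("# Run report: %s", manifest$command),
             "",
             sprintf("- seed: %s", manifest$seed))
  for (k in setdiff(names(manifest), c("command", "seed", "files")))
    if (!is.list(manifest[[k]]))
      lines <- c(lines, sprintf("- %s: %s", k, manifest[[k]]))
  for (f in list.files(run_dir, pattern = "\\.tsv$")) {
    tab <- utils::read.table(file.path(run_dir, f), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    lines <- c(lines, "", sprintf("## %s", f), "",
               paste("|", paste(names(tab), collapse = " | "), "|"),
               paste("|", paste(rep("---", ncol(tab)), collapse = " | "),
                     "|"))
    for (i in seq_len(nrow(tab)))
      lines <- c(lines, paste("|", paste(
        vapply(tab[i, ], function(x)
          if (is.numeric(x)) format(x, digits = 6) else as.character(x),
          ""), collapse = " | "), "|"))
  }
  writeLines(lines, file.path(run_dir, "report.md"))
  invisible(file.path(run_dir, "report.md"))
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{genetrees}, \code{supermatrix},
#' \code{congruence}, \code{report}. All take \code{--config FILE} (a flat
#' key = value file); \code{report} takes \code{--dir DIR}. Typical use:
#' \preformatted{Rscript -e 'phylopart::run_cli()' simulate --config sim.cfg}
#'
#' @param args command-line arguments (default: from the calling Rscript).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    cat("usage: phylopart <simulate|genetrees|supermatrix|congruence|report> [--config FILE | --dir DIR]\n")
    return(invisible(1L))
  }
  sub <- args[1L]
  rest <- args[-1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--dir", type = "character", default = NULL)))
  opts <- optparse::parse_args(parser, args = rest)
  switch(sub,
    simulate = cmd_simulate(opts$config),
    genetrees = cmd_genetrees(opts$config),
    supermatrix = cmd_supermatrix(opts$config),
    congruence = {
      config <- read_run_config(opts$config)
      trees <- read_newick(path = cfg_path(config, "gene_trees"))
      print(congruence_summary(trees,
        n_sims = as.integer(cfg_get(config, "null_sims", "1000")),
        seed = as.integer(cfg_get(config, "seed", "1"))))
    },
    report = cmd_report(opts$dir),
    stop("unknown subcommand: ", sub))
  invisible(0L)
}
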