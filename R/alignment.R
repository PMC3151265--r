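#' Site-pattern compressed alignments
#'
#' A \code{pattern_alignment} stores a nucleotide alignment as its distinct
#' site patterns with multiplicities, plus per-site labels (gene id and codon
#' position) so that the original site order can always be reconstructed.
#' Gaps, \code{N} and \code{?} are treated as fully ambiguous characters
#' (marginalized over all four states); IUPAC ambiguity codes are honored.
#'
#' @name pattern_alignment
NULL

# IUPAC nucleotide -> bitmask over (A=1, C=2, G=4, T=8)
NUC_CODE <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
              R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
              B = 14L, D = 13L, H = 11L, V = 7L,
              N = 15L, `-` = 15L, `?` = 15L, `.` = 15L)

encode_nucleotides <- function(x) {
  codes <- NUC_CODE[toupper(x)]
  if (anyNA(codes))
    stop("invalid nucleotide character(s): ",
         paste(unique(x[is.na(codes)]), collapse = " "))
  codes
}

#' Compress an alignment into site patterns
#'
#' @param mat character matrix, taxa in rows (rownames are taxon labels),
#'   sites in columns.
#' @param gene optional per-site gene label (length = number of sites, or a
#'   single value recycled).
#' @param codon_position optional per-site codon position in \code{1:3}; if
#'   \code{NULL}, positions are assigned cyclically 1,2,3 within each gene.
#' @return A \code{pattern_alignment}: list with \code{taxa},
#'   \code{patterns} (integer bitmask matrix, taxa x patterns),
#'   \code{weights}, \code{site_pattern} (pattern index per original site),
#'   \code{site_labels} (data.frame gene, codon_position) and
#'   \code{total_length}.
#' @export
compress_patterns <- function(mat, gene = NULL, codon_position = NULL) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("alignment needs at least two sequences")
  if (ncol(mat) < 1L) stop("alignment of length 0")
  taxa <- rownames(mat)
  if (is.null(taxa) || any(taxa == "")) stop("sequences must be named")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  n <- ncol(mat)
  codes <- matrix(encode_nucleotides(mat), nrow(mat), n)
  if (is.null(gene)) gene <- "g1"
  gene <- rep_len(as.character(gene), n)
  if (is.null(codon_position)) {
    codon_position <- integer(n)
    for (g in unique(gene)) {
      idx <- which(gene == g)
      codon_position[idx] <- ((seq_along(idx) - 1L) %% 3L) + 1L
    }
  } else {
    codon_position <- rep_len(as.integer(codon_position), n)
    if (any(!codon_position %in% 1:3)) stop("codon positions must be 1..3")
  }
  key <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  site_pattern <- match(key, key[first])
  patterns <- codes[, first, drop = FALSE]
  weights <- as.numeric(tabulate(site_pattern, nbins = sum(first)))
  structure(list(taxa = taxa, patterns = patterns, weights = weights,
                 site_pattern = site_pattern,
                 site_labels = data.frame(gene = gene,
                                          codon_position = codon_position,
                                          stringsAsFactors = FALSE),
                 total_length = n),
            class = "pattern_alignment")
}

is_pattern_alignment <- function(x) inherits(x, "pattern_alignment")

#' @export
print.pattern_alignment <- function(x, ...) {
  cat(sprintf("pattern alignment: %d taxa, %d sites, %d patterns, %d gene(s)\n",
              length(x$taxa), x$total_length, ncol(x$patterns),
              length(unique(x$site_labels$gene))))
  invisible(x)
}

DECODE <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T",
            `5` = "R", `10` = "Y", `6` = "S", `9` = "W", `12` = "K",
            `3` = "M", `14` = "B", `13` = "D", `11` = "H", `7` = "V",
            `15` = "N")

#' Reconstruct the character matrix of a pattern alignment
#'
#' Inverse of \code{\link{compress_patterns}} (ambiguity codes other than the
#' IUPAC set collapse to their IUPAC representative; gaps decode as N).
#' @param pa a \code{pattern_alignment}.
#' @return character matrix taxa x sites.
#' @export
alignment_matrix <- function(pa) {
  stopifnot(is_pattern_alignment(pa))
  full <- pa$patterns[, pa$site_pattern, drop = FALSE]
  out <- matrix(DECODE[as.character(full)], nrow(full), ncol(full))
  rownames(out) <- pa$taxa
  out
}

#' Extract a subset of sites as a new pattern alignment
#'
#' @param pa a \code{pattern_alignment}.
#' @param sites integer site indices (duplicates allowed, e.g. bootstrap
#'   resampling).
#' @return a \code{pattern_alignment} over the selected sites, in the given
#'   order.
#' @export
subset_sites <- function(pa, sites) {
  stopifnot(is_pattern_alignment(pa))
  if (length(sites) < 1L) stop("empty site selection")
  if (any(sites < 1L | sites > pa$total_length)) stop("site index out of range")
  pat <- pa$site_pattern[sites]
  upat <- sort(unique(pat))
  structure(list(taxa = pa$taxa,
                 patterns = pa$patterns[, upat, drop = FALSE],
                 weights = as.numeric(tabulate(match(pat, upat),
                                               nbins = length(upat))),
                 site_pattern = match(pat, upat),
                 site_labels = pa$site_labels[sites, , drop = FALSE],
                 total_length = length(sites)),
            class = "pattern_alignment")
}

#' Concatenate gene alignments into a supermatrix
#'
#' @param alignments named list of \code{pattern_alignment}s over the same
#'   taxon set (names become gene ids; existing per-gene labels are replaced
#'   unless \code{keep_labels = TRUE}).
#' @param keep_labels keep each alignment's own gene labels.
#' @return a \code{pattern_alignment} spanning all sites.
#' @export
concatenate_alignments <- function(alignments, keep_labels = FALSE) {
  stopifnot(length(alignments) >= 1L)
  taxa <- alignments[[1L]]$taxa
  for (a in alignments)
    if (!setequal(a$taxa, taxa)) stop("taxon sets differ between genes")
  nm <- names(alignments)
  if (is.null(nm)) nm <- paste0("g", seq_along(alignments))
  mats <- vector("list", length(alignments))
  genes <- character(0)
  cpos <- integer(0)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    m <- a$patterns[match(taxa, a$taxa), a$site_pattern, drop = FALSE]
    mats[[i]] <- m
    genes <- c(genes, if (keep_labels) a$site_labels$gene
               else rep(nm[i], a$total_length))
    cpos <- c(cpos, a$site_labels$codon_position)
  }
  codes <- do.call(cbind, mats)
  key <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  site_pattern <- match(key, key[first])
  structure(list(taxa = taxa,
                 patterns = codes[, first, drop = FALSE],
                 weights = as.numeric(tabulate(site_pattern,
                                               nbins = sum(first))),
                 site_pattern = site_pattern,
                 site_labels = data.frame(gene = genes, codon_position = cpos,
                                          stringsAsFactors = FALSE),
                 total_length = length(genes)),
            class = "pattern_alignment")
}

#' Split a supermatrix into per-gene alignments
#' @param pa a \code{pattern_alignment}.
#' @return named list of \code{pattern_alignment}s, one per gene, in order of
#'   first appearance.
#' @export
split_genes <- function(pa) {
  stopifnot(is_pattern_alignment(pa))
  genes <- unique(pa$site_labels$gene)
  out <- lapply(genes, function(g)
    subset_sites(pa, which(pa$site_labels$gene == g)))
  names(out) <- genes
  out
}

#' Empirical base frequencies and GC content
#'
#' Counts unambiguous characters only.
#' @param pa a \code{pattern_alignment}.
#' @return \code{base_frequencies}: probability 4-vector (A, C, G, T);
#'   \code{gc_content}: scalar in \code{[0, 1]}.
#' @export
base_frequencies <- function(pa) {
  stopifnot(is_pattern_alignment(pa))
  counts <- numeric(4)
  w <- pa$weights
  for (s in 1:4) {
    bit <- bitwShiftL(1L, s - 1L)
    pure <- pa$patterns == bit
    counts[s] <- sum(w[col(pa$patterns)[pure]])
  }
  if (sum(counts) == 0) return(rep(0.25, 4))
  stats::setNames(counts / sum(counts), NUC_STATES)
}

#' @rdname base_frequencies
#' @export
gc_content <- function(pa) {
  f <- base_frequencies(pa)
  unname(f["G"] + f["C"])
}

# ---- file I/O ---------------------------------------------------------------

#' Read and write nucleotide alignments
#'
#' FASTA and PHYLIP (sequential or interleaved, relaxed names) are supported,
#' via \code{ape::read.dna}. \code{read_alignment} returns a plain character
#' matrix; pass it to \code{\link{compress_patterns}}.
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"fasta"}, \code{"phylip"}.
#' @return character matrix taxa x sites, uppercase.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  } else {
    d <- tryCatch(
      ape::read.dna(path, format = "sequential", as.character = TRUE,
                    as.matrix = TRUE),
      error = function(e)
        ape::read.dna(path, format = "interleaved", as.character = TRUE,
                      as.matrix = TRUE))
  }
  toupper(d)
}

#' @rdname read_alignment
#' @param mat character matrix taxa x sites.
#' @export
write_fasta <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(mat))) {
    writeLines(paste0(">", rownames(mat)[i]), con)
    writeLines(paste(mat[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' @rdname read_alignment
#' @export
write_phylip <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste0(rownames(mat)[i], "  ",
                      paste(mat[i, ], collapse = "")), con)
  invisible(path)
}

# ---- partition files --------------------------------------------------------

#' Read and write partition definition files
#'
#' Two dialects: RAxML-style lines \code{"DNA, name = start-end[\\3]"}
#' (comma-separated ranges allowed; the \code{\\3} suffix expands a range
#' into every-third-site strides for codon positions) and a native
#' tab-separated table with columns \code{gene}, \code{start}, \code{end},
#' \code{frame}. Coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @return data.frame with columns \code{name} and \code{sites}
#'   (list-column of integer site indices).
#' @export
read_partition_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty partition file")
  if (!grepl("=", lines[1L], fixed = TRUE)) {
    # native TSV: gene start end frame
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene", "start", "end", "frame")
    if (!all(need %in% names(tab)))
      stop("native partition table needs columns: ",
           paste(need, collapse = ", "))
    out <- data.frame(name = paste0(tab$gene, "_pos", tab$frame),
                      stringsAsFactors = FALSE)
    out$sites <- lapply(seq_len(nrow(tab)), function(i)
      seq.int(tab$start[i] + (tab$frame[i] - 1L), tab$end[i], by = 3L))
    return(out)
  }
  parse_one <- function(line) {
    parts <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed partition line: ", line)
    lhs <- strsplit(parts[1L], ",")[[1L]]
    name <- trimws(lhs[length(lhs)])
    sites <- integer(0)
    for (rng in strsplit(parts[2L], ",")[[1L]]) {
      rng <- trimws(rng)
      stride <- 1L
      if (grepl("\\\\3$", rng)) {
        stride <- 3L
        rng <- sub("\\\\3$", "", rng)
      }
      ab <- as.integer(strsplit(rng, "-", fixed = TRUE)[[1L]])
      if (length(ab) == 1L) ab <- c(ab, ab)
      if (anyNA(ab) || ab[2L] < ab[1L])
        stop("malformed range in partition line: ", line)
      sites <- c(sites, seq.int(ab[1L], ab[2L], by = stride))
    }
    list(name = name, sites = sites)
  }
  parsed <- lapply(lines, parse_one)
  out <- data.frame(name = vapply(parsed, `[[`, "", "name"),
                    stringsAsFactors = FALSE)
  out$sites <- lapply(parsed, `[[`, "sites")
  all_sites <- unlist(out$sites)
  if (anyDuplicated(all_sites)) stop("partitions overlap")
  out
}

#' @rdname read_partition_file
#' @param genes data.frame with columns \code{gene}, \code{start}, \code{end}
#'   (1-based inclusive, length divisible by 3 if \code{by_codon}).
#' @param by_codon write three codon-position partitions per gene.
#' @export
write_partition_file <- function(genes, path, by_codon = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genes))) {
    if (by_codon) {
      for (k in 1:3)
        writeLines(sprintf("DNA, %s_pos%d = %d-%d\\3", genes$gene[i], k,
                           genes$start[i] + k - 1L, genes$end[i]), con)
    } else {
      writeLines(sprintf("DNA, %s = %d-%d", genes$gene[i], genes$start[i],
                         genes$end[i]), con)
    }
  }
  invisible(path)
}
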