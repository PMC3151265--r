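#' Nucleotide substitution models
#'
#' Constructors for time-reversible nucleotide substitution models. Three
#' nested parameterizations are supported:
#' \describe{
#'   \item{JC}{equal base frequencies, a single substitution rate.}
#'   \item{HKY}{free base frequencies plus a transition/transversion rate
#'     ratio \eqn{\kappa}.}
#'   \item{REV}{(general time reversible, GTR) free base frequencies plus one
#'     exchangeability parameter per unordered nucleotide pair, the last
#'     (G-T) fixed to 1 as the identifiability reference.}
#' }
#' States are ordered A, C, G, T throughout. Exchangeabilities are ordered
#' (AC, AG, AT, CG, CT, GT).
#'
#' @param frequencies probability 4-vector (A, C, G, T); must sum to 1.
#' @param kappa positive transition/transversion rate ratio (HKY).
#' @param exchangeabilities nonnegative 6-vector (AC, AG, AT, CG, CT, GT).
#' @return An object of class \code{nucleotide_model} with fields
#'   \code{kind}, \code{frequencies}, \code{exchangeabilities} and, for HKY,
#'   \code{kappa}.
#' @examples
#' m <- hky_model(c(0.3, 0.2, 0.2, 0.3), kappa = 2)
#' average_ts_tv_ratio(m)
#' @name nucleotide_model
NULL

NUC_STATES <- c("A", "C", "G", "T")
EXCH_PAIRS <- c("AC", "AG", "AT", "CG", "CT", "GT")
# indices of the two transition pairs within the exchangeability vector
TS_IDX <- c(2L, 5L)
TV_IDX <- c(1L, 3L, 4L, 6L)

new_nucleotide_model <- function(kind, frequencies, exchangeabilities,
                                 kappa = NULL) {
  frequencies <- as.numeric(frequencies)
  exchangeabilities <- as.numeric(exchangeabilities)
  if (length(frequencies) != 4L)
    stop("frequencies must have length 4 (A, C, G, T)")
  if (length(exchangeabilities) != 6L)
    stop("exchangeabilities must have length 6 (AC, AG, AT, CG, CT, GT)")
  if (any(!is.finite(frequencies)) || any(frequencies < 0))
    stop("frequencies must be finite and nonnegative")
  if (any(frequencies < 1e-8))
    stop("frequencies below 1e-8 are rejected (degenerate state)")
  if (abs(sum(frequencies) - 1) > 1e-12)
    stop("frequencies must sum to 1 (within 1e-12)")
  if (any(!is.finite(exchangeabilities)) || any(exchangeabilities < 0))
    stop("exchangeabilities must be finite and nonnegative")
  names(frequencies) <- NUC_STATES
  names(exchangeabilities) <- EXCH_PAIRS
  structure(
    list(kind = kind, frequencies = frequencies,
         exchangeabilities = exchangeabilities, kappa = kappa),
    class = "nucleotide_model")
}

#' @rdname nucleotide_model
#' @export
jc_model <- function() {
  new_nucleotide_model("JC", rep(0.25, 4), rep(1, 6))
}

#' @rdname nucleotide_model
#' @export
hky_model <- function(frequencies = rep(0.25, 4), kappa = 2) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  ex <- rep(1, 6)
  ex[TS_IDX] <- kappa
  new_nucleotide_model("HKY", frequencies, ex, kappa = kappa)
}

#' @rdname nucleotide_model
#' @export
rev_model <- function(frequencies = rep(0.25, 4),
                      exchangeabilities = rep(1, 6)) {
  new_nucleotide_model("REV", frequencies, exchangeabilities)
}

#' @export
print.nucleotide_model <- function(x, ...) {
  cat(sprintf("%s nucleotide model\n", x$kind))
  cat("  frequencies:", paste(sprintf("%s=%.4f", NUC_STATES, x$frequencies),
                              collapse = " "), "\n")
  if (x$kind != "JC")
    cat("  exchangeabilities:",
        paste(sprintf("%s=%.4f", EXCH_PAIRS, x$exchangeabilities),
              collapse = " "), "\n")
  invisible(x)
}

is_nucleotide_model <- function(x) inherits(x, "nucleotide_model")

#' Build the calibrated rate matrix of a reversible model
#'
#' Assembles the 4x4 generator \eqn{Q} with off-diagonal entries
#' \eqn{q_{ij} = s\, r_{ij} \pi_j}, diagonal entries set so rows sum to zero,
#' and the global scale \eqn{s} chosen so that the expected number of
#' substitutions per site per unit time, \eqn{-\sum_i \pi_i q_{ii}}, equals 1.
#' Branch lengths are therefore in expected substitutions per site.
#'
#' @param model a \code{nucleotide_model}.
#' @return 4x4 matrix with row/column names A, C, G, T.
#' @export
build_generator <- function(model) {
  stopifnot(is_nucleotide_model(model))
  pi <- model$frequencies
  r <- model$exchangeabilities
  if (all(r == 0)) stop("all exchangeabilities zero: degenerate process")
  R <- matrix(0, 4, 4, dimnames = list(NUC_STATES, NUC_STATES))
  k <- 1L
  for (i in 1:3) for (j in (i + 1):4) {
    R[i, j] <- R[j, i] <- r[k]
    k <- k + 1L
  }
  # a zero-frequency target with nonzero exchangeability is an absorbing defect
  for (i in 1:4) for (j in 1:4) {
    if (i != j && pi[j] == 0 && R[i, j] > 0)
      stop("zero frequency for state ", NUC_STATES[j],
           " with nonzero exchangeability into it")
  }
  Q <- R %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate process: zero total substitution rate")
  Q <- Q / mu
  dimnames(Q) <- list(NUC_STATES, NUC_STATES)
  Q
}

# Spectral decomposition of a reversible generator via the symmetrized form
# B = D^{1/2} Q D^{-1/2} (D = diag(pi)), which is symmetric and therefore has
# real eigenvalues. Returns values and the (non-orthogonal) right/left
# eigenvector matrices of Q itself.
decompose_generator <- function(Q, frequencies) {
  sp <- sqrt(frequencies)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  V <- diag(1 / sp) %*% e$vectors      # right eigenvectors of Q
  Vinv <- t(e$vectors) %*% diag(sp)    # inverse
  list(values = e$values, V = V, Vinv = Vinv)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by spectral decomposition of the reversible generator.
#'
#' @param Q generator from \code{\link{build_generator}}.
#' @param t branch length (expected substitutions per site), \eqn{\ge 0}.
#' @param frequencies optionally, the stationary frequencies of \code{Q}
#'   (recovered from the generator if omitted).
#' @return 4x4 stochastic matrix.
#' @export
transition_probabilities <- function(Q, t, frequencies = NULL) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("branch length t must be a single finite nonnegative number")
  if (is.null(frequencies)) frequencies <- stationary_frequencies(Q)
  d <- decompose_generator(Q, frequencies)
  P <- d$V %*% diag(exp(d$values * t)) %*% d$Vinv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# stationary distribution of a calibrated generator (left null vector)
stationary_frequencies <- function(Q) {
  ns <- eigen(t(Q))
  i <- which.min(abs(ns$values))
  v <- Re(ns$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("generator has no valid stationary distribution")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Discrete-gamma model of among-site rate variation
#'
#' Discretizes a gamma(\eqn{\alpha}, \eqn{\alpha}) distribution (mean 1) into
#' \code{K} equal-probability categories. Each category rate is the
#' conditional mean of the density on its quantile interval, computed via the
#' standard incomplete-gamma identity, then renormalized so the weighted mean
#' is exactly 1.
#'
#' @param alpha positive shape parameter.
#' @param K number of categories (default 6).
#' @return An object of class \code{gamma_rates} with fields \code{alpha},
#'   \code{n_categories}, \code{category_rates}, \code{category_probs}.
#' @export
discretize_gamma <- function(alpha, K = 6) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  if (K == 1L) {
    rates <- 1
  } else {
    q <- stats::qgamma(seq_len(K - 1) / K, shape = alpha, rate = alpha)
    # E[X | a < X < b] * P(a < X < b) = F(b; alpha+1) - F(a; alpha+1)
    cdf1 <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
    rates <- diff(cdf1) * K
  }
  probs <- rep(1 / K, K)
  rates <- rates / sum(rates * probs)  # exact mean-1 renormalization
  structure(list(alpha = alpha, n_categories = K,
                 category_rates = rates, category_probs = probs),
            class = "gamma_rates")
}

is_gamma_rates <- function(x) inherits(x, "gamma_rates")

#' @export
print.gamma_rates <- function(x, ...) {
  cat(sprintf("discrete gamma: alpha = %.4g, %d categories\n",
              x$alpha, x$n_categories))
  cat("  rates:", paste(sprintf("%.4f", x$category_rates), collapse = " "),
      "\n")
  invisible(x)
}

#' Average transition/transversion ratio R
#'
#' The stationary-flux ratio of transition to transversion substitutions,
#' \deqn{R = \frac{\pi_A \pi_G r_{AG} + \pi_C \pi_T r_{CT}}
#'            {\pi_A \pi_C r_{AC} + \pi_A \pi_T r_{AT} +
#'             \pi_C \pi_G r_{CG} + \pi_G \pi_T r_{GT}}.}
#' Invariant to rescaling all exchangeabilities by a common factor. Equals
#' 0.5 for JC and \eqn{\kappa/2} for HKY with equal frequencies.
#'
#' @param model a \code{nucleotide_model}.
#' @return dimensionless scalar R.
#' @export
average_ts_tv_ratio <- function(model) {
  stopifnot(is_nucleotide_model(model))
  pi <- model$frequencies
  r <- model$exchangeabilities
  num <- pi["A"] * pi["G"] * r["AG"] + pi["C"] * pi["T"] * r["CT"]
  den <- pi["A"] * pi["C"] * r["AC"] + pi["A"] * pi["T"] * r["AT"] +
    pi["C"] * pi["G"] * r["CG"] + pi["G"] * pi["T"] * r["GT"]
  if (den <= 0) stop("degenerate model: no transversion flux")
  unname(num / den)
}

#' Serialize / deserialize a model specification
#'
#' Flat key-value representation used by the run configuration and manifest
#' files.
#'
#' @param model a \code{nucleotide_model}.
#' @param gamma optional \code{gamma_rates}.
#' @return named character vector (\code{model_config}); or a list with
#'   elements \code{model} and \code{gamma} (\code{parse_model_config}).
#' @export
model_config <- function(model, gamma = NULL) {
  out <- c(kind = model$kind,
           frequencies = paste(format(model$frequencies, digits = 12),
                               collapse = ","),
           exchangeabilities = paste(format(model$exchangeabilities,
                                            digits = 12), collapse = ","))
  if (!is.null(model$kappa)) out["kappa"] <- format(model$kappa, digits = 12)
  if (!is.null(gamma)) {
    out["alpha"] <- format(gamma$alpha, digits = 12)
    out["n_categories"] <- as.character(gamma$n_categories)
  }
  out
}

#' @rdname model_config
#' @param config named character vector as produced by \code{model_config}.
#' @export
parse_model_config <- function(config) {
  kind <- config[["kind"]]
  fr <- as.numeric(strsplit(config[["frequencies"]], ",")[[1]])
  ex <- as.numeric(strsplit(config[["exchangeabilities"]], ",")[[1]])
  model <- switch(kind,
    JC = jc_model(),
    HKY = hky_model(fr, kappa = as.numeric(config[["kappa"]])),
    REV = rev_model(fr, ex),
    stop("unknown model kind: ", kind))
  gamma <- NULL
  if ("alpha" %in% names(config))
    gamma <- discretize_gamma(as.numeric(config[["alpha"]]),
                              as.integer(config[["n_categories"]]))
  list(model = model, gamma = gamma)
}
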