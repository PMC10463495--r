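# Substitution model layer: exchangeabilities + frequencies -> reversible
# generator Q (rescaled to unit expected rate), discrete-gamma rate
# categories, and transition probabilities via eigendecomposition of the
# reversibility-symmetrised generator.

#' Discrete-gamma rate categories
#'
#' Discretises a gamma(shape = alpha, rate = alpha) distribution (mean 1)
#' into `k` equal-probability categories, each represented by the mean of the
#' distribution over its quantile bin.  Mean-of-bin (rather than median)
#' discretisation keeps the average rate exactly 1, so branch lengths retain
#' their expected-substitutions-per-site meaning without renormalisation.
#'
#' @param alpha Gamma shape parameter (> 0); small values mean strong
#'   among-site rate variation.
#' @param k Number of categories (>= 1), conventionally 4.
#' @return Ascending numeric vector of `k` rates with mean 1.
#' @export
#' @examples
#' discrete_gamma_rates(0.5, 4)
discrete_gamma_rates <- function(alpha, k = 4) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    stop("domain error: alpha must be a positive number", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1) stop("domain error: k must be >= 1", call. = FALSE)
  if (k == 1) return(1)
  # Mean of gamma(a, a) over [q_{i-1}, q_i] with mass 1/k each equals
  # k * (F_{a+1}(q_i) - F_{a+1}(q_{i-1})) where F_{a+1} is the cdf of
  # gamma(a + 1, a) -- the standard incomplete-gamma identity.
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  cdf <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  rates <- k * diff(cdf)
  sort(rates)
}

#' Construct an amino-acid substitution model
#'
#' Bundles exchangeabilities, stationary frequencies, and discrete-gamma rate
#' heterogeneity into a single object used by the likelihood engine and the
#' simulator.
#'
#' @param exchangeabilities `"JTT"` (default) or a symmetric non-negative
#'   square matrix (diagonal ignored).
#' @param freqs `"model"` for the frequencies published with the matrix,
#'   `"empirical"` to count them from `aln` (+F), or a numeric probability
#'   vector.
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param k Number of discrete gamma categories (default 4).
#' @param aln Alignment used when `freqs = "empirical"`.
#' @return A `ccs_model` with elements `exchangeabilities`, `freqs`, `alpha`,
#'   `k`, `category_rates`.
#' @export
#' @examples
#' m <- ccs_model(alpha = 0.5)
#' m$category_rates
ccs_model <- function(exchangeabilities = "JTT", freqs = "model",
                      alpha = 1, k = 4, aln = NULL) {
  if (is.character(exchangeabilities)) {
    exchangeabilities <- match.arg(exchangeabilities, "JTT")
    s <- jtt_exchangeabilities()
    model_freqs <- jtt_frequencies()
  } else {
    s <- as.matrix(exchangeabilities)
    if (nrow(s) != ncol(s) || any(abs(s - t(s)) > 1e-12) || any(s < 0)) {
      stop("exchangeabilities must be a symmetric non-negative square matrix",
           call. = FALSE)
    }
    diag(s) <- 0
    model_freqs <- rep(1 / nrow(s), nrow(s))
  }
  if (is.character(freqs)) {
    freqs <- match.arg(freqs, c("model", "empirical"))
    if (freqs == "empirical") {
      if (is.null(aln)) stop("freqs = \"empirical\" requires an alignment", call. = FALSE)
      freqs <- empirical_freqs(aln)
    } else {
      freqs <- model_freqs
    }
  }
  freqs <- as.numeric(freqs)
  if (length(freqs) != nrow(s)) stop("freqs length does not match the matrix", call. = FALSE)
  if (any(freqs <= 0)) stop("degenerate stationary distribution: zero frequency", call. = FALSE)
  freqs <- freqs / sum(freqs)
  structure(list(
    exchangeabilities = s,
    freqs = freqs,
    alpha = alpha,
    k = as.integer(k),
    category_rates = discrete_gamma_rates(alpha, k)
  ), class = "ccs_model")
}

#' @export
print.ccs_model <- function(x, ...) {
  cat("<ccs_model> ", nrow(x$exchangeabilities), " states, alpha = ",
      signif(x$alpha, 4), ", ", x$k, " gamma categories\n", sep = "")
  invisible(x)
}

#' Update model parameters
#' @param model A `ccs_model`.
#' @param alpha,freqs Replacement values (either may be `NULL` to keep).
#' @return The updated `ccs_model`.
#' @export
update_model <- function(model, alpha = NULL, freqs = NULL) {
  if (!is.null(alpha)) {
    model$alpha <- alpha
    model$category_rates <- discrete_gamma_rates(alpha, model$k)
  }
  if (!is.null(freqs)) {
    freqs <- as.numeric(freqs)
    if (any(freqs <= 0)) stop("degenerate stationary distribution: zero frequency", call. = FALSE)
    model$freqs <- freqs / sum(freqs)
  }
  model
}

#' Empirical (+F) residue frequencies
#'
#' Counts residues over all non-missing cells of the alignment.  If any of
#' the 20 residues is absent, a pseudocount of one observation per residue is
#' added so the stationary distribution stays strictly positive.
#'
#' @param aln An `aa_alignment`.
#' @return Named probability vector over the 20 residues.
#' @export
empirical_freqs <- function(aln) {
  codes <- aa_encode(unclass(aln))
  counts <- tabulate(codes[!is.na(codes)], nbins = 20)
  if (any(counts == 0)) counts <- counts + 1
  stats::setNames(counts / sum(counts), AA_STATES)
}

#' Build the rescaled reversible generator
#'
#' Forms `Q[i, j] = s[i, j] * pi[j]` for `i != j`, sets the diagonal to minus
#' the row sum, rescales so the expected rate `-sum(pi * diag(Q))` equals 1,
#' and caches the eigendecomposition of the symmetrised generator for fast
#' transition probabilities.
#'
#' @param x A `ccs_model`, or a symmetric exchangeability matrix.
#' @param freqs Stationary distribution (only for the matrix method).
#' @param ... Unused.
#' @return A `ccs_rate_matrix` with elements `Q`, `freqs`, and eigen cache.
#' @export
build_rate_matrix <- function(x, ...) UseMethod("build_rate_matrix")

#' @rdname build_rate_matrix
#' @export
build_rate_matrix.ccs_model <- function(x, ...) {
  build_rate_matrix.default(x$exchangeabilities, x$freqs)
}

#' @rdname build_rate_matrix
#' @export
build_rate_matrix.default <- function(x, freqs, ...) {
  s <- as.matrix(x)
  freqs <- as.numeric(freqs)
  n <- nrow(s)
  if (any(freqs <= 0)) stop("degenerate stationary distribution: zero frequency", call. = FALSE)
  freqs <- freqs / sum(freqs)
  q <- s * rep(freqs, each = n)   # Q_ij = s_ij * pi_j
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(freqs * diag(q))
  if (mu <= 0) stop("degenerate generator: zero expected rate", call. = FALSE)
  q <- q / mu
  # Reversibility: B = D^{1/2} Q D^{-1/2} is symmetric; eigendecompose once.
  sq <- sqrt(freqs)
  b <- q * (sq %o% (1 / sq))
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  structure(list(
    Q = q,
    freqs = freqs,
    eig_values = eig$values,
    # P(t) = L exp(diag(values) * t) R with L = D^{-1/2} U, R = U' D^{1/2}
    eig_left = eig$vectors / sq,
    eig_right = t(eig$vectors * sq)
  ), class = "ccs_rate_matrix")
}

#' @export
print.ccs_rate_matrix <- function(x, ...) {
  cat("<ccs_rate_matrix> ", nrow(x$Q), " states, expected rate ",
      signif(-sum(x$freqs * diag(x$Q)), 6), "\n", sep = "")
  invisible(x)
}

#' Transition probability matrix
#'
#' Computes `P(r * t) = exp(Q * r * t)` from the cached eigendecomposition.
#' Entries are clipped to \[0, 1\] after a tolerance check; an entry outside
#' the interval by more than 1e-8 raises an error.
#'
#' @param rate_matrix A `ccs_rate_matrix`.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @param rate Rate multiplier (gamma category rate, >= 0).
#' @return A stochastic matrix whose rows sum to 1.
#' @export
transition_matrix <- function(rate_matrix, t, rate = 1) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("domain error: branch length must be >= 0", call. = FALSE)
  }
  if (rate < 0) stop("domain error: rate must be >= 0", call. = FALSE)
  p <- rate_matrix$eig_left %*%
    (exp(rate_matrix$eig_values * (t * rate)) * rate_matrix$eig_right)
  if (any(p < -1e-8) || any(p > 1 + 1e-8)) {
    stop("transition probabilities outside [0, 1] beyond tolerance", call. = FALSE)
  }
  p[p < 0] <- 0
  p[p > 1] <- 1
  dimnames(p) <- dimnames(rate_matrix$Q)
  p
}
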