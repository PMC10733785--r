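#' Amino-acid substitution models
#'
#' A reversible amino-acid CTMC defined by a symmetric 20x20 exchangeability
#' matrix and stationary frequencies, optionally with discrete-gamma rate
#' heterogeneity (k equal-probability categories, each represented by its
#' category mean rate). The rate matrix is normalized to one expected
#' substitution per unit branch length.
#'
#' The default is Poisson exchangeabilities (all equal). With arbitrary
#' frequencies that is the amino-acid equal-input model, whose transition
#' probabilities have the closed form
#' `P(t) = exp(-bt) I + (1 - exp(-bt)) 1 pi'` with `b = 1/(1 - sum(pi^2))`;
#' the implementation uses this as a fast path and a symmetric
#' eigendecomposition otherwise (e.g. for exchangeabilities loaded from a
#' PAML-style rate file).
#'
#' @param name Model name: `"poisson"` or a label for file-loaded rates.
#' @param exchangeabilities 20x20 symmetric matrix of exchangeabilities, or
#'   `NULL` for Poisson (all equal).
#' @param freq Stationary frequencies: `"uniform"`, or a positive numeric
#'   vector of length 20 in the package amino-acid order (ARNDCQEGHILKMFPSTWYV).
#' @param alpha Gamma shape for among-site rate variation, or `NULL` for
#'   rate homogeneity.
#' @param k Number of discrete gamma categories (used when `alpha` is set).
#' @return Object of class `subst_model`.
#' @export
subst_model <- function(name = "poisson", exchangeabilities = NULL,
                        freq = "uniform", alpha = NULL, k = 4L) {
  if (is.null(exchangeabilities)) {
    R <- matrix(1, 20L, 20L)
  } else {
    R <- as.matrix(exchangeabilities)
    stopifnot(nrow(R) == 20L, ncol(R) == 20L)
    if (max(abs(R - t(R))) > 1e-9) stop("exchangeability matrix must be symmetric")
    if (any(R[upper.tri(R)] <= 0)) stop("exchangeabilities must be positive")
  }
  diag(R) <- 0
  if (identical(freq, "uniform")) freq <- rep(1 / 20, 20L)
  freq <- as.numeric(freq)
  stopifnot(length(freq) == 20L, all(freq > 0))
  freq <- freq / sum(freq)
  names(freq) <- AA_ORDER
  dimnames(R) <- list(AA_ORDER, AA_ORDER)

  Q <- R * rep(freq, each = 20L)     # Q_ij = R_ij * pi_j (i != j)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))         # expected rate; normalize to 1
  Q <- Q / mu

  off <- R[upper.tri(R)]
  equal_input <- all(abs(off - off[1L]) < 1e-12)

  m <- list(name = name, R = R, freq = freq, Q = Q,
            alpha = alpha, k = if (is.null(alpha)) 1L else as.integer(k),
            equal_input = equal_input)
  if (equal_input) {
    m$beta <- 1 / (1 - sum(freq^2))
  } else {
    # symmetric decomposition of the reversible Q
    sp <- sqrt(freq)
    B <- Q * (sp %o% (1 / sp))       # D^{1/2} Q D^{-1/2}
    B <- (B + t(B)) / 2              # enforce symmetry numerically
    eig <- eigen(B, symmetric = TRUE)
    m$eval <- eig$values
    m$U <- eig$vectors / sp          # D^{-1/2} V
    m$W <- t(eig$vectors) * rep(sp, each = 20L)  # V' D^{1/2}
  }
  m$rates <- if (is.null(alpha)) 1 else discrete_gamma_rates(alpha, m$k)
  class(m) <- "subst_model"
  m
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> ", x$name,
      if (!is.null(x$alpha)) sprintf(" + gamma(alpha=%.3g, k=%d)", x$alpha, x$k),
      "\n", sep = "")
  invisible(x)
}

#' Discrete-gamma category rates (mean of each equal-probability slice)
#'
#' @param alpha Gamma shape (rate parameter equals shape, so the mean is 1).
#' @param k Number of categories.
#' @return Numeric vector of k category rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1L)
  if (k == 1L) return(1)
  breaks <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # mean of a gamma(shape, rate) slice via the shape+1 cdf identity
  upper <- pgamma(breaks[-1L], shape = alpha + 1, rate = alpha)
  lower <- pgamma(breaks[-(k + 1L)], shape = alpha + 1, rate = alpha)
  rates <- k * (upper - lower)
  rates / mean(rates)
}

#' Transition probability matrix P(t)
#'
#' @param model A [subst_model()].
#' @param t Branch length (expected substitutions per site), `t >= 0`.
#' @param rate Rate multiplier (gamma category rate).
#' @return 20x20 matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(t >= 0)
  d <- t * rate
  if (model$equal_input) {
    e <- exp(-model$beta * d)
    e * diag(20L) + (1 - e) * rep(1, 20L) %o% model$freq
  } else {
    P <- model$U %*% (exp(model$eval * d) * model$W)
    # clip tiny negative round-off
    P[P < 0] <- 0
    P
  }
}

# P(t) %*% L for a 20 x n partial matrix L, avoiding the full gemm for the
# equal-input fast path. Hot loop of the likelihood machinery.
#' @noRd
pmat_mult <- function(model, t, rate, L) {
  d <- t * rate
  if (model$equal_input) {
    e <- exp(-model$beta * d)
    base <- .colSums(model$freq * L, 20L, ncol(L))  # pi' L per column
    out <- e * L
    out + rep((1 - e) * base, each = 20L)
  } else {
    model$U %*% (exp(model$eval * d) * (model$W %*% L))
  }
}

#' Read a PAML-style amino-acid rate file
#'
#' The file holds the lower triangle of the 20x20 exchangeability matrix
#' (190 numbers, row by row) followed by 20 stationary frequencies;
#' whitespace and line breaks are free-form, `#` comments allowed.
#'
#' @param path Path to the rate file.
#' @return List with `exchangeabilities` (20x20 symmetric) and `freq`.
#' @export
read_paml_rates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  nums <- as.numeric(unlist(strsplit(paste(lines, collapse = " "), "\\s+")))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 210L) {
    stop("rate file needs 190 exchangeabilities + 20 frequencies; found ",
         length(nums), " numbers")
  }
  R <- matrix(0, 20L, 20L)
  R[lower.tri(R)] <- nums[1:190]
  R <- R + t(R)
  freq <- nums[191:210]
  dimnames(R) <- list(AA_ORDER, AA_ORDER)
  list(exchangeabilities = R, freq = freq / sum(freq))
}

#' Empirical amino-acid frequencies of an alignment
#'
#' Gap and X characters are ignored; zero counts are floored at a small
#' positive value so all frequencies stay positive.
#'
#' @param msa An [as_msa()] alignment.
#' @export
empirical_aa_freqs <- function(msa) {
  chars <- strsplit(paste(unclass(msa), collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = AA_ORDER))
  f <- as.numeric(counts)
  f <- pmax(f, 0.5)
  f <- f / sum(f)
  names(f) <- AA_ORDER
  f
}
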