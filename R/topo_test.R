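# Topology hypothesis testing: RELL multiscale bootstrap, the approximately
# unbiased (AU) p-value, and KH/BP baselines.

#' Per-site log-likelihood matrix for candidate topologies
#'
#' @param rows Named list of per-site log-likelihood vectors (one per
#'   candidate topology, equal lengths), or a matrix with rownames.
#' @param weights Optional column weights (duplicate-pattern compression);
#'   default 1 per column.
#' @return Object of class `site_lnl` with elements `mat` (candidates x
#'   columns) and `weights`.
#' @export
site_lnl <- function(rows, weights = NULL) {
  mat <- if (is.matrix(rows)) rows else do.call(rbind, rows)
  stopifnot(!is.null(rownames(mat)), !anyDuplicated(rownames(mat)),
            all(is.finite(mat)))
  if (is.null(weights)) weights <- rep(1, ncol(mat))
  stopifnot(length(weights) == ncol(mat), all(weights > 0))
  structure(list(mat = mat, weights = weights), class = "site_lnl")
}

#' @export
print.site_lnl <- function(x, ...) {
  cat("<site_lnl> ", nrow(x$mat), " candidates x ", ncol(x$mat),
      " columns (", sum(x$weights), " sites)\n", sep = "")
  invisible(x)
}

#' RELL multiscale bootstrap win proportions
#'
#' For each scale `r`, resamples `ceiling(r * L)` columns with replacement
#' (respecting column weights), sums each candidate's per-site
#' log-likelihoods over the resample, and records the winner. Exact ties are
#' broken by cycling round-robin through the tied candidates in
#' lexicographic name order, so a symmetric tie yields even proportions.
#'
#' @param slnl A [site_lnl()] object with at least two candidates.
#' @param scales Positive resampling scales.
#' @param n_reps Replicates per scale.
#' @param seed Integer seed.
#' @return Tibble with columns `scale`, `m` (resample size), `candidate`,
#'   `wins`, `n_reps`, `bp`.
#' @export
rell_bootstrap <- function(slnl, scales = seq(0.5, 1.4, by = 0.1),
                           n_reps = 10000L, seed = 1L) {
  stopifnot(inherits(slnl, "site_lnl"))
  if (nrow(slnl$mat) < 2L) stop("need at least two candidate topologies")
  stopifnot(all(scales > 0), n_reps >= 1L)
  cand <- rownames(slnl$mat)
  lex <- order(cand)                  # tie cycle follows lexicographic order
  L <- sum(slnl$weights)
  prob <- slnl$weights / L
  set.seed(seed)
  tie_counter <- 0L
  out <- vector("list", length(scales))
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * L)
    W <- rmultinom(n_reps, size = m, prob = prob)
    sums <- slnl$mat %*% W            # candidates x reps
    wins <- integer(length(cand))
    mx <- do.call(pmax, asplit(sums, 1L))
    is_max <- sums == rep(mx, each = nrow(sums))
    n_tied <- colSums(is_max)
    clean <- n_tied == 1L
    if (any(clean)) {
      wmax <- apply(sums[, clean, drop = FALSE], 2L, which.max)
      tab <- tabulate(wmax, nbins = length(cand))
      wins <- wins + tab
    }
    for (rep_i in which(!clean)) {
      tied <- lex[lex %in% which(is_max[, rep_i])]
      pick <- tied[(tie_counter %% length(tied)) + 1L]
      wins[pick] <- wins[pick] + 1L
      tie_counter <- tie_counter + 1L
    }
    out[[si]] <- tibble::tibble(scale = scales[si], m = m, candidate = cand,
                                wins = wins, n_reps = n_reps,
                                bp = wins / n_reps)
  }
  dplyr::bind_rows(out)
}

#' AU p-value from multiscale bootstrap proportions
#'
#' Fits `probit(1 - BP_r) = d*sqrt(r) + c/sqrt(r)` by weighted least squares
#' over scales (counts adjusted by +0.5/(n+1) before probit inversion;
#' weights `n / (BP(1-BP))`), and returns `p = 1 - pnorm(d - c)` together
#' with the fitted signed distance `d` and curvature `c`. Candidates that
#' win never (or always) at every scale are clamped to p = 0 (or 1) with a
#' degeneracy flag.
#'
#' @param bp Win proportions, one per scale.
#' @param scales The corresponding scales (at least two distinct).
#' @param n_reps Replicates per scale (scalar or vector).
#' @return List with `p`, `d`, `c`, `flag` (`"ok"`, `"all_zero"`,
#'   `"all_one"`).
#' @export
au_pvalue <- function(bp, scales, n_reps) {
  stopifnot(length(bp) == length(scales), all(bp >= 0), all(bp <= 1))
  if (length(unique(scales)) < 2L) {
    stop("need at least two distinct scales to fit the AU model")
  }
  n <- rep(n_reps, length.out = length(bp))
  x <- bp * n
  if (all(x == 0)) return(list(p = 0, d = Inf, c = 0, flag = "all_zero"))
  if (all(x == n)) return(list(p = 1, d = -Inf, c = 0, flag = "all_one"))
  p_adj <- (x + 0.5) / (n + 1)
  z <- qnorm(1 - p_adj)
  w <- n / (p_adj * (1 - p_adj))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  XtWX <- crossprod(X, w * X)
  XtWz <- crossprod(X, w * z)
  beta <- solve(XtWX, XtWz)
  d <- beta[1L]; cc <- beta[2L]
  list(p = 1 - pnorm(d - cc), d = d, c = cc, flag = "ok")
}

#' Kishino-Hasegawa p-value for two candidates (RELL, normal approximation)
#'
#' The observed log-likelihood difference is compared with the spread of its
#' centered RELL bootstrap distribution; two-sided.
#'
#' @param slnl A [site_lnl()] with exactly two candidate rows.
#' @param n_reps Bootstrap replicates.
#' @param seed Integer seed.
#' @return Two-sided p-value.
#' @export
kh_pvalue <- function(slnl, n_reps = 10000L, seed = 1L) {
  stopifnot(inherits(slnl, "site_lnl"), nrow(slnl$mat) == 2L)
  delta <- slnl$mat[1L, ] - slnl$mat[2L, ]
  obs <- sum(slnl$weights * delta)
  L <- sum(slnl$weights)
  set.seed(seed)
  W <- rmultinom(n_reps, size = L, prob = slnl$weights / L)
  boot <- as.vector(delta %*% W)
  s <- sd(boot)
  if (s == 0) return(if (abs(obs) < 1e-12) 1 else 0)
  2 * (1 - pnorm(abs(obs) / s))
}

#' Run constrained-topology tests
#'
#' Computes the unconstrained tree (NJ + NNI), the best tree under each
#' monophyly constraint, the per-site log-likelihood row of every candidate,
#' and decides the candidates jointly by RELL multiscale bootstrap: AU
#' p-value per candidate, plus scale-1 bootstrap proportion (BP) and the
#' pairwise KH p-value against the maximum-likelihood candidate.
#'
#' @inheritParams site_loglikelihoods
#' @param constraints List of [constraint_spec()] objects (at least one).
#' @param scales,n_reps,seed RELL settings (see [rell_bootstrap()]).
#' @param max_moves NNI move cap per search.
#' @param ml_result Optional precomputed unconstrained search result (a list
#'   with `tree`, as returned by [ml_tree()]), to avoid repeating it.
#' @return Object of class `au_test`: a list with `table` (tibble: one row
#'   per candidate), `detail` (per-scale BPs), `trees`, and the settings.
#' @export
run_topology_tests <- function(msa, model, constraints,
                               scales = seq(0.5, 1.4, by = 0.1),
                               n_reps = 10000L, seed = 1L, max_moves = 50L,
                               ml_result = NULL) {
  if (inherits(constraints, "constraint_spec")) constraints <- list(constraints)
  stopifnot(length(constraints) >= 1L)
  if (is.null(ml_result)) ml_result <- ml_tree(msa, model, max_moves = max_moves)
  trees <- list(ML = ml_result$tree)
  for (cs in constraints) {
    trees[[cs$name]] <- best_tree_under_constraint(
      msa, model, cs, max_moves = max_moves
    )$tree
  }
  rows <- lapply(trees, function(tr) {
    as.numeric(site_loglikelihoods(msa, tr, model))
  })
  slnl <- site_lnl(rows)
  totals <- vapply(rows, sum, numeric(1))
  best <- names(totals)[which.max(totals)]
  detail <- rell_bootstrap(slnl, scales = scales, n_reps = n_reps, seed = seed)
  cand <- rownames(slnl$mat)
  au <- lapply(cand, function(cn) {
    sub <- detail[detail$candidate == cn, ]
    au_pvalue(sub$bp, sub$scale, sub$n_reps)
  })
  names(au) <- cand
  scale1 <- scales[which.min(abs(scales - 1))]
  bp1 <- vapply(cand, function(cn) {
    detail$bp[detail$candidate == cn & detail$scale == scale1][1L]
  }, numeric(1))
  kh <- vapply(cand, function(cn) {
    if (cn == best) return(1)
    kh_pvalue(site_lnl(slnl$mat[c(best, cn), , drop = FALSE], slnl$weights),
              n_reps = n_reps, seed = seed)
  }, numeric(1))
  table <- tibble::tibble(
    candidate = cand,
    lnl = unname(totals[cand]),
    delta_lnl = unname(totals[cand] - totals[best]),
    au_p = vapply(au, `[[`, numeric(1), "p"),
    bp = unname(bp1),
    kh_p = unname(kh),
    d = vapply(au, `[[`, numeric(1), "d"),
    c = vapply(au, `[[`, numeric(1), "c"),
    flag = vapply(au, `[[`, character(1), "flag")
  )
  structure(list(table = table, detail = detail, trees = trees,
                 best = best, scales = scales, n_reps = n_reps, seed = seed),
            class = "au_test")
}

#' @export
print.au_test <- function(x, ...) {
  cat("<au_test> ", nrow(x$table), " candidates, ", length(x$scales),
      " scales x ", x$n_reps, " RELL replicates\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.au_test <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.au_test <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$table),
    best = x$best,
    n_rejected = sum(x$table$au_p < 0.05),
    n_scales = length(x$scales),
    n_reps = x$n_reps
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.au_test <- function(object, ...) {
  ggplot2::ggplot(object$detail,
                  ggplot2::aes(x = .data$scale, y = .data$bp,
                               colour = .data$candidate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "resampling scale r", y = "bootstrap win proportion",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}
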