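# Felsenstein pruning site log-likelihoods and branch-length optimization.
#
# Internal layout: trees are ape "phylo" objects reordered postorder; node
# partials are 20 x n_cols matrices; per-column log scalers are accumulated
# at every internal node so likelihoods stay finite on deep trees. The
# "up" (outside) partials U_v for an edge (parent p, child v) satisfy
#   site L = sum_j pi_j * U_v[j] * (P(t_v) L_v)[j]
# for a reversible model, which makes per-branch optimization and local NNI
# rescoring a rank-1-cheap operation under the equal-input fast path.

#' @noRd
encode_alignment <- function(msa) {
  m <- msa_matrix(as_msa(unclass(msa)))
  code <- matrix(match(m, AA_ORDER), nrow = nrow(m), dimnames = dimnames(m))
  code
}

# Tip partial: unit indicator column per site; all-ones for gap/unknown.
#' @noRd
tip_partial <- local({
  I20 <- diag(20L)
  ones <- rep(1, 20L)
  function(code_row) {
    known <- !is.na(code_row)
    if (all(known)) return(I20[, code_row, drop = FALSE])
    L <- matrix(1, 20L, length(code_row))
    L[, known] <- I20[, code_row[known], drop = FALSE]
    L
  }
})

# Shared setup for all likelihood operations on one (msa, tree) pair.
#' @noRd
lik_setup <- function(msa, tree, model) {
  msa <- as_msa(unclass(msa))
  missing_tips <- setdiff(tree$tip.label, names(msa))
  if (length(missing_tips)) {
    stop("tree tip(s) absent from alignment: ",
         paste(missing_tips, collapse = ", "))
  }
  tree <- stats::reorder(tree, "postorder")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  code <- encode_alignment(msa)
  ntip <- length(tree$tip.label)
  tipL <- lapply(seq_len(ntip), function(i) tip_partial(code[tree$tip.label[i], ]))
  list(tree = tree, tipL = tipL, ncols = ncol(code), ntip = ntip,
       nnode = tree$Nnode, model = model)
}

# Rescale partials only when their column sums drift toward underflow;
# `logsc = 0` (scalar) marks "nothing accumulated" and recycles in sums.
#' @noRd
col_rescale <- function(L) {
  s <- .colSums(L, 20L, ncol(L))
  if (min(s) > 1e-240 && max(s) < 1e240) return(list(L = L, logsc = 0))
  sdiv <- ifelse(s > 0, s, 1)
  list(L = L / rep(sdiv, each = 20L), logsc = log(s))
}

# Postorder (down) pass at one rate category. Returns per-node partials L,
# per-node accumulated log-scalers, and the per-edge P(t)%*%L products.
#' @noRd
down_pass <- function(st, rate) {
  tree <- st$tree
  nn <- st$ntip + tree$Nnode
  L <- vector("list", nn)
  logsc <- vector("list", nn)
  PL <- vector("list", nn)            # PL[[child]] = P(t_child) %*% L[[child]]
  for (i in seq_len(st$ntip)) {
    L[[i]] <- st$tipL[[i]]
    logsc[[i]] <- 0
  }
  edge <- tree$edge
  elen <- tree$edge.length
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; v <- edge[e, 2L]
    PL[[v]] <- pmat_mult(st$model, elen[e], rate, L[[v]])
    if (is.null(L[[p]])) {
      L[[p]] <- PL[[v]]
      logsc[[p]] <- logsc[[v]]
    } else {
      L[[p]] <- L[[p]] * PL[[v]]
      logsc[[p]] <- logsc[[p]] + logsc[[v]]
    }
  }
  root <- edge[nrow(edge), 1L]
  rs <- col_rescale(L[[root]])
  L[[root]] <- rs$L
  logsc[[root]] <- logsc[[root]] + rs$logsc
  list(L = L, logsc = logsc, PL = PL, root = root)
}

# Preorder (up) pass: U[[v]] conditional on the state at v's parent, with
# M[[p]] = P(t_p) %*% U[[p]] cached for NNI rescoring. logscU accumulates
# scalers of everything outside subtree v.
#' @noRd
up_pass <- function(st, dp, rate) {
  tree <- st$tree
  edge <- tree$edge
  elen <- tree$edge.length
  nn <- st$ntip + tree$Nnode
  U <- vector("list", nn)
  logscU <- vector("list", nn)
  M <- vector("list", nn)
  logscM <- vector("list", nn)
  root <- dp$root
  M[[root]] <- matrix(1, 20L, st$ncols)
  logscM[[root]] <- 0
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  # preorder = reverse postorder over edges
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1L]; v <- edge[e, 2L]
    sibs <- setdiff(children[[as.character(p)]], e)
    Uv <- M[[p]]
    lsc <- logscM[[p]]
    for (se in sibs) {
      sv <- edge[se, 2L]
      Uv <- Uv * dp$PL[[sv]]
      lsc <- lsc + dp$logsc[[sv]]
    }
    rs <- col_rescale(Uv)
    U[[v]] <- rs$L
    logscU[[v]] <- lsc + rs$logsc
    if (v > st$ntip) {
      M[[v]] <- pmat_mult(st$model, elen[e], rate, U[[v]])
      logscM[[v]] <- logscU[[v]]
    }
  }
  list(U = U, logscU = logscU, M = M, logscM = logscM)
}

#' @noRd
logmeanexp_rows <- function(mat) {
  # mat: categories x sites; returns log of column means
  if (nrow(mat) == 1L) return(mat[1L, ])
  mx <- do.call(pmax, asplit(mat, 1L))
  mx[!is.finite(mx)] <- 0
  log(colMeans(exp(sweep(mat, 2L, mx, "-")))) + mx
}

#' Per-site log-likelihoods of an alignment on a tree
#'
#' Felsenstein pruning under a reversible amino-acid model; gaps and X are
#' treated as missing data (all-ones partials). With discrete-gamma rate
#' categories the site likelihood is the equal-weight category mean. Columns
#' with zero likelihood (only possible at zero branch lengths) yield `-Inf`.
#'
#' @param msa An [as_msa()] alignment.
#' @param tree `phylo` with branch lengths; tips must appear in `msa`.
#' @param model A [subst_model()].
#' @param weights Optional per-column weights (duplicate-pattern
#'   compression); defaults to 1 per column.
#' @return Numeric vector of natural-log site likelihoods with attributes
#'   `total` (weighted sum) and `weights`.
#' @export
site_loglikelihoods <- function(msa, tree, model, weights = NULL) {
  st <- lik_setup(msa, tree, model)
  if (is.null(weights)) weights <- rep(1, st$ncols)
  stopifnot(length(weights) == st$ncols)
  per_cat <- matrix(NA_real_, length(model$rates), st$ncols)
  for (ci in seq_along(model$rates)) {
    dp <- down_pass(st, model$rates[ci])
    rootlik <- colSums(model$freq * dp$L[[dp$root]])
    per_cat[ci, ] <- log(rootlik) + dp$logsc[[dp$root]]
  }
  out <- logmeanexp_rows(per_cat)
  attr(out, "total") <- sum(weights * out)
  attr(out, "weights") <- weights
  out
}

#' Total log-likelihood of a tree
#' @inheritParams site_loglikelihoods
#' @export
tree_loglik <- function(msa, tree, model, weights = NULL) {
  attr(site_loglikelihoods(msa, tree, model, weights), "total")
}

#' Compress an alignment to unique columns with weights
#'
#' @param msa An [as_msa()] alignment.
#' @return List with `msa` (unique columns, same row ids) and `weights`
#'   (column multiplicities summing to the original length).
#' @export
compress_columns <- function(msa) {
  m <- msa_matrix(as_msa(unclass(msa)))
  key <- apply(m, 2L, paste, collapse = "")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  mm <- m[, first, drop = FALSE]
  rows <- apply(mm, 1L, paste, collapse = "")
  list(msa = as_msa(setNames(rows, rownames(m))), weights = w)
}

# Per-edge objective pieces for one edge given down/up passes at every rate
# category; returns f(t) = weighted total lnL as a function of that edge's
# length, everything else fixed. Under the equal-input fast path
#   sum_j A_j P_t(j,.) L = e(t) * (A.L) + (1-e(t)) * (A.1)(pi'L)
# per column, so each evaluation is a single length-ncols expression.
#' @noRd
edge_objective <- function(st, dps, ups, edge_row, weights) {
  v <- st$tree$edge[edge_row, 2L]
  model <- st$model
  freq <- model$freq
  k <- length(model$rates)
  nc <- st$ncols
  base <- lapply(seq_len(k), function(ci) {
    A <- ups[[ci]]$U[[v]] * freq
    L <- dps[[ci]]$L[[v]]
    lsc <- ups[[ci]]$logscU[[v]] + dps[[ci]]$logsc[[v]]
    if (model$equal_input) {
      list(u = .colSums(A * L, 20L, nc),
           ab = .colSums(A, 20L, nc) * .colSums(freq * L, 20L, nc),
           lsc = lsc)
    } else {
      list(U = A, L = L, lsc = lsc)
    }
  })
  if (model$equal_input) {
    beta <- model$beta
    rates <- model$rates
    if (k == 1L) {
      u <- base[[1L]]$u; ab <- base[[1L]]$ab
      const <- sum(weights * base[[1L]]$lsc)
      return(function(t) {
        e <- exp(-beta * t)
        sum(weights * log(e * u + (1 - e) * ab)) + const
      })
    }
    function(t) {
      per_cat <- matrix(NA_real_, k, nc)
      for (ci in seq_len(k)) {
        e <- exp(-beta * t * rates[ci])
        per_cat[ci, ] <- log(e * base[[ci]]$u + (1 - e) * base[[ci]]$ab) +
          base[[ci]]$lsc
      }
      sum(weights * logmeanexp_rows(per_cat))
    }
  } else {
    function(t) {
      per_cat <- matrix(NA_real_, k, nc)
      for (ci in seq_len(k)) {
        PLv <- pmat_mult(model, t, model$rates[ci], base[[ci]]$L)
        per_cat[ci, ] <- log(.colSums(base[[ci]]$U * PLv, 20L, nc)) +
          base[[ci]]$lsc
      }
      sum(weights * logmeanexp_rows(per_cat))
    }
  }
}

# total lnL from an existing setup (avoids re-encoding the alignment)
#' @noRd
st_total_loglik <- function(st, weights) {
  dps <- lapply(st$model$rates, function(r) down_pass(st, r))
  dps_total_loglik(st, dps, weights)
}

#' @noRd
dps_total_loglik <- function(st, dps, weights) {
  model <- st$model
  per_cat <- matrix(NA_real_, length(model$rates), st$ncols)
  for (ci in seq_along(model$rates)) {
    dp <- dps[[ci]]
    per_cat[ci, ] <- log(.colSums(model$freq * dp$L[[dp$root]], 20L, st$ncols)) +
      dp$logsc[[dp$root]]
  }
  sum(weights * logmeanexp_rows(per_cat))
}

# top-level fast objective for the equal-input, rate-homogeneous case
# (compiled once; `optimize` forwards the extra arguments)
#' @noRd
eq_edge_lnl <- function(t, u, ab, w, beta) {
  e <- exp(-beta * t)
  sum(w * log(e * u + (1 - e) * ab))
}

#' Optimize branch lengths by iterated per-branch search
#'
#' Sweeps over branches, optimizing each length by univariate search with
#' all other lengths fixed (partials are refreshed once per sweep). Stops
#' when a sweep improves the total log-likelihood by less than `tol`.
#' Lengths are bounded below by `min_len` to keep site likelihoods finite.
#'
#' @inheritParams site_loglikelihoods
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_sweeps Maximum number of sweeps (warning if reached without
#'   converging; best-so-far tree is returned).
#' @param min_len,max_len Branch-length search bounds.
#' @param edges Optional integer vector of edge rows to optimize (used for
#'   local re-optimization around an NNI move); default all edges.
#' @param warn Warn when `max_sweeps` is reached without converging.
#' @param exact When the cheap stale-partial sweep oscillates, switch to
#'   exact per-edge coordinate ascent (slower, tight optima). `FALSE`
#'   accepts the best point seen instead — appropriate inside tree search,
#'   where branch lengths only steer topology moves.
#' @param .st Internal: a precomputed likelihood setup sharing the tree's
#'   tip indexing, to avoid re-encoding the alignment in hot loops.
#' @return The tree with optimized `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(msa, tree, model, tol = 1e-2,
                                    max_sweeps = 5L, min_len = 1e-8,
                                    max_len = 10, weights = NULL,
                                    edges = NULL, warn = TRUE, exact = TRUE,
                                    .st = NULL) {
  st <- .st %||% lik_setup(msa, tree, model)
  tree <- stats::reorder(tree, "postorder")
  st$tree <- tree
  if (is.null(weights)) weights <- rep(1, st$ncols)
  edge_rows <- edges %||% seq_len(nrow(tree$edge))
  fast <- model$equal_input && length(model$rates) == 1L
  freq <- model$freq
  nc <- st$ncols
  prev_lnl <- -Inf
  best_len <- tree$edge.length
  converged <- FALSE
  safe <- FALSE   # refresh partials per edge (exact coordinate ascent)

  optimize_edge <- function(e, dps, ups) {
    cur <- tree$edge.length[e]
    hi <- max(max_len, cur)
    if (fast) {
      v <- tree$edge[e, 2L]
      A <- ups[[1L]]$U[[v]] * freq
      Lv <- dps[[1L]]$L[[v]]
      u <- .colSums(A * Lv, 20L, nc)
      ab <- .colSums(A, 20L, nc) * .colSums(freq * Lv, 20L, nc)
      opt <- optimize(eq_edge_lnl, interval = c(min_len, hi),
                      u = u, ab = ab, w = weights, beta = model$beta,
                      maximum = TRUE, tol = 1e-3)
      # the optimum may sit on the lower boundary, which Brent never
      # evaluates exactly
      cand_t <- c(cur, opt$maximum, min_len)
      cand_f <- c(eq_edge_lnl(cur, u, ab, weights, model$beta),
                  opt$objective,
                  eq_edge_lnl(min_len, u, ab, weights, model$beta))
    } else {
      f <- edge_objective(st, dps, ups, e, weights)
      opt <- optimize(f, interval = c(min_len, hi), maximum = TRUE,
                      tol = 1e-3)
      cand_t <- c(cur, opt$maximum, min_len)
      cand_f <- c(f(cur), opt$objective, f(min_len))
    }
    cand_t[which.max(cand_f)]
  }

  # each iteration first evaluates the current lengths from its own pass,
  # then (except the last) optimizes every edge against those partials;
  # if the stale-partial sweep ever lowers the likelihood (oscillation),
  # fall back to refreshing the partials before every edge
  fresh_sweep <- TRUE
  n_iter <- (if (exact) 2L * max_sweeps else max_sweeps) + 1L
  for (sweep in seq_len(n_iter)) {
    st$tree <- tree
    dps <- lapply(model$rates, function(r) down_pass(st, r))
    lnl <- dps_total_loglik(st, dps, weights)
    if (lnl < prev_lnl) {
      tree$edge.length <- best_len
      if (safe || !exact || prev_lnl - lnl <= tol) {
        # exact ascent already, oscillation below tolerance, or the caller
        # settles for the best point seen
        converged <- TRUE
        break
      }
      safe <- TRUE                    # oscillation: switch to exact ascent
      fresh_sweep <- TRUE
      st$tree <- tree
      dps <- lapply(model$rates, function(r) down_pass(st, r))
      lnl <- prev_lnl
    }
    improved <- lnl - prev_lnl
    prev_lnl <- lnl
    best_len <- tree$edge.length
    if (improved < tol && !fresh_sweep) {
      converged <- TRUE
      break
    }
    fresh_sweep <- FALSE
    if (sweep == n_iter) break
    ups <- lapply(seq_along(model$rates),
                  function(ci) up_pass(st, dps[[ci]], model$rates[ci]))
    for (e in edge_rows) {
      if (safe) {
        st$tree <- tree
        dps <- lapply(model$rates, function(r) down_pass(st, r))
        ups <- lapply(seq_along(model$rates),
                      function(ci) up_pass(st, dps[[ci]], model$rates[ci]))
      }
      tree$edge.length[e] <- optimize_edge(e, dps, ups)
    }
  }
  if (!converged && warn) {
    warning("branch-length optimization did not converge in ", max_sweeps,
            " sweeps; returning best tree so far")
  }
  tree$edge.length <- best_len
  attr(tree, "loglik") <- prev_lnl
  tree
}
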