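# NNI hill climbing (optionally under monophyly constraints), constrained
# start trees, and nonparametric bootstrap supports.

# Tip-name sets below every node of a (rooted-representation) phylo.
#' @noRd
node_tipsets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

# Is each taxon set monophyletic in the unrooted sense (some split separates
# it exactly)?
#' @noRd
sets_monophyletic <- function(tree, sets) {
  if (length(sets) == 0L) return(TRUE)
  all_tips <- tree$tip.label
  tipsets <- node_tipsets(tree)
  keys <- vapply(tipsets, function(s) paste(sort(s), collapse = "\r"), character(1))
  for (s in sets) {
    s <- intersect(s, all_tips)
    if (length(s) <= 1L || length(s) >= length(all_tips)) next
    k1 <- paste(sort(s), collapse = "\r")
    k2 <- paste(sort(setdiff(all_tips, s)), collapse = "\r")
    if (!(k1 %in% keys || k2 %in% keys)) return(FALSE)
  }
  TRUE
}

#' Constraint specification for topology tests
#'
#' @param name Constraint name.
#' @param sets List of character vectors; each set of taxa is required to be
#'   monophyletic. Sets must be pairwise disjoint or properly nested.
#' @export
constraint_spec <- function(name, sets) {
  if (is.character(sets)) sets <- list(sets)
  stopifnot(is.list(sets), length(sets) >= 1L)
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0L)) stop("constraint sets must be non-empty")
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i >= j) next
      ov <- intersect(sets[[i]], sets[[j]])
      if (length(ov) &&
          !(all(sets[[i]] %in% sets[[j]]) || all(sets[[j]] %in% sets[[i]]))) {
        stop("constraint sets must be disjoint or properly nested")
      }
    }
  }
  structure(list(name = name, sets = sets), class = "constraint_spec")
}

# Apply one NNI move: swap sibling subtree s (child of p) with child c of v,
# where (p, v) is an internal edge. Lengths travel with the subtrees.
#' @noRd
apply_nni <- function(tree, p, v, s, cc) {
  e_ps <- which(tree$edge[, 1L] == p & tree$edge[, 2L] == s)
  e_vc <- which(tree$edge[, 1L] == v & tree$edge[, 2L] == cc)
  tree$edge[e_ps, 1L] <- v
  tree$edge[e_vc, 1L] <- p
  # the stale order attribute would make reorder() a no-op
  attr(tree, "order") <- NULL
  stats::reorder(tree, "postorder")
}

# Enumerate candidate NNI moves for each internal edge of the (unrooted,
# postorder) tree: a designated sibling of v at p swapped with each child
# of v. Covers both distinct NNIs per edge.
#' @noRd
nni_moves <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  children <- split(edge[, 2L], edge[, 1L])
  moves <- list()
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; v <- edge[e, 2L]
    if (v <= ntip) next              # need an internal child
    sibs <- setdiff(children[[as.character(p)]], v)
    if (!length(sibs)) next
    s <- sibs[1L]
    for (cc in children[[as.character(v)]]) {
      moves[[length(moves) + 1L]] <- list(edge_row = e, p = p, v = v, s = s, cc = cc)
    }
  }
  moves
}

# Rescore one NNI move from cached down/up passes without rebuilding
# partials; exact total lnL of the rearranged tree at current lengths.
#' @noRd
score_nni_move <- function(st, dps, ups, move, weights) {
  model <- st$model
  k <- length(model$rates)
  edge <- st$tree$edge
  elen <- st$tree$edge.length
  t_v <- elen[move$edge_row]
  e_s <- which(edge[, 1L] == move$p & edge[, 2L] == move$s)
  e_c <- which(edge[, 1L] == move$v & edge[, 2L] == move$cc)
  e_keep <- which(edge[, 1L] == move$v & edge[, 2L] != move$cc)
  per_cat <- matrix(NA_real_, k, st$ncols)
  for (ci in seq_len(k)) {
    dp <- dps[[ci]]; up <- ups[[ci]]
    # new v-side: sibling s joins the kept child of v
    Lv <- dp$PL[[move$s]] * dp$PL[[edge[e_keep, 2L]]]
    lscLv <- dp$logsc[[move$s]] + dp$logsc[[edge[e_keep, 2L]]]
    PLv <- pmat_mult(model, t_v, model$rates[ci], Lv)
    # new p-side: everything above/beside v, with c replacing s
    Uv <- up$M[[move$p]]
    lscU <- up$logscM[[move$p]]
    other <- setdiff(which(edge[, 1L] == move$p), c(move$edge_row, e_s))
    for (oe in other) {
      ov <- edge[oe, 2L]
      Uv <- Uv * dp$PL[[ov]]
      lscU <- lscU + dp$logsc[[ov]]
    }
    Uv <- Uv * dp$PL[[move$cc]]
    lscU <- lscU + dp$logsc[[move$cc]]
    per_cat[ci, ] <- log(.colSums(model$freq * Uv * PLv, 20L, st$ncols)) +
      lscU + lscLv
  }
  sum(weights * logmeanexp_rows(per_cat))
}

#' Greedy NNI hill climbing
#'
#' Starting from `start_tree`, repeatedly evaluates all nearest-neighbor
#' interchanges, applies the best strictly improving move, locally
#' re-optimizes the branch lengths around it, and stops at a local optimum.
#' Moves that would break a monophyly constraint are never proposed.
#'
#' @inheritParams site_loglikelihoods
#' @param start_tree Starting tree (will be unrooted for the search).
#' @param constraint Optional [constraint_spec()]; the start tree must
#'   satisfy it.
#' @param max_moves Cap on accepted moves.
#' @param optimize_start Optimize all branch lengths before searching.
#' @return List with `tree` (postorder, unrooted) and `loglik`.
#' @export
nni_search <- function(msa, start_tree, model, constraint = NULL,
                       max_moves = 50L, weights = NULL,
                       optimize_start = TRUE) {
  tree <- ape::unroot(start_tree)
  if (!is.null(constraint) && !sets_monophyletic(tree, constraint$sets)) {
    stop("start tree does not satisfy constraint '", constraint$name, "'")
  }
  st <- lik_setup(msa, tree, model)
  tree <- st$tree
  if (is.null(weights)) weights <- rep(1, st$ncols)
  if (optimize_start) {
    tree <- optimize_branch_lengths(msa, tree, model, weights = weights,
                                    tol = 0.05, max_sweeps = 3L,
                                    warn = FALSE, exact = FALSE, .st = st)
    cur_lnl <- attr(tree, "loglik")
  } else {
    st$tree <- tree
    cur_lnl <- st_total_loglik(st, weights)
  }
  moves_done <- 0L
  repeat {
    st$tree <- tree
    dps <- lapply(model$rates, function(r) down_pass(st, r))
    ups <- lapply(seq_along(model$rates),
                  function(ci) up_pass(st, dps[[ci]], model$rates[ci]))
    cands <- nni_moves(tree)
    scores <- vapply(cands, function(mv) {
      score_nni_move(st, dps, ups, mv, weights)
    }, numeric(1))
    # walk the improving moves best-first; constraint checked lazily so the
    # (expensive) monophyly test runs only for moves actually considered
    best <- NULL
    for (i in order(scores, decreasing = TRUE)) {
      if (scores[i] <= cur_lnl + 1e-8) break   # strict improvement required
      if (!is.null(constraint)) {
        alt <- apply_nni(tree, cands[[i]]$p, cands[[i]]$v,
                         cands[[i]]$s, cands[[i]]$cc)
        if (!sets_monophyletic(alt, constraint$sets)) next
      }
      best <- cands[[i]]
      break
    }
    if (is.null(best) || moves_done >= max_moves) break
    tree <- apply_nni(tree, best$p, best$v, best$s, best$cc)
    # local branch-length refresh around the rearranged edge
    local <- which(tree$edge[, 1L] %in% c(best$p, best$v) |
                     tree$edge[, 2L] %in% c(best$p, best$v))
    tree <- optimize_branch_lengths(msa, tree, model, weights = weights,
                                    edges = local, max_sweeps = 2L,
                                    tol = 0.2, warn = FALSE, exact = FALSE,
                                    .st = st)
    cur_lnl <- attr(tree, "loglik")
    moves_done <- moves_done + 1L
  }
  list(tree = tree, loglik = cur_lnl, n_moves = moves_done)
}

# Constrained start tree: NJ inside each constrained set, NJ on the set
# roots plus free taxa (group-average distances), grafting the subtrees.
# Handles properly nested sets recursively (innermost first).
#' @noRd
constrained_nj <- function(D, sets) {
  if (!length(sets)) return(neighbor_joining(D))
  sets <- sets[order(lengths(sets), decreasing = TRUE)]
  top <- list()
  used <- character(0)
  for (s in sets) {
    if (!length(intersect(s, used))) {
      top <- c(top, list(s))
      used <- c(used, s)
    }
  }
  frag_of <- function(taxa, inner_sets) {
    taxa <- intersect(taxa, rownames(D))
    if (length(taxa) == 1L) return(taxa)
    subD <- D[taxa, taxa, drop = FALSE]
    inner <- Filter(function(x) all(x %in% taxa) && length(x) < length(taxa),
                    inner_sets)
    sub <- if (length(inner)) constrained_nj(subD, inner) else {
      if (length(taxa) == 2L) NULL else neighbor_joining(subD)
    }
    if (is.null(sub)) {
      return(paste0("(", taxa[1L], ":", D[taxa[1L], taxa[2L]] / 2, ",",
                    taxa[2L], ":", D[taxa[1L], taxa[2L]] / 2, ")"))
    }
    # midpoint-root the subtree so it can be written as a clade fragment
    sub <- phangorn::midpoint(sub)
    sub$node.label <- NULL
    sub(";$", "", ape::write.tree(sub))
  }
  labels <- rownames(D)
  free <- setdiff(labels, used)
  # representative distances: group-average linkage between units
  units <- c(as.list(free), top)
  unit_names <- vapply(seq_along(units), function(i) {
    if (length(units[[i]]) == 1L) units[[i]] else paste0("GRP", i, "X")
  }, character(1))
  nU <- length(units)
  if (nU < 3L) {
    # degenerate: join fragments directly under a root
    frags <- vapply(units, function(u) frag_of(u, sets), character(1))
    nwk <- paste0("(", paste(paste0(frags, ":0.05"), collapse = ","), ");")
    return(stats::reorder(ape::unroot(ape::read.tree(text = nwk)), "postorder"))
  }
  DU <- matrix(0, nU, nU, dimnames = list(unit_names, unit_names))
  for (i in seq_len(nU - 1L)) {
    for (j in (i + 1L):nU) {
      DU[i, j] <- DU[j, i] <- mean(D[units[[i]], units[[j]], drop = FALSE])
    }
  }
  backbone <- neighbor_joining(DU)
  nwk <- ape::write.tree(backbone)
  for (i in seq_along(units)) {
    if (length(units[[i]]) > 1L) {
      frag <- frag_of(units[[i]], sets)
      nwk <- sub(paste0(unit_names[i], ":"), paste0(frag, ":"), nwk, fixed = TRUE)
    }
  }
  stats::reorder(ape::unroot(ape::read.tree(text = nwk)), "postorder")
}

#' Best tree under a monophyly constraint
#'
#' Builds a constraint-respecting start tree (neighbor joining within each
#' constrained set, then on set roots and free taxa with group-average
#' distances) and refines it by constraint-respecting NNI with branch-length
#' optimization.
#'
#' @inheritParams nni_search
#' @param constraint A [constraint_spec()].
#' @return List with `tree` and `loglik`.
#' @export
best_tree_under_constraint <- function(msa, model, constraint,
                                       weights = NULL, max_moves = 50L) {
  stopifnot(inherits(constraint, "constraint_spec"))
  taxa <- names(msa)
  for (s in constraint$sets) {
    missing <- setdiff(s, taxa)
    if (length(missing)) {
      stop("constraint '", constraint$name, "' names taxa absent from the ",
           "alignment: ", paste(missing, collapse = ", "))
    }
  }
  D <- pairwise_distances(msa)
  sets <- Filter(function(s) length(s) > 1L && length(s) < length(taxa),
                 constraint$sets)
  start <- constrained_nj(D, sets)
  if (!sets_monophyletic(start, sets)) {
    stop("internal error: constrained start tree violates constraint")
  }
  vacuous <- length(sets) == 0L
  nni_search(msa, start, model,
             constraint = if (vacuous) NULL else constraint_spec(constraint$name, sets),
             weights = weights, max_moves = max_moves)
}

#' Unconstrained ML-style tree search (NJ start + NNI)
#'
#' @inheritParams nni_search
#' @export
ml_tree <- function(msa, model, weights = NULL, max_moves = 50L) {
  D <- pairwise_distances(msa)
  start <- neighbor_joining(D)
  nni_search(msa, start, model, weights = weights, max_moves = max_moves)
}

#' Nonparametric bootstrap supports
#'
#' Resamples alignment columns with replacement; each replicate is analyzed
#' by neighbor joining (Poisson-corrected distances) followed, by default,
#' by NNI hill climbing on the replicate likelihood. Support of each
#' bipartition of the reference tree is the percentage of replicate trees
#' containing it.
#'
#' @inheritParams site_loglikelihoods
#' @param n_reps Number of replicates.
#' @param seed Integer seed (all resampling is derived from it).
#' @param search `"nj+nni"` (default) or `"nj"` (distance-only replicates,
#'   appropriate when many replicates are needed on larger trees).
#' @param nni_moves_per_rep Cap on accepted NNI moves per replicate.
#' @return The reference tree with `node.label` set to supports (0-100).
#' @export
bootstrap_support <- function(msa, tree, model, n_reps = 100L, seed = 1L,
                              search = c("nj+nni", "nj"),
                              nni_moves_per_rep = 5L) {
  search <- match.arg(search)
  stopifnot(n_reps >= 1L)
  msa <- as_msa(unclass(msa))
  code <- encode_alignment(msa)
  ncols <- ncol(code)
  set.seed(seed)
  rep_trees <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncols, ncols, replace = TRUE)
    codeb <- code[, idx, drop = FALSE]
    Db <- dist_from_code(codeb)
    tr <- neighbor_joining(Db)
    if (search == "nj+nni") {
      rep_rows <- apply(matrix(AA_ORDER[codeb], nrow = nrow(codeb)), 1L,
                        function(ch) paste(ifelse(is.na(ch), "-", ch),
                                           collapse = ""))
      rep_msa <- as_msa(setNames(rep_rows, rownames(code)))
      tr <- nni_search(rep_msa, tr, model, max_moves = nni_moves_per_rep,
                       optimize_start = TRUE)$tree
    }
    rep_trees[[b]] <- tr
  }
  ref <- stats::reorder(ape::unroot(tree), "postorder")
  counts <- ape::prop.clades(ref, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(round(100 * counts / n_reps, 1))
  # the root "bipartition" of an unrooted tree is not a split; no support
  ref$node.label[1L] <- NA_character_
  ref
}
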