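# Pairwise distances and neighbor joining.

#' Pairwise distances between aligned protein sequences
#'
#' Mismatch fractions are computed over mutually ungapped columns (gap and X
#' excluded). The Poisson correction is `d = -ln(1 - p)`; saturated pairs
#' (`p` at or beyond `p_max`) are capped at `p_max` so the correction stays
#' finite.
#'
#' @param msa An [as_msa()] alignment.
#' @param correction `"p"` (raw mismatch fraction) or `"poisson"`.
#' @param p_max Cap on the mismatch fraction before Poisson correction.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(msa, correction = c("poisson", "p"),
                               p_max = 0.999) {
  correction <- match.arg(correction)
  dist_from_code(encode_alignment(msa), match.arg(correction), p_max)
}

# distance matrix from an encoded alignment (integer codes, NA = gap/X);
# split out so bootstrap replicates can resample columns without
# re-encoding strings
#' @noRd
dist_from_code <- function(code, correction = "poisson", p_max = 0.999) {
  n <- nrow(code)
  D <- matrix(0, n, n, dimnames = list(rownames(code), rownames(code)))
  has_na <- anyNA(code)
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in (i + 1L):n) {
      xj <- code[j, ]
      if (has_na) {
        ok <- !is.na(xi) & !is.na(xj)
        if (!any(ok)) {
          stop("sequences ", rownames(code)[i], " and ", rownames(code)[j],
               " share no mutually ungapped column")
        }
        p <- mean(xi[ok] != xj[ok])
      } else {
        p <- mean(xi != xj)
      }
      d <- if (correction == "p") p else -log(1 - min(p, p_max))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration, exact on additive matrices. Ties in
#' the Q criterion are broken deterministically by the lexicographically
#' smallest (sorted) pair of clade names. Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch.
#'
#' @param D Symmetric distance matrix with row/column names.
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  stopifnot(!is.null(labels), !anyDuplicated(labels), nrow(D) >= 3L)
  if (any(grepl("[(),:;[:space:]]", labels))) {
    stop("taxon labels may not contain newick metacharacters or whitespace")
  }
  n0 <- nrow(D)
  # each active cluster holds a newick fragment and the name used for ties
  frag <- setNames(labels, labels)
  key <- setNames(labels, labels)    # lexicographic tie-break key
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-10 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_keys <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[rownames(D)[ij[1L]]], key[rownames(D)[ij[2L]]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pair_keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ni <- rownames(D)[i]; nj <- rownames(D)[j]
    new_name <- paste0("(", ni, ",", nj, ")")
    new_frag <- paste0("(", frag[[ni]], ":", fmt(li), ",",
                       frag[[nj]], ":", fmt(lj), ")")
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    rn <- c(rownames(D)[keep], new_name)
    dimnames(D2) <- list(rn, rn)
    D <- D2
    frag[[new_name]] <- new_frag
    key[[new_name]] <- min(key[[ni]], key[[nj]])
  }
  # terminal 3-cluster star: three-point formulas
  a <- rownames(D)[1L]; b <- rownames(D)[2L]; c_ <- rownames(D)[3L]
  la <- (D[a, b] + D[a, c_] - D[b, c_]) / 2
  lb <- (D[a, b] + D[b, c_] - D[a, c_]) / 2
  lc <- (D[a, c_] + D[b, c_] - D[a, b]) / 2
  nwk <- paste0("(", frag[[a]], ":", fmt(la), ",", frag[[b]], ":", fmt(lb),
                ",", frag[[c_]], ":", fmt(lc), ");")
  tr <- ape::read.tree(text = nwk)
  tr
}
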