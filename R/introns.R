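# Intron position homology and Dollo dating.
#
# Convention: an intron "belongs to" the codon it precedes. Its CDS offset
# (spliced nucleotides 5' of the intron) gives codon_index = offset %/% 3
# (0-based) and phase = offset %% 3, independent of strand because gene
# models expose introns in transcription order.

#' CDS position of one intron
#'
#' @param gm A [gene_model()].
#' @param intron_index 1-based index in transcription (5' to 3') order.
#' @return List with `cds_offset` (nucleotides 5' of the intron),
#'   `codon_index` (0-based), `phase` (0, 1 or 2).
#' @export
intron_cds_position <- function(gm, intron_index) {
  stopifnot(inherits(gm, "gene_model"))
  n <- nrow(gm$introns)
  if (intron_index < 1L || intron_index > n) {
    stop("gene ", gm$gene_id, " has ", n, " intron(s); index ", intron_index,
         " out of range")
  }
  exon_lens <- gm$exons[, 2L] - gm$exons[, 1L]
  if (gm$strand == "-") exon_lens <- rev(exon_lens)
  cds_offset <- sum(exon_lens[seq_len(intron_index)])
  list(cds_offset = as.integer(cds_offset),
       codon_index = as.integer(cds_offset %/% 3L),
       phase = as.integer(cds_offset %% 3L))
}

#' Project an intron position into alignment coordinates
#'
#' The site coordinate is the alignment column of the residue at
#' `codon_index`, paired with the phase; deletions in other rows cannot
#' shift it.
#'
#' @param column_map A [build_column_map()] result.
#' @param seq_id Alignment row of the intron's gene.
#' @param codon_index 0-based codon index from [intron_cds_position()].
#' @param phase Intron phase.
#' @return List with `column` (1-based alignment column) and `phase`.
#' @export
project_intron <- function(column_map, seq_id, codon_index, phase) {
  stopifnot(inherits(column_map, "column_map"))
  cm <- column_map[[seq_id]]
  if (is.null(cm)) stop("sequence ", seq_id, " not in column map")
  res <- codon_index + 1L              # residue carrying the intron
  if (res < 1L || res > length(cm$res2col)) {
    stop("codon index ", codon_index, " has no residue in row ", seq_id)
  }
  list(column = cm$res2col[[res]], phase = as.integer(phase))
}

#' Inverse projection: alignment column back to codon index
#' @inheritParams project_intron
#' @param column 1-based alignment column.
#' @export
unproject_intron <- function(column_map, seq_id, column) {
  cm <- column_map[[seq_id]]
  if (is.null(cm)) stop("sequence ", seq_id, " not in column map")
  res <- cm$col2res[[column]]
  if (is.na(res)) stop("column ", column, " is a gap in row ", seq_id)
  res - 1L
}

#' Cluster projected intron positions into homologous sites
#'
#' Sites sharing phase and alignment column (within `tolerance` columns,
#' single linkage) merge into one homologous intron site. Sites are labeled
#' `i1`, `i2`, ... by ascending column (5' to 3'). The default tolerance 0
#' requires exact column+phase identity.
#'
#' @param projections Tibble/data frame with columns `seq_id`, `column`,
#'   `phase` (one row per intron occurrence).
#' @param tolerance Column slack for merging (>= 0).
#' @return Tibble with `site`, `column`, `phase`, `carriers` (list-column),
#'   `n_carriers`.
#' @export
cluster_homologous_introns <- function(projections, tolerance = 0) {
  stopifnot(tolerance >= 0)
  pr <- tibble::as_tibble(projections)
  stopifnot(all(c("seq_id", "column", "phase") %in% names(pr)))
  if (nrow(pr) == 0L) {
    return(tibble::tibble(site = character(0), column = integer(0),
                          phase = integer(0), carriers = list(),
                          n_carriers = integer(0)))
  }
  out <- list()
  for (ph in sort(unique(pr$phase))) {
    sub <- pr[pr$phase == ph, ]
    sub <- sub[order(sub$column, sub$seq_id), ]
    # single-linkage along the column axis
    brk <- c(TRUE, diff(sub$column) > tolerance)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      rows <- sub[grp == g, ]
      if (anyDuplicated(rows$seq_id)) {
        stop("sequence ", rows$seq_id[duplicated(rows$seq_id)][1L],
             " contributes two introns to one cluster; tolerance too large")
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        column = as.integer(round(min(rows$column))),
        phase = as.integer(ph),
        carriers = list(sort(rows$seq_id)),
        n_carriers = nrow(rows)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$column, res$phase), ]
  res$site <- paste0("i", seq_len(nrow(res)))
  res[, c("site", "column", "phase", "carriers", "n_carriers")]
}

#' Dollo dating of an intron site
#'
#' Single-gain (Dollo) parsimony: the gain node is the MRCA of the carriers
#' on the species tree; the losses are the minimal set of branches below it
#' whose removal explains every absence — the stems of the maximal
#' carrier-free subtrees under the gain node.
#'
#' @param species_tree Rooted `phylo`.
#' @param carriers Tip labels carrying the intron (non-empty).
#' @return List with `gain_node` (node id), `gain_clade` (tips below it),
#'   `loss_branches` (list of lost tip sets), `n_losses`.
#' @export
dollo_date <- function(species_tree, carriers) {
  stopifnot(length(carriers) >= 1L)
  unknown <- setdiff(carriers, species_tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  }
  tree <- stats::reorder(species_tree, "postorder")
  node <- mrca_of(tree, carriers)
  below <- node_tipsets(tree)
  gain_clade <- below[[node]]
  edge <- tree$edge
  losses <- list()
  covered <- character(0)
  # preorder below the gain node: a branch is a loss iff its subtree holds
  # no carrier and its parent's subtree does (maximality)
  for (e in rev(seq_len(nrow(edge)))) {
    ts <- below[[edge[e, 2L]]]
    if (!all(ts %in% gain_clade) || length(ts) == length(gain_clade)) next
    if (length(intersect(ts, carriers))) next
    if (all(ts %in% covered)) next
    losses[[length(losses) + 1L]] <- ts
    covered <- union(covered, ts)
  }
  list(gain_node = node, gain_clade = gain_clade,
       loss_branches = losses, n_losses = length(losses))
}

#' Intron presence/absence matrix with Dollo dating
#'
#' Combines gene models, the protein alignment, and the species tree into
#' the per-species intron table: `1` carrier, `0` gene present but intron
#' absent, `-` gene absent; plus the inferred gain clade and loss count per
#' site.
#'
#' @param gene_models Named list of [gene_model()]s (names = species with
#'   the gene).
#' @param msa Protein alignment including every modeled species.
#' @param species_tree Rooted species tree (tips a superset of the modeled
#'   species).
#' @param species Optional full species set for the table rows (defaults to
#'   the eukaryote tips of the tree present in the alignment).
#' @param tolerance Column tolerance for [cluster_homologous_introns()].
#' @return Object of class `intron_matrix`: list with `table` (tibble,
#'   rows = species), `sites` (per-site tibble with carriers, gain clade,
#'   losses), `matrix` (character matrix of 1/0/-).
#' @export
intron_matrix <- function(gene_models, msa, species_tree, species = NULL,
                          tolerance = 0) {
  msa <- as_msa(unclass(msa))
  cmap <- build_column_map(msa)
  with_gene <- names(gene_models)
  species <- species %||% intersect(species_tree$tip.label, names(msa))
  proj <- list()
  for (sp in with_gene) {
    gm <- gene_models[[sp]]
    n <- nrow(gm$introns)
    if (n == 0L) next
    for (i in seq_len(n)) {
      pos <- intron_cds_position(gm, i)
      pj <- project_intron(cmap, sp, pos$codon_index, pos$phase)
      proj[[length(proj) + 1L]] <- tibble::tibble(
        seq_id = sp, column = pj$column, phase = pj$phase
      )
    }
  }
  proj <- if (length(proj)) dplyr::bind_rows(proj) else {
    tibble::tibble(seq_id = character(0), column = integer(0),
                   phase = integer(0))
  }
  sites <- cluster_homologous_introns(proj, tolerance = tolerance)
  dollo <- lapply(sites$carriers, function(cs) {
    dollo_date(species_tree, intersect(cs, species_tree$tip.label))
  })
  sites$gain_clade <- lapply(dollo, `[[`, "gain_clade")
  sites$n_losses <- vapply(dollo, `[[`, integer(1), "n_losses")

  mat <- matrix("-", nrow = length(species), ncol = nrow(sites),
                dimnames = list(species, sites$site))
  mat[intersect(species, with_gene), ] <- "0"
  for (j in seq_len(nrow(sites))) {
    carr <- intersect(sites$carriers[[j]], species)
    mat[carr, j] <- "1"
  }
  table <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                             rownames = "species")
  structure(list(table = table, sites = sites, matrix = mat),
            class = "intron_matrix")
}

#' @export
print.intron_matrix <- function(x, ...) {
  cat("<intron_matrix> ", nrow(x$matrix), " species x ", ncol(x$matrix),
      " intron site(s)\n", sep = "")
  print(x$table, n = 10)
  invisible(x)
}

#' Rank intron sites by phylogenetic breadth
#'
#' A site shared among more eukaryote supergroups is inferred to be older.
#' Breadth = number of supergroups represented among carriers; ties break
#' by 5'-to-3' column order.
#'
#' @param im An [intron_matrix()].
#' @param taxonomy Taxonomy tibble covering all carriers.
#' @return Tibble `site`, `column`, `phase`, `n_carriers`, `breadth`,
#'   `supergroups` (list), `n_losses`, `age_rank` (1 = oldest), plus a
#'   `statement` column summarizing each site.
#' @export
intron_age_report <- function(im, taxonomy) {
  stopifnot(inherits(im, "intron_matrix"))
  tax <- as_taxonomy(taxonomy)
  sgof <- setNames(tax$supergroup, tax$seq_id)
  sites <- im$sites
  missing <- setdiff(unlist(sites$carriers), tax$seq_id)
  if (length(missing)) {
    stop("taxonomy missing carrier(s): ", paste(missing, collapse = ", "))
  }
  sites$supergroups <- lapply(sites$carriers,
                              function(cs) sort(unique(unname(sgof[cs]))))
  sites$breadth <- lengths(sites$supergroups)
  ord <- order(-sites$breadth, sites$column, sites$phase)
  sites$age_rank <- NA_integer_
  sites$age_rank[ord] <- seq_len(nrow(sites))
  sites$statement <- vapply(seq_len(nrow(sites)), function(j) {
    sprintf("%s is shared among %d lineage(s) (%s); %d carrier(s), %d inferred loss branch(es)",
            sites$site[j], sites$breadth[j],
            paste(sites$supergroups[[j]], collapse = ", "),
            sites$n_carriers[j], sites$n_losses[j])
  }, character(1))
  tibble::as_tibble(sites[order(sites$age_rank),
                          c("site", "column", "phase", "n_carriers", "breadth",
                            "supergroups", "n_losses", "age_rank", "statement")])
}

#' Write an intron presence/absence matrix as TSV
#' @param im An [intron_matrix()].
#' @param path Output path.
#' @export
write_intron_matrix <- function(im, path) {
  utils::write.table(im$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.intron_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(object$table, -"species",
                            names_to = "site", values_to = "state")
  df$site <- factor(df$site, levels = colnames(object$matrix))
  df$species <- factor(df$species, levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$species,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::scale_fill_manual(values = c(`1` = "black", `0` = "grey85",
                                          `-` = "white"),
                               labels = c(`1` = "intron present",
                                          `0` = "intron absent",
                                          `-` = "gene absent")) +
    ggplot2::labs(x = "homologous intron site (5' to 3')", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
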