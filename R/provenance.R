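# Evidence extraction from the gene tree + tests + introns + composition,
# and the deterministic scenario classifier.
#
# Scenarios: a vertical (LECA) + losses; b endosymbiotic transfer;
# c prokaryote->eukaryote HGT + losses; d = c + eukaryote->eukaryote HGTs;
# e independent HGTs from distinct donors.

#' @noRd
maximal_euk_clades <- function(tree, is_euk_tip) {
  # maximal clades whose tips are all eukaryotic, on the rooted tree
  tree <- stats::reorder(tree, "postorder")
  below <- node_tipsets(tree)
  ntip <- length(tree$tip.label)
  all_euk <- vapply(below, function(ts) all(is_euk_tip[ts]), logical(1))
  edge <- tree$edge
  parent_of <- rep(NA_integer_, ntip + tree$Nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  clades <- list()
  for (nd in seq_along(below)) {
    if (!all_euk[nd]) next
    p <- parent_of[nd]
    if (is.na(p) || !all_euk[p]) clades[[length(clades) + 1L]] <- below[[nd]]
  }
  clades[order(-lengths(clades))]
}

# Rooting-free placement of a clade: look at the attachment point of the
# clade in the (arbitrarily rooted representation of the) tree and
# decompose the rest of the tree into the subtrees adjacent to it. The
# clade is nested inside a prokaryote clade X iff one adjacent side is a
# PROPER subset of X's tips (the attachment edge lies strictly within X);
# attachment on the backbone, or on a clade's stem, is "outside".
#' @noRd
attachment_sides <- function(tree, clade) {
  tree <- stats::reorder(tree, "postorder")
  below <- node_tipsets(tree)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  all_tips <- tree$tip.label
  keys <- vapply(below, function(s) paste(sort(s), collapse = "\r"),
                 character(1))
  k_clade <- paste(sort(clade), collapse = "\r")
  k_comp <- paste(sort(setdiff(all_tips, clade)), collapse = "\r")
  supports <- node_supports(tree)
  parent_of <- rep(NA_integer_, ntip + tree$Nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  sides <- NULL
  support <- NA_real_
  if (k_clade %in% keys) {
    nd <- which(keys == k_clade)[1L]
    p <- parent_of[nd]
    if (is.na(p)) return(NULL)          # clade is the whole tree
    sibs <- setdiff(edge[edge[, 1L] == p, 2L], nd)
    sides <- lapply(sibs, function(s) below[[s]])
    above <- setdiff(all_tips, c(clade, unlist(sides)))
    if (length(above)) sides <- c(sides, list(above))
    if (nd > ntip) support <- supports[nd - ntip]
  } else if (k_comp %in% keys) {
    nd <- which(keys == k_comp)[1L]     # clade spans the root; complement
    kids <- edge[edge[, 1L] == nd, 2L]  # is a clade: its children are the sides
    sides <- lapply(kids, function(s) below[[s]])
    if (nd > ntip) support <- supports[nd - ntip]
  } else {
    return(NULL)                        # clade is not a split of the tree
  }
  list(sides = sides, support = support)
}

# donor context of one eukaryote clade: NA when the clade attaches outside
# all prokaryote clades, otherwise the supergroup it is nested inside
#' @noRd
clade_donor_context <- function(tree, clade, sg, prok_groups) {
  at <- attachment_sides(tree, clade)
  if (is.null(at)) return(list(donor = NA_character_, support = NA_real_))
  for (side in at$sides) {
    gs <- unique(sg[side])
    if (length(gs) == 1L && gs %in% prok_groups) {
      full <- names(sg)[sg == gs]
      full <- intersect(full, tree$tip.label)
      if (length(side) < length(full)) {
        return(list(donor = gs, support = at$support))
      }
    }
  }
  list(donor = NA_character_, support = at$support)
}

#' @noRd
detect_outliers <- function(tree, taxonomy, support_threshold = 50) {
  tree <- stats::reorder(tree, "postorder")
  tax <- as_taxonomy(taxonomy)
  sg <- setNames(tax$supergroup, tax$seq_id)
  dom <- setNames(tax$domain, tax$seq_id)
  is_euk <- setNames(dom[tree$tip.label] == "eukaryote", tree$tip.label)
  below <- node_tipsets(tree)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  supports <- node_supports(tree)
  parent_of <- rep(NA_integer_, ntip + tree$Nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  out <- list()
  for (i in which(is_euk[tree$tip.label])) {
    tp <- tree$tip.label[i]
    a <- parent_of[i]
    others <- character(0)
    while (!is.na(a)) {
      others <- setdiff(below[[a]], tp)
      others <- others[is_euk[others]]
      if (length(others)) break
      a <- parent_of[a]
    }
    if (!length(others) || is.na(a)) next
    sup <- supports[a - ntip]
    if (is.na(sup) || sup < support_threshold) next
    grp <- table(sg[others])
    dom_grp <- names(grp)[which.max(grp)]
    if (dom_grp == sg[[tp]]) next
    if (max(grp) <= length(others) / 2) next
    # "surrounded" check: the enclosing clade's parent holds further tips of
    # the dominating supergroup (rules out a mere sister-to-clade position)
    p <- parent_of[a]
    if (is.na(p)) next
    beyond <- setdiff(below[[p]], below[[a]])
    if (!any(sg[beyond[is_euk[beyond]]] %in% dom_grp)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      tip = tp, own_group = unname(sg[[tp]]), nested_in = dom_grp,
      support = sup
    )
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(tip = character(0), own_group = character(0),
                   nested_in = character(0), support = numeric(0))
  }
}

#' Extract the evidence bundle for scenario classification
#'
#' Computes, from a rooted gene tree with supports and the companion
#' analyses: eukaryote monophyly (and its support), placement of the
#' eukaryote clade relative to the prokaryote clades, the number of maximal
#' eukaryote-only clades and the donor context of each, outlier eukaryote
#' tips nesting inside another supergroup's clade, the AU p-value per named
#' constraint, the breadth of the oldest intron site, and the composition
#' verdict.
#'
#' @param gene_tree Rooted `phylo` with bootstrap supports in `node.label`.
#' @param taxonomy Taxonomy tibble covering every tip.
#' @param au_results Optional [run_topology_tests()] result (or its tidied
#'   table) with an `egt_grouping` candidate.
#' @param intron_report Optional [intron_age_report()] tibble.
#' @param composition Optional [amelioration_placement()] profile.
#' @param support_threshold Bootstrap support needed before a clade counts
#'   as "well supported" in outlier detection.
#' @return Object of class `evidence_bundle`.
#' @export
extract_evidence <- function(gene_tree, taxonomy, au_results = NULL,
                             intron_report = NULL, composition = NULL,
                             support_threshold = 50) {
  tax <- as_taxonomy(taxonomy)
  gaps <- setdiff(gene_tree$tip.label, tax$seq_id)
  if (length(gaps)) {
    stop("taxonomy missing tip(s): ", paste(gaps, collapse = ", "))
  }
  if (is.null(attr(gene_tree, "order")) || ape::is.rooted(gene_tree) == FALSE) {
    gene_tree <- midpoint_root(gene_tree)
  }
  gene_tree <- stats::reorder(gene_tree, "postorder")
  dom <- setNames(tax$domain, tax$seq_id)
  sg <- setNames(tax$supergroup, tax$seq_id)
  is_euk <- setNames(dom[gene_tree$tip.label] == "eukaryote",
                     gene_tree$tip.label)
  euk_tips <- names(is_euk)[is_euk]
  if (!length(euk_tips)) stop("gene tree carries no eukaryote tips")

  # monophyly judged on the unrooted topology so the verdict cannot depend
  # on where the midpoint root happened to fall
  mono <- length(euk_tips) == 1L ||
    sets_monophyletic(gene_tree, list(euk_tips))
  clades <- if (mono) list(euk_tips) else
    maximal_euk_clades(gene_tree, is_euk)
  n_euk_clades <- length(clades)
  prok_groups <- unique(sg[names(is_euk)[!is_euk]])
  contexts <- lapply(clades, function(cl) {
    clade_donor_context(gene_tree, cl, sg, prok_groups)
  })
  donor_of <- vapply(contexts, `[[`, character(1), "donor")
  mono_support <- if (mono) contexts[[1L]]$support else NA_real_
  placement <- if (is.na(donor_of[[1L]])) {
    "outside_all_prokaryotes"
  } else {
    "nested_in_prokaryotes"
  }
  main_ctx <- contexts[[1L]]

  au_p <- NULL
  if (!is.null(au_results)) {
    tb <- if (inherits(au_results, "au_test")) au_results$table else
      tibble::as_tibble(au_results)
    au_p <- setNames(tb$au_p, tb$candidate)
  }
  outlier_tbl <- detect_outliers(gene_tree, tax, support_threshold)
  breadth <- if (is.null(intron_report) || nrow(intron_report) == 0L) {
    NA_integer_
  } else {
    max(intron_report$breadth)
  }
  comp_verdict <- if (is.null(composition)) NA_character_ else
    composition$verdict[[1L]]

  structure(
    list(euk_monophyly = mono, euk_monophyly_support = mono_support,
         placement = placement, enclosing_support = main_ctx$support,
         n_euk_clades = n_euk_clades, euk_clades = clades,
         euk_clade_donors = donor_of, au_p = au_p,
         outliers = outlier_tbl$tip, outlier_table = outlier_tbl,
         oldest_intron_breadth = breadth,
         composition_verdict = comp_verdict,
         n_euk_carriers = length(euk_tips),
         support_threshold = support_threshold),
    class = "evidence_bundle"
  )
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat("<evidence_bundle>\n",
      "  eukaryote monophyly: ", x$euk_monophyly,
      " (support ", x$euk_monophyly_support, ")\n",
      "  placement: ", x$placement, "\n",
      "  maximal eukaryote clades: ", x$n_euk_clades,
      " (donors: ", paste(x$euk_clade_donors, collapse = ", "), ")\n",
      "  outliers: ", if (length(x$outliers)) paste(x$outliers, collapse = ", ")
      else "none", "\n",
      "  oldest intron breadth: ", x$oldest_intron_breadth, "\n",
      "  composition: ", x$composition_verdict, "\n", sep = "")
  if (!is.null(x$au_p)) {
    cat("  AU p-values: ",
        paste(names(x$au_p), sprintf("%.3g", x$au_p), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Classify the five origin scenarios from an evidence bundle
#'
#' A fixed, ordered rule pass (deterministic and auditable):
#' \describe{
#'   \item{R1}{two or more eukaryote clades, each nested among prokaryotes
#'     (distinct donor contexts): independent HGTs — e supported, a-d
#'     rejected.}
#'   \item{R2}{eukaryote clade outside all prokaryote clades: vertical
#'     presence plausible; nested placement rejects it.}
#'   \item{R3}{the constraint grouping the eukaryote homologs with
#'     alpha-proteobacteria not rejected by the AU test (p >= alpha):
#'     endosymbiotic transfer plausible, otherwise rejected.}
#'   \item{R4}{nested placement with eukaryote monophyly: single HGT with
#'     losses (c) and HGT plus eukaryote transfers (d) both plausible.}
#'   \item{R5}{outlier tips nesting inside another supergroup's clade:
#'     upgrade d to supported (c stays plausible).}
#'   \item{R6}{oldest intron shared by >= `ancient_breadth` supergroups:
#'     annotate the acquisition as ancient.}
#'   \item{R7}{host-like composition annotates ancient; donor-like,
#'     recent.}
#' }
#' Missing fields skip their rules with a logged notice. Ranking:
#' supported > plausible > rejected, ties by scenario letter.
#'
#' @param evidence An [extract_evidence()] bundle.
#' @param alpha Rejection threshold for the AU test.
#' @param ancient_breadth Supergroup breadth counting as "ancient".
#' @return Object of class `scenario_verdict` with `status`, `rationale`,
#'   `ranking`, `primary`, `annotations`, and the rule `trace`.
#' @export
classify_scenarios <- function(evidence, alpha = 0.05, ancient_breadth = 3L) {
  stopifnot(inherits(evidence, "evidence_bundle"))
  sc <- c("a", "b", "c", "d", "e")
  status <- setNames(rep("rejected", 5L), sc)
  rationale <- setNames(vector("list", 5L), sc)
  note <- function(s, msg) rationale[[s]] <<- c(rationale[[s]], msg)
  trace <- list()
  log_rule <- function(rule, fired, value, effect) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      rule = rule, fired = fired, value = value, effect = effect
    )
  }
  annotations <- character(0)

  # R1: independent transfers
  nested_clades <- sum(!is.na(evidence$euk_clade_donors))
  r1 <- evidence$n_euk_clades >= 2L &&
    nested_clades == evidence$n_euk_clades
  log_rule("R1", r1,
           sprintf("n_euk_clades=%d, donor contexts: %s",
                   evidence$n_euk_clades,
                   paste(evidence$euk_clade_donors, collapse = ", ")),
           if (r1) "e supported; a-d rejected" else "e rejected")
  if (r1) {
    status["e"] <- "supported"
    note("e", sprintf(
      "%d separate eukaryote clades, each nested among prokaryotes (%s): independent acquisitions",
      evidence$n_euk_clades,
      paste(evidence$euk_clade_donors, collapse = " / ")))
    for (s in c("a", "b", "c", "d")) {
      note(s, "rejected: eukaryote homologs do not form a single clade, so a single origin cannot explain them")
    }
  } else {
    note("e", sprintf(
      "rejected: eukaryote homologs form %d clade(s)%s, not two independently nested groups",
      evidence$n_euk_clades,
      if (evidence$euk_monophyly) " (monophyletic)" else ""))

    # R2: vertical / LECA
    outside <- evidence$placement == "outside_all_prokaryotes"
    log_rule("R2", outside, sprintf("placement=%s", evidence$placement),
             if (outside) "a plausible" else "a rejected")
    if (outside) {
      status["a"] <- "plausible"
      note("a", "eukaryote clade sits outside all prokaryote clades, as expected for presence in the LECA")
    } else {
      note("a", "rejected: eukaryote clade is nested within prokaryote clades, not outside them")
    }

    # R3: endosymbiotic transfer, via the AU test on the EGT constraint
    egt_p <- if (!is.null(evidence$au_p) &&
                 "egt_grouping" %in% names(evidence$au_p)) {
      evidence$au_p[["egt_grouping"]]
    } else {
      NA_real_
    }
    if (is.na(egt_p)) {
      log_rule("R3", NA, "egt_grouping AU p missing", "skipped (missing)")
      note("b", "no AU result for the alpha-proteobacteria grouping; endosymbiotic transfer not assessed")
      status["b"] <- "rejected"
    } else {
      r3 <- egt_p >= alpha
      log_rule("R3", r3, sprintf("AU p(egt_grouping)=%.4g", egt_p),
               if (r3) "b plausible" else "b rejected")
      if (r3) {
        status["b"] <- "plausible"
        note("b", sprintf(
          "grouping the eukaryote homologs with alpha-proteobacteria is not rejected (AU p = %.3g >= %.2g)",
          egt_p, alpha))
      } else {
        note("b", sprintf(
          "rejected: the alpha-proteobacteria grouping is rejected by the AU test (p = %.3g < %.2g)",
          egt_p, alpha))
      }
    }

    # R4: single HGT (with losses / with eukaryote transfers)
    r4 <- !outside && evidence$euk_monophyly
    log_rule("R4", r4,
             sprintf("placement=%s, euk_monophyly=%s", evidence$placement,
                     evidence$euk_monophyly),
             if (r4) "c and d plausible" else "c and d unchanged")
    if (r4) {
      status["c"] <- "plausible"
      status["d"] <- "plausible"
      note("c", "monophyletic eukaryote clade nested among prokaryotes: one transfer followed by losses can explain the distribution")
      note("d", "monophyletic eukaryote clade nested among prokaryotes: one transfer followed by eukaryote-to-eukaryote transfers can explain the distribution")
    } else if (!outside) {
      note("c", "rejected: eukaryote homologs are not monophyletic, so a single transfer does not explain them")
      note("d", "rejected: eukaryote homologs are not monophyletic, so a single transfer does not explain them")
    } else {
      note("c", "rejected: eukaryote clade is not nested within prokaryotes; no transfer needed")
      note("d", "rejected: eukaryote clade is not nested within prokaryotes; no transfer needed")
    }

    # R5: outliers upgrade d
    r5 <- r4 && length(evidence$outliers) > 0L
    log_rule("R5", r5,
             sprintf("%d outlier tip(s)%s", length(evidence$outliers),
                     if (length(evidence$outliers)) {
                       paste0(": ", paste(evidence$outliers, collapse = ", "))
                     } else ""),
             if (r5) "d supported; c plausible" else "no upgrade")
    if (r5) {
      status["d"] <- "supported"
      note("d", sprintf(
        "supported: tip(s) %s nest inside another supergroup's clade, the signature of eukaryote-to-eukaryote transfer",
        paste(evidence$outliers, collapse = ", ")))
      note("c", "demoted below d: explaining the outlier tips under c alone requires extra independent losses, making d the more parsimonious account")
    }
  }

  # R6: intron breadth annotation
  br <- evidence$oldest_intron_breadth
  if (is.na(br)) {
    log_rule("R6", NA, "intron breadth missing", "skipped (missing)")
  } else {
    r6 <- br >= ancient_breadth
    log_rule("R6", r6, sprintf("oldest intron breadth=%d", br),
             if (r6) "acquisition annotated ancient" else "no annotation")
    if (r6) {
      annotations <- c(annotations, sprintf(
        "ancient acquisition: the oldest intron site is shared across %d supergroups",
        br))
    }
  }

  # R7: composition annotation
  cv <- evidence$composition_verdict
  if (is.na(cv)) {
    log_rule("R7", NA, "composition verdict missing", "skipped (missing)")
  } else {
    log_rule("R7", cv != "ambiguous", sprintf("composition=%s", cv),
             switch(cv,
                    "host-like" = "acquisition annotated ancient (ameliorated)",
                    "donor-like" = "acquisition annotated recent",
                    "no annotation"))
    if (cv == "host-like") {
      annotations <- c(annotations,
                       "GC/codon usage ameliorated to the host: consistent with an ancient acquisition")
    } else if (cv == "donor-like") {
      annotations <- c(annotations,
                       "GC still donor-like: consistent with a recent acquisition")
    }
  }

  if (all(status == "rejected")) {
    # guard: the bundle matched no scenario cleanly; the irregular pattern
    # is still best covered by transfers among eukaryotes
    status["d"] <- "plausible"
    note("d", "no rule matched cleanly; the irregular distribution is provisionally assigned to HGT with eukaryote-to-eukaryote transfers")
  }
  score <- c(rejected = 0, plausible = 1, supported = 2)[status]
  ranking <- sc[order(-score, sc)]
  structure(
    list(status = status,
         rationale = lapply(rationale, function(r) r %||% character(0)),
         ranking = ranking, primary = ranking[[1L]],
         annotations = annotations,
         trace = dplyr::bind_rows(trace)),
    class = "scenario_verdict"
  )
}

#' @export
print.scenario_verdict <- function(x, ...) {
  cat("<scenario_verdict> primary: scenario ", x$primary, "\n", sep = "")
  for (s in x$ranking) {
    cat("  ", s, " [", x$status[[s]], "] ",
        paste(x$rationale[[s]], collapse = "; "), "\n", sep = "")
  }
  if (length(x$annotations)) {
    cat("  annotations: ", paste(x$annotations, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scenario_verdict <- function(x, ...) {
  tibble::tibble(
    scenario = names(x$status),
    status = unname(x$status),
    rank = match(names(x$status), x$ranking),
    rationale = vapply(x$rationale, paste, character(1), collapse = "; ")
  )
}

#' @exportS3Method generics::glance
glance.scenario_verdict <- function(x, ...) {
  tibble::tibble(primary = x$primary,
                 n_supported = sum(x$status == "supported"),
                 n_plausible = sum(x$status == "plausible"),
                 n_rejected = sum(x$status == "rejected"))
}

#' Render a scenario verdict as a Markdown report
#'
#' Byte-deterministic for identical inputs: evidence table, rule trace
#' (which rule fired on which value), ranked verdict, annotations.
#'
#' @param verdict A [classify_scenarios()] verdict.
#' @param evidence The [extract_evidence()] bundle it was computed from.
#' @param node_dates Optional tibble (`node`, `age_mya`) of user-supplied
#'   literature dates attached as annotations, never computed.
#' @return Character vector of Markdown lines (invisibly printable via
#'   `cat(..., sep = "\n")`).
#' @export
scenario_report <- function(verdict, evidence, node_dates = NULL) {
  stopifnot(inherits(verdict, "scenario_verdict"),
            inherits(evidence, "evidence_bundle"))
  lines <- c(
    "# Gene provenance report",
    "",
    "## Evidence",
    "",
    "| field | value |",
    "|---|---|",
    sprintf("| eukaryote monophyly | %s (support %s) |",
            evidence$euk_monophyly,
            format(evidence$euk_monophyly_support)),
    sprintf("| placement | %s |", evidence$placement),
    sprintf("| maximal eukaryote clades | %d |", evidence$n_euk_clades),
    sprintf("| donor contexts | %s |",
            paste(evidence$euk_clade_donors, collapse = ", ")),
    sprintf("| outlier tips | %s |",
            if (length(evidence$outliers))
              paste(evidence$outliers, collapse = ", ") else "none"),
    sprintf("| oldest intron breadth | %s supergroup(s) |",
            format(evidence$oldest_intron_breadth)),
    sprintf("| composition | %s |", format(evidence$composition_verdict))
  )
  if (!is.null(evidence$au_p)) {
    lines <- c(lines, sprintf("| AU p (%s) | %.4g |",
                              names(evidence$au_p), evidence$au_p))
  }
  lines <- c(lines, "", "## Rule trace", "",
             "| rule | fired | value | effect |", "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |", verdict$trace$rule,
                     format(verdict$trace$fired), verdict$trace$value,
                     verdict$trace$effect),
             "", "## Verdict", "")
  for (s in verdict$ranking) {
    lines <- c(lines, sprintf("%d. **scenario %s** (%s): %s",
                              match(s, verdict$ranking), s,
                              verdict$status[[s]],
                              paste(verdict$rationale[[s]], collapse = "; ")))
  }
  if (length(verdict$annotations)) {
    lines <- c(lines, "", "## Annotations", "",
               paste0("- ", verdict$annotations))
  }
  if (!is.null(node_dates) && nrow(node_dates)) {
    lines <- c(lines, "", "## Literature dates (user-supplied annotations)", "",
               sprintf("- %s: ~%s MYA", node_dates$node, node_dates$age_mya))
  }
  lines
}
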