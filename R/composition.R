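# GC content, codon usage, and amelioration evidence: does a candidate
# gene's composition track its host (ancient acquisition) or its putative
# donor clade (recent acquisition)?

#' GC content of a nucleotide sequence
#'
#' Fraction of G+C among counted positions; N and other ambiguity codes are
#' excluded from both numerator and denominator (a message is emitted when
#' they exceed 1% of the sequence).
#'
#' @param cds A single nucleotide string.
#' @return Fraction in \[0,1\].
#' @export
gc_content <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L, nchar(cds) > 0L)
  chars <- strsplit(toupper(cds), "")[[1]]
  counted <- chars %in% c("A", "C", "G", "T")
  if (mean(!counted) > 0.01) {
    message(sprintf("%.1f%% ambiguous bases excluded from GC calculation",
                    100 * mean(!counted)))
  }
  if (!any(counted)) stop("no unambiguous bases to count")
  sum(chars[counted] %in% c("G", "C")) / sum(counted)
}

#' Third-codon-position GC content
#' @param cds CDS string, length divisible by 3.
#' @export
gc3 <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  chars <- strsplit(toupper(cds), "")[[1]]
  third <- chars[seq(3L, length(chars), by = 3L)]
  counted <- third %in% c("A", "C", "G", "T")
  if (!any(counted)) stop("no unambiguous third positions")
  sum(third[counted] %in% c("G", "C")) / sum(counted)
}

#' Codon usage table of one or more CDSs
#'
#' Counts codons in frame, dropping stop codons and codons with ambiguity
#' characters. An internal (non-terminal) stop codon is an error.
#'
#' @param cds Character vector of CDS strings (lengths divisible by 3).
#' @param label Source label stored on the table.
#' @return Tibble `aa`, `codon`, `count`, `freq` (within the amino acid's
#'   synonymous family), `rscu`; class `codon_usage`.
#' @export
codon_usage <- function(cds, label = "gene") {
  stopifnot(is.character(cds), length(cds) >= 1L)
  all_codons <- character(0)
  for (s in toupper(cds)) {
    if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3")
    cods <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    is_stop <- !is.na(match(cods, names(GENETIC_CODE_TABLE))) &
      GENETIC_CODE_TABLE[cods] == "*"
    if (any(is_stop[-length(cods)])) {
      stop("internal stop codon at codon ", which(is_stop)[1L])
    }
    all_codons <- c(all_codons, cods[!is_stop])
  }
  sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  counts <- table(factor(all_codons, levels = sense))
  df <- tibble::tibble(
    aa = unname(GENETIC_CODE_TABLE[sense]),
    codon = sense,
    count = as.integer(counts)
  )
  df <- dplyr::group_by(df, .data$aa)
  df <- dplyr::mutate(
    df,
    family_size = dplyr::n(),
    family_total = sum(.data$count),
    freq = ifelse(.data$family_total > 0, .data$count / .data$family_total, NA_real_),
    rscu = ifelse(.data$family_total > 0,
                  .data$count / (.data$family_total / .data$family_size),
                  NA_real_)
  )
  df <- dplyr::ungroup(df)
  df <- df[, c("aa", "codon", "count", "freq", "rscu")]
  attr(df, "label") <- label
  class(df) <- c("codon_usage", class(df))
  df
}

#' Relative synonymous codon usage
#'
#' `RSCU(codon) = count / (family total / family size)`; values average 1
#' within each synonymous family that occurs.
#'
#' @inheritParams codon_usage
#' @return The [codon_usage()] tibble (which carries the `rscu` column).
#' @export
rscu <- function(cds, label = "gene") {
  codon_usage(cds, label = label)
}

#' Preferred-codon concordance between a gene and its host
#'
#' For every multi-codon amino acid with at least `min_count` occurrences
#' in the gene: does the gene's modal codon equal the host's modal codon?
#' Ties within the gene are reported as ties; exceptions list the rank of
#' the gene's modal codon in the host table.
#'
#' @param gene_table,host_table [codon_usage()] tables.
#' @param min_count Minimum occurrences of the amino acid in the gene.
#' @return List with `fraction` (concordant / evaluated), `n_evaluated`,
#'   `exceptions` (tibble: aa, gene_codon, host_codon, host_rank, tie).
#' @export
preferred_codon_concordance <- function(gene_table, host_table,
                                        min_count = 5L) {
  stopifnot(inherits(gene_table, "codon_usage"),
            inherits(host_table, "codon_usage"))
  multi <- unique(gene_table$aa[duplicated(gene_table$aa)])
  ok_aa <- vapply(multi, function(a) {
    sum(gene_table$count[gene_table$aa == a]) >= min_count
  }, logical(1))
  eval_aa <- multi[ok_aa]
  if (!length(eval_aa)) stop("no multi-codon amino acid reaches min_count")
  concordant <- 0L
  exceptions <- list()
  for (a in sort(eval_aa)) {
    g <- gene_table[gene_table$aa == a, ]
    h <- host_table[host_table$aa == a, ]
    if (sum(h$count) == 0L) {
      stop("host table has no occurrences of amino acid ", a)
    }
    gmax <- g$count == max(g$count)
    tie <- sum(gmax) > 1L
    gene_modal <- g$codon[gmax]
    host_ranked <- h$codon[order(-h$count, h$codon)]
    host_modal <- host_ranked[1L]
    if (!tie && gene_modal == host_modal) {
      concordant <- concordant + 1L
    } else if (tie && host_modal %in% gene_modal) {
      # modal tie that includes the host's preferred codon: report, and
      # count as concordant (the host codon is used maximally)
      concordant <- concordant + 1L
      exceptions[[length(exceptions) + 1L]] <- tibble::tibble(
        aa = a, gene_codon = paste(gene_modal, collapse = "/"),
        host_codon = host_modal, host_rank = 1L, tie = TRUE
      )
    } else {
      gm <- gene_modal[1L]
      exceptions[[length(exceptions) + 1L]] <- tibble::tibble(
        aa = a, gene_codon = paste(gene_modal, collapse = "/"),
        host_codon = host_modal,
        host_rank = match(gm, host_ranked), tie = tie
      )
    }
  }
  list(
    fraction = concordant / length(eval_aa),
    n_evaluated = length(eval_aa),
    exceptions = if (length(exceptions)) dplyr::bind_rows(exceptions) else
      tibble::tibble(aa = character(0), gene_codon = character(0),
                     host_codon = character(0), host_rank = integer(0),
                     tie = logical(0))
  )
}

#' Place a gene's GC between host and donor backgrounds
#'
#' z-scores the gene's GC against the host and donor background GC
#' distributions. Verdict: `"host-like"` if `|z_host| < |z_donor|`,
#' `"donor-like"` otherwise, `"ambiguous"` when the gene value sits inside
#' both distributions (`|z| < 1` for both).
#'
#' @param gene_gc Gene GC fraction.
#' @param host_gene_gcs,donor_gene_gcs Numeric vectors (>= 2 values each)
#'   of background gene GC fractions.
#' @return Object of class `composition_profile` (a one-row tibble with
#'   `gene_gc`, host/donor means and sds, `z_host`, `z_donor`, `verdict`).
#' @export
amelioration_placement <- function(gene_gc, host_gene_gcs, donor_gene_gcs) {
  stopifnot(is_scalar_number(gene_gc),
            length(host_gene_gcs) >= 2L, length(donor_gene_gcs) >= 2L)
  hsd <- sd(host_gene_gcs); dsd <- sd(donor_gene_gcs)
  if (hsd == 0 || dsd == 0) {
    stop("zero standard deviation in a background set; supply a larger or ",
         "more diverse background")
  }
  z_host <- (gene_gc - mean(host_gene_gcs)) / hsd
  z_donor <- (gene_gc - mean(donor_gene_gcs)) / dsd
  verdict <- if (abs(z_host) < 1 && abs(z_donor) < 1) {
    "ambiguous"
  } else if (abs(z_host) < abs(z_donor)) {
    "host-like"
  } else {
    "donor-like"
  }
  out <- tibble::tibble(
    gene_gc = gene_gc,
    host_mean = mean(host_gene_gcs), host_sd = hsd,
    donor_mean = mean(donor_gene_gcs), donor_sd = dsd,
    z_host = z_host, z_donor = z_donor, verdict = verdict
  )
  class(out) <- c("composition_profile", class(out))
  out
}

#' Full composition profile of a gene against host and donor CDS sets
#'
#' @param gene_cds Single CDS string.
#' @param host_cds,donor_cds Character vectors of background CDSs.
#' @return `composition_profile` tibble with GC, GC3 and the z-placement.
#' @export
composition_profile <- function(gene_cds, host_cds, donor_cds) {
  prof <- amelioration_placement(
    gc_content(gene_cds),
    vapply(host_cds, gc_content, numeric(1)),
    vapply(donor_cds, gc_content, numeric(1))
  )
  prof$gene_gc3 <- gc3(gene_cds)
  prof
}

#' @exportS3Method ggplot2::autoplot
autoplot.composition_profile <- function(object, ...) {
  df <- tibble::tibble(
    set = c("host", "donor"),
    mean = c(object$host_mean, object$donor_mean),
    sd = c(object$host_sd, object$donor_sd)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                                          ymax = .data$mean + 2 * .data$sd)) +
    ggplot2::geom_hline(yintercept = object$gene_gc, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(y = "GC fraction", x = NULL,
                  subtitle = paste("gene GC (dashed) vs backgrounds; verdict:",
                                   object$verdict)) +
    ggplot2::theme_minimal()
}
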