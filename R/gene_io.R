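#' Read sequences from a FASTA file
#'
#' Reads nucleotide or protein FASTA into a named character vector, one
#' element per record, names taken from the record ids (first whitespace-
#' delimited token). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param type `"auto"` (default) guesses from residue content, otherwise
#'   `"dna"` or `"protein"`. Nucleotide records are restricted to
#'   `A,C,G,T,N`; protein records to the 20 amino-acid letters plus `X`
#'   (and `-`/`*` only when `aligned = TRUE`).
#' @param aligned Allow gap (`-`) characters, for alignment FASTA.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein"), aligned = FALSE) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty record(s) in ", path, ": ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  if (type == "auto") {
    letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    type <- if (all(letters_used %in% c("A", "C", "G", "T", "N", "-"))) "dna" else "protein"
  }
  validate_alphabet(seqs, type, aligned)
  seqs
}

#' @noRd
validate_alphabet <- function(seqs, type, aligned = FALSE) {
  allowed <- if (type == "dna") c("A", "C", "G", "T", "N") else c(AA_ORDER, "X")
  if (aligned) allowed <- c(allowed, "-", "*")
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stop("invalid ", type, " characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  invisible(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code. A terminal stop codon is stripped; an internal stop
#' is an error (it signals a frame or annotation problem, and is never
#' silently masked).
#'
#' @param cds A single CDS string (A/C/G/T/N), length divisible by 3.
#' @return Protein string (X for codons containing N).
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    if.fuzzy.codon = "solve"
  ))
  n <- nchar(aa)
  if (n > 0L && substr(aa, n, n) == "*") aa <- substr(aa, 1L, n - 1L)
  if (grepl("*", aa, fixed = TRUE)) {
    stop("internal stop codon at amino-acid position ",
         regexpr("*", aa, fixed = TRUE)[1])
  }
  aa
}

#' Reverse complement of a nucleotide sequence
#' @param x Single DNA string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---------------------------------------------------------------------------
# Gene models

#' Construct a gene model
#'
#' A gene model is one gene's CDS in genomic coordinates. All coordinates are
#' 0-based half-open internally; GFF3's 1-based closed convention is applied
#' only at the I/O boundary. Introns are derived as the gaps between
#' consecutive exons and stored in genomic order; [introns_tx()] returns them
#' in transcription order so that intron phase is strand-independent
#' downstream.
#'
#' @param gene_id Gene identifier.
#' @param seq_region Scaffold/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`,`end` (0-based half-open
#'   CDS intervals in genomic coordinates).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_region, strand, exons) {
  stopifnot(is.matrix(exons), ncol(exons) == 2L, nrow(exons) >= 1L,
            strand %in% c("+", "-"))
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  colnames(exons) <- c("start", "end")
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("gene ", gene_id, ": empty or inverted exon interval")
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("gene ", gene_id, ": overlapping CDS intervals")
  }
  introns <- if (nrow(exons) > 1L) {
    cbind(start = exons[-nrow(exons), 2L], end = exons[-1L, 1L])
  } else {
    matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  }
  cds_length <- sum(exons[, 2L] - exons[, 1L])
  if (cds_length %% 3L != 0L) {
    stop("gene ", gene_id, ": CDS length ", cds_length, " not divisible by 3")
  }
  structure(
    list(gene_id = gene_id, seq_region = seq_region, strand = strand,
         exons = exons, introns = introns, cds_length = cds_length),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " (", x$strand, ") ", x$seq_region,
      ": ", nrow(x$exons), " exon(s), ", nrow(x$introns), " intron(s), CDS ",
      x$cds_length, " nt\n", sep = "")
  invisible(x)
}

#' Introns of a gene model in transcription order
#'
#' @param gm A [gene_model()].
#' @return Integer matrix of 0-based half-open genomic intervals, first row
#'   the 5'-most intron of the transcript.
#' @export
introns_tx <- function(gm) {
  stopifnot(inherits(gm, "gene_model"))
  if (gm$strand == "+" || nrow(gm$introns) <= 1L) return(gm$introns)
  gm$introns[rev(seq_len(nrow(gm$introns))), , drop = FALSE]
}

#' Extract and splice the CDS of a gene model from its scaffold sequence
#'
#' Concatenates the exon sequences and reverse-complements for minus-strand
#' models, so the result is always the sense-strand CDS.
#'
#' @param gm A [gene_model()].
#' @param region_seq The scaffold sequence (single string) of
#'   `gm$seq_region`.
#' @export
spliced_cds <- function(gm, region_seq) {
  stopifnot(inherits(gm, "gene_model"))
  pieces <- apply(gm$exons, 1L, function(iv) {
    substr(region_seq, iv[1L] + 1L, iv[2L])
  })
  cds <- paste(pieces, collapse = "")
  if (gm$strand == "-") cds <- reverse_complement(cds)
  cds
}

#' Read gene models from a GFF3 file
#'
#' Expects a gene -> mRNA -> CDS feature hierarchy. CDS intervals are
#' converted from GFF3's 1-based closed coordinates to the package's 0-based
#' half-open convention; introns are derived as the gaps between consecutive
#' CDS intervals.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [gene_model()] objects (by gene id).
#' @export
read_gff_gene_models <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  mrna <- gr[tolower(as.character(gr$type)) == "mrna"]
  mrna_parent <- setNames(
    vapply(mrna$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    mrna$ID
  )
  parent_of_cds <- vapply(cds$Parent, function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, character(1))
  # map CDS parent (mRNA) up to the gene when the hierarchy is present
  gene_of <- ifelse(parent_of_cds %in% names(mrna_parent),
                    mrna_parent[parent_of_cds], parent_of_cds)
  split_idx <- split(seq_along(cds), gene_of)
  models <- lapply(names(split_idx), function(gid) {
    idx <- split_idx[[gid]]
    exons <- cbind(start = GenomicRanges::start(cds)[idx] - 1L,
                   end = GenomicRanges::end(cds)[idx])
    strand <- as.character(GenomicRanges::strand(cds)[idx][1L])
    if (!strand %in% c("+", "-")) strand <- "+"
    gene_model(gene_id = gid,
               seq_region = as.character(GenomicRanges::seqnames(cds)[idx][1L]),
               strand = strand, exons = exons)
  })
  setNames(models, names(split_idx))
}

#' Write gene models to GFF3
#'
#' Emits the gene -> mRNA -> CDS hierarchy with a `##gff-version 3` header.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gff_gene_models <- function(models, path) {
  rows <- lapply(models, function(gm) {
    span <- c(min(gm$exons[, 1L]), max(gm$exons[, 2L]))
    n_ex <- nrow(gm$exons)
    # GFF3 phase: bases to skip at each exon start, in transcription order
    exon_lens <- gm$exons[, 2L] - gm$exons[, 1L]
    tx_order <- if (gm$strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
    cum_before <- cumsum(c(0L, exon_lens[tx_order]))[seq_len(n_ex)]
    phase_tx <- (3L - cum_before %% 3L) %% 3L
    phase <- integer(n_ex)
    phase[tx_order] <- phase_tx
    tibble::tibble(
      seqnames = gm$seq_region,
      start = c(span[1L] + 1L, span[1L] + 1L, gm$exons[, 1L] + 1L),
      end = c(span[2L], span[2L], gm$exons[, 2L]),
      strand = gm$strand,
      type = c("gene", "mRNA", rep("CDS", n_ex)),
      phase = c(NA_integer_, NA_integer_, phase),
      ID = c(gm$gene_id, paste0(gm$gene_id, ".t1"),
             paste0(gm$gene_id, ".cds", seq_len(n_ex))),
      Parent = c(NA_character_, gm$gene_id, rep(paste0(gm$gene_id, ".t1"), n_ex))
    )
  })
  df <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  # rtracklayer wants Parent as a CharacterList; empty for parentless rows
  gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p) {
    if (is.na(p)) character(0) else p
  }))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Alignments and column maps

#' Validate a protein multiple alignment
#'
#' @param rows Named character vector of aligned (gapped) protein strings.
#' @return The input, classed `msa`, with attribute `n_cols`.
#' @export
as_msa <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate row ids in alignment")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows differ in length: ",
         paste(names(rows)[widths != widths[1L]], collapse = ", "))
  }
  validate_alphabet(rows, "protein", aligned = TRUE)
  structure(rows, n_cols = widths[[1L]], class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x), " sequences x ", attr(x, "n_cols"), " columns\n",
      sep = "")
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences)
#' @param msa An [as_msa()] alignment.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Residue/column maps for every alignment row
#'
#' For each sequence: `res2col[i]` is the alignment column of residue `i`,
#' and `col2res[j]` is the residue index at column `j` (`NA` at gaps). The
#' maps are mutually inverse on non-gap positions.
#'
#' @param msa An [as_msa()] alignment.
#' @return Named list of lists with elements `res2col` and `col2res`,
#'   classed `column_map`.
#' @export
build_column_map <- function(msa) {
  msa <- as_msa(unclass(msa))
  maps <- lapply(unclass(msa), function(row) {
    chars <- strsplit(row, "")[[1]]
    nongap <- which(chars != "-")
    col2res <- rep(NA_integer_, length(chars))
    col2res[nongap] <- seq_along(nongap)
    list(res2col = nongap, col2res = col2res)
  })
  structure(maps, class = "column_map")
}

#' Strip gaps from one alignment row
#' @param msa An alignment; `seq_id` a row name.
#' @param seq_id Row identifier.
#' @export
ungapped_row <- function(msa, seq_id) {
  gsub("-", "", unclass(msa)[[seq_id]], fixed = TRUE)
}

# ---------------------------------------------------------------------------
# Taxonomy and trees

#' Read a taxonomy table
#'
#' Tab-separated file with header `seq_id<TAB>domain<TAB>supergroup`.
#' Domains are restricted to bacteria, archaea, eukaryote, virus.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `seq_id`, `domain`, `supergroup`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_taxonomy(df)
}

#' Validate a taxonomy table
#' @param df Data frame with columns `seq_id`, `domain`, `supergroup`.
#' @export
as_taxonomy <- function(df) {
  stopifnot(all(c("seq_id", "domain", "supergroup") %in% names(df)))
  bad <- setdiff(unique(df$domain), c("bacteria", "archaea", "eukaryote", "virus"))
  if (length(bad)) stop("unknown domain value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$seq_id)) stop("duplicate seq_id in taxonomy")
  tibble::as_tibble(df[, c("seq_id", "domain", "supergroup")])
}

#' Write a taxonomy table as TSV
#' @param tax Taxonomy tibble.
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as_taxonomy(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Newick tree
#'
#' Internal-node labels are parsed as bootstrap supports when numeric;
#' absent labels mean "no support" (`NA`), never 0.
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object; numeric supports (if any)
#'   are kept in `node.label`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (!is.null(tr$node.label)) {
    tr$node.label[tr$node.label == ""] <- NA_character_
  }
  tr
}

#' Write a tree as Newick
#' @param tree `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Numeric node supports of a tree
#'
#' @param tree `phylo` with optional `node.label`.
#' @return Numeric vector (length = number of internal nodes) of supports in
#'   \[0,100\], `NA` where absent.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}
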