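# File formats, gene models, coordinate conventions.

test_that("FASTA round-trips, preserves order, and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">a\nACGT", f)
  one <- read_fasta(f)
  expect_identical(one, c(a = "ACGT"))

  set.seed(101)
  ids <- paste0("seq", sample(100, 50))
  seqs <- vapply(ids, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(30:90, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  write_fasta(seqs, f)
  back <- read_fasta(f, type = "dna")
  expect_identical(back, seqs)

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(c(">a", "", ">b", "ACGT"), f)
  expect_error(read_fasta(f), "empty")
})

test_that("translation follows the standard code and flags internal stops", {
  expect_identical(translate_cds("ATGAAATAA"), "MK")
  expect_error(translate_cds("ATGTAAAAA"), "internal stop")
  expect_error(translate_cds("ATGAA"), "divisible by 3")
  # random stop-free CDS against an independent codon-table lookup
  set.seed(7)
  sense <- names(genetrace:::GENETIC_CODE_TABLE)[
    genetrace:::GENETIC_CODE_TABLE != "*"]
  cods <- sample(sense, 300, replace = TRUE)
  cds <- paste(cods, collapse = "")
  expect_identical(
    translate_cds(cds),
    paste(unname(genetrace:::GENETIC_CODE_TABLE[cods]), collapse = "")
  )
})

test_that("gene models derive introns and enforce the frame invariant", {
  gm <- gene_model("g1", "chr1", "+", cbind(0L, 300L))
  expect_equal(nrow(gm$introns), 0L)
  expect_equal(gm$cds_length, 300L)

  expect_error(gene_model("g2", "chr1", "+", rbind(c(0L, 100L), c(160L, 260L))),
               "g2.*200.*not divisible")
  gm3 <- gene_model("g3", "chr1", "+", rbind(c(0L, 99L), c(160L, 262L)))
  expect_equal(unname(gm3$introns[1, ]), c(99L, 160L))
  expect_equal(gm3$cds_length, 201L)

  expect_error(gene_model("g4", "chr1", "+", rbind(c(0L, 100L), c(50L, 150L))),
               "overlapping")
  # exon + intron lengths fill the genomic span
  span <- max(gm3$exons[, 2]) - min(gm3$exons[, 1])
  expect_equal(sum(gm3$exons[, 2] - gm3$exons[, 1]) +
                 sum(gm3$introns[, 2] - gm3$introns[, 1]), span)
})

test_that("GFF3 gene models round-trip and keep minus-strand intron order", {
  models <- list(
    plus = gene_model("plus", "scaf1", "+",
                      rbind(c(100L, 190L), c(250L, 310L), c(400L, 550L))),
    minus = gene_model("minus", "scaf2", "-",
                       rbind(c(100L, 190L), c(250L, 310L), c(400L, 550L)))
  )
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff_gene_models(models, f)
  expect_match(readLines(f, n = 1), "gff-version 3")
  back <- read_gff_gene_models(f)
  for (nm in names(models)) {
    expect_equal(back[[nm]]$exons, models[[nm]]$exons)
    expect_equal(back[[nm]]$strand, models[[nm]]$strand)
  }
  # transcription order reverses genomic order on the minus strand
  tx <- introns_tx(back$minus)
  expect_equal(unname(tx[1, ]), c(310L, 400L))
  expect_equal(unname(tx[2, ]), c(190L, 250L))
})

test_that("spliced minus-strand CDS equals the strand-corrected translation", {
  set.seed(11)
  exon_seqs <- c("ATGGCCAAA", "GGTACCTTT", "TGTTAA")
  scaffold_plus <- paste0(
    strrep("T", 10), exon_seqs[1], strrep("A", 7), exon_seqs[2],
    strrep("G", 5), exon_seqs[3], strrep("C", 4)
  )
  starts <- c(10L, 10L + 9L + 7L, 10L + 9L + 7L + 9L + 5L)
  ends <- starts + c(9L, 9L, 6L)
  gm_plus <- gene_model("p", "s", "+", cbind(starts, ends))
  cds_plus <- spliced_cds(gm_plus, scaffold_plus)
  expect_identical(cds_plus, paste(exon_seqs, collapse = ""))

  # mirror the layout; the minus-strand model must yield the same CDS
  L <- nchar(scaffold_plus)
  scaffold_minus <- reverse_complement(scaffold_plus)
  gm_minus <- gene_model("m", "s", "-", cbind(L - ends, L - starts))
  expect_identical(spliced_cds(gm_minus, scaffold_minus), cds_plus)
  expect_identical(translate_cds(spliced_cds(gm_minus, scaffold_minus)),
                   translate_cds(cds_plus))
})

test_that("column maps invert on non-gap positions", {
  msa <- as_msa(c(x = "A-CG", y = "AACG"))
  cm <- build_column_map(msa)
  expect_equal(cm$x$res2col, c(1L, 3L, 4L))
  expect_true(is.na(cm$x$col2res[2]))
  # all-gap columns map to no residue
  msa2 <- as_msa(c(x = "A-G", y = "C-T"))
  cm2 <- build_column_map(msa2)
  expect_true(all(is.na(c(cm2$x$col2res[2], cm2$y$col2res[2]))))
  # round-trip property over random gapped rows
  set.seed(5)
  for (i in 1:20) {
    chars <- sample(c(genetrace:::AA_ORDER, "-"), 60, replace = TRUE,
                    prob = c(rep(1, 20), 8))
    row <- paste(chars, collapse = "")
    cm3 <- build_column_map(as_msa(c(z = row, w = strrep("A", 60))))$z
    for (r in seq_along(cm3$res2col)) {
      expect_identical(cm3$col2res[[cm3$res2col[[r]]]], r)
    }
  }
  expect_error(as_msa(c(a = "AC", b = "A")), "differ in length")
})

test_that("newick supports parse from node labels, absent means NA", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:2)95:0.5,(c:1,d:1):0.3);", f)
  tr <- read_newick(f)
  sup <- node_supports(tr)
  expect_true(95 %in% sup)
  expect_true(anyNA(sup))
  write_newick(tr, f)
  expect_equal(ape::read.tree(f)$tip.label, tr$tip.label)
})

test_that("taxonomy tables validate domains and round-trip", {
  tax <- tibble::tibble(seq_id = c("a", "b"), domain = c("bacteria", "eukaryote"),
                        supergroup = c("Planctomycetes", "Amoebozoa"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, f)
  expect_equal(read_taxonomy(f), as_taxonomy(tax))
  expect_error(as_taxonomy(transform(tax, domain = c("bug", "eukaryote"))),
               "unknown domain")
})

test_that("result writers round-trip constraints and emit valid artifacts", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("egt_grouping:",
               "  - [a, b, x]",
               "pair:",
               "  - [a, b]"), yml)
  cs <- read_constraints_yaml(yml)
  expect_named(cs, c("egt_grouping", "pair"))
  expect_s3_class(cs$pair, "constraint_spec")
  expect_setequal(cs$egt_grouping$sets[[1]], c("a", "b", "x"))

  set.seed(70)
  tr <- ape::rtree(4, br = function(n) runif(n, 0.1, 0.3))
  seqs <- evolve_sequences(tr, sim_config(seed = 70, seq_length = 80))
  m <- subst_model("poisson")
  au <- run_topology_tests(
    seqs$alignment, m,
    list(constraint_spec("pair", list(sort(tr$tip.label)[1:2]))),
    n_reps = 100, seed = 1
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_au_test(au, tsv, js)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$candidate, au$table$candidate)
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))

  v <- classify_scenarios(extract_evidence(midpoint_root(au$trees$ML),
    tibble::tibble(seq_id = tr$tip.label, domain = "eukaryote",
                   supergroup = "Amoebozoa")))
  vjson <- withr::local_tempfile(fileext = ".json")
  write_verdict(v, vjson)
  parsed <- jsonlite::read_json(vjson)
  expect_true(parsed$primary %in% letters[1:5])
})
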