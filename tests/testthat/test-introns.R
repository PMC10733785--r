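# Intron coordinates, alignment projection, homology clustering, Dollo
# dating, age ranking.

test_that("intron CDS positions follow the offset/codon/phase arithmetic", {
  # two introns after CDS nt 300 and 301: 3 exons of 300, 1, remainder
  gm <- gene_model("g", "s", "+",
                   rbind(c(0L, 300L), c(400L, 401L), c(500L, 700L)))
  p1 <- intron_cds_position(gm, 1)
  expect_equal(p1$cds_offset, 300L)
  expect_equal(p1$codon_index, 100L)
  expect_equal(p1$phase, 0L)
  p2 <- intron_cds_position(gm, 2)
  expect_equal(p2$cds_offset, 301L)
  expect_equal(p2$codon_index, 100L)
  expect_equal(p2$phase, 1L)
  expect_error(intron_cds_position(gm, 3), "out of range")
})

test_that("minus-strand genes give the same codon and phase as their mirror", {
  exons <- rbind(c(100L, 190L), c(250L, 310L), c(400L, 550L))
  gm_plus <- gene_model("p", "s", "+", exons)
  span <- 650L
  gm_minus <- gene_model("m", "s", "-",
                         cbind(span - exons[, 2L], span - exons[, 1L]))
  for (i in 1:2) {
    expect_equal(intron_cds_position(gm_plus, i),
                 intron_cds_position(gm_minus, i))
  }
})

test_that("projection through the alignment is gap-stable and invertible", {
  msa <- as_msa(c(u = "ARNDQE", g = "-----A", five = "-----R"))
  cm <- build_column_map(msa)
  # ungapped row: column is codon_index + 1 (1-based columns)
  expect_equal(project_intron(cm, "u", 3, 2)$column, 4L)
  # row with 5 leading gaps: shifted by the gaps
  expect_equal(project_intron(cm, "five", 0, 1)$column, 6L)
  expect_error(project_intron(cm, "five", 3, 0), "no residue")
  # round-trip over random gap patterns
  set.seed(41)
  for (i in 1:15) {
    chars <- sample(c(genetrace:::AA_ORDER, "-"), 40, replace = TRUE,
                    prob = c(rep(1, 20), 10))
    if (!any(chars != "-")) next
    row <- paste(chars, collapse = "")
    m2 <- as_msa(c(a = row, b = strrep("A", 40)))
    cm2 <- build_column_map(m2)
    n_res <- sum(chars != "-")
    for (ci in seq_len(n_res) - 1L) {
      col <- project_intron(cm2, "a", ci, 0)$column
      expect_equal(unproject_intron(cm2, "a", col), ci)
    }
  }
})

test_that("clustering merges same-position introns and separates phases", {
  pr <- tibble::tibble(
    seq_id = c("sp1", "sp2", "sp1", "sp3"),
    column = c(40L, 40L, 40L, 77L),
    phase = c(0L, 0L, 1L, 0L)
  )
  cl <- cluster_homologous_introns(pr)
  expect_equal(nrow(cl), 3L)
  shared <- cl[cl$column == 40 & cl$phase == 0, ]
  expect_equal(shared$n_carriers, 2L)
  expect_setequal(shared$carriers[[1]], c("sp1", "sp2"))
  expect_equal(cl$site, c("i1", "i2", "i3"))   # 5' to 3' labels
  # non-zero tolerance merges neighbours; duplicate carrier is an error
  pr2 <- tibble::tibble(seq_id = c("a", "b"), column = c(10L, 11L),
                        phase = 0L)
  expect_equal(nrow(cluster_homologous_introns(pr2, tolerance = 1)), 1L)
  pr3 <- tibble::tibble(seq_id = c("a", "a"), column = c(10L, 11L),
                        phase = 0L)
  expect_error(cluster_homologous_introns(pr3, tolerance = 1),
               "two introns")
})

test_that("Dollo dating matches exhaustive minimization on random trees", {
  # trivial cases first
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  single <- dollo_date(tr, "d")
  expect_equal(single$gain_clade, "d")
  expect_equal(single$n_losses, 0L)
  clade <- dollo_date(tr, c("d", "e"))
  expect_setequal(clade$gain_clade, c("d", "e"))
  expect_equal(clade$n_losses, 0L)
  expect_error(dollo_date(tr, c("a", "zz")), "unknown tip")

  set.seed(47)
  for (i in 1:60) {
    ntip <- sample(4:10, 1)
    tree <- ape::rtree(ntip)
    carriers <- sample(tree$tip.label, sample(1:ntip, 1))
    mine <- dollo_date(tree, carriers)
    oracle <- brute_force_dollo(tree, carriers)
    expect_setequal(mine$gain_clade, oracle$gain_clade)
    expect_equal(mine$n_losses, oracle$n_losses)
    # losses never cover a carrier
    expect_false(any(carriers %in% unlist(mine$loss_branches)))
  }
})

test_that("the intron matrix mirrors simulated truth and ranks by breadth", {
  cfg <- sim_config(seed = 53, scenario = "a", loss_rate = 0,
                    intron_gain_rate = 2, intron_loss_rate = 0.3)
  sim <- simulate_gene_family(cfg)
  im <- intron_matrix(sim$gene_models, sim$alignment, sim$species_tree)
  ev <- sim$intron_events
  expect_equal(nrow(im$sites), nrow(ev))
  # the recovered carrier sets equal the simulator's per-site carriers
  truth_by_key <- split(ev$carriers, paste(ev$codon - 1L + 1L, ev$phase))
  for (j in seq_len(nrow(im$sites))) {
    key <- paste(im$sites$column[j], im$sites$phase[j])
    expect_true(key %in% names(truth_by_key))
    expect_setequal(im$sites$carriers[[j]], truth_by_key[[key]][[1]])
  }
  # matrix states: 1 for carriers, 0 for gene-bearing non-carriers,
  # '-' for species without the gene
  expect_true(all(im$matrix %in% c("1", "0", "-")))
  rep <- intron_age_report(im, sim$taxonomy)
  expect_equal(rep$age_rank, seq_len(nrow(rep)))
  expect_true(all(diff(rep$breadth) <= 0))
  # equal breadth ties break by 5' column order
  ties <- rep[rep$breadth == max(rep$breadth), ]
  if (nrow(ties) > 1) expect_true(all(diff(ties$column) > 0))
})

test_that("a broadly shared site is ranked oldest across supergroups", {
  # hand-built pattern: i1 carried across three supergroups, i2 unique
  tax <- tibble::tibble(
    seq_id = c("Amoebozoa_1", "Obazoa_1", "Discoba_1"),
    domain = "eukaryote",
    supergroup = c("Amoebozoa", "Obazoa", "Discoba")
  )
  tree <- ape::read.tree(
    text = "((Amoebozoa_1:1,Obazoa_1:1):1,Discoba_1:2);")
  aln <- as_msa(setNames(rep(strrep("A", 30), 3), tax$seq_id))
  mk <- function(id, offs) {
    genetrace:::build_gene_model_with_introns(
      paste0(id, "_g"), id, 93L, offs, rep(80L, length(offs)))
  }
  gms <- list(
    Amoebozoa_1 = mk("Amoebozoa_1", c(30L, 60L)),
    Obazoa_1 = mk("Obazoa_1", 30L),
    Discoba_1 = mk("Discoba_1", 30L)
  )
  im <- intron_matrix(gms, aln, tree)
  rep <- intron_age_report(im, tax)
  expect_equal(rep$breadth[rep$site == "i1"], 3L)
  expect_equal(rep$age_rank[rep$site == "i1"], 1L)
  expect_equal(rep$breadth[rep$site == "i2"], 1L)
  # label-equivariance: renaming species permutes but never changes content
  ren <- function(x) sub("_1", "_X", x)
  tax2 <- tax; tax2$seq_id <- ren(tax2$seq_id); tax2$supergroup <- tax$supergroup
  tree2 <- tree; tree2$tip.label <- ren(tree2$tip.label)
  aln2 <- as_msa(setNames(unclass(aln), ren(names(aln))))
  gms2 <- setNames(gms, ren(names(gms)))
  im2 <- intron_matrix(gms2, aln2, tree2)
  m1 <- im$matrix
  rownames(m1) <- ren(rownames(m1))
  expect_identical(m1[rownames(im2$matrix), , drop = FALSE], im2$matrix)
})
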