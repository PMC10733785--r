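# The gene-family simulator: tree shapes, scenario histories, sequence
# evolution, amelioration, intron dynamics, determinism.

test_that("species trees have the configured shape and are deterministic", {
  cfg_min <- sim_config(n_euk_supergroups = 2, tips_per_group = 1,
                        n_prok_clades = 1, seed = 3)
  tr_min <- simulate_species_tree(cfg_min)
  expect_equal(length(tr_min$tip.label), 4L)   # 2 euks + alpha + 1 donor

  cfg <- sim_config(seed = 5)
  t1 <- simulate_species_tree(cfg)
  t2 <- simulate_species_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  expect_equal(length(t1$tip.label), 6 * 3 + 3 * 3)  # 18 euks + 9 proks
  tax <- attr(t1, "taxonomy")
  expect_equal(sum(tax$domain == "eukaryote"), 18L)
  for (g in attr(t1, "euk_groups")) {
    expect_true(ape::is.monophyletic(t1, tax$seq_id[tax$supergroup == g]))
  }
  expect_true(all(t1$edge.length > 0))
  expect_true(ape::is.rooted(t1))
})

test_that("scenario a with no loss keeps the gene in every eukaryote", {
  cfg <- sim_config(scenario = "a", loss_rate = 0, seed = 8)
  sp <- simulate_species_tree(cfg)
  hist <- simulate_gene_history(sp, cfg)
  tax <- attr(sp, "taxonomy")
  euk <- tax$seq_id[tax$domain == "eukaryote"]
  expect_setequal(hist$truth$carriers, euk)
  expect_setequal(hist$gene_tree$tip.label, sp$tip.label)
  expect_length(hist$truth$losses, 0)
})

test_that("scenario b grafts the eukaryote clade inside alpha-proteobacteria", {
  cfg <- sim_config(scenario = "b", seed = 9)
  sp <- simulate_species_tree(cfg)
  hist <- simulate_gene_history(sp, cfg)
  gt <- hist$gene_tree
  tax <- attr(sp, "taxonomy")
  carriers <- hist$truth$carriers
  alpha <- intersect(tax$seq_id[tax$supergroup == "Alphaproteobacteria"],
                     gt$tip.label)
  # the carriers plus part of alpha form a clade strictly inside alpha
  ctx <- genetrace:::clade_donor_context(
    gt, carriers, setNames(tax$supergroup, tax$seq_id),
    unique(tax$supergroup[tax$domain == "bacteria"])
  )
  expect_equal(ctx$donor, "Alphaproteobacteria")
  expect_identical(hist$truth$donor, "Alphaproteobacteria")
})

test_that("scenario e yields two eukaryote clades nested in distinct donors", {
  cfg <- sim_config(scenario = "e", seed = 10)
  sp <- simulate_species_tree(cfg)
  hist <- simulate_gene_history(sp, cfg)
  truth <- hist$truth
  expect_length(truth$acquisition, 2L)
  expect_length(unique(truth$donor), 2L)
  tax <- attr(sp, "taxonomy")
  sg <- setNames(tax$supergroup, tax$seq_id)
  gt <- hist$gene_tree
  for (i in 1:2) {
    carr <- intersect(truth$acquisition[[i]], truth$carriers)
    ctx <- genetrace:::clade_donor_context(
      gt, carr, sg, unique(tax$supergroup[tax$domain == "bacteria"]))
    expect_equal(ctx$donor, truth$donor[[i]])
  }
})

test_that("scenario d records transfers and errors without recipients", {
  cfg <- sim_config(scenario = "d", seed = 12)
  sp <- simulate_species_tree(cfg)
  hist <- simulate_gene_history(sp, cfg)
  expect_gte(nrow(hist$truth$transfers), 1L)
  expect_true(all(hist$truth$transfers$recipient %in% hist$truth$carriers))
  # recipients come from supergroups outside the acquisition clade
  tax <- attr(sp, "taxonomy")
  sg <- setNames(tax$supergroup, tax$seq_id)
  acq_groups <- unique(sg[hist$truth$acquisition[[1]]])
  expect_false(any(hist$truth$transfers$recipient_group %in% acq_groups))
})

test_that("frozen branch lengths copy the root to every tip", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  seqs <- evolve_sequences(tr, sim_config(seed = 2, seq_length = 50))
  expect_length(unique(unname(seqs$proteins)), 1L)
})

test_that("amelioration moves CDS composition from donor to host", {
  # tau ~ 0: fully ameliorated; expected GC equals the host-bias analytic
  # mean given the realized amino-acid sequence
  cfg_host <- sim_config(seed = 23, seq_length = 120, amelioration_tau = 1e-9,
                         host_gc = 0.25, donor_gc = 0.65, scenario = "a",
                         loss_rate = 0)
  sim_host <- simulate_gene_family(cfg_host)
  euk <- sim_host$truth$carriers
  gc_host <- vapply(sim_host$cds[euk], gc_content, numeric(1))

  cfg_fresh <- sim_config(seed = 23, seq_length = 120, amelioration_tau = 1e9,
                          host_gc = 0.25, donor_gc = 0.65, scenario = "a",
                          loss_rate = 0)
  sim_fresh <- simulate_gene_family(cfg_fresh)
  gc_fresh <- vapply(sim_fresh$cds[euk], gc_content, numeric(1))
  # same proteins (same seed), so the GC difference is purely codon bias
  expect_identical(sim_host$alignment, sim_fresh$alignment)
  expect_gt(mean(gc_fresh) - mean(gc_host), 0.05)

  # analytic check: mean GC of host-biased codons for the realized proteins
  host_w <- codon_bias_weights(0.25)
  expected_gc <- local({
    tot_gc <- 0; tot_len <- 0
    for (tp in euk) {
      aas <- strsplit(sim_host$alignment[[tp]], "")[[1]]
      for (aa in aas) {
        fam <- genetrace:::codons_for_aa(aa)
        pr <- host_w[fam] / sum(host_w[fam])
        ngc <- vapply(strsplit(fam, ""), function(b) sum(b %in% c("G", "C")),
                      numeric(1))
        tot_gc <- tot_gc + sum(pr * ngc)
        tot_len <- tot_len + 3
      }
      tot_len <- tot_len + 3          # terminal TAA adds 0 GC
    }
    tot_gc / tot_len
  })
  se <- 2 / sqrt(120 * length(euk))   # generous binomial-scale envelope
  expect_equal(mean(gc_host), expected_gc, tolerance = 3 * se)

  # amelioration weights: prokaryote tips sit at w = 0, weights increase
  # with time since acquisition
  expect_true(all(sim_host$w[setdiff(names(sim_host$w), euk)] == 0))
  expect_true(all(sim_host$w[euk] > 0.999))
  expect_true(all(sim_fresh$w[euk] < 0.001))
})

test_that("intron simulation is Dollo and maps onto valid gene models", {
  cfg0 <- sim_config(seed = 31, intron_gain_rate = 0)
  sim0 <- simulate_gene_family(cfg0)
  expect_equal(nrow(sim0$intron_events), 0L)
  expect_true(all(vapply(sim0$gene_models, function(g) nrow(g$introns) == 0L,
                         logical(1))))

  cfg <- sim_config(seed = 32, scenario = "a", loss_rate = 0,
                    intron_gain_rate = 3, intron_loss_rate = 0.4)
  sim <- simulate_gene_family(cfg)
  ev <- sim$intron_events
  expect_gt(nrow(ev), 0L)
  expect_false(anyDuplicated(paste(ev$codon, ev$phase)) > 0)
  for (j in seq_len(nrow(ev))) {
    expect_true(all(ev$carriers[[j]] %in% ev$gain_clade[[j]]))
  }
  # gene models place every intron in frame within the CDS
  for (tp in names(sim$gene_models)) {
    gm <- sim$gene_models[[tp]]
    expect_equal(gm$cds_length, 3L * (cfg$seq_length + 1L))
    n <- nrow(gm$introns)
    if (n > 0) {
      for (i in seq_len(n)) {
        pos <- intron_cds_position(gm, i)
        expect_true(pos$cds_offset > 0 && pos$cds_offset < gm$cds_length)
      }
    }
  }
})

test_that("a gain with no losses reaches every carrier and dates correctly", {
  cfg <- sim_config(seed = 33, scenario = "a", loss_rate = 0,
                    intron_gain_rate = 1.5, intron_loss_rate = 0)
  sim <- simulate_gene_family(cfg)
  ev <- sim$intron_events
  expect_gt(nrow(ev), 0)
  for (j in seq_len(nrow(ev))) {
    expect_setequal(ev$carriers[[j]], ev$gain_clade[[j]])
    expect_equal(ev$n_loss_branches[j], 0L)
  }
  # feeding the simulated carriers to Dollo dating recovers the gain clade
  recovered <- 0L
  for (s in 1:20) {
    cfg2 <- sim_config(seed = 300 + s, scenario = "a", loss_rate = 0,
                       intron_gain_rate = 1, intron_loss_rate = 0.05)
    sim2 <- simulate_gene_family(cfg2)
    ev2 <- sim2$intron_events
    if (nrow(ev2) == 0) { recovered <- recovered + 1L; next }
    ok <- TRUE
    for (j in seq_len(nrow(ev2))) {
      dd <- dollo_date(sim2$gene_tree, ev2$carriers[[j]])
      # single gain: the inferred gain clade is the carrier MRCA clade,
      # always contained in the true gain clade
      if (!all(dd$gain_clade %in% ev2$gain_clade[[j]])) ok <- FALSE
    }
    if (ok) recovered <- recovered + 1L
  }
  expect_equal(recovered, 20L)
})

test_that("identical configs give byte-identical artifacts on disk", {
  cfg <- sim_config(seed = 37, seq_length = 60)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_gene_family(simulate_gene_family(cfg), d1)
  write_gene_family(simulate_gene_family(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # and a YAML round-trip of the config drives the same simulation
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), yml)
  cfg2 <- read_sim_config(yml)
  expect_identical(ape::write.tree(simulate_species_tree(cfg2)),
                   ape::write.tree(simulate_species_tree(cfg)))
})
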