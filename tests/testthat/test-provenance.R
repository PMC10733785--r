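# Evidence extraction and the deterministic scenario classifier.

make_bundle <- function(euk_monophyly = TRUE,
                        placement = "nested_in_prokaryotes",
                        n_euk_clades = 1L,
                        euk_clade_donors = "Planctomycetes",
                        egt_p = 0.001, outliers = character(0),
                        breadth = NA_integer_,
                        composition = NA_character_) {
  structure(
    list(euk_monophyly = euk_monophyly, euk_monophyly_support = 90,
         placement = placement, enclosing_support = 95,
         n_euk_clades = n_euk_clades,
         euk_clades = replicate(n_euk_clades, "tip", simplify = FALSE),
         euk_clade_donors = euk_clade_donors,
         au_p = c(ML = 1, egt_grouping = egt_p),
         outliers = outliers,
         outlier_table = tibble::tibble(tip = outliers),
         oldest_intron_breadth = breadth,
         composition_verdict = composition,
         n_euk_carriers = 6L, support_threshold = 50),
    class = "evidence_bundle"
  )
}

test_that("a bundle like the dcd1 evidence ranks eukaryote transfers first", {
  # monophyletic, nested, EGT not rejected, outliers present, old broad
  # intron, host-like composition
  b <- make_bundle(egt_p = 0.073, outliers = c("Cryptista_1", "Haptista_2"),
                   breadth = 3L, composition = "host-like")
  v <- classify_scenarios(b)
  expect_equal(v$primary, "d")
  expect_equal(unname(v$status[c("b", "c", "d")]),
               c("plausible", "plausible", "supported"))
  expect_equal(unname(v$status[c("a", "e")]), c("rejected", "rejected"))
  expect_true(any(grepl("ancient", v$annotations)))
  # the trace names the numeric value each rule fired on
  expect_true(any(grepl("0.073", v$trace$value)))
})

test_that("two clades nested in distinct donors support independent HGTs", {
  b <- make_bundle(euk_monophyly = FALSE, n_euk_clades = 2L,
                   euk_clade_donors = c("Planctomycetes", "Firmicutes"),
                   egt_p = 1e-5)
  v <- classify_scenarios(b)
  expect_equal(v$primary, "e")
  expect_equal(unname(v$status["e"]), "supported")
  expect_true(all(v$status[c("a", "b", "c", "d")] == "rejected"))
})

test_that("placement outside all prokaryotes puts vertical descent first", {
  b <- make_bundle(placement = "outside_all_prokaryotes",
                   euk_clade_donors = NA_character_, egt_p = 0.4)
  v <- classify_scenarios(b)
  expect_equal(v$primary, "a")
  expect_equal(unname(v$status["a"]), "plausible")
  expect_equal(unname(v$status["b"]), "plausible")  # EGT not rejected
  expect_equal(v$ranking[1:2], c("a", "b"))
})

test_that("missing evidence fields skip their rules with a logged notice", {
  b <- make_bundle()
  b$au_p <- NULL
  v <- classify_scenarios(b)
  expect_true(any(v$trace$rule == "R3" & grepl("skipped", v$trace$effect)))
  expect_true(any(v$trace$rule == "R6" & grepl("skipped", v$trace$effect)))
  # every non-empty status has a rationale
  expect_true(all(lengths(v$rationale) > 0))
  # at least one scenario always survives
  expect_true(any(v$status != "rejected"))
})

test_that("the verdict is a pure function of the bundle", {
  b <- make_bundle(egt_p = 0.2, outliers = "x")
  expect_identical(classify_scenarios(b), classify_scenarios(b))
  td <- generics::tidy(classify_scenarios(b))
  expect_s3_class(td, "tbl_df")
  expect_equal(td$scenario, letters[1:5])
})

test_that("scenario reports are byte-deterministic and cite evidence", {
  b <- make_bundle(egt_p = 0.073, outliers = "Cryptista_1", breadth = 3L,
                   composition = "host-like")
  v <- classify_scenarios(b)
  r1 <- scenario_report(v, b)
  r2 <- scenario_report(v, b)
  expect_identical(r1, r2)
  expect_true(any(grepl("Rule trace", r1)))
  for (s in letters[1:5]) {
    line <- grep(sprintf("scenario %s", s), r1, value = TRUE)
    expect_true(nchar(line[1]) > 30)    # every status line carries rationale
  }
  dates <- tibble::tibble(node = "acquisition", age_mya = 1500)
  r3 <- scenario_report(v, b, node_dates = dates)
  expect_true(any(grepl("1500 MYA", r3)))
})

test_that("evidence extraction reads the gene tree correctly per scenario", {
  # scenario a, no losses: outside all prokaryote clades by construction
  cfg_a <- sim_config(scenario = "a", loss_rate = 0, seed = 71)
  sim_a <- simulate_gene_family(cfg_a)
  rooted <- midpoint_root(sim_a$gene_tree)
  ev_a <- extract_evidence(rooted, sim_a$taxonomy)
  expect_equal(ev_a$placement, "outside_all_prokaryotes")
  expect_true(ev_a$euk_monophyly)

  # scenario e: exactly two eukaryote clades
  cfg_e <- sim_config(scenario = "e", seed = 72)
  sim_e <- simulate_gene_family(cfg_e)
  ev_e <- extract_evidence(midpoint_root(sim_e$gene_tree), sim_e$taxonomy)
  expect_equal(ev_e$n_euk_clades, 2L)
  expect_false(ev_e$euk_monophyly)
  expect_equal(sort(ev_e$euk_clade_donors), sort(sim_e$truth$donor))

  expect_error(extract_evidence(rooted, sim_a$taxonomy[-1, ]),
               "taxonomy missing")
})

test_that("outlier detection flags transferred tips, not loss survivors", {
  # scenario d: the regrafted recipients should be the outliers
  hits <- 0L; n_with_outliers <- 0L
  for (s in 1:6) {
    cfg <- sim_config(scenario = "d", seed = 80 + s)
    sim <- simulate_gene_family(cfg)
    res <- trace_provenance_sim(sim)
    out <- res$evidence$outliers
    rec <- sim$truth$transfers$recipient
    if (length(out)) {
      n_with_outliers <- n_with_outliers + 1L
      # flagged tips are recipients, or natives sandwiched between
      # recipients of one supergroup (a symmetric, equally valid reading)
      nested_in <- res$evidence$outlier_table$nested_in
      ok <- out %in% rec | nested_in %in% sub("_[0-9]+$", "", rec)
      if (all(ok)) hits <- hits + 1L
    }
  }
  expect_gte(n_with_outliers, 3L)
  expect_equal(hits, n_with_outliers)
  # scenario c: reports never claim outliers (no transfers simulated)
  cfg_c <- sim_config(scenario = "c", seed = 91)
  sim_c <- simulate_gene_family(cfg_c)
  res_c <- trace_provenance_sim(sim_c)
  expect_length(res_c$evidence$outliers, 0L)
  expect_true(any(grepl("outlier tips \\| none", res_c$report)))
})

test_that("the end-to-end pipeline recovers a known scenario", {
  cfg <- sim_config(scenario = "c", seed = 97)
  sim <- simulate_gene_family(cfg)
  res <- trace_provenance_sim(sim)
  expect_equal(res$verdict$primary, "c")
  expect_s3_class(res$au, "au_test")
  expect_true(!is.null(res$composition))
  expect_true(is.character(res$report))
})
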