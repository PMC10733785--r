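# Distances, neighbor joining, pruning likelihoods, branch-length
# optimization, NNI search, bootstrap, rooting.

test_that("pairwise distances match direct counts and the Poisson closed form", {
  row_a <- strrep("A", 100)
  row_b <- paste0(strrep("R", 10), strrep("A", 90))
  msa <- as_msa(c(a = row_a, b = row_b))
  expect_equal(unname(pairwise_distances(msa, "p")["a", "b"]), 0.10)
  expect_equal(unname(pairwise_distances(msa, "poisson")["a", "b"]), -log(0.9))
  expect_equal(diag(pairwise_distances(msa)), c(a = 0, b = 0))
  # identical rows at distance zero
  msa2 <- as_msa(c(a = row_a, b = row_a))
  expect_equal(unname(pairwise_distances(msa2)["a", "b"]), 0)
  # no mutually ungapped column is an error
  msa3 <- as_msa(c(a = "A-", b = "-A"))
  expect_error(pairwise_distances(msa3), "no mutually ungapped")
})

test_that("neighbor joining solves the three-point equations on 3 taxa", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  d <- stats::cophenetic(tr)
  expect_equal(d[rownames(D), colnames(D)], D, tolerance = 1e-12)
  expect_error(neighbor_joining(D * matrix(c(1, 1, 1, 2, 1, 1, 1, 1, 1), 3)),
               "symmetric")
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(21)
  for (i in 1:10) {
    cs <- random_additive_case(sample(5:8, 1))
    nj <- neighbor_joining(cs$D)
    expect_equal(phangorn::RF.dist(ape::unroot(cs$tree), nj), 0)
    expect_lt(max(abs(stats::cophenetic(nj)[rownames(cs$D), colnames(cs$D)] -
                        cs$D)), 1e-9)
    # independent cross-check against ape's NJ topology
    expect_equal(phangorn::RF.dist(ape::nj(cs$D), nj), 0)
  }
})

test_that("neighbor joining is deterministic under ties", {
  # perfectly symmetric matrix: every Q entry ties
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("pruning site likelihoods match brute-force state enumeration", {
  set.seed(31)
  f <- withr::local_tempfile(fileext = ".dat")
  write_random_rates_file(f)
  r <- read_paml_rates(f)
  models <- list(subst_model("poisson"),
                 subst_model("file", r$exchangeabilities, r$freq))
  for (m in models) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.6))
    msa <- random_protein_msa(tr$tip.label, 12)
    mine <- site_loglikelihoods(msa, tr, m)
    oracle <- brute_force_site_lnl(msa, tr, m)
    expect_equal(as.numeric(mine), oracle, tolerance = 1e-10)
  }
})

test_that("gaps are treated as missing data and frozen limits behave", {
  m <- subst_model("poisson")
  # two tips at zero distance: identical column gives ln(pi), differing -Inf
  tr <- ape::read.tree(text = "(a:0,b:0);")
  same <- site_loglikelihoods(as_msa(c(a = "A", b = "A")), tr, m)
  expect_equal(as.numeric(same), log(1 / 20))
  diff <- site_loglikelihoods(as_msa(c(a = "A", b = "R")), tr, m)
  expect_identical(as.numeric(diff), -Inf)
  # a fully gapped tip contributes nothing
  tr2 <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,(c:0.1,d:0.1):0.2);")
  full <- site_loglikelihoods(as_msa(c(a = "AR", b = "AR", c = "A-", d = "AR")),
                              tr2, m)
  marg <- site_loglikelihoods(as_msa(c(a = "AR", b = "AR", c = "AX", d = "AR")),
                              tr2, m)
  expect_equal(as.numeric(full), as.numeric(marg))
  expect_error(site_loglikelihoods(as_msa(c(x = "A", y = "A")), tr2, m),
               "absent from alignment")
})

test_that("total likelihood is invariant to rerooting and compression", {
  set.seed(33)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.5))
  msa <- random_protein_msa(tr$tip.label, 80)
  m <- subst_model("poisson", freq = empirical_aa_freqs(msa), alpha = 0.8, k = 4)
  base <- tree_loglik(msa, tr, m)
  for (og in tr$tip.label[1:3]) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(tree_loglik(msa, rerooted, m), base, tolerance = 1e-8)
  }
  cmp <- compress_columns(msa)
  expect_equal(sum(cmp$weights), 80)
  expect_equal(attr(site_loglikelihoods(cmp$msa, tr, m, cmp$weights), "total"),
               base, tolerance = 1e-10)
})

test_that("branch-length optimization recovers lengths and fixes points", {
  set.seed(41)
  # two-tip recovery: simulated divergence 0.3
  cfg <- sim_config(seed = 41, seq_length = 2000)
  tr2 <- ape::read.tree(text = "(a:0.15,b:0.15);")
  seqs <- evolve_sequences(tr2, cfg)
  m <- subst_model("poisson")
  fit <- optimize_branch_lengths(seqs$alignment, tr2, m, tol = 1e-6)
  expect_equal(sum(fit$edge.length), 0.3, tolerance = 0.05)
  # an already-optimal tree moves less than tol in one extra sweep
  refit <- optimize_branch_lengths(seqs$alignment, fit, m, tol = 1e-6)
  expect_lt(abs(attr(refit, "loglik") - attr(fit, "loglik")), 1e-3)
  # no signal drives lengths to the lower bound
  flat <- as_msa(c(a = strrep("A", 50), b = strrep("A", 50),
                   c = strrep("A", 50)))
  tr3 <- ape::read.tree(text = "(a:0.2,b:0.3,c:0.1);")
  fit3 <- optimize_branch_lengths(flat, tr3, m)
  expect_true(all(fit3$edge.length <= 1e-6))
})

test_that("branch-length optimum agrees with an independent ML fit", {
  set.seed(43)
  tr <- ape::rtree(5, br = function(n) runif(n, 0.05, 0.4))
  msa <- evolve_sequences(tr, sim_config(seed = 43, seq_length = 300))$alignment
  m <- subst_model("poisson")
  fit <- optimize_branch_lengths(msa, tr, m, tol = 1e-8, max_sweeps = 50)
  pd <- phangorn::phyDat(msa_matrix(msa), type = "AA")
  ph <- phangorn::optim.pml(
    phangorn::pml(ape::unroot(tr), pd, bf = rep(1 / 20, 20)),
    optEdge = TRUE, control = phangorn::pml.control(trace = 0, eps = 1e-10)
  )
  expect_equal(attr(fit, "loglik"), ph$logLik, tolerance = 1e-4)
})

test_that("NNI search is monotone, respects constraints, recovers topologies", {
  set.seed(51)
  m <- subst_model("poisson")
  tr <- ape::rtree(5, br = function(n) runif(n, 0.1, 0.3))
  msa <- random_protein_msa(tr$tip.label, 100)
  res <- nni_search(msa, tr, m)
  expect_gte(res$loglik, tree_loglik(msa, ape::unroot(tr), m) - 1e-8)
  # constraint always respected in the output
  cs <- constraint_spec("pair", list(tr$tip.label[1:2]))
  csat <- best_tree_under_constraint(msa, m, cs)
  expect_true(genetrace:::sets_monophyletic(csat$tree, cs$sets))
  # recovery: data simulated on a known 5-taxon tree, start from a
  # deliberately perturbed NJ tree
  hits <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    true <- ape::rtree(5, br = function(n) runif(n, 0.1, 0.4))
    cfg <- sim_config(seed = 1000 + s, seq_length = 500)
    seqs <- evolve_sequences(true, cfg)
    D <- pairwise_distances(seqs$alignment)
    Dp <- D + matrix(runif(25, 0, 0.3), 5)  # asymmetric noise
    Dp <- (Dp + t(Dp)) / 2; diag(Dp) <- 0
    start <- neighbor_joining(Dp)
    out <- nni_search(seqs$alignment, start, m)
    if (phangorn::RF.dist(out$tree, ape::unroot(true)) == 0) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("vacuous constraints reproduce the unconstrained search", {
  set.seed(55)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.1, 0.3))
  msa <- random_protein_msa(tr$tip.label, 120)
  m <- subst_model("poisson")
  un <- ml_tree(msa, m)
  vac <- best_tree_under_constraint(
    msa, m, constraint_spec("all", list(tr$tip.label))
  )
  expect_equal(phangorn::RF.dist(un$tree, vac$tree), 0)
  expect_equal(vac$loglik, un$loglik, tolerance = 1e-6)
  # restricting to a wrong grouping can only lower the likelihood
  wrong <- best_tree_under_constraint(
    msa, m, constraint_spec("wrong", list(sort(tr$tip.label)[c(1, 4)]))
  )
  expect_lte(wrong$loglik, un$loglik + 1e-6)
})

test_that("bootstrap supports are deterministic and track signal strength", {
  set.seed(61)
  true <- ape::rtree(6, br = function(n) runif(n, 0.3, 0.6))
  cfg <- sim_config(seed = 61, seq_length = 800)
  seqs <- evolve_sequences(true, cfg)
  m <- subst_model("poisson")
  ml <- ml_tree(seqs$alignment, m)
  b1 <- bootstrap_support(seqs$alignment, ml$tree, m, n_reps = 30, seed = 5)
  b2 <- bootstrap_support(seqs$alignment, ml$tree, m, n_reps = 30, seed = 5)
  expect_identical(b1$node.label, b2$node.label)
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 90))   # long branches, long alignment
  # an alignment of one repeated column carries no signal
  flat <- as_msa(setNames(rep(strrep("A", 50), 6), true$tip.label))
  bf <- bootstrap_support(flat, ml$tree, m, n_reps = 20, seed = 5,
                          search = "nj")
  supf <- suppressWarnings(as.numeric(bf$node.label))
  expect_true(all(supf[!is.na(supf)] < 100))
})

test_that("midpoint rooting minimizes the maximum root-to-tip distance", {
  # two-tip arithmetic
  tr2 <- ape::read.tree(text = "(a:1,b:3);")
  mp2 <- midpoint_root(tr2)
  depths <- genetrace:::depths_below(mp2, length(mp2$tip.label) + 1L)
  expect_equal(unname(depths[c("a", "b")]), c(2, 2))
  # random trees: exhaustive check over all candidate root edges
  set.seed(71)
  for (i in 1:5) {
    tr <- ape::unroot(ape::rtree(10, br = function(n) runif(n, 0.1, 1)))
    mp <- midpoint_root(tr)
    got <- max(genetrace:::depths_below(mp, length(mp$tip.label) + 1L))
    half <- max(stats::cophenetic(tr)) / 2
    expect_equal(got, half, tolerance = 1e-8)
  }
})

test_that("outgroup rooting validates monophyly and handles single tips", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  r1 <- outgroup_root(tr, "a")
  expect_true(ape::is.rooted(r1))
  kids <- genetrace:::node_tipsets(r1)
  expect_true(any(vapply(kids, function(k) identical(k, "a"), logical(1))))
  r2 <- outgroup_root(tr, c("d", "e"))
  expect_true(ape::is.monophyletic(r2, c("d", "e")))
  expect_error(outgroup_root(tr, c("a", "d")), "not monophyletic")
  expect_error(outgroup_root(tr, c("a", "zz")), "not in tree")
})
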