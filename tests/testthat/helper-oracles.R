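# Independent oracles and small fixture builders shared across tests.

# Exhaustive-enumeration reference implementations live in the package
# (R/experiments.R) so the acceptance script can call them too; thin
# aliases here keep test code readable.
brute_force_site_lnl <- function(msa, tree, model, rate = 1) {
  site_loglikelihoods_enum(msa, tree, model, rate)
}

brute_force_dollo <- function(tree, carriers) {
  dollo_date_enum(tree, carriers)
}

# random aligned protein rows (no gaps)
random_protein_msa <- function(ids, ncols) {
  rows <- vapply(ids, function(i) {
    paste(sample(genetrace:::AA_ORDER, ncols, replace = TRUE), collapse = "")
  }, character(1))
  as_msa(rows)
}

# write a small PAML-style rate file with random positive exchangeabilities
write_random_rates_file <- function(path) {
  ex <- runif(190, 0.1, 5)
  freq <- runif(20, 0.5, 2)
  freq <- freq / sum(freq)
  writeLines(c(
    paste(sprintf("%.6f", ex), collapse = " "),
    paste(sprintf("%.8f", freq), collapse = " ")
  ), path)
  path
}

# additive distance matrix from a random tree
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.05, 1))
  tr$tip.label <- sort(tr$tip.label)          # deterministic labels t1..tn
  list(tree = tr, D = stats::cophenetic(tr))
}
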