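# Synthetic gene families under five origin scenarios:
#   a  vertical presence in the eukaryote common ancestor, then losses
#   b  endosymbiotic transfer from the alpha-proteobacterial lineage
#   c  one prokaryote-to-eukaryote HGT onto an internal eukaryote branch,
#      then losses
#   d  as c, plus eukaryote-to-eukaryote transfers into other supergroups
#   e  two independent HGTs from distinct prokaryote donors
#
# Every stochastic stage draws from a seed derived from the config seed, so
# identical configs give byte-identical outputs.

EUK_SUPERGROUP_POOL <- c("Amoebozoa", "Obazoa", "Discoba", "Metamonada",
                         "Archaeplastida", "SAR", "Rhizaria", "Cryptista",
                         "Haptista", "CRuMs")
PROK_DONOR_POOL <- c("Planctomycetes", "Firmicutes", "Chloroflexi",
                     "Cyanobacteria", "Deltaproteobacteria", "CPR")
ALPHA_CLADE <- "Alphaproteobacteria"

#' Simulation configuration
#'
#' Defines one synthetic gene family: the taxon sample, the origin
#' scenario, sequence length and model, intron dynamics, and the
#' compositional-amelioration parameters. The defaults are the package's
#' reference study conditions.
#'
#' @param scenario One of `"a"`..`"e"` (see module description).
#' @param n_euk_supergroups Number of eukaryote supergroups (>= 2).
#' @param tips_per_group Tips per supergroup and per prokaryote clade.
#' @param n_prok_clades Number of generic prokaryote donor clades; an
#'   alpha-proteobacteria clade (the endosymbiotic donor stand-in) is always
#'   present in addition.
#' @param loss_rate Gene-loss events per unit branch length.
#' @param euk_hgt_count Eukaryote-to-eukaryote transfers (scenario d).
#' @param seq_length Protein length in codons.
#' @param subst_model Model name (`"poisson"`) or path to a PAML-style
#'   amino-acid rate file.
#' @param intron_gain_rate,intron_loss_rate Intron events per unit branch
#'   length on eukaryotic branches after acquisition.
#' @param amelioration_tau Time constant of codon-bias amelioration: a tip
#'   whose lineage acquired the gene `t` ago samples codons from
#'   `w * host + (1-w) * donor` with `w = 1 - exp(-t / tau)`.
#' @param host_gc,donor_gc GC knobs of the host and donor codon-bias tables
#'   (fractions in (0,1)).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(scenario = c("a", "b", "c", "d", "e"),
                       n_euk_supergroups = 6L, tips_per_group = 3L,
                       n_prok_clades = 2L, loss_rate = 0.05,
                       euk_hgt_count = 2L, seq_length = 600L,
                       subst_model = "poisson",
                       intron_gain_rate = 2.0, intron_loss_rate = 0.5,
                       amelioration_tau = 1.0, host_gc = 0.30,
                       donor_gc = 0.60, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_euk_supergroups >= 2L, tips_per_group >= 1L,
            n_prok_clades >= 1L, loss_rate >= 0, euk_hgt_count >= 0L,
            seq_length >= 1L, intron_gain_rate >= 0, intron_loss_rate >= 0,
            amelioration_tau >= 0, host_gc > 0, host_gc < 1,
            donor_gc > 0, donor_gc < 1)
  seed <- as.integer(seed)
  stopifnot(is.finite(seed))
  structure(
    list(scenario = scenario, n_euk_supergroups = as.integer(n_euk_supergroups),
         tips_per_group = as.integer(tips_per_group),
         n_prok_clades = as.integer(n_prok_clades), loss_rate = loss_rate,
         euk_hgt_count = as.integer(euk_hgt_count),
         seq_length = as.integer(seq_length), subst_model = subst_model,
         intron_gain_rate = intron_gain_rate,
         intron_loss_rate = intron_loss_rate,
         amelioration_tau = amelioration_tau,
         host_gc = host_gc, donor_gc = donor_gc, seed = seed),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys match the [sim_config()] arguments.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# --------------------------------------------------------------------------
# small phylo helpers (label-based so they survive node renumbering)

#' @noRd
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  node_tipsets(tree)[[node]]
}

#' @noRd
mrca_of <- function(tree, tips) {
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# distance from a node to each of its descendant tips
#' @noRd
depths_below <- function(tree, node) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  depth <- rep(NA_real_, ntip + tree$Nnode)
  depth[node] <- 0
  edge <- tree$edge
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    p <- edge[e, 1L]; v <- edge[e, 2L]
    if (!is.na(depth[p]) && is.na(depth[v])) {
      depth[v] <- depth[p] + tree$edge.length[e]
    }
  }
  tips <- which(!is.na(depth[seq_len(ntip)]))
  setNames(depth[tips], tree$tip.label[tips])
}

# one-tip phylo usable with ape::bind.tree
#' @noRd
one_tip_tree <- function(label, stem) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 tip.label = label, edge.length = 0,
                 Nnode = 1L, root.edge = stem),
            class = "phylo")
}

# graft `sub` (rooted phylo, may be a single tip) onto the branch above the
# node whose tip set is `target_tips`, at a fraction of that branch, with
# the given stem length
#' @noRd
graft_subtree <- function(tree, sub, target_tips, stem, frac = 0.5) {
  node <- mrca_of(tree, target_tips)
  edge_row <- which(tree$edge[, 2L] == node)
  stopifnot(length(edge_row) == 1L)
  pos <- tree$edge.length[edge_row] * frac
  sub$root.edge <- stem
  out <- ape::bind.tree(tree, sub, where = node, position = pos)
  stats::reorder(out, "postorder")
}

# sample "at least one event" indicators for a set of branch lengths
#' @noRd
branch_events <- function(lens, rate) {
  runif(length(lens)) < (1 - exp(-rate * lens))
}

# Poisson losses below `top_tips`'s MRCA: returns list of lost tip sets
# (each the clade below one loss branch), processed top-down so nested
# losses collapse into their ancestral event.
#' @noRd
sample_losses <- function(tree, top_tips, rate) {
  if (rate <= 0) return(list())
  node <- mrca_of(tree, top_tips)
  if (length(top_tips) == 1L) return(list())
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  below <- node_tipsets(tree)
  # an edge is in scope iff its child's tip set is a proper subset of the
  # acquisition clade's tips (i.e. the branch lies strictly below the node)
  desc <- below[[node]]
  in_scope <- vapply(seq_len(nrow(edge)), function(e) {
    ts <- below[[edge[e, 2L]]]
    all(ts %in% desc) && length(ts) < length(desc)
  }, logical(1))
  hit <- branch_events(tree$edge.length, rate) & in_scope
  lost <- list()
  lost_tips <- character(0)
  # top-down: preorder over edges
  for (e in rev(seq_len(nrow(edge)))) {
    if (!hit[e]) next
    ts <- below[[edge[e, 2L]]]
    if (all(ts %in% lost_tips)) next   # already lost higher up
    lost[[length(lost) + 1L]] <- ts
    lost_tips <- union(lost_tips, ts)
  }
  lost
}

# --------------------------------------------------------------------------

#' Simulate the species tree
#'
#' A rooted binary tree with `n_euk_supergroups` monophyletic eukaryote
#' supergroups on one side of the root and a prokaryote donor pool on the
#' other: one alpha-proteobacteria clade (the endosymbiotic-donor stand-in)
#' plus `n_prok_clades` generic donor clades on long stems, so donors are
#' phylogenetically well separated.
#'
#' @param config A [sim_config()].
#' @return Rooted `phylo`; tip labels are `<group>_<i>`. Attributes:
#'   `taxonomy` (tibble), `euk_groups`, `prok_clades` (generic donors),
#'   `alpha` (the alpha clade name).
#' @export
simulate_species_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$tips_per_group
  euk_groups <- EUK_SUPERGROUP_POOL[seq_len(config$n_euk_supergroups)]
  prok_clades <- PROK_DONOR_POOL[seq_len(config$n_prok_clades)]

  clade_newick <- function(labels, len_range) {
    if (length(labels) == 1L) return(labels)
    frags <- as.list(sample(labels))
    while (length(frags) > 1L) {
      i <- sample(length(frags), 2L)
      l1 <- runif(1, len_range[1], len_range[2])
      l2 <- runif(1, len_range[1], len_range[2])
      merged <- paste0("(", frags[[i[1L]]], ":", l1, ",",
                       frags[[i[2L]]], ":", l2, ")")
      frags <- c(frags[-i], list(merged))
    }
    frags[[1L]]
  }
  group_frag <- function(group, len_range) {
    clade_newick(paste0(group, "_", seq_len(k)), len_range)
  }

  # supergroup clades carry their own stems; the backbone randomly joins
  # the clade fragments with backbone-scale internal branch lengths
  euk_frags <- vapply(euk_groups, function(g) {
    paste0(group_frag(g, c(0.02, 0.08)), ":", runif(1, 0.1, 0.2))
  }, character(1))
  euk_sub <- {
    frags <- as.list(euk_frags)
    while (length(frags) > 1L) {
      i <- sample(length(frags), 2L)
      merged <- paste0("(", frags[[i[1L]]], ",", frags[[i[2L]]], "):",
                       runif(1, 0.05, 0.15))
      frags <- c(frags[-i], list(merged))
    }
    sub("\\):[0-9.eE+-]+$", ")", frags[[1L]])
  }

  prok_frag <- function(name, stem) {
    paste0(group_frag(name, c(0.05, 0.15)), ":", stem)
  }
  prok_units <- c(prok_frag(ALPHA_CLADE, 0.4),
                  vapply(prok_clades, function(p) prok_frag(p, 0.5), character(1)))
  prok_sub <- if (length(prok_units) == 1L) {
    sub(":[0-9.eE+-]+$", "", prok_units)
  } else {
    frags <- as.list(prok_units)
    while (length(frags) > 1L) {
      merged <- paste0("(", frags[[1L]], ",", frags[[2L]], "):0.3")
      frags <- c(frags[-(1:2)], list(merged))
    }
    sub("\\):0\\.3$", ")", frags[[1L]])
  }
  nwk <- paste0("(", euk_sub, ":0.3,", prok_sub, ":0.3);")
  tree <- stats::reorder(ape::read.tree(text = nwk), "postorder")

  tax <- tibble::tibble(
    seq_id = tree$tip.label,
    supergroup = sub("_[0-9]+$", "", tree$tip.label)
  )
  tax$domain <- ifelse(tax$supergroup %in% euk_groups, "eukaryote", "bacteria")
  attr(tree, "taxonomy") <- as_taxonomy(tax[, c("seq_id", "domain", "supergroup")])
  attr(tree, "euk_groups") <- euk_groups
  attr(tree, "prok_clades") <- prok_clades
  attr(tree, "alpha") <- ALPHA_CLADE
  tree
}

#' Simulate the gene's history on the species tree
#'
#' Builds the gene tree for the configured scenario and the ground-truth
#' record of every event. The gene is present throughout the prokaryote
#' pool; eukaryote carriers depend on the scenario (see [sim_config()]).
#'
#' @param species_tree Output of [simulate_species_tree()].
#' @param config The same [sim_config()].
#' @return List with `gene_tree` (rooted `phylo`), `truth` (class
#'   `sim_truth`): scenario, acquisition clades, donor(s), losses,
#'   transfers, per-tip time since acquisition.
#' @export
simulate_gene_history <- function(species_tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tax <- attr(species_tree, "taxonomy")
  euk_groups <- attr(species_tree, "euk_groups")
  prok_clades <- attr(species_tree, "prok_clades")
  euk_tips <- tax$seq_id[tax$domain == "eukaryote"]
  sg <- setNames(tax$supergroup, tax$seq_id)
  scn <- config$scenario
  stem <- 0.15                        # acquisition stem length

  draw_losses <- function(tree, top_tips, min_left = 2L) {
    for (try in 1:100) {
      lost <- sample_losses(tree, top_tips, config$loss_rate)
      left <- setdiff(top_tips, unlist(lost))
      if (length(left) >= min_left || length(top_tips) < min_left) {
        return(list(lost = lost, left = left))
      }
    }
    stop("could not draw a loss pattern leaving >= ", min_left, " carriers")
  }

  prok_only <- ape::drop.tip(species_tree, euk_tips)
  euk_clade <- ape::extract.clade(species_tree, mrca_of(species_tree, euk_tips))

  pick_graft_edge_tips <- function(tree, clade_name) {
    # a uniformly chosen branch inside the named prokaryote clade,
    # identified by the tip set below it
    members <- tax$seq_id[tax$supergroup == clade_name]
    tree <- stats::reorder(tree, "postorder")
    below <- node_tipsets(tree)
    ok <- which(vapply(below, function(ts) {
      all(ts %in% members) && length(ts) >= 1L
    }, logical(1)))
    ok <- ok[ok != mrca_of(tree, members) | length(members) == 1L]
    node <- if (length(ok) > 1L) sample(ok, 1L) else ok[1L]
    below[[node]]
  }

  transfers <- NULL
  if (scn == "a") {
    lr <- draw_losses(species_tree, euk_tips)
    carriers <- lr$left
    gene_tree <- ape::drop.tip(species_tree, setdiff(euk_tips, carriers))
    acquisition <- list(euk_tips)
    donor <- NA_character_
    losses <- lr$lost
    acq_stem <- 0
  } else if (scn == "b") {
    lr <- draw_losses(species_tree, euk_tips)
    carriers <- lr$left
    sub <- ape::drop.tip(euk_clade, setdiff(euk_tips, carriers))
    target <- pick_graft_edge_tips(prok_only, ALPHA_CLADE)
    gene_tree <- graft_subtree(prok_only, sub, target, stem)
    acquisition <- list(euk_tips)
    donor <- ALPHA_CLADE
    losses <- lr$lost
    acq_stem <- stem
  } else if (scn %in% c("c", "d")) {
    # acquisition on an internal eukaryote branch spanning >= 2 supergroups
    # but not all of them
    below <- node_tipsets(species_tree)
    ntip_sp <- length(species_tree$tip.label)
    cand <- which(vapply(seq_along(below), function(nd) {
      ts <- below[[nd]]
      nd > ntip_sp && all(ts %in% euk_tips) &&
        length(unique(sg[ts])) >= 2L &&
        length(unique(sg[ts])) < length(euk_groups)
    }, logical(1)))
    if (!length(cand)) stop("no eligible acquisition branch for scenario ", scn)
    acq_node_tips <- below[[if (length(cand) > 1L) sample(cand, 1L) else cand]]
    lr <- draw_losses(species_tree, acq_node_tips)
    carriers <- lr$left
    sub <- ape::drop.tip(
      ape::extract.clade(species_tree, mrca_of(species_tree, acq_node_tips)),
      setdiff(acq_node_tips, carriers)
    )
    donor <- if (length(prok_clades) > 1L) sample(prok_clades, 1L) else prok_clades
    target <- pick_graft_edge_tips(prok_only, donor)
    gene_tree <- graft_subtree(prok_only, sub, target, stem)
    acquisition <- list(acq_node_tips)
    losses <- lr$lost
    acq_stem <- stem
    if (scn == "d") {
      recipients_pool <- setdiff(euk_tips, acq_node_tips)
      if (!length(recipients_pool)) {
        stop("scenario d: no eligible recipient lineage outside the carrier clade")
      }
      n_tr <- min(config$euk_hgt_count, length(recipients_pool))
      rec <- sample(recipients_pool, n_tr)
      for (r in rec) {
        # graft the recipient tip inside the carrier clade of the gene tree
        host_clade <- intersect(gene_tree$tip.label, carriers)
        below_g <- node_tipsets(gene_tree)
        mr <- mrca_of(gene_tree, host_clade)
        desc <- below_g[[mr]]
        ok <- which(vapply(seq_along(below_g), function(nd) {
          ts <- below_g[[nd]]
          all(ts %in% desc) && length(ts) < length(desc)
        }, logical(1)))
        tgt <- below_g[[if (length(ok) > 1L) sample(ok, 1L) else ok[1L]]]
        gene_tree <- graft_subtree(gene_tree, one_tip_tree(r, 0.05), tgt,
                                   stem = 0.05)
        carriers <- c(carriers, r)
      }
      transfers <- tibble::tibble(recipient = rec,
                                  recipient_group = unname(sg[rec]))
    }
  } else {                            # scenario e
    if (length(prok_clades) < 2L) {
      stop("scenario e needs at least two generic donor clades")
    }
    groups2 <- sample(euk_groups, 2L)
    donors2 <- sample(prok_clades, 2L)
    gene_tree <- prok_only
    acquisition <- list()
    losses <- list()
    carriers <- character(0)
    for (i in 1:2) {
      gtips <- tax$seq_id[tax$supergroup == groups2[i]]
      lr <- draw_losses(species_tree, gtips, min_left = 1L)
      keep <- lr$left
      losses <- c(losses, lr$lost)
      sub <- if (length(gtips) == 1L) {
        one_tip_tree(gtips, 0)
      } else {
        ape::drop.tip(
          ape::extract.clade(species_tree, mrca_of(species_tree, gtips)),
          setdiff(gtips, keep)
        )
      }
      target <- pick_graft_edge_tips(prok_only, donors2[i])
      gene_tree <- graft_subtree(gene_tree, sub, target, stem)
      acquisition <- c(acquisition, list(gtips))
      carriers <- c(carriers, keep)
    }
    donor <- donors2
    acq_stem <- stem
  }

  # per-tip time since acquisition (path length in the gene tree from the
  # acquisition point, which sits `acq_stem` above the carrier MRCA)
  t_acq <- numeric(0)
  for (aq in acquisition) {
    carr <- intersect(gene_tree$tip.label, aq)
    if (!is.null(transfers)) carr <- union(carr, transfers$recipient)
    carr <- intersect(carr, gene_tree$tip.label)
    if (!length(carr)) next
    node <- mrca_of(gene_tree, carr)
    d <- depths_below(gene_tree, node)
    t_acq <- c(t_acq, d[intersect(names(d), carr)] + acq_stem)
  }
  truth <- structure(
    list(scenario = scn, acquisition = acquisition, donor = donor,
         losses = losses, transfers = transfers,
         carriers = sort(intersect(gene_tree$tip.label,
                                   c(carriers, transfers$recipient))),
         t_since_acquisition = t_acq),
    class = "sim_truth"
  )
  list(gene_tree = stats::reorder(gene_tree, "postorder"), truth = truth)
}

# --------------------------------------------------------------------------
# sequences

#' Codon-bias weights from a single GC knob
#'
#' Per-codon weight proportional to `gc^nGC * (1-gc)^nAT` over the codon's
#' bases; normalized within each synonymous family at use time. Stop codons
#' excluded.
#'
#' @param gc GC fraction knob in (0,1).
#' @return Named numeric vector over the 61 sense codons.
#' @export
codon_bias_weights <- function(gc) {
  stopifnot(gc > 0, gc < 1)
  codons <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  ngc <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")),
                numeric(1))
  w <- gc^ngc * (1 - gc)^(3 - ngc)
  setNames(w, codons)
}

#' @noRd
sample_codons_for_protein <- function(protein, w_host, host_w, donor_w) {
  aas <- strsplit(protein, "")[[1]]
  cods <- character(length(aas))
  for (aa in unique(aas)) {
    fam <- codons_for_aa(aa)
    pr <- w_host * host_w[fam] + (1 - w_host) * donor_w[fam]
    pr <- pr / sum(pr)
    idx <- which(aas == aa)
    cods[idx] <- sample(fam, length(idx), replace = TRUE, prob = pr)
  }
  paste0(paste(cods, collapse = ""), "TAA")
}

#' Evolve sequences along the gene tree
#'
#' Amino-acid evolution under the configured reversible CTMC: the root is
#' drawn from the stationary frequencies and substitutions are sampled per
#' branch from `exp(Qt)`. Simulation is indel-free, so the true alignment is
#' the tip matrix itself. Each tip's CDS realizes the protein by sampling
#' synonymous codons from the mixture `w * host + (1-w) * donor` codon-bias
#' tables, with `w = 1 - exp(-t/tau)` for eukaryote tips (`t` = time since
#' acquisition) and `w = 0` for prokaryote tips.
#'
#' @param gene_tree Gene tree from [simulate_gene_history()].
#' @param config The [sim_config()].
#' @param truth The `sim_truth` (for per-tip acquisition times); optional —
#'   without it all tips use donor bias.
#' @return List with `alignment` (the true [as_msa()]), `proteins`,
#'   `cds` (named vectors), and `w` (per-tip amelioration weights).
#' @export
evolve_sequences <- function(gene_tree, config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  model <- sim_subst_model(config$subst_model)
  tree <- stats::reorder(gene_tree, "postorder")
  ntip <- length(tree$tip.label)
  L <- config$seq_length
  nn <- ntip + tree$Nnode
  states <- vector("list", nn)
  root <- tree$edge[nrow(tree$edge), 1L]
  states[[root]] <- sample.int(20L, L, replace = TRUE, prob = model$freq)
  edge <- tree$edge
  for (e in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[e, 1L]; v <- edge[e, 2L]
    P <- transition_matrix(model, tree$edge.length[e])
    parent <- states[[p]]
    child <- integer(L)
    for (s in unique(parent)) {
      idx <- which(parent == s)
      child[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[[v]] <- child
  }
  proteins <- vapply(seq_len(ntip), function(i) {
    paste(AA_ORDER[states[[i]]], collapse = "")
  }, character(1))
  names(proteins) <- tree$tip.label

  host_w <- codon_bias_weights(config$host_gc)
  donor_w <- codon_bias_weights(config$donor_gc)
  w_tip <- setNames(rep(0, ntip), tree$tip.label)
  if (!is.null(truth)) {
    t_acq <- truth$t_since_acquisition
    shared <- intersect(names(t_acq), names(w_tip))
    if (config$amelioration_tau == 0) {
      w_tip[shared] <- 1
    } else {
      w_tip[shared] <- 1 - exp(-t_acq[shared] / config$amelioration_tau)
    }
  }
  cds <- vapply(tree$tip.label, function(tp) {
    sample_codons_for_protein(proteins[[tp]], w_tip[[tp]], host_w, donor_w)
  }, character(1))
  list(alignment = as_msa(proteins), proteins = proteins, cds = cds, w = w_tip)
}

#' @noRd
sim_subst_model <- function(name) {
  if (identical(name, "poisson")) return(subst_model("poisson"))
  if (file.exists(name)) {
    r <- read_paml_rates(name)
    return(subst_model(basename(name), r$exchangeabilities, r$freq))
  }
  stop("unknown substitution model: ", name)
}

# --------------------------------------------------------------------------
# introns

#' Simulate intron gain and Dollo loss; emit gene models
#'
#' Introns are gained on eukaryotic branches after acquisition (Poisson per
#' branch), each at a unique (codon, phase) site, and lost under Dollo
#' dynamics (no regain on a lineage that lost the site). Gene models are
#' emitted for every eukaryote carrier with the introns placed at the
#' corresponding CDS coordinates; strands are drawn at random so minus-
#' strand coordinate handling is exercised.
#'
#' @param gene_tree Gene tree.
#' @param truth `sim_truth` from [simulate_gene_history()].
#' @param config The [sim_config()].
#' @return List with `gene_models` (named list for eukaryote carriers),
#'   `events` (tibble: site, codon, phase, carriers, gain clade, number of
#'   loss branches).
#' @export
simulate_introns <- function(gene_tree, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  tree <- stats::reorder(gene_tree, "postorder")
  below <- node_tipsets(tree)
  edge <- tree$edge
  euk_carriers <- truth$carriers
  L <- config$seq_length

  # eukaryotic branches after acquisition: edges whose tip set is a
  # non-empty subset of the carriers
  scope <- which(vapply(seq_len(nrow(edge)), function(e) {
    ts <- below[[edge[e, 2L]]]
    length(ts) >= 1L && all(ts %in% euk_carriers)
  }, logical(1)))

  used_sites <- character(0)
  events <- list()
  if (config$intron_gain_rate > 0 && length(scope)) {
    for (e in scope) {
      n_gain <- rpois(1L, config$intron_gain_rate * tree$edge.length[e])
      if (n_gain == 0L) next
      for (g in seq_len(n_gain)) {
        repeat {
          codon <- sample.int(L, 1L)          # 1-based codon index
          phase <- sample(0:2, 1L)
          if (codon == 1L && phase == 0L) next # no intron before the first base
          key <- paste(codon, phase)
          if (!key %in% used_sites) break
        }
        used_sites <- c(used_sites, key)
        gain_tips <- below[[edge[e, 2L]]]
        # Dollo losses below the gain branch
        lost <- character(0)
        sub_edges <- which(vapply(seq_len(nrow(edge)), function(e2) {
          ts <- below[[edge[e2, 2L]]]
          all(ts %in% gain_tips) && length(ts) < length(gain_tips)
        }, logical(1)))
        n_loss_branches <- 0L
        if (config$intron_loss_rate > 0 && length(sub_edges)) {
          hit <- branch_events(tree$edge.length[sub_edges],
                               config$intron_loss_rate)
          for (e2 in rev(sub_edges[hit])) {   # preorder-ish top-down
            ts <- below[[edge[e2, 2L]]]
            if (all(ts %in% lost)) next
            lost <- union(lost, ts)
            n_loss_branches <- n_loss_branches + 1L
          }
        }
        carr <- setdiff(gain_tips, lost)
        if (!length(carr)) next               # site extinct; leaves no trace
        events[[length(events) + 1L]] <- tibble::tibble(
          codon = codon, phase = phase,
          carriers = list(sort(carr)),
          gain_clade = list(sort(gain_tips)),
          n_loss_branches = n_loss_branches
        )
      }
    }
  }
  events <- if (length(events)) dplyr::bind_rows(events) else {
    tibble::tibble(codon = integer(0), phase = integer(0),
                   carriers = list(), gain_clade = list(),
                   n_loss_branches = integer(0))
  }
  if (nrow(events)) {
    events <- events[order(events$codon, events$phase), ]
    events$site <- paste0("i", seq_len(nrow(events)))
    events <- events[, c("site", "codon", "phase", "carriers",
                         "gain_clade", "n_loss_branches")]
  } else {
    events$site <- character(0)
  }

  cds_len <- 3L * (L + 1L)             # includes the terminal stop codon
  models <- lapply(euk_carriers, function(tp) {
    offs <- integer(0)
    if (nrow(events)) {
      has <- vapply(events$carriers, function(cs) tp %in% cs, logical(1))
      offs <- sort(3L * (events$codon[has] - 1L) + events$phase[has])
    }
    intron_lens <- if (length(offs)) {
      60L + 3L * sample.int(30L, length(offs), replace = TRUE)
    } else integer(0)
    build_gene_model_with_introns(
      gene_id = paste0(tp, "_gene"), tip = tp, cds_len = cds_len,
      intron_offsets = offs, intron_lens = intron_lens,
      strand = sample(c("+", "-"), 1L)
    )
  })
  names(models) <- euk_carriers
  list(gene_models = models, events = events)
}

# lay exons/introns on a scaffold; `intron_offsets` are CDS nucleotide
# offsets (5' of the intron) in transcription order
#' @noRd
build_gene_model_with_introns <- function(gene_id, tip, cds_len,
                                          intron_offsets, intron_lens,
                                          strand = "+", lead = 100L) {
  bounds <- c(0L, intron_offsets, cds_len)
  exon_lens <- diff(bounds[!duplicated(bounds)])
  stopifnot(all(exon_lens > 0L))
  exons_tx <- matrix(0L, length(exon_lens), 2L)
  pos <- lead
  for (i in seq_along(exon_lens)) {
    exons_tx[i, ] <- c(pos, pos + exon_lens[i])
    pos <- pos + exon_lens[i] + if (i <= length(intron_lens)) intron_lens[i] else 0L
  }
  span_end <- pos + lead
  if (strand == "-") {
    # mirror the layout so transcription runs right to left
    exons <- cbind(span_end - exons_tx[, 2L], span_end - exons_tx[, 1L])
  } else {
    exons <- exons_tx
  }
  gene_model(gene_id = gene_id, seq_region = paste0(tip, "_scaffold"),
             strand = strand, exons = exons)
}

# --------------------------------------------------------------------------

#' Simulate host/donor background coding sequences
#'
#' Independent genes with uniform random proteins and codons drawn entirely
#' from the host (or donor) bias table — the backgrounds the composition
#' module compares a candidate gene against.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of background genes.
#' @param len Protein length of each.
#' @param which `"host"` or `"donor"`.
#' @export
simulate_background_cds <- function(config, n_genes = 8L, len = 400L,
                                    which = c("host", "donor")) {
  which <- match.arg(which)
  set.seed(config$seed + if (which == "host") 4L else 5L)
  w <- codon_bias_weights(if (which == "host") config$host_gc else config$donor_gc)
  out <- vapply(seq_len(n_genes), function(i) {
    prot <- paste(sample(AA_ORDER, len, replace = TRUE), collapse = "")
    sample_codons_for_protein(prot, 1, w, w)
  }, character(1))
  setNames(out, paste0(which, "_bg_", seq_len(n_genes)))
}

#' Simulate a complete gene family
#'
#' Orchestrates [simulate_species_tree()], [simulate_gene_history()],
#' [evolve_sequences()], [simulate_introns()], and
#' [simulate_background_cds()] under one seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `gene_family_sim`: species/gene trees, truth,
#'   alignment, CDS, gene models, intron events, taxonomy (restricted to
#'   gene-tree tips), host/donor background CDS sets, and the config.
#' @export
simulate_gene_family <- function(config) {
  sp <- simulate_species_tree(config)
  hist <- simulate_gene_history(sp, config)
  seqs <- evolve_sequences(hist$gene_tree, config, hist$truth)
  intr <- simulate_introns(hist$gene_tree, hist$truth, config)
  tax <- attr(sp, "taxonomy")
  structure(
    list(species_tree = sp, gene_tree = hist$gene_tree, truth = hist$truth,
         alignment = seqs$alignment, cds = seqs$cds, w = seqs$w,
         gene_models = intr$gene_models, intron_events = intr$events,
         taxonomy = tax[tax$seq_id %in% hist$gene_tree$tip.label, ],
         host_background = simulate_background_cds(config, which = "host"),
         donor_background = simulate_background_cds(config, which = "donor"),
         config = config),
    class = "gene_family_sim"
  )
}

#' @export
print.gene_family_sim <- function(x, ...) {
  cat("<gene_family_sim> scenario ", x$config$scenario, ": ",
      length(x$gene_tree$tip.label), " gene-tree tips (",
      length(x$truth$carriers), " eukaryote carriers), ",
      nrow(x$intron_events), " intron site(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated gene family to standard formats
#'
#' FASTA (alignment and CDS), GFF3 gene models, Newick trees, taxonomy TSV,
#' and the truth record as JSON.
#'
#' @param sim A [simulate_gene_family()] result.
#' @param dir Output directory (created if needed).
#' @export
write_gene_family <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(unclass(sim$alignment), file.path(dir, "alignment.fasta"))
  write_fasta(sim$cds, file.path(dir, "cds.fasta"))
  write_fasta(sim$host_background, file.path(dir, "host_background.fasta"))
  write_fasta(sim$donor_background, file.path(dir, "donor_background.fasta"))
  write_newick(sim$species_tree, file.path(dir, "species_tree.nwk"))
  write_newick(sim$gene_tree, file.path(dir, "gene_tree.nwk"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (length(sim$gene_models)) {
    write_gff_gene_models(sim$gene_models, file.path(dir, "gene_models.gff3"))
  }
  truth <- sim$truth
  truth_json <- list(
    scenario = truth$scenario,
    acquisition = truth$acquisition,
    donor = truth$donor,
    losses = truth$losses,
    transfers = if (is.null(truth$transfers)) NULL else truth$transfers,
    carriers = truth$carriers,
    t_since_acquisition = as.list(truth$t_since_acquisition)
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
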