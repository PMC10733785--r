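---
title: "Inferring gene provenance: models, tests, and the simulator behind genetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene provenance: models, tests, and the simulator behind genetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetrace)
```

## The inference problem

Some eukaryotic genes sit, phylogenetically, in the middle of the bacteria.
A dCTP deaminase or a flavin-dependent thymidylate synthase found in a social
amoeba, with its closest relatives in Planctomycetes or Clostridia, could
have arrived there along five quite different historical routes:

* **a — vertical (LECA):** the gene was present in the last eukaryotic
  common ancestor and was subsequently lost in most lineages;
* **b — endosymbiotic transfer (EGT):** the gene entered the nuclear genome
  from the mitochondrial ancestor, i.e. from the alpha-proteobacterial
  lineage;
* **c — a single prokaryote-to-eukaryote horizontal transfer (HGT)** into an
  ancestor of a subset of eukaryotes, followed by losses;
* **d — that same HGT followed by eukaryote-to-eukaryote transfers** into
  unrelated supergroups;
* **e — independent HGTs** from distinct prokaryote donors into unrelated
  eukaryote lineages.

The scenarios leave different fingerprints in three places: the topology of
the gene tree (where the eukaryote homologs attach, and whether constrained
alternatives survive a topology test), the pattern of spliceosomal intron
positions (introns are gained only after a gene lives in a eukaryotic
nucleus, so shared intron positions date the acquisition), and base
composition (a transferred gene ameliorates from the donor's GC and codon
usage toward the host's). `genetrace` implements each evidence channel and a
deterministic rule engine that combines them into a ranked verdict.

## Likelihood machinery

Site likelihoods are computed by Felsenstein's pruning algorithm under a
reversible amino-acid CTMC: a symmetric exchangeability matrix $R$ and
stationary frequencies $\pi$ give $Q_{ij} = R_{ij}\pi_j$, normalized to one
expected substitution per unit branch length. Gaps and `X` are missing data
(all-ones partials). With discrete-gamma rate variation the site likelihood
is the equal-probability category mean, categories represented by their
slice means.

The default exchangeabilities are Poisson (all equal). With arbitrary
frequencies that is the amino-acid *equal-input* model, whose transition
matrix has the closed form $P(t) = e^{-\beta t} I + (1-e^{-\beta t})
\mathbf{1}\pi^\top$ with $\beta = 1/(1-\sum_i \pi_i^2)$. The implementation
exploits this: the per-branch likelihood objective collapses to a single
length-$L$ vector expression, which is what makes the simulation studies
below affordable in pure R. A PAML-style rate file can be supplied instead
(`read_paml_rates()`), in which case a symmetric eigendecomposition of $Q$
is used; the test suite exercises both paths against exhaustive
state-enumeration likelihoods.

Numerical choices worth knowing about:

* partials are rescaled per column only when their sums approach the double
  underflow range, so zero-likelihood columns surface as `-Inf` rather than
  `NaN`;
* branch lengths are optimized by iterated univariate Brent search with the
  lower bound $10^{-8}$ (keeps site likelihoods finite) and an explicit
  boundary evaluation, since a zero-length optimum sits on the interval
  edge that Brent never visits;
* per-sweep partials are reused across branches (fast, slightly stale);
  if a sweep ever lowers the likelihood the optimizer reverts and, when the
  caller asked for `exact` optima, switches to refreshing partials before
  every branch — inside tree search the best-seen point is accepted
  instead, because there branch lengths only steer topology moves;
* tree search is greedy NNI with local branch-length refreshes around each
  accepted move; candidate moves are rescored from cached inside/outside
  partials without rebuilding the tree. NNI (not SPR) is deliberate: the
  package targets desk-scale gene families (tens of tips), not large-tree
  search performance.

Neighbor joining (the start tree, and the bootstrap replicate engine) is
the standard agglomeration, exact on additive matrices; Q-criterion ties
break on the lexicographically smallest clade-name pair, and negative
branch lengths are clamped to zero with the deficit moved to the sibling.

## Constrained topology tests and the AU p-value

Each hypothesis ("the eukaryote homologs group with alpha-proteobacteria")
is a monophyly constraint. The constrained best tree starts from NJ within
each constrained set, NJ on group-average distances between set roots and
free taxa, grafting, then constraint-respecting NNI. Candidates (the
unconstrained tree plus one per constraint) are compared through their
per-site log-likelihood vectors only — RELL resampling, no re-optimization
per replicate.

The multiscale bootstrap resamples $\lceil r L\rceil$ columns at scales
$r \in \{0.5, 0.6, \ldots, 1.4\}$ (10,000 replicates per scale by default;
the simulation studies use 1,000). Winner ties cycle round-robin through
the tied candidates in lexicographic order, so a perfectly symmetric tie
yields even win proportions — on short alignments ties are not rare enough
to ignore. Per candidate the win proportions $BP_r$ are probit-transformed
with a $+0.5/(n+1)$ count adjustment and fitted by weighted least squares
(weights $n/(BP(1-BP))$) to

$$\Phi^{-1}(1 - BP_r) = d\sqrt{r} + c/\sqrt{r},$$

giving the approximately unbiased p-value $p_{AU} = 1 - \Phi(d - c)$.
Candidates that never (always) win are clamped to $p = 0$ ($1$) and
flagged. A candidate is "rejected" at $p < 0.05$. Kishino–Hasegawa
p-values (normal approximation on the centered RELL distribution of
$\Delta\ln L$) and the scale-1 bootstrap proportion are reported alongside.

The forward model is invertible: proportions generated from known $(d, c)$
recover the p-value to within 0.005 at $10^6$ replicates, and on simulated
four-taxon data with the true tree among three candidates the test rejects
the truth at $\alpha = 0.05$ in well under 10% of 200 datasets (both are
asserted in the test suite and recomputed by `scripts/acceptance.R`).

## Intron dating

Intron positions are expressed as (codon index, phase), where the intron
"belongs to" the codon it precedes: the CDS offset in spliced nucleotides
gives `codon = offset %/% 3` and `phase = offset %% 3`. Gene models store
genomic coordinates 0-based half-open (GFF3's 1-based closed convention is
converted only at the I/O boundary), and minus-strand introns are indexed
in transcription order, so the (codon, phase) pair is strand-independent.
Positions are projected through the protein alignment via residue-to-column
maps (columns are 1-based, the R convention); deletions in other rows
cannot shift a projected site.

Sites sharing column and phase are homologous introns (tolerance 0 by
default; a column-slack knob exists for alignment wobble but is opt-in,
and a cluster that would absorb two introns from one sequence is an error,
signaling that the tolerance is too large). Each site is dated by Dollo
parsimony: one gain at the carrier MRCA, losses the stems of the maximal
carrier-free subtrees below it — provably the minimal single-gain
explanation, and checked against an exhaustive subset-enumeration oracle.
A site shared by more eukaryote supergroups is older; breadth ≥ 3
supergroups annotates the acquisition as ancient. Species-specific sites
are retained and reported, never dropped.

## Composition

GC and GC3 exclude ambiguity codes from numerator and denominator. Codon
usage tables carry counts, within-family frequencies and RSCU
(`count / (family total / family size)`; family means are exactly 1).
Preferred-codon concordance asks, for every multi-codon amino acid with at
least 5 occurrences (modal codons of rarer amino acids are noise), whether
the gene's modal codon equals the host's, reporting exceptions with the
host-table rank of the gene's choice and flagging within-gene ties.
`amelioration_placement()` z-scores the gene GC against host and donor
background distributions; the verdict is host-like, donor-like, or
ambiguous when the gene value sits inside both backgrounds.

## The scenario rule engine

`classify_scenarios()` freezes the prose reasoning into an ordered,
auditable rule pass (R1–R7; see the function documentation for the exact
conditions). Two points deserve emphasis. First, placement of the
eukaryote clade is judged *rooting-free*: the clade is nested inside a
prokaryote clade X exactly when one side of its attachment edge is a
proper subset of X's tips; attachment on a backbone or on a clade stem is
"outside". This keeps the verdict independent of where midpoint rooting
happens to fall. Second, scenarios b and c/d are **by design not forced
apart** when the donor context is alpha-proteobacterial: an EGT and an HGT
from an alpha-like donor predict identical tree shapes, so when the AU
test cannot reject the alpha grouping the engine reports b as plausible
alongside c/d rather than fabricating a choice. Eukaryote tips nesting
inside another supergroup's well-supported clade (support ≥ 50, and with
members of that supergroup on both sides, which rules out a mere
sister-to-clade position) upgrade d over c. Literature divergence dates
are attached to the report only as user-supplied annotations, never
computed.

Every rule firing logs the numeric value that triggered it, and the
Markdown report is byte-deterministic.

## The simulator: what it emulates, and what it does not

`simulate_gene_family()` generates one gene family per config under a
single integer seed (each stage derives its own stream, so outputs are
byte-identical across runs). The species tree carries
`n_euk_supergroups` monophyletic supergroups (default 6 × 3 tips) and a
prokaryote pool: an alpha-proteobacteria clade plus `n_prok_clades`
generic donors (default 2) on long stems (0.4–0.5 substitutions/site) so
donors are well separated; within-supergroup branches are drawn from
U(0.02, 0.08), backbone branches U(0.05, 0.15). Gene histories follow the
five scenarios by pruning and regrafting the eukaryote (sub)tree: scenario
b attaches it on a branch strictly inside the alpha clade; c/d pick an
internal eukaryote branch spanning at least two supergroups; d additionally
regrafts recipient tips (default 2) from non-carrying supergroups into the
carrier clade; e grafts two supergroup subtrees into two distinct donors.
Losses are per-branch Poisson events (default rate 0.05 per unit branch
length), redrawn if fewer than two eukaryote carriers survive, since the
inference task is undefined otherwise.

Sequences evolve indel-free under the configured CTMC, so the true
alignment is the tip matrix itself — intron positions, not alignment gaps,
carry the dating signal. Codons are realized per tip from the mixture
$w \cdot \text{host} + (1-w)\cdot\text{donor}$ of single-knob bias tables
(per-codon weight $\propto gc^{n_{GC}}(1-gc)^{n_{AT}}$), with
$w = 1 - e^{-t/\tau}$ and $t$ the path length from the acquisition point.
Defaults: host GC 0.30 (an AT-rich amoeba-like host), donor GC 0.60,
$\tau = 1$. Intron gains are Poisson on post-acquisition eukaryotic
branches (default 2.0 per unit length — an intron-rich regime), each at a
unique (codon, phase) site, with Dollo losses (default 0.5); regain at a
lost site never occurs by construction, and the event log records every
gain clade and loss branch.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: alignment error and indels, rate variation across
sites and lineages beyond the optional gamma model, compositional
heterogeneity across the tree (all eukaryotes share one host bias),
duplication/paralogy, incomplete taxon sampling biases, and contamination.
The recovery rates below are properties of this generator at these
settings, not field error rates.

## Reference study sizes

The validation experiments (also recomputed by `scripts/acceptance.R`) use:
exhaustive-enumeration likelihood checks on all 4- and 5-tip topologies at
50 columns; 100 random additive matrices of 5–8 taxa; AU calibration on
200 four-taxon datasets of 600 columns with 1,000 RELL replicates at 10
scales; Dollo checks on 500 random trees of up to 10 tips; scenario
recovery with 50 simulations per scenario (25 in the faster acceptance
script, recorded in its `n` fields) at the reference conditions — 6
supergroups × 3 tips, 600 codons, loss rate 0.05, 1,000 RELL replicates,
100 distance-NJ bootstrap replicates for supports; and 50 seeds per
condition for the composition study at 300 codons. The pipeline's
scenario studies use the rate-homogeneous Poisson model with empirical
frequencies, matching the generator.

## A small worked run

```{r worked, eval = FALSE}
cfg <- sim_config(scenario = "d", seed = 101)
sim <- simulate_gene_family(cfg)
res <- trace_provenance_sim(sim)
res$verdict          # ranked scenarios with rationale
generics::tidy(res$au)         # AU / BP / KH per candidate topology
cat(res$report, sep = "\n")    # the full Markdown report
```

## Known limitations

* The AU fit uses the standard two-term probit model; very small scale
  grids or extremely short alignments leave few informative scales.
* Outlier detection needs bootstrap support ≥ 50 around the transferred
  tip; transfers into positions adjacent to their own supergroup, or two
  recipients flanking a native tip, are genuinely ambiguous and are
  reported as such.
* Scenario b is only ever "plausible", never "supported": the package
  inherits the identifiability limit of EGT vs alpha-like HGT rather than
  hiding it.
* The equal-input fast path is what makes the pure-R implementation quick;
  with file-loaded exchangeabilities everything still works but the
  simulation studies would be several-fold slower.
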