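---
title: "Detecting convergent substitutions at conservative sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent substitutions at conservative sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccscan)
```

## The problem

When a trait such as dedicated cleaning behaviour evolves repeatedly in
different lineages, the amino-acid substitutions shared by the trait-bearing
("foreground") species but absent from all other ("background") species are
candidate molecular correlates of the trait.  Naive site scans for such
patterns are noisy in two distinct ways:

* **random convergence** — with twenty residues, long branches, and millions
  of sites, unrelated lineages regularly hit the same residue by chance;
* **false convergence** — when the background itself is variable at a site,
  the reconstructed ancestral residue is uncertain, and an apparent
  "derived, shared, foreground-specific" state can be an artefact of
  ancestral-state misreconstruction.

The *convergence at conservative sites* (CCS) idea attacks both at once:
a detected convergence is only retained if **every** background species
carries one identical residue at the site.  Background unanimity makes the
ancestral state nearly certain (suppressing false convergences entirely) and
shrinks the residue space available for chance hits (suppressing random
convergences).  `ccscan` implements the full calibration loop for this rule:
a null-sequence simulator, a likelihood engine with marginal ancestral
reconstruction, the site classifier, and the noise report that quantifies
what the restriction buys.

## Model

Sites evolve independently under a reversible continuous-time Markov chain
on the 20 amino acids.  The generator is built from the Jones–Taylor–
Thornton (JTT) exchangeabilities $s_{ij}$ and a stationary distribution
$\pi$:

$$Q_{ij} = s_{ij}\,\pi_j \quad (i \ne j), \qquad
  Q_{ii} = -\sum_{j \ne i} Q_{ij},$$

rescaled so the expected rate $-\sum_i \pi_i Q_{ii}$ is one, which keeps
branch lengths in expected substitutions per site.  Among-site rate
variation is a discrete gamma mixture: rates are drawn from
$\Gamma(\alpha, \alpha)$ (mean one) discretised into $K$ equal-probability
categories, each represented by its bin mean.  Mean-of-bin (rather than
median) discretisation keeps the average rate exactly one, so no silent
rescaling of branch lengths occurs.

Transition probabilities use the eigendecomposition of the
reversibility-symmetrised generator $D^{1/2} Q D^{-1/2}$ ($D =
\mathrm{diag}(\pi)$), which is numerically stable and gives
$P(t) = D^{-1/2} U e^{\Lambda t} U^{\top} D^{1/2}$ at any branch length.

Likelihoods are computed by Felsenstein pruning with per-node column-wise
log-scaling of the partial likelihoods, so alignments of any depth are safe
from underflow; the scaled implementation is tested against exhaustive
internal-state enumeration on small trees to $10^{-10}$.  Gaps and ambiguity
codes contribute all-ones partials (missing data), the convention of common
codon/amino-acid ML software when sites are not discarded.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 | gamma shape; proteome-wide concatenations typically show strong rate variation ($\alpha \approx 0.3$–$1$) |
| `k` | 4 | gamma categories; the conventional compromise between accuracy and cost |
| `freqs` | `"model"` (simulation), `"empirical"` (fitting) | stationary residue frequencies; `+F` counting is used when estimating from data |
| `min_foreground` | 3 | minimum foreground carriers for a relaxed convergence call |
| `gap_policy` | `exclude_site` | any gap/unknown among the scanned taxa removes the site (conservative) |
| branch-length bounds | $[10^{-8}, 50]$ | optimizer box constraints |

## Maximum-likelihood fitting

`fit_parameters()` estimates branch lengths and $\alpha$ on a fixed
topology.  Each cycle is one exact Gauss–Seidel sweep over the edges —
a depth-first traversal that keeps the inside and outside partial
likelihoods current at every step, so each one-dimensional golden-section
search is an exact coordinate ascent and the total log-likelihood is
monotone non-decreasing — followed by a bounded search on $\alpha$.  Cycles
stop when the relative improvement falls below $10^{-6}$ (or after 100
cycles).  There are no stochastic restarts: fits are deterministic.
Alignment columns are compressed to unique patterns with multiplicities
before fitting.

At the study scale used throughout the package (14 taxa, 5,000 sites),
branch lengths are recovered with a median relative error under 10% and
$\alpha$ within 15%, which the test suite verifies over three simulation
seeds.

## Ancestral reconstruction

`marginal_ancestral_states()` computes, per internal node and site, the
marginal posterior over residues given the tips:

$$\Pr(x_v = a \mid \text{tips}) \propto
  \sum_k \Pr(r_k) \, \text{In}_k(v, a)\, \text{Out}_k(v, a),$$

where the inside/outside partials are mixed across rate categories by their
per-site posterior weights (empirical Bayes over categories), matching the
behaviour of standard ML phylogenetics software.  The MAP residue breaks
posterior ties — exact or within $10^{-12}$ — by alphabetical order, for
determinism.  Sites are processed in blocks (default 20,000) to bound
memory.

## The site rules

Writing $a$ for a candidate convergent residue and $m$ for
`min_foreground`:

* **relaxed convergence** — at least $m$ foreground taxa carry $a$, and $a$
  is absent from every background taxon.  "Differs from any background
  species" is read as *differs from every background residue at the site*;
  this is the only reading under which the conservative-site restriction is
  a subset of the relaxed rule.
* **CCS convergence** — relaxed, and additionally all background taxa share
  one identical residue $b$ (then $b \ne a$ automatically).
* **strict parallel** (gene-level rule) — *all* foreground taxa carry $a$
  and all background taxa carry the same $b \ne a$.  A gene with at least
  one strict parallel site is called a convergently evolving gene (CEG).

If two residues each reach $m$ carriers at one site, the site yields one
call per qualifying residue, reported separately.  Site indices are 1-based
in every table the package writes.

## Noise attribution

On null simulations each detected convergence is attributed to a noise
class by comparing the MAP residue at the ancestor of the background clade
— operationalised as the MRCA of the background taxa minus the outgroup;
because the background is paraphyletic in the study system this node also
subtends the foreground, which is accepted as-is — with the outgroup's
observed residue:

* ancestor ≠ outgroup residue → **false** convergence (misreconstruction);
* otherwise → **random** convergence (chance substitutions).

The two textual definitions of the noise classes overlap ("more than two
foreground taxa showing the same residue as background taxa" describes
random hits, but detected convergences already differ from all background
residues).  The package therefore adopts the reconstruction test as the
primary classifier and records the literal more-than-two diagnostic as a
flag (`fg_matches_bg_gt2`) without letting it drive the classification.

`noise_report()` runs the whole loop — classify, reconstruct, attribute —
and reports counts per stage with percent reductions
$100\,(1 - \text{after}/\text{before})$, shown as `n/a` when the
before-count is zero.

## The simulator as study conditions

`simulate_null()` and `generate_orthogroup_set()` define the conditions
under which the method is exercised: the built-in 14-taxon tree
(`cleaner_fish_tree()`) mirrors the study system's shape — six cleaner
wrasses as foreground, two non-cleaner wrasses nested among them, six
reference species, spotted gar as outgroup — with branch lengths chosen
once to give a realistic proteome-scale depth (root-to-tip roughly 0.3
amino-acid substitutions per site, wrasse radiation an order of magnitude
shallower than the distance to the outgroup).  The root sequence is drawn
from the stationary distribution.  Sub-seeds per gene follow a documented
splitting rule (`seed + 7919 * gene_index`), so gene sets are
order-independent and manifest replays are byte-identical.

What the simulator does **not** emulate: indels and alignment error
(columns are never misaligned), selection-driven convergence (planted sites
are overwritten outright rather than evolved under positive selection),
compositional heterogeneity across lineages, and correlated rates along
the sequence.  Passing tests therefore demonstrate the *statistical logic*
of the restriction under the substitution model — not robustness to
alignment artefacts, which real pipelines handle upstream with masking.

Null runs in the package use 100,000 sites (tests and the acceptance
script) — large enough that both noise classes are populated at the relaxed
stage, small enough that a full run takes seconds.

## Evidence filters

The downstream screens consume result tables from codon-model and
differential-expression software; the package applies only the stated
post-hoc thresholds and never refits those models.

* `curate_dnds()` removes free-ratio records with `dS > 1`,
  `N > sequence_length`, `N + S_sites >= sequence_length + 50` (the reading
  of "exceeds the sequence length by 50 or more"), `N*dN < 1`, or
  `S_sites*dS < 1`, recording every reason that applies.
* `intersect_psgs()` keeps genes passing both selection frameworks with the
  strict comparisons the screens state (`FDR < 0.05`, BEB posterior
  `> 0.95`).
* `filter_degs()` uses inclusive thresholds (`fdr <= 0.05`,
  `basemean >= 10`, `|log2fc| >= 0.3`); the effect size is applied to the
  magnitude because both up- and down-regulated genes are reported.
* `summarize_deg_direction()` reports both readings of "reduced across all
  regions": down in every region where the gene is differentially
  expressed, and the stricter down-and-differentially-expressed in all
  three regions.

## Worked example

```{r example, eval = FALSE}
tree <- cleaner_fish_tree()
traits <- cleaner_fish_traits()
model <- ccs_model(alpha = 0.5)

null_aln <- simulate_null(tree, model, n_sites = 100000, seed = 1)
report <- noise_report(null_aln, tree, traits, model)
report
autoplot(report)

# planted-recovery loop
dir <- tempfile()
gen <- generate_orthogroup_set(dir, tree, traits, model,
                               n_genes = 20, sites_per_gene = 300,
                               planted_fraction = 0.25,
                               sites_per_planted_gene = 2, seed = 7)
scan <- scan_orthogroups(dir, traits)
setequal(scan$cegs$orthogroup, unique(gen$truth$orthogroup))
```

## Known limitations

* The likelihood engine is amino-acid only; codon-level convergence and
  joint (as opposed to marginal) ancestral reconstruction are out of scope.
* Topology is fixed; only branch lengths and the gamma shape are estimated.
* The strict parallel rule requires complete foreground unanimity, so a
  single missing or divergent foreground sequence hides a genuine signal;
  this mirrors the deliberately conservative gene-level rule.
* The random/false split is defined only on simulated data, where truth is
  known; on real data the same machinery reports CCS sites without noise
  labels.
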