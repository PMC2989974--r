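---
title: "Methods: modelling the gain and loss of RNA editing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the gain and loss of RNA editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editevol)
```

## The problem

Plant mitochondrial mRNAs are edited post-transcriptionally, almost always
C-to-U, so the protein differs from the DNA's direct translation. Over
evolutionary time an edited C can be replaced by a genomic T — the edit is
then hard-wired and the site is *lost* — or, more rarely, a T can revert to
an editable C (*gain*). Because a C-to-T change at an edited site and a
C-to-T change at a synonymous third codon position are both silent at the
protein level, comparing their rates asks whether selection actively purges
edited sites or whether they decay at the neutral background rate. A second,
qualitatively different route wipes out many edited sites at once: gene
conversion with a reverse-transcribed cDNA copy of the edited transcript
(retroprocessing), which leaves a signature of clustered, simultaneous
losses. `editevol` implements this whole analysis chain against a fixed,
user-supplied phylogeny, plus a simulator that generates data with known
ground truth for every stage.

## Edit calling and its exclusion rule

A column is an edited site when at least one cDNA-covered taxon has genomic
`C` and transcript `T` at that column. Taxa with genomic `C` but no cDNA are
reported as `UNEDITED_C` with `evidence = "none"`; downstream, the binary
character matrix treats such a C as edited (editing competence is assumed
conserved at a site edited elsewhere), with a `strict` mode that scores them
as missing instead. Columns where cDNA evidence shows the site edited in
some taxa but unedited (still C in the transcript) in others cannot be
scored as a presence/absence character and are excluded; a genomic `T` in
other taxa is a loss, not heterogeneity, and never triggers exclusion.
Missing data (`-`, `?`) are excluded from all site counts — the conservative
reading where the sources are silent.

The profile predictor is deliberately simple: a genomic C is virtually
edited, both codons translated, and the score is the fraction of reference
proteins matching the edited but not the unedited residue (exact identity,
no substitution-matrix weighting); sites scoring at or above the threshold
(default 0.6) are predicted edited. When cDNA exists it always overrules the
prediction. This is a transparent stand-in for profile-based editing
predictors whose exact internal scoring is not public; the cDNA path is the
authoritative one throughout.

Protein-level consequences use the standard genetic code (plant mitochondria
use it) and the Kyte–Doolittle hydropathy scale; each edited column is
evaluated as a single-site edit of its codon.

## Parsimony mapping

Editing presence/absence characters are mapped with unit-cost parsimony
(Fitch counts, implemented as a vectorised dynamic programme that handles
polytomies natively and treats missing tips as fully ambiguous). Ambiguous
most-parsimonious reconstructions are resolved in a preorder pass that picks,
at each node, a state achieving the exact dynamic-programming minimum given
the parent's state; ties are broken toward the parent's state under DELTRAN
(changes delayed tipward, favouring parallel losses) and away from it under
ACCTRAN (changes pulled rootward, favouring an early loss plus reversal).
Because every step picks an argmin of the exact recursion, both resolutions
realise the Fitch minimum for every character; the test suite verifies on
enumerated instances that both are members of the full MPR set. An ambiguous
root state is resolved deterministically (state `1` first in the editing
coding, keeping the site ancestrally edited so losses map below the root)
and the ambiguity is visible in the reported state sets. Tree statistics
follow the usual conventions: `L` sums Fitch lengths over all characters,
CI and RI are computed over parsimony-informative characters with
min steps = observed states − 1 and max steps = non-missing tips minus the
largest state class.

## Synonymous rates

Ancestral codon sequences are reconstructed per nucleotide (Fitch + DELTRAN;
an HKY maximum-likelihood marginal reconstruction via phangorn is available
as an alternative engine). Columns containing any gap or ambiguity are
masked from reconstruction — the sources do not state how gapped codons were
handled, so they are excluded rather than guessed, and skipped codon-wise in
the distance counts. Per-branch synonymous divergence is counting-based in
the Nei–Gojobori style: synonymous site fractions per codon position
averaged between the two sequences, observed differences classified by
averaging over all shortest mutational paths (orderings through stop codons
dropped when avoidable), and the synonymous proportion corrected as
`dS = -3/4 log(1 - 4/3 p_s)`. A full codon-model likelihood is deliberately
out of scope: the analyses this feeds (ranks, ratios, contrasts) need an
unbiased, self-contained estimator, which the parameter-recovery tests
confirm at the divergences involved (< 0.3 per site); a hook for an external
codon-ML engine would slot in at `tree_branch_ds()`.

The relative-rate comparison is realised as Tajima's one-degree test
restricted to third codon positions, with an exact two-sided binomial on the
two exclusive-difference counts — the simplest exact test consistent with a
"pairwise relative rate test" description.

Where the most-parsimonious ancestral state is not unique, per-branch event
extraction offers a `fractional` mode: the expected event count under
uniform random resolution of ties in the preorder dynamic programme (each
realisation of which is itself most parsimonious). The default reports the
single DELTRAN resolution, which keeps event counts integral.

## Dating and absolute rates

Non-parametric rate smoothing minimises the sum over branches of squared
rate differences between each branch and its parent branch, with the root
term taken as the squared deviations of the root children's rates from
their mean (the convention of the original smoothing implementation, since
the objective needs a parent rate that the root lacks). Ages are
parameterised as fractions of the parent's age, which enforces the age
ordering by construction; optimisation is BFGS on logit-transformed
fractions from a deterministic start (ages proportional to the deepest tip
distance below each node) plus five randomly perturbed restarts, keeping the
best objective. A duration floor of `1e-6 x root age` guards zero-length
branches. On clock-like input the deterministic start is already the global
optimum and the returned chronogram equals the input rescaled (verified to
1e-6 relative error).

Because single-gene branch dS estimates often hit zero on short branches,
per-taxon absolute rates use the node-to-tip workaround:
`R_S = (sum of dS from the focal ancestor to the tip) / (focal age in
years)`. The pipeline defaults fix the root at 130 Ma and the focal node at
79.1 Ma; both are configuration values, and the focal age can instead be
taken from the smoothed chronogram. One deliberate resolution: the sources
name both rate smoothing and penalized likelihood in different places; the
protocol section's rate smoothing is implemented, and only it.

## Comparative statistics

`rate_summary()` compares, per taxon, the fraction of focal-ancestor edited
sites that read `T` in the tip against the fraction of focal-ancestor
third-position Cs that read `T`, with a two-sided Fisher exact test on the
2x2 table. The "changed" count compares the reconstructed focal state with
the tip state rather than summing path events; this keeps rates in [0, 1]
(a site lost, regained and lost again counts once) and reproduces the
definitional anchors — a taxon that lost every ancestral edited site has an
edited-site rate of exactly 1. Cumulative path events remain available via
`cumulative_changes()` for the contrast analyses, which by default count
gains plus losses ("changes"), with losses-only as a flag.

Sister-clade contrasts average branch values from the tips down (tip branch
value; internal = own branch + mean of daughters), difference the two
daughters at every binary node, and orient each pair so the x contrast is
non-negative. The regression is forced through the origin (contrasts have
mean zero): `slope = sum(xy)/sum(x^2)`,
`r = sum(xy)/sqrt(sum(x^2) sum(y^2))`, with `t = r sqrt((n-1)/(1-r^2))` on
`n - 1` degrees of freedom — the degrees-of-freedom convention matching the
n−1 pattern of the source tables. PIC contrasts standardise by branch
durations (the age of the split) via the classic pruning algorithm with
variance augmentation, computed through `ape::pic()`. Zero-editing clades —
lineages that cannot lose any more sites and therefore attenuate the
correlation — can be pruned to a single representative, keeping either the
longest or the shortest terminal branch.

The Fisher two-sided rule is the standard sum of all tables no more probable
than the observed one (stated explicitly because conventions differ); the
implementation is direct hypergeometric summation, checked in the tests
against both full enumeration and `stats::fisher.test`.

## The retroprocessing scan

The scan formalises the qualitative clustering argument: for each branch
with at least two mapped losses, and for every cluster size k from 3 up, it
finds the tightest window containing k losses and asks how often losses
redrawn uniformly from the branch's at-risk edited-site positions (those
still edited in the branch's ancestor) produce an equally tight window.
Per-window p-values are permutation fractions; the branch-level p calibrates
the minimum per-k p against its own permutation distribution, so scanning
several k on one branch does not inflate the branch-level false-positive
rate (verified ≈ α on null simulations). A branch that loses every at-risk
site is flagged as a whole-gene conversion candidate regardless of the
window test. Defaults: α = 0.05, 10,000 permutations in the pipeline
(smaller in the simulation harnesses); the seed is whatever the caller set,
and the pipeline logs it.

## The simulator and what it does (and does not) emulate

`sim_params()` defaults mirror the study system: 46 taxa on a Yule tree
rescaled to a 130 Ma root; five genes totalling ~4356 aligned positions with
5/44/25/30/25 edited sites concentrated at 1st/2nd codon positions
(the aggregate printed codon-position mix); shallow divergence
(`subst_scale = 0.08` expected substitutions per site root-to-tip, the order
implied by rates around 0.5 × 10⁻⁹ per site per year over 130 Ma); an
HKY-like per-position process with transition/transversion ratio κ = 2; and
a C-to-T multiplier at edited sites of `lambda_es = 3`, the few-fold
elevation the genes with signal display. Clade rate multipliers, windowed or
whole-gene conversion events with a completeness fraction (partially edited
cDNA templates), and partial cDNA coverage are all available. Everything is
logged: root sequence, all node sequences, and a per-branch mutation log
that replays exactly from root to tips (a tested invariant).

The simulator is per-position, not a full codon model: it does not impose
selection on amino acids, indels, or base-composition drift, and edited
sites evolve independently of their neighbours. Passing recovery tests on
these simulations therefore demonstrates that the estimators are correct
under the assumed process, not that real mitochondrial genes satisfy those
assumptions — in real data, codon-level selection and context effects will
add noise the harness does not model.

Harness conditions were fixed once, as the study conditions: rate-ratio
recovery uses 30 taxa, 40 edited sites, 200 third-position Cs and
root-to-tip depth 0.1 with equal position rates (so the realised
edited/third rate ratio equals `lambda_es`); dating recovery uses
autocorrelated lognormal branch rates with per-branch log-sd 0.15 — a
smooth, moderate violation of the clock of the kind rate smoothing is
designed for; PIC recovery co-simulates two Brownian traits at generating
correlation 0.5; the retro sensitivity grid is conversion-only
(`es_rate_mult = 0`: edited sites change only through the planted event),
isolating the detector from background noise whose effect on specificity
the null grid measures separately. The pooled rate-ratio estimator converts
per-lineage change fractions to hazards (`-log(1-p)`) before taking the
ratio, which removes the saturation bias at high ratios.

## Numerical choices and degenerate inputs

* Coordinates are 1-based in every user-facing table; codon index and
  position derive from the frame offset.
* Child order in all tree traversals is fixed by the smallest tip label in
  each subtree, making polytomy resolution and event placement
  deterministic.
* `branch_ds()` raises a saturation error when the synonymous proportion
  reaches 3/4 (the correction's domain edge); degenerate Fisher margins
  return p = 1; a relative-rate test with no informative sites warns and
  returns p = 1; an all-missing character is an error, as is a character
  matrix with no parsimony-informative columns when RI is requested.
* NPRS reports non-convergence only if every restart fails; the returned
  objective is never worse than the deterministic start.
* All simulator randomness flows from the caller's RNG state; the pipeline
  seeds it from the YAML config and logs the seed in `summary.json`.

## Known limitations

Editing in introns, tRNAs and non-coding regions, U-to-C editing, and
quantitative partial editing are out of scope. The dS estimator is a
counting approximation; branch-specific codon-model likelihoods would be
needed for absolute dN/dS inference, which this package does not attempt.
The whole-gene conversion flag requires the mapped losses to cover every
at-risk site on one branch, so a single conflicting site (e.g. a regain
inside the converted clade that parsimony re-explains more cheaply) can
mask a true event — visible in the sensitivity contrast between the
conversion-only and background-noise grids. Pruning variants recompute
branch statistics on the pruned tree, which is the defensible but not
unique choice when pruning merges branches.
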