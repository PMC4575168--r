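---
title: "Repertoire analysis of combinatorial scaffold libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

`loopscape` analyses deep-sequenced combinatorial libraries of the
hydrophilic Fn3 scaffold (and, generically, any three-loop scaffold with a
conserved framework) before and after binder selection. This vignette is
the package's own account of the underlying models, the choices that were
genuinely open, and what its tests do and do not establish.

## 1. Library model

A library design is a pool of sublibraries; each sublibrary specifies, per
loop (BC, DE, FG), a set of length variants, and each variant an ordered
list of site specifications. A site is either *conserved* (one residue),
a *fixed set* (an explicit amino-acid probability map, as synthesised from
tailored degeneracies or trimer codons), or a *degenerate codon* (three
per-position nucleotide mixtures). Degenerate-codon site distributions are
computed by exact enumeration of all 64 codons — the probability of a
codon is the product of its positional nucleotide fractions — so stop
probabilities fall out exactly (the CDR′ mixture yields 2 % stop, all of
it TAG, because its third position contains no A).

Two conventions required a decision:

* **Length-variant priors.** The published designs state that loop lengths
  were "guided by natural sequence frequency" without numbers; the
  packaged specs default to uniform priors over the listed variants and
  any prior can be supplied in the JSON spec.
* **Insertion labels.** Variable mid-loop blocks reuse the wild-type
  labels of the span they replace, in order; positions beyond the
  wild-type span get insertion-coded labels (`28a`, `54a`, …). Shorter
  blocks keep the *first* k wild-type labels. This keeps the fixed flank
  sites comparable across length classes, which is what every sitewise
  statistic needs; the arbitrary part (which wild-type labels a deletion
  removes) only affects how mid-CDR′ positions are named, not any flanked
  site.
* **Half-conserved sites.** The generation-2 notation "A/ASYDNT" (either
  conserved wild-type or a small set) is modelled as a single site-level
  50/50 mixture of the two alternatives, equivalent to two equimolar
  sub-pools differing only at that site.
* **Alphabet.** The 20 canonical residues plus `*` for stop; `X` and other
  ambiguity codes are rejected rather than silently dropped.

The framework sequence is *synthetic*: the canonical 94-residue human
tenth FN3 domain with the published hydrophilic substitutions, reverse
translated with a fixed one-codon-per-residue table (the original
construct's DNA is not public). No statistic in the package depends on
the codon choice; users with the real construct can supply their own
framework.

## 2. Synthetic populations and what they emulate

`sample_population()` draws clones i.i.d.: sublibrary by pool weight,
length variant per loop by prior, then residues site by site, with
degenerate codons sampled at the nucleotide level. The generator therefore
reproduces, by construction: sublibrary pooling, loop-length diversity,
the designed sitewise distributions, and stop codons at their designed
rate (the generation-1 design is 80.7 % stop-free). `inject_errors()` adds
per-base substitutions and single-base indels, emulating the
synthesis/sequencing error classes that produce frameshifted reads.

`simulate_selection()` is a *planted-truth* stand-in for bead/FACS
selection: a clone's log-fitness is a sum of per-site amino-acid scores
and per-loop length scores, clones with stops or indels get `-Inf`, and
each round resamples counts multinomially with probability proportional to
`count × exp(stringency × logfitness)`, preserving total reads exactly.
One selection round with score ln 3 on a 50/50 site moves it to 75 %, two
rounds to 90 % — the closed forms the tests check. Mid- versus
high-affinity tiers are emulated as 1 versus 3 rounds by default.

The model is deliberately sitewise-multiplicative (no epistasis), with no
avidity, off-target depletion, PCR amplification bias or paired-end read
artefacts. A green recovery test therefore establishes that the pipeline
recovers *independent sitewise effects* from realistic population sizes —
not that it would capture epistatic or avidity-driven selection, which the
real experiments may contain.

Every operation that consumes randomness takes an explicit seed and
restores the caller's RNG state; identical seed and inputs give identical
output.

## 3. Read processing

Reads are classified against the design framework via six 12-nt anchor
flanks around the three loops. Exact anchor matching is the default: the
framework is conserved by design and framework mutations are rare. The
consequences are spelled out rather than hidden: a substitution inside an
anchor makes a read `unidentified` (about 7 % of reads at a 0.1 % per-base
error rate), an indel inside a loop is a `frameshift`, an indel between
anchors is caught by the rigid inter-anchor spacing check, and an indel in
the terminal framework outside the anchored region is invisible to loop
analysis and leaves the read `full_length`. Because an anchor 12-mer can
also arise by chance inside a CDR′ loop (~1 in 20 000 clean reads), a
fallback resolver re-searches all anchor occurrences jointly under the
spacing constraints before a read is declared unidentified, which makes
classification exact on error-free simulated populations. Reads whose
loop length matches no design variant stay `full_length` but are flagged
unaligned and excluded from sitewise counts.

## 4. Clustering and weighting

Loop sequences are clustered per loop region at 80 % identity by greedy
centroid clustering: sequences are visited in descending read-count order
(lexicographic tie-break, making the procedure deterministic); each joins
the first centroid at or above threshold, else founds a cluster. Identity
is matches / alignment length under a global alignment scoring match 1,
mismatch 0, gap 0; among equal-score optima the alignment with the fewest
gaps is taken, so equal-length single substitutions score (n−1)/n while
cross-length comparisons are still possible. The identity denominator for
unequal lengths (alignment length, i.e. max length plus unmatched
overhang) is a convention the source analysis does not state — a noted
divergence risk. The inner loop is a small C++ dynamic programme with a
character-multiset pruning bound, which keeps 10^5-read populations in
seconds.

"Weighted by a power of one-half" is interpreted as transforming
within-cluster per-site read counts c → c^0.5 before summing across
clusters (`mode = "within"`); the alternative reading — cluster weight
√(cluster size) distributed over internal frequencies — is available as
`mode = "cluster_sqrt"` and satisfies the same probability-row invariants.
Background removal drops the rarest sequences by *cumulative read share*
(≤ 2 %), removing tied count groups only whole; it is intended for
mid-affinity populations, where bead sorting carries rare non-binders.

A consequence worth knowing: on low-diversity loops dominated by a few
huge clusters (e.g. the DE loop of sublibrary-1-heavy populations), the
power-½ transform deliberately flattens the distribution toward rare
variants. Frequency matrices from such loops are *biased* relative to read
frequencies even without selection — that is the point of the weighting
(overcounting protection), but it means null-calibration statements (§6)
hold in the high-diversity regime where clusters are mostly small, not
uniformly across loops.

## 5. Diversity statistics

Entropy is Shannon's H = −Σ p log p per site. The printed scale of the
source analysis (maximum 4.3 for a uniform 20-residue distribution) equals
log₂ 20, so **log base 2 is the default** even though the formula is often
written with ln; the base is an argument. Enrichment significance uses a
two-sample t-test per (site, amino acid) across replicate campaigns with
Bonferroni correction over all tests performed, flagged at α = 0.005;
with fewer than two replicates per group the report is produced with
undefined flags and a warning. Cysteine pair frequencies among
exactly-two-cysteine clones are normalised within that subset by default
(per-population normalisation is a flag). Framework enrichment compares
the translated framework of full-length reads against the reference and
reports non-reference residue frequencies in both populations.

## 6. LOOCV log-odds

Sequence probability assumes sitewise independence — the model implied by
training a sitewise frequency matrix — times an optional loop-length
prior: log₁₀ P = log₁₀ P(length) + Σ log₁₀ max(f, floor). The floor
(default 10⁻⁴, applied symmetrically to naive and evolved models) keeps
structural zeros of the designed library finite. Naive probabilities come
from the design's exact theoretical distributions by default (an empirical
naive matrix can be substituted); evolved probabilities are rebuilt for
each held-out cluster from the remaining clusters with the same weighting
pipeline, so no sequence informs its own score. Scores are reported in
log₁₀ with percent likelihood changes as 10^score − 1. Null calibration
(binder population drawn from the naive design) yields a fraction of
positive scores near ½ on the broadly diversified BC loop; see §4 for why
low-diversity loops are not expected to be null-calibrated under the
power-½ weighting.

## 7. The constrained design fit

The evolved sitewise distribution F is modelled as
F(s, a) = Σₖ (αₖ + βₖ ε_s) · fₖ(s, a) with equality constraints Σα = 1 and
Σβ = 0, so the effective weights αₖ + βₖ ε sum to one at every exposure.
The fit is the closed-form KKT solution of the equality-constrained least
squares problem; rank-deficient input sets (e.g. duplicated matrices)
raise a non-identifiability error rather than returning an arbitrary
solution. No sign constraints are imposed — boundary weights (0 %) are
reachable and negative weights are reported, not forbidden.

Identifiability at realistic noise deserves a note. With probability-row
inputs and 25 sites, objective noise of SD 0.01 leaves the *weight
functions* w_k(ε) = αₖ + βₖ ε well determined across ε ∈ [0, 1] (and α
exactly at ε = 0), while the split of a given w_k into intercept and slope
is poorly conditioned: α and β·ε trade off along the exposure direction,
and the β estimate of the exact least-squares solution has errors
approaching 0.07 in the worst few percent of random instances. The
acceptance suite therefore measures noisy recovery on the effective
weight curves — the quantity the model reports — not on the raw (α, β)
split.

Supporting inputs: homolog frequencies weight replicate alignment
sequences by the square root of their occurrence count (gaps excluded per
site); stability matrices (site × 20 ΔΔG values) convert to frequencies by
Boltzmann weighting exp(−ΔΔG/RT) with RT = 0.59 kcal/mol by default — the
original conversion is unstated, so RT is exposed and any externally
supplied stability-derived frequency matrix is accepted instead. The
convergence driver wraps a pluggable ΔΔG oracle and stops when the running
mean has moved less than 0.2 kcal/mol over the last five evaluations after
more than 50 evaluations, erroring with diagnostics on non-convergence.
The z-score against an unbiased control replaces every input by the
uniform 5 % matrix (under the constraints any weights then give F =
uniform, so the control residual needs no fit) and scales the residual
difference by its bootstrap SD over site resamples — bootstrap over sites
because the source's SD definition is unstated; this is a reporting
convention, and the package does not claim to reproduce any printed
z-value.

## 8. Structural exposure

SASA is Shrake–Rupley with a 960-point golden-spiral sphere per atom,
probe 1.4 Å, and element radii C 1.7 / N 1.55 / O 1.52 / S 1.8 Å (unknown
elements fall back to 1.7 Å with a warning). Relative SASA divides by
Gly-X-Gly extended-state reference areas, with exposure classified at
≥ 40 %. Target accessibility mutates the diversified loops to alanine
(side chains truncated past Cβ; glycines untouched), represents each
diversified side chain as a single Cβ sphere of 1.7 Å, and searches
viewing orientations (two angles; in-plane rotation is irrelevant under
orthographic projection) for the maximal total visible projected area of
the diversified spheres, computed by an orthographic z-buffer on a 0.25 Å
raster with *all* atoms as occluders (backbone occlusion on — a noted
divergence risk, as the original raster and occlusion conventions are
unstated). A coarse 10° grid is refined at 1° around the optimum, all
orientations within 5 % of the best total are kept, and each site reports
its maximum visible area over that orientation set. The exposure score ε
is mean relative SASA × mean accessibility across structures, rescaled to
[0, 1] by the maximum across sites (the source does not state its
normalisation; [0, 1] is the convention assumed by the fit).

## 9. Testing strategy and limits

All fixtures are generated in code: tiny designs over a synthetic
28-residue framework, toy PDB files written by the test helpers, and the
packaged synthetic homolog alignment (40 mutated framework variants plus
planted duplicates, for the √-occurrence weighting). Independent oracles
back every nontrivial computation: a brute-force 64-codon enumerator, an R
dynamic-programming identity oracle against the C++ clustering, plain
counting against the weighted pipeline at exponent 1, exhaustive
enumeration of two-site sequence spaces against the probability model,
closed-form softmax reweighting against the selection simulator, and
analytic spheres/discs against the geometry. End-to-end recovery runs the
full generator → processing → statistics chain at n = 10⁵ with planted
selection (the 20-random-model sign-agreement property runs at n = 2×10⁴
to stay within the suite's time budget; the binomial error there is far
below the tested effect sizes).

Known limitations, beyond those noted above: anchor matching is exact
(a 1-mismatch mode is a natural extension but is not implemented);
`inject_errors()` applies one error realisation per clone record rather
than per read copy; the LOOCV length prior is estimated from raw read
counts of the training clusters; and the orientation search scales with
raster area × orientations, which is fine for domains and test fixtures
but not optimised for large complexes.
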