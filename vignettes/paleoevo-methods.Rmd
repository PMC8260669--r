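---
title: "Dating retrotransposon insertions and genome duplications with paleoevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating retrotransposon insertions and genome duplications with paleoevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoevo)
```

## What the package computes

`paleoevo` reconstructs two kinds of events in a plant genome's recent
history from sequence alone:

1. **LTR retrotransposon insertions.** An LTR-RT inserts with two identical
   long terminal repeats. Each repeat then accumulates neutral substitutions
   at a rate $r$ per site per year. The observed divergence $\lambda$
   (mismatch proportion between the two LTRs of one element), corrected for
   multiple hits with the Jukes–Cantor transform
   $$K = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4\lambda}{3}\right),$$
   estimates the total pairwise distance $2rT$, so the insertion time is
   $$T = \frac{K}{2r}.$$
   The default $r = 7.0\times10^{-9}$ substitutions/site/year is the rate
   conventionally applied to plant LTR-RTs; it is a single global constant
   per run (per-lineage rates are out of scope).

2. **Whole-genome duplications.** Paralogous gene pairs retained from a WGD
   share a common divergence, visible as (a) a modal syntenic depth of 2
   when an unduplicated relative is used as reference — every reference
   gene is covered by two collinear blocks — and (b) a mode in the
   distributions of synonymous divergence ($K_s$) and of the
   fourfold-degenerate transversion proportion (4dTv) across paralog pairs.
   Two superimposed events leave two modes, the older one further right.

Every estimator is validated against a synthetic-genome simulator that
plants elements of known age, paralog pairs of known $K_s$, and a known
collinear layout.

## The simulator and what it does (not) emulate

The mutation model is site-independent Jukes–Cantor with **no indels**: a
site mutates with probability $p = \tfrac34(1-e^{-4d/3})$ to a uniformly
chosen different base, which is exactly the JC transition kernel at
distance $d$. Two LTR copies evolved independently at $d = rT$ therefore
show an expected mismatch fraction $\tfrac34(1-e^{-8rT/3})$, and the JC
correction applied by the dating layer is exactly the right inverse. This
is deliberate: it makes recovery tests sharp. It also means passing tests
do **not** demonstrate robustness to indel accumulation, nested or solo
LTRs, gene conversion between repeats, codon-usage bias, or among-site rate
heterogeneity — all genuine features of real genomes that the simulator
omits (and that the structural scanner only partially absorbs through its
gapped-alignment identity stage).

Elements are planted with TG…CA termini, identical flanking target-site
duplications (TSDs, 5 bp by default), and five fixed 30-bp marker motifs
standing in for the GAG/PR/INT/RT/RH protein domains; integrase before
reverse transcriptase encodes Ty1/copia, the reverse order Ty3/gypsy.
Domain *detection* is out of scope — classification consumes domain hits
as input, planted or user-supplied.

Duplicated gene copies accumulate strictly synonymous third-position
changes by proposal/rejection (a change is kept only if the amino acid is
preserved), so $K_a = 0$ holds by construction and $K_s$ recovery is
isolated from selection effects. Mutation continues until the package's own
Nei–Gojobori estimator, applied to the true gap-free alignment, is within
0.02 of the target (genes of 350–550 codons make the single-substitution
granularity ≈0.01–0.02, and the closest state is kept). The transversion
share of proposals at fourfold-degenerate sites is a parameter; setting it
to zero forces 4dTv $= 0$ exactly for every pair. With several hundred
codons per gene the realized values cluster tightly: planting $K_s \in
\{0.3, 0.7\}$ in two rounds produces distribution modes within ±0.01 of the
targets.

A clean WGD simulation emits both paralog anchors (original → mutated
duplicate) and identity anchors (reference gene → its retained copy), so
the reference-versus-duplicated-genome comparison carries the expected
depth-2 signal; $K_s$/4dTv are computed over paralog anchors only.

## Structural detection of intact elements

The scanner is a deliberate simplification of suffix-array maximal-repeat
tools: exact $k$-mer seeds ($k = 20$) shared at separations within
[`min_sep`, `max_sep`] are grouped per diagonal, split at gaps >150 bp,
extended outward ungapped with an X-drop rule (match +1, mismatch −2, drop
12), and then refined by searching ±25 bp for insertion hallmarks — the
longest exact 4–6 bp TSD flank match plus TG…CA termini on both copies.
Candidates are scored by gapped-alignment identity × length (a missing TSD
demotes the score by 10% but does not reject, and TG…CA termini are
recorded as flags, not required), conflicts resolved greedily by score with
a leftmost tie-break. Boundary refinement matters quantitatively: a few
background columns leaking into a young element's LTR alignment would
inflate $\lambda$ by ~0.05 per 20 bp and bias its age by megayears; with
hallmark snapping, planted boundaries are recovered exactly for virtually
all elements and mean age recovery stays within a few percent down to
0.5 Myr.

Thresholds (`min_ltr` 100, `max_ltr` 3500, `min_sep` 1000, `max_sep`
15000, `min_identity` 0.8) follow tool-community conventions for "intact"
elements; no published threshold set exists for the counts this class of
study reports, so all are configurable.

## Dating, saturation, and classification

$\lambda$ is computed over alignment columns where both bases are
unambiguous nucleotides — gap and N columns are excluded from numerator and
denominator alike (the alternative, full-length normalization, is not used;
this choice is the conventional one and is documented here because the
field's papers rarely state it). Elements with fewer than 50 usable columns
are reported `too_short`; elements with $\lambda \ge 0.75$ are reported
`saturated` and never assigned a time, mirroring the standard practice of
filtering divergences beyond the JC domain. The boundary is exclusive at
exactly 0.75, where the transform diverges. One caveat worth knowing: for
pairs near saturation, *any* alignment-based $\lambda$ is pulled downward
because the aligner converts clustered mismatches into gaps; truly
saturated elements can therefore surface as finite but absurd ages rather
than as `saturated`. Downstream summaries should treat ages beyond ~20 Myr
with suspicion at the default rate.

Pairwise alignment is exact Needleman–Wunsch (match 1, mismatch −1, gap −2,
linear gaps) with a deterministic traceback (diagonal, then gap in the
second sequence, then gap in the first); a progressive aligner is not
emulated since only two homologous sequences are compared. Superfamily
classification is rule-based on domain order (INT strictly before RT ⇒
Ty1/copia; RT — and RH if present — strictly before INT ⇒ Ty3/gypsy;
anything else `unknown`; duplicated domain types raise an ambiguity error).
Lineage assignment joins the query RT sequence to a neighbor-joining tree
of reference exemplars built from uncorrected p-distances and takes the
lineage of the nearest reference leaf by path length, exact ties yielding
`unknown`. The NJ implementation clamps negative branch lengths to zero,
transferring the deficit to the sister branch, and breaks Q-criterion ties
by label order, making output deterministic; it reproduces additive
matrices exactly (to 1e−9 in tests).

Insertion-time histograms use half-open bins $[iw, (i+1)w)$ with
$w = 0.5$ Myr by default (no width is standard in the literature);
saturated and too-short elements are tallied separately, never silently
dropped.

## Collinearity and syntenic depth

Chaining works in gene-rank space (order index along each chromosome, not
bp), ignoring individual gene strand; only block orientation (rank order on
the second genome increasing or decreasing) is kept. Within each chromosome
pair, a dynamic program maximizes
$\sum \text{anchor scores} - \text{gap\_penalty}\sum \text{skipped ranks}$
with at most `max_gap` (default 25) rank steps between consecutive anchors
on both genomes. Chains are extracted greedily by score from a shared
anchor pool (anchors are single-use; determinism is preferred over global
optimality), and chains with fewer than `min_pairs` anchors are discarded.
The field convention "more than 5 gene pairs" is ambiguous between ≥5 and
≥6; the default is `min_pairs = 5`, configurable. On instances small enough
to enumerate, the DP provably attains the exhaustive optimum (a test
enumerates all monotone chains on 200 random instances).

Syntenic depth of a reference gene is the number of blocks whose rank span
on the reference side contains it. The ploidy call is declarative: modal
nonzero depth 2 together with <10% of genes at depth ≥3 reads as
"duplication consistent" (a 1:2 copy ratio); in self-comparisons, trivial
self-pairs and mirror-duplicate blocks are removed first, so an
unduplicated control yields no signal rather than a spurious depth-1 mode.

## Ks, 4dTv, and peak detection

The synonymous/nonsynonymous estimator is Nei–Gojobori pathway counting
with JC-style correction, chosen over opaque tool internals because every
number it produces can be re-derived by enumeration: per-codon synonymous
site fractions from the standard code averaged over both sequences (changes
to stop codons count as nonsynonymous, so syn + nonsyn sites = 3 per
codon), multi-substitution codons averaged over all minimal pathways with
stop-traversing pathways excluded, and $K_s = -\tfrac34\ln(1-4p_S/3)$,
$K_a$ analogously. Codon alignment translates, aligns proteins (match 2,
mismatch −1, gap −4), and back-translates so gaps are whole codons;
pairs with <30 analyzable codons are `too_short`, $p_S \ge 0.75 - 10^{-5}$
is `saturated`. Maximum-likelihood codon models are out of scope.

4dTv is reported **raw**: the transversion proportion among third positions
whose codon prefix is identical in both sequences and fourfold-degenerate.
No HKY-style correction is applied — the raw proportion is exactly
countable and the planted-transversion tests are exact. Prefix identity in
*both* sequences is required, a conservative rule that avoids miscounting
at nonsynonymously diverged codons.

Peaks of a distance distribution are strict local maxima of a Gaussian KDE
(Silverman bandwidth by default) whose drop to the nearest flanking local
minima is at least 5% of the global density maximum. Distances live on
$[0,\infty)$, so the sample is reflected at zero to remove the kernel
boundary rolloff, and the grid extends 4 bandwidths past the data maximum
so a mode near the top of the range stays an interior maximum. Finite
samples temper the null behavior: KDE wiggle noise scales as
$(n\,\mathrm{bw})^{-1/2}$ and exceeds the 5% prominence threshold below
roughly $3\times10^4$ values, where a featureless distribution can yield a
spurious low-prominence peak; the null property is therefore guaranteed
only for large samples, and callers analyzing a few hundred pairs should
read single marginal peaks with care. Peak positions are invariant to value
ordering, and to duplication of the input at a fixed bandwidth (the
automatic bandwidth varies as $n^{-1/5}$ by construction).

The event report combines both lines of evidence with declarative, echoed
rules: modal depth 2 plus the youngest peak ⇒ a recent WGD at that
distance; each additional older peak ⇒ an older shared event; no peaks and
modal depth ≤1 ⇒ no duplication signal.

## Reproducibility and problem sizes

One global seed governs every stochastic stage; per-stage seeds derive from
a stable hash of (seed, stage name), so stages are reproducible in
isolation and pipeline reruns are byte-identical (checksums are recorded in
the run manifest). The test suite exercises dating recovery at 500 elements
per planted age on a ~4.4 Mb simulated genome, detection on a 2 Mb
background plus a 2 Mb random-sequence null, Nei–Gojobori agreement with a
pathway-enumeration oracle on 500 random 60-codon pairs, chaining
optimality on 200 instances of ≤12 anchors, and $K_s$ recovery at 200 pairs
per planted value — sizes chosen to make Monte-Carlo error comfortably
smaller than the tolerances they are checked against while keeping a full
run in the low minutes on one core.

## Known limitations

- No indel evolution, nested/solo-LTR formation, recombination, or rate
  heterogeneity in the simulator; recovery results bound estimator error
  under the model, not under real-genome messiness.
- Domain hits are inputs; there is no profile-HMM stage against a curated
  retroelement domain database.
- Saturated LTR pairs can masquerade as finite old ages (see above).
- The chaining DP is greedy across chains; a globally optimal multi-chain
  partition is not attempted.
- Absolute dating of WGDs in years from $K_s$/4dTv is intentionally not
  provided; modes are reported on the distance scale.
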