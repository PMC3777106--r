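---
title: "Profile-HMM DNA homology search: models, calibration and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-HMM DNA homology search: models, calibration and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profscan)
```

profscan searches nucleotide sequence databases with profile hidden Markov
models: probabilistic models of a DNA sequence family with
position-specific residue and indel preferences. This vignette is the
package's account of its science: the model and its assumptions, the
parameters that matter, how scores become E-values, what the synthetic
benchmark emulates (and what it does not), and the numerical and design
choices a maintainer would want written down.

## The model

A profile HMM of length $M$ has, for each consensus position $k$, a match
state $M_k$ with its own emission distribution $e_{M_k}(a)$ over
$\{A,C,G,T\}$, an insert state $I_k$, and a silent delete state $D_k$.
Transitions $t_k(\mathrm{MM}), t_k(\mathrm{MI}), \dots$ encode
position-specific indel propensities. Scores are log-odds in bits against
an i.i.d. background `null1` $f(a)$ (uniform by default):
$\mathrm{lod}_k(a) = \log_2 e_{M_k}(a)/f(a)$.

For searching, the core model is wrapped in a *unihit local* alignment
layer:

* flanking states $N$ (before) and $C$ (after) emit background residues at
  zero log-odds, with a length-dependent self-loop probability
  $\eta = L/(L+2)$ for a sequence of length $L$, so a full-length flank
  costs a constant $\approx 2.9$ bits rather than growing with $L$;
* fragment entry $B \to M_k$ with probability $2(M-k+1)/(M(M+1))$ (the
  uniform-fragment prior over alignment start points), and exit
  $M_k \to E$ from every match state at zero cost, the tool family's
  implicit-model convention for local alignment;
* an explicit $B \to E$ edge so the state space also contains the
  *no-alignment* path; an empty sequence therefore scores exactly 0 bits;
* one aligned segment per pass (*unihit*). Multiple hits on one target
  arise from multiple windows in the pipeline, not from a multi-hit core
  model; this removes one state from every recursion and from the
  enumeration oracle that validates them.

Three scores are computed on this state space. The *Viterbi* score is the
log-odds of the single best path; the *Forward* score sums over all paths
(including no-alignment) and is the quantity reported for hits; *posterior
decoding* combines Forward and Backward passes into
$P(\text{state } s \text{ emitted } x_i \mid x)$, the per-position
alignment confidence printed as `0-9,*` under each alignment.

Numerics: Forward/Backward run in row-scaled linear space (one scaling
constant per target position), which is exact double arithmetic with no
per-cell transcendental calls; Viterbi runs in natural-log space with an
explicit $-\infty$ sentinel. Agreement with an exhaustive path enumerator
is tested to $10^{-9}$ bits; the Forward/Backward identity holds to
$10^{-6}$ bits on fuzzed inputs (the package's stated tolerance for all DP
equality assertions).

## Profile construction

`build_profile()` estimates parameters from a weighted alignment:

* **Match columns**: a column is consensus when its unweighted non-gap
  fraction is $\ge$ `gap_threshold` (default 0.5); ties resolve to match.
* **Weights**: Henikoff position-based weights, normalized to the number
  of rows. They are cheap, standard, and hand-checkable.
* **Match emissions**: weighted counts plus a Laplace `pseudocount`
  (default $+1$) per nucleotide. The four-letter alphabet is small enough
  that Dirichlet mixture priors would add little; this is an acknowledged
  simplification.
* **Insert emissions** are fixed to `null1`, so insert emissions score
  exactly 0 bits. This keeps the ungapped filter semantics clean and is a
  common profile-search simplification.
* **Transitions**: weighted counts of the observed per-row state paths
  plus a pseudocount of total mass `pseudocount` per source state, shaped
  as (MM .90, MI .05, MD .05), (IM .80, II .20), (DM .80, DD .20). A
  symmetric $+1$ on each alternative would imply gap-open probabilities
  near $1/6$ at typical row counts — an absurdly indel-rich model — so the
  pseudocount mass follows the usual strong match-match prior instead.
  This is the one place the package deliberately departs from plain
  Laplace counting; the shape is a package constant (`TRANS_PRIOR`).
* **Degenerate codes** count fractionally across their compatible
  nucleotides on the query side; on the target side a degenerate residue
  scores $\log_2 (\sum_{a \in S} e(a) / \sum_{a \in S} f(a))$ over its
  compatibility set $S$, so `N` is always 0 bits and the DP needs no
  special cases.

Single sequences become profiles via `profile_from_single_sequence()`:
`match_prob` (default 0.85) on the query residue — odds of $+1.77$ bits
for a match and $-2.32$ for a mismatch, the same spirit as the classic
+2/-3 DNA scoring ratio tuned for ~70-80% identity — with
position-independent `gap_open` 0.02 and `gap_extend` 0.4.

## The acceleration pipeline

Scoring every target position with Forward/Backward is prohibitive, so
`search()` runs a cascade on each strand of each target:

1. **SSV** (single segment ungapped Viterbi): for every diagonal, the
   maximal-scoring contiguous run of match log-odds cells. The score is
   transition-free — the filter stays strictly cheaper than Viterbi and
   its threshold calibration absorbs the constant offset. Seeds at
   P $\le$ `p_ssv` (0.02).
2. **Windows**: seeds grow by `pad_factor` $\times M$ (default 2, which
   bounds any plausible gapped alignment of a $\le M$-node model) and
   merge when overlapping or adjacent. Chromosome-length targets are first
   cut into 256 kb blocks with $2M$ overlap, which guarantees no diagonal
   segment (length $\le M$) is lost at a join.
3. **Viterbi filter** at P $\le$ `p_vit` ($10^{-3}$).
4. **Forward/Backward** with posterior decoding, the composition-bias
   correction (below), and the final threshold P $\le$ `p_fwd`
   ($10^{-5}$); surviving windows become hits with envelope, alignment and
   confidence annotation, ranked by E-value.

The stage defaults mirror the published defaults of the tool family; all
are configurable, and `max_mode` (the `--max` flag of the CLI) disables
the cascade by tiling the whole target into windows and carrying
everything to the Forward stage. Note a deliberate property of the
defaults: `p_fwd` clips the weak tail of the hit list, so raising the
reporting E-value beyond a few hundredths of
$\mathrm{searched}/\mathrm{calib}_L$ adds nothing — filters, not the
report threshold, bound sensitivity at the low end.

**Composition bias (null2).** Genomic DNA is compositionally lumpy; an
AT-rich model aligned to an AT-rich region scores well for the wrong
reason. The correction builds an alignment-specific null
$\mathrm{null2}(a) = \sum_s u_s e_s(a) / \sum_s u_s$ from the posterior
usage $u_s$ of each emitting model state, scores the window residues
against $\log_2 \mathrm{null2}/\mathrm{null1}$ weighted by each position's
aligned-state posterior, and subtracts the clamped-at-zero total from the
raw Forward score. With emissions equal to `null1` the correction is
identically zero.

**Envelopes** are the smallest interval containing all positions with
aligned-state posterior $\ge 0.1$, unioned with the Viterbi alignment
span. The rule is simple, monotone in the posterior field, and testable;
nothing downstream depends on its fine details.

**Coordinates** are 0-based half-open internally and 1-based inclusive in
all output; minus-strand hits report `ali_from > ali_to`.

## Score statistics and E-values

`calibrate()` simulates `n` null targets of length `L` (defaults 200 and
10 kb) from `null1` and records, per target: the best SSV diagonal
segment; and — after building windows exactly as the pipeline does, from a
permissive seed floor at the SSV P = 0.999 quantile — the best window
Viterbi score and the best window bias-corrected Forward score. Gumbel
laws (location/scale by maximum likelihood) are fitted to the SSV and
Viterbi maxima, as extreme-value theory prescribes for optimal-alignment
scores. The Forward score is a sum, not a maximum; its right tail is
modeled as exponential with $\lambda$ fixed at 1 per bit (its known
asymptotic slope), anchored at $\tau$, the empirical $1 - 0.04$ quantile.
Below $\tau$ the P-value interpolates the stored empirical quantile grid
of the calibration scores — the tail law alone misprices mid-range scores,
and an honest body is what makes null P-values uniform over the whole
(0, 1) range, a property the test suite checks by Kolmogorov-Smirnov on
held-out nulls.

Because calibration windows are built by the same seeding machinery the
search uses, the calibrated distributions describe exactly the quantity
the pipeline reports. Calibration uses the raw-seeded windows of
*composition-neutral* null targets, where the null2 correction is
essentially zero; on biased real targets the correction then acts
conservatively, which is its purpose.

`score_to_evalue()` converts a stage score to a P-value per `calib_L`
scanned residues and rescales linearly:
$E = P \times \mathrm{searched\ residues} / \mathrm{calib}_L$ (both
strands counted). Linear rescaling ignores finite-length edge effects,
which is adequate for $L \gg M$ and documented as a limitation. The
self-consistency target — a search of null sequence yields on average one
forward-stage window with $E \le 1$ — is verified by
`forward_stage_hits()`, which scores windows without the filter cascade
(with default filters no $E \approx 1$ hit can survive `p_fwd`, by
design, so self-consistency is only observable at the forward stage).

Calibration defaults run automatically in `build_search_profile()` and are
serialized inside the profile text format, so any profile file reproduces
its E-values exactly.

## The synthetic benchmark

The benchmark reproduces, structurally, the classic remote-homology
protocol: split each family so that no query-side sequence is more than
60% identical to any test-side sequence; embed the test sequences at
random positions and strands in simulated genomic background; search with
(i) one profile per family, (ii) the family consensus as a single
sequence, and (iii) every query member separately with hit lists merged by
best E-value (*fpw*); pool hits over families, rank by E-value, and trace
sensitivity against false positives per decoy megabase per search. A
positive is an embedded instance with more than half its length covered by
a same-family hit (strictly more); a hit mostly covering background is a
false positive; hits mostly covering an instance of a *different* family
are ignored — the protocol's source is silent on that case, and ignoring
avoids punishing genuine cross-family homology detection.

**The family simulator** (`simulate_family()`) generates what the split
protocol needs without any external data. Each family: an ancestral
sequence of length 80-400 nt with its own Dirichlet-drawn base composition
(families differ in GC, as real repeat families do); two clades whose
ancestors each diverge from the root by a per-family substitution
probability drawn from 0.08-0.26, so families span the difficulty range
from just inside the 60% ceiling down to deeply remote; within each clade,
leaves branch serially off a *master lineage* that keeps accumulating
substitutions (steps of 0.06-0.14 per leaf, private twigs of 0.01-0.05, so each copy is a near-snapshot of the master) —
the ladder-like expansion typical of transposable-element subfamilies.
The ladder matters for the baselines: it makes family members
heterogeneously distant from the test clade, so the best single member
(what fpw exploits) sits closer than the member average (what a consensus
approximates). Indels open at 0.01/site with geometric length (mean 2).
The alignment is known by construction; no aligner is involved.

**The background** is a 15-state fully connected HMM trained by
Baum-Welch on the family simulator's mutated concatenates (heterogeneous
composition), then sampled for the decoy. EM from a symmetric start stalls
on a saddle, so training runs five dispersed random starts and keeps the
best likelihood; the winning run's log-likelihood trace is non-decreasing,
which the tests assert.

**Scale.** The package's benchmark protocol uses 20 families in 2 Mb of
decoy with five replicate seeds for the mode-ordering comparison, and
per-profile calibration with 80 null targets of 800 nt — sizes chosen so a
full three-mode replicate completes in a few minutes on one core while
leaving the Poisson counting regime of the E-values intact. The
acceptance script runs a lighter single-seed variant (12 families, 1 Mb).

**What passing does and does not show.** The simulator produces
substitution/indel divergence with compositional heterogeneity, uniform
embedding, and known truth. It does not produce tandem repetition,
low-complexity tracts, nested or fragmented insertions, lineage-specific
deletions of model regions, or the heavy-tailed length and copy-number
distributions of real genomes. Passing the benchmark shows the engine
orders query representations correctly on remote substitution-divergence
homology — the mechanism the method targets — not that real-genome
annotation would reach any particular sensitivity.

## Degenerate and edge inputs

* Empty targets score 0 bits everywhere and produce no hits.
* Fully degenerate (`N`) stretches score 0 bits per position and cannot
  seed.
* Targets longer than the raw-DP window cap (32,768 nt) are refused by
  `forward()`/`viterbi()`/`backward()` with a pointer to `search()`;
  the pipeline windows them instead.
* Lowercase input is uppercased; `U` maps to `T`; there is no soft-mask
  semantics (deliberately: case in genomic FASTA is annotation, and the
  engine's statistics make no use of it).
* Ties: equal-scoring Viterbi predecessors resolve in the fixed order
  B, M, I, D; consensus ties resolve alphabetically; equal-size identity
  clusters are dealt to sides in first-seen order.

## Known limitations

* Laplace emission pseudocounts (not Dirichlet mixtures) and fixed
  prior-shaped transition pseudocounts; both are package constants, not
  data-driven.
* The exponential Forward tail with $\lambda = 1$/bit is asymptotic;
  short models on short windows can deviate. The empirical body absorbs
  most of the error in practice.
* Linear E-value length rescaling without edge corrections.
* Unihit-per-window means a single window containing two distinct
  instances reports the better one; the other is usually recovered from
  its own seed window, but pathological overlaps can lose it.
* The SSV filter scores match columns only; a family whose signal lives
  mostly in indel structure (rare in DNA repeats) would be under-seeded.
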