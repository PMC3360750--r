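---
title: "Surveying EF-hand proteins and their calcium-binding affinity tiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying EF-hand proteins and their calcium-binding affinity tiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efhandscan)
```

## The biology being modelled

The EF-hand is the most common calcium-binding motif in eukaryotic
proteins: a helix-loop-helix unit of about 29 residues in which a
12-residue loop (motif residues 10–21) chelates a Ca²⁺ ion. Six of the
seven coordinating ligands come from loop positions 1, 3, 5, 7, 9 and 12:
positions 1, 3, 5 and 12 contribute side-chain oxygens (position 12 is
typically a Glu donating both carboxylate oxygens), position 7 coordinates
through its backbone carbonyl — and therefore tolerates any residue — and
position 9 binds through a bridging water. The Gly at motif residue 15
(loop position 6) is strongly conserved for steric reasons. EF-hands
function in pairs; proteins with an odd number of EF-hands typically
complete the pair by homo- or heterodimerisation (S100 proteins, calpain).

Calmodulin (CaM), the canonical four-EF-hand sensor, binds many of its
targets at IQ motifs, an approximately 25-residue amphipathic segment whose
sequence signature is the 11-position consensus
`(I/L/V) Q x x x R x x x x (R/K)`.

This package turns that structural knowledge into a self-contained,
testable survey pipeline: detect candidate EF-hands and IQ motifs in any
protein FASTA, compare each detected coordination loop with a CaM-derived
consensus, and grade its expected Ca²⁺ affinity into qualitative tiers.

## The detection grammar

Database-profile searches (InterProScan, PSI-BLAST) are the usual route to
EF-hand annotation, but they are irreproducible offline and their residue
logic is opaque. `scanEFHands()` instead evaluates an explicit grammar on
every 12-residue window whose placement admits a full 29-residue motif
(loop position 1 at motif residue 10):

* **Required checks** (all must hold): position 1 ∈ {D,E,N,S};
  position 12 ∈ {D,E}.
* **Scored checks** (at least `minScoredMatches = 3` of 4 must hold):
  position 3 ∈ oxygen donors {D,E,N,Q,S,T}; position 5 ∈ donors ∪ {G};
  position 6 = G; position 9 ∈ donors ∪ {G}.

Position 7 carries no constraint (backbone coordination is
residue-agnostic), and helix content is not evaluated — the 29-residue
window requirement is purely positional, as the identification is
sequence-based. An unknown residue `X` fails any check it is tested
against, because unknown chemistry cannot be asserted to coordinate. The
grammar is a reconstruction from the structural description of the
canonical motif, not a published residue table, and every set and threshold
is configurable (`PatternConfig()`, YAML via `readPatternConfig()`) so
users can tighten or relax specificity.

Overlapping candidate loops are resolved greedily left-to-right: a
candidate is dropped when its 12-mer overlaps an already-accepted loop.
This prevents one physical loop from being counted as several EF-hands in
the per-protein tallies. `allCandidates = TRUE` disables the resolution and
exposes the raw window set; note that only the raw candidate set is
guaranteed to shrink monotonically as `minScoredMatches` rises — greedy
resolution can shift which of two overlapping candidates survives.

### Expected background match rate

The grammar's stringency can be computed in closed form. On a uniform
background over the 20 residues, the required checks pass with probability
(4/20)·(2/20) = 0.02 and at least 3 of the 4 scored checks pass with
probability ≈ 0.0479 (the dominant term is missing only the rare exact-Gly
check at position 6). The per-window acceptance probability is therefore
≈ 9.6 × 10⁻⁴ — roughly one accepted candidate per thousand background
residues, which the motif-free benchmark (`falsePositiveRate()`) confirms
empirically at ≈ 8–9 accepted hits per 10,000 residues after overlap
resolution. Reaching substantially lower false-positive densities (e.g.
below 1 per 10,000 residues) requires `minScoredMatches = 4`, at the cost
of missing naturally degenerate loops; the package keeps 3 as the default
for sensitivity and reports the measured density rather than hiding it.

## The affinity model

Variation in Ca²⁺-binding constants across EF-hand proteins correlates with
the identity of loop positions 1, 3, 5, 7 and 9 — the five *critical
positions*. The package grades each detected loop by identity to a CaM
consensus at those positions:

1. `buildConsensus()` stacks fixed-length 12-mer reference loops into a
   gap-free column alignment (canonical loops are length-invariant, so no
   gapped alignment is needed and the procedure stays deterministic),
   records per-column residue frequencies, and takes the per-column
   majority as the consensus. Frequency ties are broken by a fixed residue
   ordering (`DENQSTGAVLIMFWYHKRCP`, first wins), so the profile is a pure
   function of its inputs.
2. `criticalIdentity()` returns the fraction of critical positions at
   which a loop matches the consensus string — with five positions, a
   multiple of 0.2. Comparison is against the consensus string, not a
   frequency-weighted score; the frequencies are retained in the profile
   for users who want to build weighted variants.
3. `classifyAffinity()` maps the fraction to a tier with an associated
   qualitative binding-constant range (association constants, M⁻¹):

   | tier   | rule                | Ka range  |
   |--------|---------------------|-----------|
   | strong | fraction = 1        | `1e4-1e7` |
   | medium | 0.5 ≤ fraction < 1  | `<1e4`    |
   | low    | fraction < 0.5      | `<1e2`    |

   The three published anchor points (100 % → strong, below 70 % → medium,
   below 50 % → low) do not by themselves cover the attainable grid — 0.8
   falls between them. The partition above honours all three anchors and is
   total and monotone on {0, 0.2, 0.4, 0.6, 0.8, 1}; 0.8 is deliberately
   graded *medium*, the conservative reading (anything short of perfect
   critical-position identity is expected to bind more weakly than CaM).
   The ranges are approximate bounds, never point estimates, which is why
   they are reported as strings.

### The packaged reference loop set

The consensus defaults to `referenceLoops()`: the four coordination loops
of the canonical vertebrate calmodulin (`DKDGDGTITTKE`, `DADGNGTIDFPE`,
`DKDGNGYISAAE`, `DIDGDGQVNYEE`), listed for ten vertebrate species. The
vertebrate CaM protein is 100 % identical across vertebrates, so the loops
repeat verbatim — 40 loops in total, which is exactly the point: CaM's
extreme conservation is what makes it a usable affinity yardstick.
Non-vertebrate calmodulins (yeast, plants, protists) do diverge; their
loops were deliberately not bundled because they could not be verified
against a primary database offline. The file is a plain TSV under
`inst/extdata/` and any user-supplied set with columns `label` and `loop`
(or a FASTA of 12-mers) can replace it. The resulting default consensus is
`DKDGDGTIDTEE`; positions 9–11 are tie-broken (each reference loop differs
there), which is why the tie order is fixed and documented.

## The survey layer

`runSurvey()` composes the stages deterministically: read FASTA →
optional length filter → EF-hand scan → per-loop affinity call → IQ scan →
summaries. The length filter (inclusive 100–2200 residues by default)
reproduces the usual practice of excluding fragments and giant proteins
whose length disparity distorts downstream alignments; boundary lengths
are retained because the exclusion rules are strict inequalities.
Summaries are the per-protein EF-hand count histogram (proteins with zero
hits appear only in the totals) and the pairing annotation: an even count
of ≥ 2 is "paired within protein", an odd count ≥ 3 is "putative
homo-/heterodimer pairing", and a single EF-hand is flagged as such.
`writeSurvey()` emits `hits.tsv`, `affinity.tsv`, `iq_hits.tsv`,
`histogram.tsv`, `pairing.tsv` and `run.json`; all written coordinates are
1-based inclusive (the in-memory data frames use the same convention —
this is R), and the metadata includes an MD5 digest of the pattern
configuration so runs are auditable. The timestamp is the only
non-deterministic field and is isolated in the metadata.

`pairwiseIdentity()` supports the survey's comparative use case (e.g.
target-vs-template identity before homology modelling): Needleman–Wunsch
global alignment with affine gaps via `Biostrings::pairwiseAlignment`
(match 1, mismatch 0, gap opening 10, gap extension 0.5 — EMBOSS-needle
style defaults, all configurable), with identity defined as
100 × identical pairs / alignment length *including gap columns*. The
denominator choice is stated because published identity percentages rarely
define it; with it, the measure is symmetric and equals 100 exactly for
identical sequences. The packaged
`synthetic_cam_like_pair.fasta` used in examples is a constructed,
clearly-labelled synthetic pair — no natural sequences are bundled.

## The synthetic proteome generator

`generateProteome()` exists so that every pipeline stage can be exercised
against known truth without downloads. It emulates the statistical shape
of a real survey input — proteins of 120–600 residues, a minority carrying
one or two EF-hand units, occasional IQ motifs, random background — while
controlling exactly what a scanner should find:

* **Background**: uniform over the 20 standard residues by default.
  Uniform is the simplest null for false-positive measurement; a named
  frequency vector can be supplied for composition-realistic runs (real
  proteomes are enriched in the donor residues, which *raises* the
  background match rate).
* **Embedded EF-hands**: each unit is guard(2) + helix E(9) + loop(12) +
  helix F(8). The loop is the reference consensus mutated at exactly *k*
  positions drawn from the affinity positions {3,5,7,9}; each mutation
  substitutes a residue outside both the position's allowed set and its
  consensus residue, so it is guaranteed to break that position's check
  and its consensus identity simultaneously. Mutating only {3,5,7,9}
  leaves the required positions 1 and 12 intact, separating *affinity*
  degradation (tier drops) from *detectability*; a separate
  `detectabilityMutationRate` deliberately breaks position 1 or 12 to
  produce scanner-invisible motifs for negative controls. The truth table
  records, per embedding, the mutation set, the intended tier
  (`classifyAffinity((5-k_critical)/5)`) and a `detectable` flag derived
  by rule (required positions intact and enough scored checks surviving —
  with the default threshold, two mutations among {3,5,9} already sink a
  loop).
* **Recoverability guarantee**: helix E and the two guard residues before
  each unit are drawn from residues outside the position-1 required set.
  No candidate window overlapping an embedded loop from the left can then
  pass the required checks, so greedy overlap resolution can never
  displace an embedded loop with a background artefact. Without this
  guard, roughly 1 % of embeddings would be displaced by chance and
  sensitivity benchmarks would be noisy by construction.
* **Defaults as study conditions**: 500 proteins with the repeating
  per-protein count template (1,2,0,0,1,2,0,0,0,0) — 300 embedded motifs
  in 200 proteins — mutation load uniform on k ∈ {0..4}, IQ motifs in 10 %
  of proteins. These sizes keep a full benchmark (generation + scan +
  classification) under half a minute on one CPU while leaving dozens of
  motifs in every tier.

Everything is seeded; identical seeds give byte-identical FASTA and truth
tables, and the generator restores the caller's RNG state.

What passing benchmarks on this generator does **not** show: performance
on real proteomes. The generator embeds canonical loops in random
background — it does not simulate homologous divergence, domain
architecture, compositional bias, pseudo-EF-hands (e.g. the S100 N-terminal
variant) or the non-canonical loops that database profiles catch. Scanner
sensitivity of 100 % against this truth means the implementation is
faithful to its grammar, not that the grammar captures every natural
EF-hand.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere, matching R and
  Bioconductor convention; report columns are explicitly suffixed
  `_1based`.
* Consensus ties: fixed residue order, documented above. Classifier
  boundary: `strong` uses a 10⁻⁹ tolerance on fraction = 1 so that 5/5
  computed in floating point cannot fall to `medium`.
* Empty inputs fail fast with typed messages (`empty-input error`,
  `validation error`, `configuration error`); invalid FASTA records are
  rejected with a warning naming the record, never silently altered.
* Sequences shorter than 29 residues produce no admissible EF windows
  (unless `requireFullMotifWindow = FALSE`); shorter than 11, no IQ
  windows.
* The infeasibility check for motif placement (`syntheticConfig()`)
  rejects configurations whose minimum protein length cannot hold the
  requested units before any sampling happens.

## Known limitations

* The grammar trades the sensitivity of profile HMMs for transparency; it
  will miss non-canonical EF-hands and accept ~1 candidate per 1000
  residues of random background at the default threshold (see above).
* Affinity tiers are qualitative. No Kd/Ka regression, no cooperativity
  between paired EF-hands, no structural validation.
* The ~25-residue context of natural IQ motifs is not modelled; only the
  11-position consensus is matched.
* The packaged reference set is vertebrate-only; users surveying divergent
  taxa should supply taxon-appropriate calmodulin loops.
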