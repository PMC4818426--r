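---
title: "Insertion-site analysis for Tol2 transposition assays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion-site analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tol2sites)
```

## Scope and model

This package analyzes transposon integration products recovered from a
circular target plasmid: junction sequences in, mapped insertion events,
target-site-duplication (TSD) calls, occupancy-bias statistics, hotspots
and a consensus motif out. Three models underlie it.

**The junction model.** An integration at 0-based position `p` with
duplication length `k` converts the target
`... [p, p+k) ...` into
`... [p, p+k) | transposon | [p, p+k) ...`: the duplicated word flanks
the transposon on both sides. A junction read is written 5'→3' from
inside the transposon terminal outward into `flank_len` bases of target.
Orientation `+` means the transposon left arm abuts the lower-coordinate
flank. All coordinates are 0-based, half-open, reduced mod the plasmid
length `L`; the insertion position is the first base of the duplicated
word. (GFF3/BED output uses each format's native convention.)

**The null model for occupancy.** Under no targeting preference, each of
`n_total` insertions falls into feature `i` with probability
`p_i = length_i / Σ length` over a disjoint feature set. Events outside
every annotated feature are counted under an explicit `unannotated`
feature whose length is the uncovered remainder, so the probabilities
sum to 1 and the multinomial is proper. Overlapping features are
rejected rather than resolved silently.

**The generative bias model.** The synthetic generator draws positions
with weights `w(p) ∝ exp(beta_at · ATfrac(window centered on p))`,
orientation Bernoulli(0.5), and a canonical 8-bp TSD with probability
`tsd_fidelity`; otherwise an exact duplication of aberrant length drawn
uniformly from {0..7, 9, 10}. The exponential-in-windowed-AT form is the
simplest monotone model that reproduces a preference for AT-rich
sequence; the assays this emulates establish *that* AT-rich segments are
favored, not a functional form, so `beta_at` is a free calibration knob
rather than a measured constant. The non-canonical length distribution
is likewise a modeling choice: the observed in vitro canonical rate
(86%) counts the non-8-bp outcomes without describing their structure.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `beta_at` | 8 | log-weight per unit AT fraction | weight ratio `exp(8·0.14) ≈ 3` between a 64%-AT and a 50%-AT window — a modest, realistic preference |
| `window` | 51 | bp | local-AT smoothing scale; odd so windows center on a base |
| `tsd_fidelity` | 0.86 | probability | canonical-TSD rate observed in vitro |
| `flank_len` | 30 | bp | ≥ 12 required: flanks shorter than the TSD search window are unparseable |
| `min_terminal_match` | 14 | bp | exact terminal anchor; the two miniTol2 terminals first differ at base 13, so 14 distinguishes them |
| `min_anchor` | 16 | bp | exact flank anchor; effectively unique on plasmid-scale targets |
| `max_tsd` | 12 | bp | > 8 so over-long duplications are observed, not clipped; canonical is a classification |
| `n_sims` | 10000 | draws | Monte Carlo resolution; add-one floor `1/(n_sims+1) ≈ 1e-4` |

## Numerical and design choices

**Exact matching only.** Flank anchors and terminal anchors are matched
exactly (no mismatch-tolerant alignment). On a few-kb plasmid a 16-mer
anchor is essentially unique; exactness keeps the mapping oracle-simple
and makes every failure mode an explicit reject category. `N`-containing
anchors never match and surface as unparseable. Circularity is handled
by searching the doubled sequence and reducing hits mod `L`; both
strands are searched via the anchor's reverse complement.

**Ambiguity.** A flank whose anchor hits more than one (position,
strand) is flagged ambiguous, reported with its lowest-coordinate hit,
and excluded from statistics — counting it would inflate hotspots.

**TSD from geometry, verified on reads.** For a concordant pair the two
transposon-adjacent coordinates imply the duplication length
`k = (p_out − p_in + 1) mod L` exactly; `k > max_tsd` is discordant.
The read flanks are then compared with `detect_tsd()` and the event is
canonical iff `k = 8` and the copies agree over at least 8 bases. Chance
homology can extend a suffix–prefix overlap beyond the true duplication,
so the mapped geometry, not the overlap length, is authoritative.

**p-values.** Both one-sided empirical p-values are reported with the
add-one correction `(1 + #extreme)/(1 + n_sims)`, so p is never 0 and
the smallest reportable value is `1/(n_sims + 1)`. No two-sided folding
is applied; how often simulated counts are bigger and smaller are
separate questions and both are answered. `exact_multinomial_tail()`
enumerates all count vectors (feasible for `n_total ≤ 12`, ≤ 4 features)
as an independent oracle.

**Hotspots.** A hotspot is an exact position recovered in ≥ 2 distinct
experiments (any orientations) or in both orientations within one
experiment. A `tolerance` parameter (default 0) allows ±k-bp grouping by
single-linkage for noisier data; the default stays exact because the
rule marks positions, not windows.

**Consensus.** The motif window is fixed at 3+8+3 = 14 to match the
reference signature `TNA(C/G)TTATAA(G/C)TNA`. A column yields a single
base at frequency ≥ `strong_threshold` (0.8), a two-base IUPAC code when
the top two jointly reach 0.8 and each reaches `majority_threshold/2`
(0.25), else `N`. Compatibility with the reference is IUPAC subset
inclusion per position, so a sharper consensus is compatible with a
looser one.

**Rounding.** Founder-table percentages round half-up to integer
percent (`87.5 → 88`), matching the usual table formatting; R's
round-half-to-even is deliberately not used.

**Seeds.** Every randomized operation takes an explicit seed and
restores the caller's RNG state. The pipeline derives stage seeds
deterministically from the master seed plus a stage offset, so any stage
reruns identically in isolation and two runs of one config are
byte-identical.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the analysis
assumes: circular coordinates, both orientations, AT-biased positions,
canonical/non-canonical TSDs at a set rate, multiple experiments.
It does not model sequencing error, chimeric library artifacts, PCR
duplicates, near-duplications with mismatched copies, or excision
chemistry. Passing round-trip tests therefore demonstrates that the
parser/mapper/caller chain is internally correct and that the
statistics behave as designed under their own assumptions — not that
the pipeline is robust to real library noise. The reject-accounting
categories (unparseable, chimeric, unmapped, ambiguous, discordant,
orphan) are exercised with constructed corruptions in the tests.

## Problem sizes used in validation

The test suite works at deliberately small scales: 2–4-kb plasmids,
libraries of 30–500 events (333 for the canonical-rate recovery check,
matching the in vitro junction count), 10,000-draw Monte Carlo for
headline p-values and 2,000–4,000 draws inside property loops. The
null-uniformity check simulates 200 replicate libraries of 2,000
uniform insertions each and pools the four per-feature `p_greater`
values per replicate before comparing with U(0,1) by
Kolmogorov–Smirnov distance; pooling is used because per-feature
p-values are discrete (multinomial counts), and 2,000 events per
replicate keeps that granularity fine relative to the 0.05 distance
bound.

## Known limitations

- Exact anchors assume a low-complexity-free target; highly repetitive
  or extremely AT-skewed plasmids can make 16-mers non-unique (such
  flanks surface as ambiguous rather than being force-called).
- The occupancy test conditions on the observed total and feature
  lengths; it does not model per-experiment overdispersion.
- `detect_tsd` reports exact-copy duplications only; mismatch-tolerant
  "near-duplication" scanning is out of scope for the canonical call.
- The bias model is phenomenological. Recovering `beta_at` from data is
  not attempted; the parameter exists to generate realistic test
  conditions, not to estimate biology.
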