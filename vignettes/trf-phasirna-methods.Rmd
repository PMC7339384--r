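---
title: "Methods: tRF and phasiRNA discovery, differential expression and target analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tRF and phasiRNA discovery, differential expression and target analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfphas)
```

# Scope and design

`trfphas` analyses two small-RNA libraries — a control (`C1D`) and a
treated (`A1D`) condition, one mixed-sample library each — for two
classes of plant small RNA: tRNA-derived fragments (tRFs) and 21-nt
phased secondary siRNAs (phasiRNAs). The pipeline runs in five stages:

1. exact (mismatch-free) alignment of 18–30-nt reads to a tRNA
   reference and read-end peak calling of tRFs;
2. structural classification of each tRF against the tRNA cloverleaf;
3. detection of 21-nt phased loci by a phased
   ratio/number/abundance score, with tRNA/rRNA exclusion;
4. joint reads-per-million (RPM) normalization of tRF, phasiRNA and
   miRNA counts and Audic–Claverie differential expression;
5. miRanda-style phasiRNA target prediction with a nearest-neighbour
   duplex-energy gate, integrated with transcript expression status.

Every stage is driven by a synthetic-data generator with planted
ground truth, so the whole chain is testable at desk scale without any
sequencing download. The packaged reference tables (a curated table of
15 stress-related phasiRNAs with target families and a per-class RPM
total table from a tomato abscisic-acid response experiment) anchor the
exact aggregate checks.

# The cloverleaf partition and tRF classification

A mature tRNA (72–90 nt) is represented by six contiguous landmark
intervals — 5' acceptor side, D-arm, anticodon arm, variable loop,
T-arm, 3' acceptor side — plus the three loop sub-intervals. From these
the five tRF source regions are derived (0-based half-open):

| region | interval | anchor |
|--------|----------|--------|
| `5e` | `[0, d_loop_end - 2)` | third-from-last base of the D-loop |
| `D`  | `[d_loop_start - 2, ac_arm_start + 2)` | D-arm ± flank |
| `A`  | `[ac_arm_start - 2, ac_arm_end + 2)` | anticodon arm ± flank |
| `V`  | `[v_loop_start - 2, t_loop_start + 4)` | variable loop, extended |
| `3e` | `[t_loop_start + 2, len)` | third base of the T-loop |

Only the `5e` boundary is anatomically canonical (a D-loop ending at
position 22 gives the standard 20-nt 5' fragment); the remaining
boundaries are design choices. The ±2 flanks create the deliberate
overlap zones between adjacent regions that the dual-classification
rule requires. The `V` region extends to two bases past the `3e`
anchor rather than stopping at `v_loop_end + 2`: a symmetric ±2 flank
would leave the 5' half of the T-stem in no region, breaking the
coverage invariant (every position in exactly one or two regions).

A fragment receives the label of every region containing at least 75%
of the fragment's own length (the fragment length, not the region
length, is the denominator); two qualifying regions give a dual label,
none gives `others`. The rule is checked against a brute-force
per-position counting oracle on 10,000 random fragments, including
fragments at exactly 75%.

# tRF peak calling and quantification

The caller works on copy-weighted 5'/3'-end profiles of the pooled
libraries (pooling gives one shared tRF catalogue, which both
conditions then quantify). Iteratively: take the highest-support
unassigned 5'-end position (at least `min_support`, default 2 copies),
gather reads whose 5' ends lie within ±2 nt, take the copy-weighted
modal 3' end of that cluster (ties toward the longer fragment, which
keeps the dominant 20-nt boundary stable under symmetric noise), emit
the candidate, mask the cluster, repeat.

Two consequences of the modal-end design are worth stating plainly:

* Planted fragments sharing a 5' end (e.g. 19/20/22-nt variants of one
  cleavage site, as the dominant leaf tRF population shows) are
  reported as a single modal fragment. Boundary-exact recovery is
  guaranteed only for fragments whose 5' ends are separated by more
  than the clustering tolerance.
* Recovery is conditional on support. With diffuse background noise, a
  planted fragment must out-vote the noise inside its ±2 clustering
  window — roughly `depth × noise_fraction × 5 / (n_tRNAs ×
  positions_per_tRNA)` copies (about 40 at the recovery experiment's
  conditions). The recovery experiments therefore use a 50-copy
  support floor; below it, no end-density caller can fix the boundary,
  and the tests make that precondition explicit rather than assert the
  impossible.

Expression of a tRF is the copy sum of reads with at most 3 bases
outside the tRF interval (`max(0, trf_start - read_start) + max(0,
read_end - trf_end) <= 3`). A read within the slack of several
overlapping tRFs counts toward each: the per-tRF phrasing of the rule
implies independent counting, and no deduplication is attempted. tRFs
below 2 RPM in *both* libraries are removed as noise; detailed
reporting further restricts to features reaching 10 RPM in at least
one library.

# Phased-locus detection

A read's *phase position* is its 5' end; antisense reads are shifted
+2 nt (the Dicer 2-nt 3'-overhang convention), so a minus-strand read
of the ladder at sense register `r` satisfies `(start + 2) mod p = r`.
Windows of 9 cycles (189 nt at `p = 21`) slide in 1-cycle steps; for
each register the components are

* `A_p` — copy count of phased reads (phase position in register,
  length exactly `p`),
* `A_t` — copy count of all reads in the window,
* `N_p` — distinct occupied phased positions (per strand),
* `R = A_p / A_t` — the phased ratio,

and the score is `N_p × R × ln(1 + A_p)`: zero without phased reads,
strictly increasing in each component, and translation-invariant. The
combination is a design decision — the cited scoring systems name the
three components but not their formula — and both formula inputs and
the threshold are configuration keys. `p = 24` is supported but not
exercised by default, since the phasiRNAs modelled here are 21 nt.

The default calling threshold (3) was calibrated on simulation before
the sensitivity checks were run: across 200 uniform-noise runs
(1,500-nt reference, 800 read copies, lengths 18–24) the best
qualifying window score exceeded 0 in under 1% of runs and never
exceeded 2.1, while planted ladders (8 cycles, 30% noise, 800 copies)
scored at least 45. Windows also need 4 distinct occupied phased
positions; merged same-register windows are trimmed to their occupied
positions, so a locus always spans at least 4 cycles. Loci overlapping
tRNA/rRNA-style exclusion annotations are dropped and logged —
tRNA-derived ladders are the classical false positives of phasing
scans. Individual phasiRNAs are one per occupied position, counted per
library from reads matching position, strand and length exactly; ids
follow the `<ref>_<locus>_<pos>(<strand>)` convention with the duplex
position indexed from 1 within the precursor.

# Joint normalization and the Audic–Claverie test

The RPM denominator of each library is the *combined* tRF + phasiRNA +
miRNA read total — miRNAs enter only through this denominator, which
is why the generator emits miRNA reads as a single per-library total.
Within one library the three class totals therefore sum to one
million RPM.

For counts `x` (library 1, total `N1`) and `y` (library 2, total
`N2`), the conditional probability mass is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$

computed in log space; the two-sided p-value doubles the smaller tail
(both tails including `y`, capped at 1), and the upper tail is summed
directly rather than via `1 - lower` so extreme divergences keep full
relative accuracy. The identity `p(y|x) = dnbinom(y, size = x + 1,
prob = N1/(N1+N2))` provides the independent oracle: tail sums from
`pnbinom` agree with the package's summation to better than 1e-12
relative error over the full `x, y ≤ 200` grid at `N2/N1 ∈ {0.5, 1,
2}`. One property worth knowing: because the construction conditions
on `x`, the doubled-tail p-value is *directional* — `p(7, 19)` and
`p(19, 7)` differ even for equal totals (0.0290 vs 0.0192), although
the pmf itself is symmetric there. The tests assert the pmf symmetry
and a factor-2 bound between the two orientations.

Response tiers use the raw p-value (single library per condition; no
replicate structure exists for a dispersion model, which is also why
no DESeq2-style machinery is involved): `|log2FC| < 0.25` is
`unchanged`; `|log2FC| ≥ 0.25` with `p < 0.05` is `up`/`down` by sign,
`significant` when additionally `|log2FC| ≥ 1`; fold-change passes
with `p ≥ 0.05` are reported as `non_responsive` rather than folded
into `unchanged`. Zero handling: one-sided zeros give infinite fold
changes and classify by sign with significance from the p-value;
both-zero features are `unchanged`; a pseudocount is available but off
by default. A Benjamini–Hochberg q-value column is emitted for
transparency, but no multiple-testing correction enters the tiers.

# Target prediction

The duplex scorer is a local alignment of the sRNA against the target
window in antiparallel orientation: Watson–Crick pair +5, G:U wobble
+1, mismatch −3, gap open −9, gap extend −4, substitution scores ×4
over sRNA positions 2–8 (gap penalties unscaled), opposite gap types
never adjacent, deterministic tie-breaks. A perfect 21-nt duplex
scores `4×(7×5) + 14×5 = 210`. The scorer is verified against an
exhaustive alignment enumeration on small instances and an independent
plain-R dynamic program at production size.

Free energy sums nearest-neighbour stack terms over consecutive paired
columns plus a duplex-initiation penalty of +4.09 kcal/mol; mismatches
and gaps interrupt stacking; no stack means 0. The Watson–Crick stack
values are the standard Turner nearest-neighbour set; wobble-containing
stacks carry representative mid-range values (−1.5 against a G:C
neighbour, −0.8 against A:U, −0.4 for tandem wobbles) — adequate for
gate logic, not for quantitative thermodynamics. AU-end and
self-symmetry corrections are omitted. Because the initiation penalty
is physical, a duplex with a single weak stack can have slightly
positive ΔG; energies only become reliably negative from a few
contiguous stacks on.

The published gates (score ≥ 500, energy ≤ −50 kcal/mol) are kept as
the configuration defaults, but no standard weight set brings a
perfect 21-nt duplex anywhere near 500 — the original score scale is
not reconstructible from the published description, so those defaults
pass nothing under the decided weights. Analyses on synthetic data use
calibrated gates instead: under the default weights, random background
windows reach scores around 150 (the seed multiplier inflates partial
seed matches), while planted perfect sites score 210 with energies
below −25 kcal/mol, so the calibrated gates are (180, −25). Site
conservation across related genomes, the third property of the
original method, is out of scope; the site record keeps a `passes`
flag only for the two implemented gates.

# Integration

Transcript status (`elevated` / `decreased` / `unaltered` /
`undetected`) uses a 0.1-FPKM detection floor and a 1.5-fold
(`|log2| ≥ 0.585`) change threshold — decided defaults, since the
transcriptome criteria live outside this pipeline; `undetected` is
kept as a fourth status rather than folded into "no change". The
report has one row per (responsive phasiRNA, target family with a
passing site), counting distinct target genes and detected transcripts
by status; transcripts shared between phasiRNAs are annotated, not
deduplicated away. Per-direction abundance sums deduplicate phasiRNAs
across family rows — a phasiRNA targeting three families still counts
its RPM once — which is exactly what reproduces the published
4091.77 → 2330.79 (down) and 316.07 → 590.39 (up) R-gene sums. Class
shares are percentages of the combined miRNA + tRF + phasiRNA RPM sum
per library; the reference totals sum to 999,998 RPM in the control
library, and shares are computed against the actual sum, which
reproduces the printed two-decimal percentages.

# The synthetic generator

What it emulates: cleavage-biased tRF production (default profile: 80%
canonical 20-nt 5' fragment, 10% each 19- and 22-nt variants sharing
the 5' end, on tRNAs whose Ala members start with G and carry the
D-loop U — the dominant leaf signature), a log-normal abundance
hierarchy with tRNA-Ala weighted 10×, phased 21-nt ladders with a
configurable antisense fraction under the 2-nt overhang convention,
diffuse uniform background noise (the number of background categories
scales with the noise copy mass so each carries only a few copies),
two-condition counts that are negative-binomial around `mean` and
`mean × effect` (Poisson at dispersion 0), and a per-library miRNA
total sized so the miRNA block dominates the joint denominator.

What it does not emulate: adapter artefacts, sequencing error and
quality scores, real tomato sequence composition, multi-locus tRF
families with shared subsequences, or replicate structure. Passing
tests therefore demonstrate the correctness of the algorithms under
the stated generative model, not performance on real libraries — in
particular, real data contain boundary heterogeneity and mapping
ambiguity the generator deliberately leaves out.

Problem sizes used by the test-suite and the acceptance script, chosen
to exercise each property at meaningful signal levels: 8–60 tRNAs,
library depths of 800–30,000 copies, 100 simulation runs each for
phasing sensitivity (8 cycles, 30% noise) and the uniform-noise false
positive rate, a 10,000-instance classification oracle, the full
`x, y ≤ 200` Audic grid at three library ratios, and 200 items at a
combined depth of order 10^5 for fold-direction recovery.

# Known limitations

* Dataset-scale counts from real libraries (hundreds of tRFs, the
  locus census of a genome-wide phasing scan) depend on tool-version
  exact behaviour of the original peak caller and phasing scorer and
  on the deposited sequencing data; they are out of reach at desk
  scale and are not reproduced here.
* The phased-score formula and threshold are this package's decided
  defaults, not the cited tool's; locus counts are comparable only
  within this package.
* The duplex energy model is a stack-sum approximation (no loop,
  bulge or dangling-end terms) with representative wobble values.
* Single-library designs have no dispersion estimate: the
  Audic–Claverie p-value treats all variation as Poisson counting
  noise, so its p-values are anti-conservative for biological
  replication questions.
* tRF target prediction is deliberately absent (the field considers
  it unreliable), as is the miRNA identification pipeline — miRNA
  totals are consumed as an input.
* The partition is defined on the provided tRNA sequence as-is; no
  assumption is made about a post-transcriptional 3'-CCA, and genes
  with one simply have it inside the `3e` region.
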