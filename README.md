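# trfphas

Discovery and differential analysis of two classes of regulatory plant
small RNA — tRNA-derived fragments (tRFs) and 21-nt phased secondary
siRNAs (phasiRNAs) — in a two-library design (a control and a treated
condition, one mixed-sample library each), as used to study how
exogenous abscisic acid (ABA) reshapes the small-RNA landscape of
tomato leaves. The package is aimed at plant small-RNA analysts who
need the full chain — fragment calling, structural classification,
phasing detection, joint normalization, exact two-library testing, and
target integration — as tested, reusable functions rather than a
one-off collection of scripts.

## What it computes

**tRF calling and classification.** Reads of 18–30 nt are aligned to a
tRNA reference with no mismatches; tRF boundaries are called from
copy-weighted read-end profiles (modal 5'/3' ends, iterative masking).
Each tRF is classified against the tRNA cloverleaf into
5e-/D-/A-/V-/3e-tRF: a fragment gets a region's label when at least
75 % of the fragment lies inside the region, two labels when it sits in
an overlap zone, and `others` otherwise. Expression is the copy sum of
reads with ≤ 3 bases outside the tRF interval.

**PHAS locus detection.** A sliding 9-cycle window is scanned over all
21 phase registers; a read is phased when its 5' end (antisense reads
shifted by the Dicer 2-nt overhang) matches the register and its
length is exactly 21. With phased abundance A_p, total abundance A_t,
occupied positions N_p and ratio R = A_p/A_t, the score is

    score = N_p · R · ln(1 + A_p)

with a simulation-calibrated calling threshold, merging of
same-register windows and removal of loci overlapping tRNA/rRNA
annotations.

**Differential expression.** tRF, phasiRNA and miRNA reads are
normalized as one pool: RPM = count / (tRF + phasiRNA + miRNA reads) ×
10⁶. Two libraries are compared with the Audic–Claverie exact test,

    p(y | x) = (N2/N1)^y (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) ),

two-sided as the doubled smaller tail. Features with |log2FC| ≥ 0.25
and p < 0.05 respond (significant at |log2FC| ≥ 1); |log2FC| < 0.25 is
unchanged; a 2-RPM noise filter and a 10-RPM reporting filter apply.

**Target prediction and integration.** phasiRNA–transcript duplexes
are scored by a miRanda-style local alignment (WC +5, G:U +1, mismatch
−3, gaps −9/−4, seed positions 2–8 scaled ×4; a perfect 21-mer scores
210) and a nearest-neighbour stack-sum free energy; sites pass on a
score and an energy gate. Passing sites of responsive phasiRNAs are
joined with transcript expression status into a per-family report with
per-direction abundance sums.

## Worked example

The packaged reference table holds the 15 differentially expressed
stress-related phasiRNAs of the tomato ABA experiment with their RPM in
the control (C1D) and ABA-treated (A1D) libraries:

```r
library(trfphas)
tb <- phasirna_target_table()
aggregate_direction_sums(tb, "down", families = c("NBS-LRR", "STK", "RLK"))
#> # A tibble: 1 × 5
#>   direction n_phasirnas   c1d   a1d  delta
#>   <chr>           <int> <dbl> <dbl>  <dbl>
#> 1 down                6 4092. 2331. -1761.
```

Six down-regulated phasiRNAs target resistance-gene families, and
their combined abundance falls from 4091.77 to 2330.79 RPM under ABA
(each phasiRNA counted once even when it targets several families).
Family-group counts and the class-share summary come from the same
tables:

```r
count_target_families(tb)
#>   n_phasirnas n_targeting_r_genes n_targeting_tfs
#> 1          15                  12               7

class_share_summary(srna_class_totals())
#>   library class       rpm share_pct
#> 1 C1D     miRNA    833750     83.4
#> 2 C1D     tRF       50520      5.05
#> 3 C1D     phasiRNA 115728    11.6
#> ...
```

so tRFs make up 5.05 % of the jointly normalized small-RNA pool in the
control library. The exact two-library test works directly on raw
counts and library totals:

```r
audic_pvalue(x = 120, y = 40, n1 = 1e6, n2 = 1e6)
#> [1] 1.161408e-10
```

A feature falling from 120 to 40 copies between two libraries of a
million reads is differential far beyond the p < 0.05 bar. For a full
synthetic run — simulated tRNAs, planted tRFs and a phased locus, two
libraries, differential expression, target prediction and the
integration report — see `run_all(pipeline_config(seed = 1))` or the
`analysis/` scripts.

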