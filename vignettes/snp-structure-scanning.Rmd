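---
title: "Scanning point mutations for local RNA structure disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning point mutations for local RNA structure disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpfoldscan)
```

## The problem

Many regulatory RNA elements — IRE hairpins in UTRs, miRNA target sites,
structured ncRNAs — work because of their secondary structure. A single
nucleotide substitution can melt a stem or create a competing one
(a *riboSNitch*), and the phenotype follows the structure, not the
sequence. Comparing only the two minimum-free-energy (MFE) structures is
brittle: the MFE structure is one draw from a thermodynamic ensemble, and a
mutation that redistributes ensemble mass can matter even when the MFE
drawing barely changes. `snpfoldscan` therefore compares the *ensembles*
of the two alleles, localizes where they diverge, and calibrates the
divergence against what random substitutions do to random sequences of the
same length and GC content.

## The model and the statistic

For each allele the package computes the base-pair probability matrix
$P = (p_{ij})$: the Boltzmann-ensemble probability that positions $i$ and
$j$ pair, obtained from McCaskill-style inside/outside recursions over all
pseudoknot-free structures. The structural difference between wild type and
mutant on a sequence interval $[i, j]$ is either the Euclidean distance

$$d(i,j) \;=\; \sqrt{\sum_{i \le k < l \le j}
  \bigl(p^{\mathrm{wt}}_{kl} - p^{\mathrm{mut}}_{kl}\bigr)^2}$$

or the Pearson correlation $r(i,j)$ of the two probability vectors over the
same cells. Only pairs with *both* endpoints inside the interval
contribute: the local regions of interest are self-contained structural
elements, and this convention makes $d$ monotone under interval inclusion,
which the scan exploits. The reported *local region* is the interval
maximizing $d$ (or minimizing $r$) subject to a minimum length; all
interval scores are obtained in $O(n^2)$ by two-dimensional cumulative
sums.

Significance is empirical. A background table holds, for each (length, GC)
stratum, $N$ scores obtained by mutating one uniformly random position of a
random sequence to a uniformly random alternative base and running the
identical pipeline. The add-one estimator
$p = (1 + \#\{\text{null} \ge d\})/(N+1)$ avoids $p = 0$ and bounds $p$ in
$[1/(N+1),\, 1]$; for the correlation measure the tail is reversed.

### The three modes

* **Mode 1** (short sequences): global fold of the region ±`flank` around
  the variant, full interval scan.
* **Mode 2** (long sequences): sliding-window local folding (window `W`,
  maximum pair span `L`), then a two-step scan — all intervals of a fixed
  length first, then refinement of every sub-interval of the winner.
* **Mode 3** (screen): every one of the $3n$ possible substitutions is
  scored with Mode 2; substitutions below `screen_cutoff` are re-scored
  with Mode 1, and those below `report_cutoff` are reported.

## The energy model

The folding engine is self-contained compiled code using a
nearest-neighbor model: sequence-dependent stacking energies for the 21
distinct stacked combinations of the six admissible pairs (AU, UA, GC, CG,
GU, UG), size-dependent hairpin/bulge/internal-loop initiation penalties
with Jacobson–Stockmayer logarithmic extrapolation and an asymmetry term,
an affine multibranch-loop model ($a + b\cdot\text{branches} +
c\cdot\text{unpaired}$, defaults 3.4/0.4/0.0 kcal/mol), minimum hairpin
size 3, interior loops capped at 30 unpaired bases, and
$kT = 0.6163$ kcal/mol (37 °C). Watson–Crick×Watson–Crick stack values are
the standard unified nearest-neighbor set; wobble-containing stacks are
plausible approximations. Deliberately *not* modeled: dangling ends,
coaxial stacking, tetraloop bonuses and the special 1×1/2×2 interior-loop
tables. The model is therefore not energy-compatible with the reference
Vienna implementation, and published P-values computed with that engine
(e.g. the FTL U22G example) are compatibility benchmarks rather than exact
targets; all calibration in this package is internally consistent because
foreground and null runs share the same model.

This trade buys exactness where it matters for validation: every energy
term is reproducible by explicit loop decomposition of a fixed structure
(`structure_energy()`), so exhaustive enumeration of all structures of a
short sequence (`enumerate_structures()`, guarded to 14 nt) yields
reference pair probabilities that the dynamic program must reproduce to
numerical precision — the test suite holds this to $10^{-9}$ over hundreds
of random sequences, and the same oracle pins the MFE fold. Partition
function arrays are scaled per nucleotide by a factor derived from the MFE
to keep long folds inside double-precision range.

### Local folding

Windows of width `W` start at every position (stride 1; the trailing
truncated windows are included so every position is covered), each window
is folded globally, and $p_{ij}$ is averaged over all windows containing
both $i$ and $j$. Pairs with span $\ge L$ are zero. With `W` and `L`
covering the sequence this reduces *exactly* to the global fold, which is
both a correctness check and the reason a 100-nt Mode 2 run equals a
Mode 1 run under the defaults.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `flank` | 200 | nt | folding region on each side of the variant; Mode 1 accepts 100–800, Modes 2/3 200–800 in steps of 50 |
| `min_len` | 50 | nt | smallest reportable local region; the method's showcased disrupted region is exactly 50 nt |
| `W` / `L` | 200 / 120 | nt | local-folding window and maximum pair span |
| `fixed_len` | 120 | nt | first-pass window of the two-step scan, matched to `L` |
| `prob_floor` | 0.01 | — | correlation only: cells where neither allele reaches this are excluded, otherwise the sea of near-zero cells dominates $r$ |
| `screen_cutoff` | 0.2 | — | permissive Mode 2 pass so the Mode 1 confirmation dominates final calls |
| `report_cutoff` | 0.05 | — | the significance level of the published screen |
| `N` per stratum | 500 | — | resolution floor $1/(N+1) \approx 0.002$ |

Tie-breaking in all scans is deterministic: best score, then shortest
interval, then smallest start. Degenerate inputs fold to the open chain
(all probabilities zero, score 0, $p = 1$); an unscorable correlation
interval is an explicit NA result, and the null sampler redraws rather
than recording NA.

## What the synthetic null emulates — and what it does not

Null sequences are i.i.d. mononucleotide draws at the stratum's GC
(`P(G) = P(C) = gc/2`), with one substitution, position and alternative
base uniform. This is the minimal reading of "distributions of
substitution effects as a function of length and GC": it preserves
composition but not dinucleotide content, codon structure, or any
phylogenetic signal of real transcripts. A green calibration test
establishes that the *pipeline* is internally unbiased — on matched null
inputs, P-values are uniform and ~5% of substitutions clear $p < 0.05$ —
not that 5% of substitutions in any real UTR are riboSNitches. Because the
substitutions of one sequence share a folding context, their significant
fraction fluctuates strongly between sequences; the calibration check
pools several independent sequences so the measurement self-averages the
way a long genomic screen does. Nearest-bin stratum lookup (with clamping
outside the grid) was chosen over interpolation for monotonicity safety.

## Design choices that were genuinely open

* **Backend.** The method names the Vienna global/local folding engines;
  no R binding to them exists here, so the package ships its own engine
  (above) and treats engine-specific published values as compatibility
  benchmarks. The alternative — re-deriving a full Turner-2004
  implementation — would have made the enumeration oracle (the package's
  strongest correctness instrument) impractically intricate.
* **Pair inclusion.** Boundary-straddling pairs are excluded from interval
  scores; including them would break monotonicity and blur localization.
* **Null substitution count.** One substitution per null draw, mirroring
  the single-SNP foreground question; compound mutants are scored against
  the same single-substitution null, which makes their P-values
  conservative for disruption.
* **Mode 3 intermediate cutoff.** The published method states the final
  0.05 level but not the screen cutoff; 0.2 keeps the confirmation stage
  decisive while skipping ~80% of Mode 1 re-folds on null-like input.

## Known limitations

* No pseudoknots, no dangles/coaxial terms; wobble stack energies are
  approximate. Absolute energies (and hence which variant ranks first)
  can differ from Turner-2004 engines even though calibration holds.
* Empirical P-values cannot resolve below $1/(N+1)$; no parametric tail
  extension is attempted.
* Insertions/deletions are out of scope; only substitutions are modeled.
* The brute-force Mode 3 screen is $O(n)$ folds of $O(n^3)$ each; the
  published 1000-nt cap is kept as a warning.

## A worked example

```{r example, eval = FALSE}
library(snpfoldscan)

# null substitution effects at 100 nt / GC 0.5, then screen a sequence
params <- run_params(mode = 2)
tab <- build_background_table(length_bins = 100, gc_bins = 0.5, n = 500,
                              params = params, seed = 1001)

set.seed(34)
s <- random_sequence(100, 0.5, id = "demo")
hits <- run_mode3(s, params, tab)
length(hits)      # substitutions confirmed at p < 0.05
hits[[1]]
write_results_tsv(hits, "demo-screen.tsv")
```

The README shows this example with the numbers it actually prints. A note
on interpretation it illustrates: a substitution that removes a single
pair from an otherwise stable long stem scores a Euclidean distance near 1
and is *not* significant against the null — significance requires a
genuine ensemble rearrangement (a melted helix or a switch between
competing conformations), which is exactly the riboSNitch phenotype the
method is after.
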