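---
title: "Methods: marker panels, recovery scoring and backcross simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker panels, recovery scoring and backcross simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabcr)
```

## The problem

Transgenes and other target loci usually arrive in genotypes with poor
agronomics, because transformation works only in a few amenable lines.
Marker-assisted backcrossing (MABC) moves the locus into an elite
*recurrent* parent: cross donor × recurrent, then repeatedly backcross
carriers to the recurrent parent. Each backcross halves the expected
donor genome, so after $g$ backcrosses the expected donor fraction is
$2^{-(g+1)}$ — 25% in BC1, 12.5% in BC2. Genome-wide markers speed this
up twice over: *foreground* markers (or an assay) identify carriers, and
*background* markers rank carriers by how much recurrent genome they
already carry, so the best individuals parent the next generation.

`mabcr` implements the desk side of such a program: design of an InDel
marker panel from two-parent variant data, recovery scoring and
selection, the small supporting statistics, and a forward simulator
that reproduces the expected recovery trajectories.

## Background recovery

For one individual scored at $I$ markers with $S$ homozygous-recurrent
(`RR`), $h$ heterozygous (`RD`) and $d$ donor-homozygous (`DD`) calls,
the package computes the recurrent-allele fraction

$$ R_g \;=\; \frac{2S + h}{2I} \times 100\% $$

which reduces **exactly** to the classical backcross formula
$R_g = (I+S)/(2I) \times 100\%$ whenever $d = 0$. Donor homozygotes
cannot arise in a clean backcross but do occur in real data (scoring
errors, outcrossing); the allele-counting form degrades gracefully
instead of failing, and a property test asserts the reduction on random
matrices. Missing calls shrink $I$, so scored-marker counts are
per-individual — this is visible in published tables, where printed
percentages within one experiment are fractions over slightly different
denominators.

### The integer-inversion oracle

A printed percentage $R_g$ determines the integer pair $(I, S)$ almost
uniquely: `infer_marker_count()` scans candidate $I$ and asks, for each,
whether every printed entry equals $(I+S)/(2I) \times 100$ for some
integer $S$ within ±0.011 (the tolerance absorbs truncation versus
rounding of two printed decimals). For the BC1 table shipped in
`bc1_recovery_table()`, $I = 108$ is the unique count in 90–130
explaining all 18 entries. The BC2 table is deliberately *not* forced
to one count: $I = 87$ is modal (51/70 entries), $I = 86$ explains 14
more, and a few plants resolve to 83–86 — exactly the missing-data
pattern the per-individual denominator predicts.
`resolve_marker_count()` therefore resolves each plant to the
representable $(I, S)$ nearest the modal count.

## The meiosis model

Gametes are simulated per chromosome with a crossover count drawn
$\mathrm{Poisson}(L/100)$ for a chromosome of $L$ cM, crossover
positions uniform, and no interference — the Haldane model, under which
the recombination fraction at map distance $d$ Morgans is
$r = (1 - e^{-2d})/2$. Genomes are ancestry mosaics (segment lists per
haplotype), so arbitrary cross sequences preserve an exact tiling of
$[0, L]$; a property test checks the tiling across chained meioses, and
the Haldane fraction is checked by simulation at 10 cM
($r \approx 0.0906$).

Assumptions worth naming: no crossover interference and no obligate
chiasma (so short chromosomes sometimes transmit whole); a fully inbred
recurrent parent (its gametes are non-recombinant by construction); an
error-free carrier assay by default (`foreground_select()` takes an
optional flip rate); and selection acting only through the statistics
computed here, not through fitness.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| GQ threshold | > 30, strict | Phred | standard variant-calling practice; equality drops |
| length difference | [30, 50], closed | bp | resolvable on agarose at 100–200 bp amplicons |
| flank window | 120–150 | bp | amplicon-scale context for GC/repeat screening |
| flank GC | [0.55, 0.60], closed | fraction | primer-friendly window |
| repeat policy | motif 1–6 bp spanning ≥ 12 bp | — | flags homopolymers/microsatellites that blur sizing |
| divergence envelope | (0,≤2), (1,≤1), (2,0) | bp, count | uniqueness vs the reference assembly |
| panel spacing | 20 | cM | one marker per 15–20 cM covers a maize genome with ~100 markers |
| spacing tolerance | ± spacing/2 | cM | greedy window; gaps logged where candidates run out |
| BC1/BC2 thresholds | > 80%, > 90%, strict | $R_g$ | the program's printed selection rules |
| homozygosity floor | $0.75^n \le 0.05$ | probability | all-carrier verdict needs $n \ge 11$ progeny |

Boundary conventions ("30 to 50", "between 55% and 60%") are read as
closed intervals — the plain reading — and are arguments, not
constants. The χ² test is uncorrected by default with a Yates flag,
since which form produced a published statistic is rarely stated; for
a 111:113 split the uncorrected value is 0.0179 and the Yates value
0.0045 (both far below 3.84 — a published "0.01" for this split matches
neither exactly and is left unreproduced).

## The synthetic world

The generator emulates, with one seed fixing everything:

* **Map**: 10 chromosomes, lengths 288 down to 148 cM, 2040 cM total —
  inside the usual 2000–2200 cM quoted for maize. The lengths were
  chosen once so a saturated 20 cM greedy spacing yields exactly
  $\sum_c (\lfloor L_c/20 \rfloor + 1) = 108$ markers, the scored-marker
  count recovered from the BC1 table; published sources give no map
  geometry, so this is a modeling choice, flagged as such.
* **Candidate sites**: length differences uniform on 1–80 bp (so the
  30–50 filter keeps ≈ 21/80), per-site flank GC sampled from
  0.45–0.70, a 15% tandem-repeat injection rate, GQ ~ round
  N(40, 15²) clipped to [0, 99] (straddling 30), divergence counts
  uniform on 0–4. Every filter has true positives and true negatives by
  construction.
* **Founders**: a random recurrent genome (GC 0.47), a donor genome
  identical except at the variant sites, and a transgene locus
  mid-chromosome 8 carried by the donor — the published insertion
  chromosome; the mid-arm position is a default, not a claim.
* **Populations**: backcrosses and selfs via the meiosis model above.

What a green test does **not** establish: real InDel discovery depends
on resequencing depth, repeat content and reference quality that the
generator does not model (its genome is i.i.d. sequence with injected
repeats); published cascade counts (tens of thousands of raw sites
down to ~10³ screened and ~10² panel markers) are property of those
data and are deliberately not acceptance targets. Likewise amplicon
behaviour (primer thermodynamics, touch-down PCR, gel resolution) is
out of scope — the package stops at sequence-level screening rules.

## Linkage drag around the foreground locus

Scoring is done on foreground-*selected* carriers. Conditional on donor
ancestry at the transgene locus, every linked marker is donor with
probability $1 - r$ rather than $1/2$, so the carrier-conditioned BC1
expectation is slightly below 75%. On the default map and panel the
nine chromosome-8 markers contribute an expected deficit of about one
percentage point; simulations in the acceptance suite land at ~74%,
bracketing the published 74.80% together with the unconditional 75%.
This is biology, not bias: the package reports it rather than
correcting it away.

## Numerical and design choices

* **Alignment for divergence screening** is a fitting alignment (whole
  flank vs best reference window) with unit match/mismatch/gap scores
  via `Biostrings::pairwiseAlignment()`, replacing an external BLAST
  step so the package stays self-contained; tests verify planted
  mutations against an independent dynamic-programming oracle.
* **bp → cM interpolation** is linear per chromosome (no recombination
  profile is assumed); positions are 1-based in VCF/TSV and 0-based
  half-open in BED, with a round-trip test guarding the off-by-one.
* **Greedy panel selection** takes the first candidate per chromosome,
  then the candidate nearest `last + spacing` within ± spacing/2;
  empty windows restart beyond the window and are logged as gaps.
* **Selection order** is descending $R_g$ with id as tie-break, so
  picks are deterministic.
* **Homozygosity testing** assumes lethal screening of non-carriers:
  selfed-hemizygote survivors are carriers with probability 1 and the
  all-carrier null probability is $0.75^n$; with a single progeny the
  verdict is withheld (`inconclusive`) rather than asserted.
* **The 2^−ΔΔCt calibrator** is an explicit argument: when the
  recurrent parent does not express the transgene there is no natural
  within-experiment calibrator, so none is guessed.
* **Scheme sizes** default to the published program (224 BC1 seedlings,
  103 scored positives, 7 BC1 parents, ~70 BC2 positives, 2 picks,
  two selfing generations) and are all configurable.

## Known limitations

* No crossover interference; recombination hot/cold spots and the
  genetic-vs-physical map distinction are collapsed into linear
  interpolation.
* The phenotype-similarity criterion used alongside $R_g$ in real
  programs is an external boolean hook, not a model.
* The repeat policy is perfect-tandem only; diverged low-complexity
  regions pass it.
* `read_vcf()` supports exactly the two-sample GT:GQ subset the
  pipeline needs; symbolic and multi-allelic records are skipped with a
  warning, not interpreted.
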