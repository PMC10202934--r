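---
title: "Models and methods behind oncomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oncomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomir)
```

oncomir models the computational workflow of a CDK2AP1/DOC1 oncomiR
study in oral squamous cell carcinoma: prioritize candidate miRNAs from
an array screen, quantify their repression of the CDK2AP1 3'-UTR in
reporter assays, localize the miR-21/CDK2AP1 antagonism on tissue
microarrays at single-cell resolution, screen tumor-only exomes, and
tie marker expression to disease-free survival. This vignette explains
each model, its assumptions and tunable parameters, the design choices
that were genuinely open, and what the synthetic-data generators do and
do not emulate.

## The prioritization score

Candidate miRs are scored as the sum of two components.

**Expression component** (`quantile_group_score()`): the mean
normalized log-intensity of each miR across the CDK2AP1-deficient cell
lines is binned into the empirical quartiles of the per-miR means — 0
for the first quartile up to 3 above the third. Quartile boundaries use
linear-interpolation empirical quantiles (R's default type 7), and a
value exactly on a boundary goes to the lower group. This tie rule is
deterministic and has the convenient degenerate behavior that an
all-ties cohort scores 0 everywhere. The deficient-only mean is the
default because the screen profiles deficient lines; `expr_samples =
"all"` switches to the whole panel.

**Evidence component** (`evidence_tier_score()`): three tiers of
miR–target interaction evidence. With `v` = experimentally validated in
at least one curated database (TarBase, miRWalk, miRTarBase, miRecords
are represented simply as source labels) and `p` = predicted by at
least `min_algorithms = 6` of the 12 prediction programs:
tier 1 when neither `v` nor `p`, tier 5 when both, tier 3 otherwise.
The numeric mapping {1, 3, 5} is a design choice: the source procedure
describes three ranked criteria and a combined range of 1–8, and with
the expression component in {0..3} the minimal odd-step mapping {1, 3, 5}
is the unique natural assignment reproducing that range. It also gives
the selection cutoff a crisp meaning: a combined score ≥ 7 requires
validation, broad in-silico support, *and* expression in the upper half
of the screen. The mapping and the prediction cutoff are both
arguments, not constants. "In-silico predicted" inside the
both-supported tier is interpreted with the same ≥ 6-algorithm cutoff
as the middle tier, for internal consistency.

`combine_and_select()` joins the two components, selects at `threshold
= 7`, sorts by combined score (ties broken lexicographically by miR
id), and assigns tier 1 with a warning to miRs lacking an evidence
record — absence of evidence is the weakest evidence.

## Assay models

**qPCR** (`fold_change()`): plain `2^-ΔΔCt` with the per-target ΔCt of
a calibrator sample subtracted; replicate calibrator wells are averaged
on the ΔCt scale. No amplification-efficiency correction is modeled —
the quantification this package mirrors uses the plain method, and
adding efficiency models would change the estimand.

**Dual luciferase** (`normalize_luciferase()`): each well's firefly
counts are divided by its renilla counts (transfection-efficiency
control), and well ratios are normalized to the mean mock ratio *of the
same plate*. Per-plate anchoring is deliberate: transfection batches
differ systematically, and mock-relative activities are only
comparable within a batch. The mock condition is exactly 1 by
construction, which the tests exploit.

**Coefficient of Drug Interaction** (`cdi()`): defined here as the
combination readout divided by the *average* of the single readouts.
This deviates from the more common product convention
(`combo / (a × b)`); both are implemented (`method = "product"`)
because the two can disagree qualitatively and a reader comparing
against the product convention should be able to reproduce either. The
classification thresholds 0.9/1.1 are a reporting convenience with no
deeper justification; the raw CDI is always returned and the thresholds
are arguments. CDI uses condition means rather than per-replicate
pairing — wells are not physically paired across conditions, so a
pairing would be artificial.

## The spatial TMA pipeline

The pipeline starts from segmented-cell measurement tables (one row per
cell: coordinates, tumor/stroma compartment from the pan-cytokeratin
channel, and mean/median/SD intensities per channel and cell region).
Image analysis itself — segmentation, AI tissue classification — is out
of scope; a pixel size of 0.345 µm is carried as metadata only.

1. **Outlier exclusion** (`merge_and_filter()`): z-scores are computed
   per median-intensity channel over the *merged* cohort (all cores
   together, matching how a cohort-level artifact filter is actually
   run), and a cell is flagged when |z| > 3 in any median channel.
   Two-sided by default — staining dropouts and saturation artifacts
   both occur — with a `high_only` mode for saturation-only filtering.
   Flagged cells are retained with `excluded = TRUE`; no stage ever
   drops rows, so cell counts are conserved and decisions are
   auditable. A zero-variance channel cannot yield z-scores and is
   skipped with a warning rather than an error.
2. **Core summaries** (`summarize_cores()`): per core, the mean of the
   median cytoplasmic miR-21 and median nuclear CDK2AP1 over
   non-excluded tumor cells, plus their cell-level Pearson correlation.
   Cores with fewer than 500 non-excluded tumor cells are flagged
   `included = FALSE` — small cores make both the means and the
   correlation unstable. The correlation uses tumor cells only by
   default (core aggregates are tumor-compartment quantities); an
   all-cells mode exists for sensitivity analysis.
3. **Ranking** (`rank_cores()`): ascending Pearson r, so the strongest
   miR-21/CDK2AP1 anti-correlation ranks first; undefined correlations
   (constant channels) rank last; ties break by core id.
4. **Compartment comparison** (`compare_compartments()`): per-core
   stroma/tumor ratios of the two markers with cohort-level inference
   on log2 ratios (one-sample t against 0 by default; Welch and
   Wilcoxon available). Ratios are scale-free, so the comparison is
   robust to per-core staining intensity differences.
5. **Stratification** (`stratify_and_test()`): cores with mean tumor
   miR-21 above 150 are `high`, the rest `low`; exact equality goes to
   `low` so the rule is a strict inequality as printed. The 150 cutoff
   lives on the raw (8-bit-like) intensity scale — log2 normalization
   is used only for visualization (`reconstruct()`). CDK2AP1 is
   compared by Welch's t (unpaired default) or a patient-paired t on
   per-patient group means restricted to patients represented in both
   groups; the pairing unit is genuinely ambiguous in this kind of
   design, so both modes are exposed.

## The variant filter cascade

Tumor-only calling has no matched normal, so germline and artifact
removal is entirely filter-based. `filter_cascade()` applies four
independent predicates in a fixed order: functional class (exonic
non-synonymous or splicing only), recurrence across sequenced samples
(≥ 5 samples ⇒ artifact), population MAF (≥ 1% in 1000 Genomes,
ESP6500 or gnomAD ⇒ germline; a *missing* MAF counts as rare, because
absence from population databases is exactly the signal this filter
exploits), and repeat/low-complexity indels. Because the rules are
independent, the surviving set does not depend on rule order — a
property the tests assert on random tables — but each removal is
attributed to the first triggering rule so the tallies are reproducible
and sum to the input size. The recurrence cutoff is a parameter since
the number of co-sequenced lines varies between designs.
`classify_cnv()` applies strict |log2 ratio| > 0.5 and p < 0.05
thresholds; boundary values stay neutral.

## Survival stratification

`ihc_classify()` dichotomizes tumors at ≥ 45% CDK2AP1-negative cancer
cells. The boundary is inclusive by default: of the two readings a
threshold like this admits ("more than 45%" vs "≥ 45%"), the inclusive
one matches the patient counts such cohorts report, and a flag switches
to the strict reading. `scan_optimal_threshold()` makes the "optimal
threshold" procedure explicit: it scans a grid, maximizes the log-rank
statistic, and — because a maximum over a grid is optimistic — attaches
a permutation p-value for the maximal statistic rather than the nominal
one.

Expression splits (`dichotomize()`) default to the median (values equal
to the cutpoint go low), with quantile and fixed-cutpoint rules
available; the exact cutpoint used in public-cohort analyses of this
kind is rarely stated, and the median is the convention that needs no
tuning. `stratify_two_markers()` crosses two splits into four groups,
reports the overall log-rank and the clinically interesting contrast
(both-high versus everyone else), and tolerates empty joint groups by
dropping them with a status note. Kaplan–Meier estimation and the
log-rank test are delegated to the survival package; a no-event cohort
yields a flat curve and an uninformative statistic of 0 rather than an
error. Cox modeling and multivariable adjustment are deliberately not
provided. The endpoint is labeled disease-free survival throughout.

## The synthetic cohorts

The generators define the study conditions; they are not tuning knobs.
Defaults: 144 patients × 3 cores (432 cores, ~950 cells each, 65%
tumor), a target tumor-cell Pearson correlation of −0.6 between
cytoplasmic miR-21 and nuclear CDK2AP1 medians, stromal miR-21 elevated
2-fold, 3% planted outliers displaced by 8 channel SDs, a 4 + 3
deficient/proficient expression design with a planted log-scale effect
of 2 for the 12 upregulated miRs, triplicate reporter plates at 5% CV
with expected activities 0.25 (miR-21-5p) to 0.58 (miR-155-5p) — the
end points follow the reported 75%-to-42% repression range, the middle
three (0.40/0.45/0.50) are plausible interpolations chosen once — and
exponential survival with a baseline median DFS of 36 months, hazard
ratio 2.5 for the high-risk group, and 30% independent exponential
censoring.

Intensities are log-normal: biological intensities are positive and
right-skewed, and a multiplicative model makes compartment shifts exact
ratios (so the stroma shift is recoverable as a ratio without bias).
Correlation is induced on the log scale by a bivariate normal, with the
log-scale correlation *calibrated* by the exact log-normal/Pearson
inversion `ρ = log(1 + r·sqrt((e^{σ²}−1)(e^{σ²}−1))) / σ²` so that the
raw-scale Pearson correlation — the quantity the pipeline actually
computes — matches the target rather than being attenuated by the
exponentiation. Between-core variation uses the same anti-correlation
at the core level, which is what makes the miR-21 high/low
stratification separate CDK2AP1 across cores. The log-scale dispersions
(0.08 between cores, 0.08 within) emulate well-controlled staining with
coefficient of variation near 11%; at this dispersion the clean-cell
false-exclusion rate of the |z| > 3 filter stays near the Gaussian
0.27% tail, which is the regime the filter is designed for. Real IF/ISH
data can be heavier-tailed, in which case the filter would trade more
clean cells for the same artifact recovery — passing tests here
demonstrate correctness of the machinery, not the false-positive rate
on any particular scanner's output.

Outliers are displaced additively by `outlier_magnitude_sd ≥ 8` clean
SDs in one randomly chosen median channel per affected cell, with an
exact (deterministic) count of cells; large displacement keeps recovery
tests sharp (the filter should catch essentially all of them) without
making them trivial, since the planted outliers themselves inflate the
channel SD the filter sees. Ground truth is carried in `.sim_`-prefixed
columns that no analysis stage reads — the prefix convention, enforced
by the channel-name matching in the filter, prevents leakage of truth
into analysis.

Every generator draws from a stream derived from the single config
seed (distinct fixed offsets per generator), restores the global RNG
state afterwards, and is byte-identical under a fixed config. What the
generators do *not* emulate: array preprocessing (inputs are emitted
already normalized), image formation and segmentation error, spatial
autocorrelation of intensities within a core (coordinates are
decorative for the reconstruction view), marker-marker correlations
beyond the designed pair, and non-proportional hazards.

## Numerical choices and degenerate inputs

- Quartile boundaries: type-7 quantiles, boundary to the lower group;
  all-ties cohorts score 0.
- Pearson correlation: undefined (NA, never an error) for constant
  channels or fewer than 2 cells; it agrees with a naive two-pass
  computation to 1e-12, which the tests assert.
- Stratification at the cutoff: exact equality goes low (high means
  strictly greater).
- CNV and MAF boundaries: strict as documented; `n = 4` survives a
  recurrence cutoff of 5, `MAF = 0.01` does not survive a 1% cutoff.
- Empty groups: stratification and contrasts skip with an explicit
  status, never silently, and never crash.
- The luciferase SEM is NA for single-well conditions rather than 0.

## Problem sizes

The default test suite runs the full 432-core (~410,000 cell) cohort
once, 500 null survival replicates of n = 100 and 100 powered
replicates of n = 200, 2,000-permutation log-rank cross-checks on
n = 50, and 100-replicate reporter plates — sizes at which every
Monte-Carlo tolerance in the tests has comfortable margin while the
whole suite completes in well under a minute.

## Known limitations

- The evidence tier mapping reproduces the documented 1–8 range but the
  exact numeric tiers of the original procedure are not printed
  anywhere; {1, 3, 5} is a reconstruction and is configurable.
- The variant module consumes annotated tables (TSV); it does not parse
  VCF, call variants, or annotate — by design, the cascade operates on
  the tabular output of upstream tools.
- TCGA/cBioPortal retrieval is out of scope; survival analyses run on
  user-supplied or synthetic cohorts only.
- `scan_optimal_threshold()`'s permutation p-value accounts for the
  grid search but not for any earlier, undocumented selection steps a
  real cohort analysis may contain.
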