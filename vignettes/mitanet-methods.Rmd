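---
title: "Methods and modeling decisions in mitanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling decisions in mitanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitanet)
```

# The model

`mitanet` implements the computational chain of a pressure-overload
cardiology study design: rats undergo abdominal aortic banding (AB) or sham
surgery; at terminal follow-up (week 12) banded survivors split into
compensated hypertrophy (AB_LVH, ejection fraction ≥ 30%) and systolic
heart failure (AB_HF, EF < 30%). Left-ventricular miRNA counts are compared
between the two banded arms; differential miRNAs seed a signed bipartite
miRNA–target network whose per-gene *node strength* — the sum of incident
edge weights, +1 per distinct upregulated regulator and −1 per
downregulated one — predicts the direction of target dysregulation
(positive strength ⇒ predicted downregulation, because miRNAs repress their
targets). High-strength targets are then checked by qPCR.

# Phenotyping conventions

The raw inputs are per-animal echo measurements (wall thicknesses, chamber
diameters, long-axis lengths, heart rate) and necropsy weights. Derived
quantities are always computed, never measured or drawn:

* **Volumes**: biplane ellipsoid `V = (π/6)·L·D²` with one long-axis length
  (apex to aortic root) and one transverse diameter, in mm, reported as µl.
  Only these two measurements are described for the source protocol, so the
  prolate-spheroid form is the default; a two-diameter variant is exposed
  as an optional third argument.
* **EF**: the source tables tabulate EF without a formula; we fix
  `EF = 100·(LVEDV − LVESV)/LVEDV`, which reproduces the tabulated
  terminal sham cell (300/511 → 59%).
* **LV mass**: the cube-law "Devereux" convention
  `1.053·[(AWTd + PWTd + LVEDD)³ − LVEDD³]` (mg, lengths in mm). The
  constant is a parameter because conventions differ between labs; 1.053
  reproduces the week-6 sham reference mass (≈ 1.26 g) to within rounding.
  The reference table prints LV mass under an "mg" header with g-scale
  numbers; our outputs declare units in every column name (`LV_mass_mg`).
* **Group assignment** is strict: AB with terminal EF < 30 → AB_HF, AB with
  EF ≥ 30 → AB_LVH, sham always Sham; non-survivors and banded animals with
  missing terminal EF are excluded with a recorded reason. Oversized arms
  are balanced by seeded sampling without replacement (`subsample_arm`).
* Blood pressures (SBP/DBP/MAP) are treated as measured pass-through
  values; no MAP formula is imposed.

# Differential expression

The DE criterion is deliberately simple because that is what it emulates:
per-miRNA two-sample tests on CPM-normalized counts, with direction called
only when *both* `p < 0.05` and linear fold change `> 1.5` (or `< 1/1.5`)
hold, all inequalities strict. No multiple-testing correction is applied by
default — the stated criterion is a raw p-value — but `p_adjust` accepts
any `stats::p.adjust` method. Fold change is the ratio of group means of
CPM with a configurable pseudocount (default 0.5 CPM) guarding division by
zero. Whether the original analysis used variance stabilization or an exact
NB test is not stated anywhere we could verify, so the test per miRNA is
the same normality-gated machinery used for every other comparison (below),
which is what the source's statistics section prescribes for group
comparisons in general.

## Test choice

All group comparisons share one gate: a Kolmogorov–Smirnov test of each
group against a normal with moments estimated from that group. Two groups:
Student's t (Welch) when all pass at 0.05, else Mann–Whitney U. Three or
more: ANOVA + Tukey when all pass, else Kruskal–Wallis + Dunn. Estimating
the parameters makes the KS gate conservative (the Lilliefors situation);
we accept that because the gate only selects a test, and the nonparametric
fallback is valid under either outcome. Dunn's z-tests are implemented
directly (pooled midranks with tie correction); pairwise p-values are
unadjusted by default to match the absence of any stated correction.

For small samples the Mann–Whitney p-value is computed by exact enumeration
of all group-label assignments (two-sided, on the rank-sum distance from
its null mean), which handles ties correctly and gives exact values such as
p = 2/70 for fully separated 4-vs-4 groups. Beyond an enumeration budget
(`choose(n, nA) > 1e5`) the normal approximation with continuity correction
is used. Degenerate inputs follow an exact-tie convention: identical
constant groups give p = 1; distinct constants give p = 0 under the t
branch.

# Network scoring

Interactions arrive in three dialects with different inclusion rules:
validated rows are always kept; prediction rows are kept when score > 80.0
or mirSVR-style score < −1.2, both strict — the boundary values themselves
are excluded. The three sources are unioned (the per-source threshold
language implies per-source inclusion); an intersection mode exists as an
option. Duplicate (miRNA, gene) pairs collapse to a single edge with merged
provenance: this is required for node strength to equal the count of
distinct regulating miRNAs, which is how "unidirectionally modulated by 6
miRNAs" is meaningful. Multi-source support therefore does not up-weight an
edge.

miRNA identifiers are matched case-insensitively with species-prefix
normalization (a bare `miR-…` is treated as `rno-miR-…`); arm suffixes
(`-3p`/`-5p`) must match exactly. Genes targeted only by non-differential
miRNAs are absent from the network rather than scored zero — the network is
built from the signed set only. Ranking ties are broken lexicographically
by gene id for reproducibility; the original ordering rule is unstated.

Target selection mirrors the validation design: tier 1 is *every* gene at
the maximal |strength|; tier 2 is the unidirectional genes at a stated next
level; tier 3 is a seeded random sample above a strong-regulation floor.

# qPCR validation

Relative expression is `2^−ΔCT` with ΔCT = target Ct − housekeeping Ct;
with several housekeeping wells the arithmetic mean of their Ct is used
(equivalent to the geometric mean of their expression), since the
housekeeping combination rule is not stated in the emulated protocol.
Values are then normalized per gene to the reference arm's mean, making the
reference mean exactly 1 and cancelling any global Ct offset. Sample
exclusions ("technical issues") are an explicit blacklist input, never an
automatic rule. A gene is *validated* when its change is significant at
α = 0.05 (two-sided, uncorrected across genes) **and** in the predicted
direction; a point estimate moving the predicted way without significance
is *trend only*; significant opposition is *discordant*; these statuses
partition the tested genes.

# The synthetic world

The generator's defaults state one world and the tests live in it:

* **Design**: Sham n = 8, AB_LVH n = 8, AB_HF n = 5; 200 miRNAs; 500
  candidate genes; a 50-miRNA planted signature split 44 up / 6 down
  between AB_HF and AB_LVH.
* **Counts** are negative binomial (dispersion 0.15, a typical small-RNA
  UMI overdispersion) around log-normal baselines, with per-sample library
  factors in [0.7, 1.3]. The emulated study reports neither library sizes
  nor dispersion, so these are plausibility choices, made once.
* **Compositional closure**: planting 44 strongly upregulated miRNAs adds
  library mass to the case arm, and per-sample CPM renormalization pushes
  every unplanted miRNA down by the inverse factor. The generator therefore
  draws planted miRNAs at moderate baseline abundance and planted |log2FC|
  from [1, 2], keeping the compositional factor inside (1/1.5, 1.5): the
  unplanted majority can shift significantly but never crosses the
  fold-change threshold, and planted effects stay beyond it. This is a
  design requirement of making planted truth recoverable under plain CPM,
  not a tuning knob; real data analyzed with ratio-based normalizations
  (TMM, median-of-ratios) would relax it.
* **Echo** draws each *measured* quantity independently from a Gaussian
  around published group/week means with SD = SEM·√n; long-axis lengths are
  back-solved from the tabulated volumes so the ellipsoid model reproduces
  them at zero noise. Heart-failure animals are redrawn until their
  terminal measurements imply EF < 30%. Derived indices are never drawn.
  Necropsy means (heart/lung weight, tibia) are synthetic plausibility
  values for 12-week-old Sprague-Dawley rats with congestion in the HF arm.
* **qPCR** plants ΔCt shifts (default +1 cycle ⇒ halved expression) in the
  case arm only; the housekeeping channel never shifts.
* `noise_free = TRUE` zeroes every stochastic component (counts become
  rounded expected values) for golden-run tests.

What a green test does *not* establish: the generator does not model
miRNA–miRNA correlation, batch structure, GC or length biases, library
composition dominated by a few species, or qPCR efficiency differences;
independence across measured echo quantities ignores their physiological
correlation. Green means the algorithms are correct on their stated
contracts, not that the defaults match any particular real dataset.

# Numerical and interface choices

* Strict inequalities everywhere a threshold is stated (`> 1.5`, `< 0.05`,
  `> 80.0`, `< −1.2`, `EF < 30`).
* All tables cross stage boundaries as TSV with headers; the run manifest
  (JSON) records the config, package version and MD5 checksums, so a rerun
  with an identical config is byte-identical and auditable stage by stage
  (row counts in/out are logged, making threshold effects visible).
* The printed signature lists shipped under `inst/extdata/mir_lists/` carry
  43 up names although the stated count is 44; the parser reports what is
  printed rather than inventing the missing name.
* Headline dataset-scale numbers of the emulated study (14/153/50 DE
  miRNAs, 3007 predicted genes, strength-7 genes against the real
  databases, 5/17 validated) require the deposited sequencing data and
  dated database snapshots; they are out of scope by design. The test suite
  instead verifies the printed worked-example arithmetic exactly and the
  algorithmic properties on synthetic fixtures of matching shape.

# Known limitations

Exact Mann–Whitney enumeration is O(choose(n, nA)) and silently switches to
the normal approximation beyond its budget; p-values very close to the
0.05 boundary can differ between the two regimes for mid-sized samples.
The KS gate at n < 3 forces the nonparametric branch with a warning. The
pipeline is single-process and in-memory; it targets study-sized inputs
(hundreds of miRNAs, thousands of genes), not genome-scale atlases.
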