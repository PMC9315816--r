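---
title: "From CNVs to neural circuits: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CNVs to neural circuits: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvCircuits)
```

## The inference chain and its assumptions

`cnvCircuits` formalizes a linear evidence chain: a pathogenic CNV names a
set of spanned genes; membership in an over-represented pathway, a
high-confidence protein–protein interaction (PPI) inside the candidate set,
and strong mRNA co-expression inside the set each certify that a gene acts
with the others rather than being an innocent bystander; the surviving
genes are localized by their developmental expression peak to a brain
region and epoch; regions tie genes to RDoC neural circuits; and carriers
of circuit-mapped variants are compared behaviorally against subjects with
normal microarrays. The chain assumes additivity (no epistasis between
candidate genes), that a gene's single argmax expression cell is the
relevant site of action, and that circuit membership of the peak region is
a sufficient link from molecule to behavior. These are strong, deliberately
simple assumptions: the pipeline is a hypothesis-screening device, not a
causal model.

## Statistical components

**Over-representation.** For a background of $N$ genes containing a
$K$-gene pathway and an $n$-gene query overlapping it in $k$ genes, the
enrichment p-value is the upper tail
$P(X \ge k),\ X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated through
`stats::phyper` on the log-scale tail so large universes remain stable.
Significance is $p \le \alpha$ inclusive, with $\alpha = 0.001$ by default
and no multiplicity correction — the convention of the web enrichment tools
this stage emulates; Benjamini–Hochberg FDR across pathways is available as
`mtc = "bh"` because a second published pass used an FDR threshold. The two
modes are selectable per run and never mixed. Query genes absent from the
background are dropped with a logged count rather than an error, matching
how such tools treat mixed-source gene lists.

**Evidence filters.** Both filters are induced-subgraph rules: a gene is
retained only if its qualifying partner is itself in the current candidate
set. This is the only reading under which each filter is a contraction
(output ⊆ input), which is how the published gene-count trail behaves; an
edge to an arbitrary outside protein would let almost everything survive.
The PPI threshold is applied inclusively at 0.9 — the conventional
"highest confidence" tier of STRING-style scores, which the reader also
accepts as 0–1000 integers and rescales — while the co-expression rule is
strict, $|r| > 0.7$, following the wording of the procedure it reproduces.
Correlation is computed across *all* samples of the bundle, not per region,
because co-expression screening precedes the regional mapping stage.
Zero-variance genes are excluded with a warning (their correlation is
undefined), and genes absent from the bundle are dropped with a logged
count.

**Developmental mapping.** Ages in post-conceptional weeks (pcw) are cut
into trimesters at 13/26/38 pcw — standard obstetric boundaries; the
procedure being reproduced names the four epochs but not the cut points —
with the left edge inclusive, and any postnatal-days age is postnatal. The
cell statistic is the arithmetic mean of the samples in a populated
(region, epoch) cell; unpopulated cells are not candidates, since atlas
donors are sparse. Whether the original lookup used donor-level maxima or
cell means is unstated; means are the more stable choice and are adopted.
Ties break deterministically toward the earlier epoch, then the
lexicographically smaller region code — biased toward the antenatal
emphasis of the method. The postnatal epoch competes in the argmax, so a
postnatally peaking gene receives no antenatal site.

**Group contrast.** Group 1 is every normal-microarray subject and Group 2
every CNV subject whose CNV overlaps a circuit gene, following the cohort
table convention (the methods prose of the source analysis swaps the labels
once; the table convention is adopted). The default test is the two-sided
Welch t-test with Satterthwaite degrees of freedom; a pooled-variance
variant exists for parity with point-and-click statistics packages, and a
Mann–Whitney option for ordinal items — ordinal Likert responses are tested
with the t machinery by default, as the original analysis did. P-values are
unadjusted by default (the published per-circuit tables plainly are), with
BH across the scan as an explicit opt-in. Degenerate inputs are defined,
not errors: both groups constant and equal gives $t = 0, p = 1$; constant
and unequal gives a p-value guarded at the smallest positive representable
number. `welchFromSummary()` reconstructs the same test from printed group
means and standard errors,
$t = (m_1 - m_2)/\sqrt{se_1^2 + se_2^2}$ with
$\nu = (se_1^2+se_2^2)^2 / (se_1^4/(n_1-1) + se_2^4/(n_2-1))$.

## Containers and coordinates

Intervals live in `GRanges` and expression in a `SummarizedExperiment`
subclass, the native containers of the Bioconductor stack this package sits
on. `GRanges` stores 1-based closed coordinates, so the readers convert at
the boundary: BED input (0-based half-open) gains 1 on the start, and the
`one_based_inclusive` dialect for clinical-style interval lists is stored
unchanged. Each writer inverts its reader exactly (round-trip tests are
field-exact for integers and strings, 1e-9 for floats). Gene symbols are
case-preserved but always compared case-insensitively, since microarray
reports mix cases. The region vocabulary is an explicit, user-extensible
list seeded with the twelve codes used in the published circuit tables.

## Default settings

| Parameter | Default | Unit / range | Why |
|---|---|---|---|
| `enrichmentAlpha` | 0.001 | probability | the published significance level |
| `ppiMinConfidence` | 0.9 (inclusive) | score in [0,1] | highest-confidence STRING tier |
| `coexprThreshold` | 0.7 (strict) | absolute Pearson r | the published cut, "greater than 0.7 or less than −0.7" |
| `minOverlapBp` | 1 | base pairs | most inclusive reading of "genes present in the affected loci" |
| `epochBoundaries` | 13, 26, 38 | pcw | standard obstetric trimesters |
| `testMethod` | welch | — | robust default; pooled offered for parity |
| `mtcMethod` | none | — | matches the unadjusted published tables |

## What the synthetic generator emulates — and what it does not

`simulateStudy()` produces the full input bundle under one seed: 1200 genes
laid contiguously and non-overlapping on six synthetic chromosomes, 30
pathways of which exactly one (12 genes) is causal, a PPI list holding a
causal clique (confidence ~ Normal(0.95, 0.02), clipped to [0,1]) over a
background of 2000 random edges (Beta-distributed, mean 0.4), an expression
grid of 12 regions × 4 epochs × 3 samples, a 120-gene neurodevelopmental
list that contains the causal pathway, and a cohort of 47 normal-microarray
and 90 CNV subjects — the group sizes of the clinical cohort being
emulated. Including the causal pathway in the neurodevelopmental list
mirrors the premise of the original design (the seeded
neurodevelopmental list is where disease-relevant genes live) and
guarantees the enrichment query contains the planted pathway even when the
carrier draw misses some causal genes.

Causal-gene expression follows a one-factor model
$x_{gs} = \mu + b\,[s \in \text{peak cell}] + \lambda f_s +
\varepsilon_{gs}$ with a flat baseline $\mu = 10$, peak boost $b = 8$,
loading $\lambda = 2$ and noise $\sigma = 1$, truncated at zero (which at
these levels essentially never binds). Off the peak cell the pairwise
causal correlation is exactly $\lambda^2/(\lambda^2+\sigma^2) = 0.8$; the
shared peak elevation adds a small extra covariance term, so the
calibration test compares the empirical correlation to the closed form on
the non-peak samples. Non-causal genes get independent per-cell baselines
uniform on $\mu \pm 2$, emulating region- and age-varying expression.
Decoy pathway membership is sampled without replacement per pathway but
genes may recur across pathways, like real gene-set overlap.

CNVs are one interval per subject: carriers (a `carrierFraction` share of
CNV subjects, default 0.5) anchor on a causal gene and extend over 0–5
contiguous bystander genes, mirroring the many-genes-per-CNV reality at
desk scale; non-carriers anchor on non-causal genes with the same bystander
rule, re-drawn if the window would touch a causal gene. Behavioral items
are latent-normal; PCQ items are discretized to 1–5 at cuts (−1, 0, 1, 2)
of the latent scale (mean ≈ 2.5, as in the published score tables), and
Vineland scores are scaled to mean 75, SD 10, a plausible standard-score
regime; the published study reports neither item distributions nor subscale
variances, so these are conventions, not estimates. The planted effect
shifts the carriers' latent target item by `effectSizeSd` pooled-SD units
(default 1); Likert discretization attenuates the observed-scale shift to
roughly 0.75 SD, which is the effect size the power gates actually see.

Not emulated: realistic genome coordinates or linkage, real pathway
topology, dosage (deletion vs duplication), epistasis, donor-level atlas
sparsity, item covariance structure, or missing data. Passing tests
therefore demonstrate that the machinery recovers structure *of this
planted form* at these sample sizes — not that the pipeline's published
gene counts or clinical p-values would reproduce, which depend on external
database versions and an undeposited cohort.

## Problem sizes used by the test gates

The suite checks the hypergeometric tail against direct
binomial-coefficient enumeration exhaustively for all $N \le 60$ (agreement
within 1e-12), and checks interval overlap, PPI retention, co-expression
retention, argmax sites and circuit assignment against quadratic
brute-force scans on over a thousand randomized instances each. Null
calibration regenerates 2000 cohorts at zero effect size against one fixed
universe and requires the unadjusted rejection rate at $\alpha = 0.05$ to
land in 0.05 ± 0.01; planted recovery runs 200 fully fresh studies at one
pooled-SD effect and requires detection of the target circuit–item contrast
in ≥ 90% and intact causal-gene recovery in ≥ 95%. `scripts/acceptance.R`
recomputes the same operating characteristics at 500 and 100 replicates
respectively — enough for two-digit stability of the reported rates — with
every seed derived from its `--seed` argument.

## Circuit map defaults

Only three circuits (Positive Valence; Cognitive; Social Processes) come
with printed region lists in the tables being emulated; they are seeded
verbatim. Negative Valence (Amy, ACC, MPFC) and Sensorimotor (STR, MD) are
seeded from standard RDoC construct anatomy restricted to the same
twelve-code vocabulary, and users can replace the whole map with
`CircuitMap()` or a `circuits.tsv`/YAML file. A region may belong to many
circuits, so one gene routinely lands in several systems (a striatal peak
joins Positive Valence, Cognitive and Social Processes at once).

## Known limitations

* The induced-subgraph reading of both filters is an interpretation; the
  original text does not state whether co-expression partners were required
  inside the candidate set or against the whole external trait set.
* The argmax site uses cell means; donor-level maxima would be noisier but
  are a defensible alternative.
* Subjects sharing circuits across distinct genes are pooled by union; an
  intersection rule would give smaller, purer carrier groups.
* The association scan treats items and circuits as exchangeable tests; no
  hierarchical or item-response modeling is attempted, and unadjusted
  p-values across a scan of dozens of cells must be read as screening
  statistics.
* EEG spectral analysis and histology quantification are out of scope; of
  the animal arm only the printed summary arithmetic (percent changes,
  summary-statistic Welch tests) is reproduced.
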