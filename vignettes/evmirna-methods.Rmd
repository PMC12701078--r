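---
title: "Methods: paired EV-miRNA qPCR analysis from CT values to networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired EV-miRNA qPCR analysis from CT values to networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmirna)
```

## The problem

Circulating extracellular vesicles (EVs) carry miRNAs that are candidate
humoral mediators of systemic conditioning stimuli such as remote ischemic
preconditioning. Profiling them is done on fixed qPCR panels (384 assays)
in very small paired cohorts: the same patient is sampled immediately
before and shortly after the stimulus. The data have three awkward
properties that drive every design choice in this package:

* **Censoring at the limit of detection.** A large fraction of assays never
  amplifies within 40 cycles and is reported as "undetermined". This is
  left-censoring of abundance (right-censoring of CT), not missingness at
  random.
* **Technical yield variation.** EV isolation and RNA extraction yields
  differ per sample, shifting *every* CT in a sample by a common offset.
  An exogenous spike-in (*cel*-miR-39, added before extraction) tracks this
  offset.
* **Tiny paired samples.** With five patients, only the pairing structure
  (per-patient offsets shared between the two timepoints) makes inference
  possible at all.

## CT processing and the detection filter

`read_ct_table()` ingests wide or long tabular exports. Cells that are
`"undetermined"` (case-insensitive) or empty are imputed at the ceiling
(default 40 cycles) and flagged not-detected; numeric values at or above
the ceiling are treated identically. The rationale for clamping numeric
values ≥ 40 is that the ceiling *is* the limit of detection — a reported
CT of 41.2 carries no more information than "undetermined". The ceiling is
a parameter so the policy is testable rather than hard-coded.

`filter_by_detection()` retains an assay iff it is detected in at least
`min_detected` (default 2) samples of the **pre** group *or* of the
**post** group. The one-sided "either group" form deliberately keeps
miRNAs that are switched fully on or off by the intervention — requiring
detection in both groups would delete exactly the most interesting
candidates. The report counts a three-stage cascade (total target assays,
detected anywhere, retained); the spike-in is excluded from all counts
because it is exogenous and can never be a candidate.

Imputed cells **do** enter downstream statistics for retained miRNAs.
A partially detected miRNA contributes its ceiling value as a floor on
expression; excluding those cells would bias paired differences toward
zero. The cost is a known pathology — a miRNA censored in every sample of
both timepoints has zero variance — handled explicitly in the DE stage.

## Normalization

For retained miRNA $i$ and sample $j$,

$$\mathrm{expr}_{ij} = -\Delta CT_{ij} = -(CT_{ij} - CT_{\text{spike},j}).$$

Under the usual efficiency-2 assumption one PCR cycle is one doubling, so
$-\Delta CT$ is log2-scale expression relative to the spike-in. Any
per-sample additive offset common to all assays cancels exactly; the
package's tests assert this cancellation bit-for-bit. A sample in which
the spike-in itself is undetected has no defined normalization and is a
fatal error, not a warning.

## Paired differential expression

Per miRNA, with per-patient differences $d = \text{post} - \text{pre}$ on
the $-\Delta CT$ scale:

* $\log_2\mathrm{FC} = \bar{d}$ (mean post minus mean pre expression);
* paired two-tailed Student's t: $t = \bar d / (s_d/\sqrt n)$ with the
  sample ($n-1$) standard deviation, $p$ from the $t_{n-1}$ distribution;
* Benjamini–Hochberg q-values across all testable miRNAs; significance is
  strict, $q < 0.2$;
* a directional consistency call: `down` (`up`) iff at least
  `consistency_min` = 3 of the patients moved in that direction; zero
  differences count toward neither side.

**Degenerate records.** If $s_d = 0$ — which imputation at the ceiling
produces whenever a miRNA is censored in all ten samples — the t statistic
is undefined. Such records are flagged, excluded from the BH adjustment
(so they do not dilute $m$), and can never be significant. Assigning them
$p = 0$ or $p = 1$ would either fabricate significance or distort the
step-up; exclusion is the only option that does neither.

The q-value threshold of 0.2 is liberal by design: with $n = 5$ the study
is a screen, and the FDR scale means an expected one in five reported
candidates is false — acceptable for hypothesis generation, not for
confirmation.

PCA (`pca_scores()`) treats samples as observations, centers features and
does not scale them (all features share the $-\Delta CT$ scale; scaling
would up-weight noise-dominated, near-censored miRNAs). Component signs
are fixed by requiring the largest-magnitude loading to be positive, so
score plots are reproducible across runs and platforms.

## From miRNAs to a ranked gene list

`normalize_mirna_id()` canonicalises assay labels (whitespace and
assay-suffix decorations dropped, species prefix ensured, lower-cased
matching key) so array annotations can be joined to target databases.
`build_ranked_list()` then scores each validated target gene by the
**inverse-regulation metric**: the negative $\log_2$FC of its most
strongly regulated targeting miRNA. A miRNA represses its targets, so a
strongly *down*-regulated miRNA predicts *de-repression* — its targets
receive large positive scores and rise to the top of the list.

Two choices here were genuinely open and are exposed as parameters:

* *"Most strongly regulated"* is interpreted as the largest
  $|\log_2\mathrm{FC}|$, with smaller p-value and then lexicographic key
  as tie-breaks. Magnitude is the natural reading of "strongly", and the
  tie-breaks make the list a deterministic total order, which downstream
  permutation results inherit.
* *Which miRNAs feed the ranking*: the default is every retained miRNA
  (`all_retained`), because preranked GSEA needs a dense background list —
  ranking only a handful of significant miRNAs would leave most gene sets
  without rankable members. A `nominal_p` mode restricts to $p < 0.05$
  for sensitivity analyses.

## Preranked GSEA, from scratch

`enrichment_score()` implements the weighted Kolmogorov–Smirnov-like
running sum: walking down the ranked list, a set member ("hit") adds
$|r_g|^w / \sum_{\text{hits}} |r_h|^w$, a non-member subtracts
$1/(N - n_{\text{hits}})$; the enrichment score (ES) is the signed value
at the maximum absolute deviation. Defaults follow the field's reference
tool: weight $w = 1$; set-size bounds 15–500 applied to the intersection
with the ranked list. If all hit metrics are zero under $w > 0$ the
increments fall back to the unweighted $1/n_{\text{hits}}$.

Numerical corner cases are pinned down explicitly:

* the running sum returns to zero at the end of the walk by construction;
* with few hits, the trough before the first hit can exactly mirror the
  peak after the last one (both are whole multiples of the miss step), so
  the signed ES is ambiguous; ties resolve to the **earliest position in
  the walk**, with a $10^{-9}$ tolerance so the outcome cannot depend on
  floating-point accumulation order;
* a set covering the whole ranked list has an undefined miss step and is
  rejected.

`prerank_gsea()` builds the null by **gene-label permutation** — random
same-size draws from the ranked universe — which is the only permutation
scheme available to preranked input (there are no phenotype labels left to
permute). Per set and tail:

* nominal $p$ is the same-sign tail frequency with add-one smoothing,
  $(b+1)/(B_{\text{side}}+1)$, so $p = 0$ is impossible at finite $B$;
* NES divides the ES by the mean $|$null ES$|$ of the matching sign;
* FDR q is the canonical tail-wise ratio of normalized-null to observed
  tail fractions, computed separately for positive and negative NES,
  capped at 1, and made monotone so a less extreme NES never gets a
  smaller q.

1,000 permutations (the default) put the smallest attainable nominal p
near $2/B$ and give the q-values a resolution adequate for a 0.2
threshold; the seed argument makes every result bit-reproducible.

## The tripartite network

`build_network()` connects the three layers under strict thresholds:
miRNAs with nominal $p < 0.05$, pathways with GSEA $q < 0.2$, and the
genes that are **both** validated targets of at least one included miRNA
**and** leading-edge members of at least one included pathway. The two
gene conditions are evaluated independently (a gene may enter via one
miRNA's targets and another pathway's leading edge); the quoted inclusion
rule is a conjunction of memberships, not of linked pairs. Nodes and
edges are emitted in a fixed order (type, then label) so exports are
byte-identical across runs; layout (e.g. Kamada–Kawai) is presentation,
not contract, and is deliberately out of the core.

## What the simulator emulates — and what it does not

`simulate_ct()` generates paired CT matrices under

$$CT_{ij}^{tp} = b_i + u_j + \varepsilon_{ij}^{tp} +
  \delta_i\,[tp = \text{post}],$$

with per-miRNA baselines $b_i$ (a well-expressed regime,
$\mathcal N(30, 4^2)$, mixed with a near-LOD regime,
$\mathcal N(38, 1.5^2)$, in proportion `fraction_near_lod` = 0.4),
per-patient offsets $u_j \sim \mathcal N(0, 1.5^2)$ shared between the
patient's two samples (this is what the paired test exploits),
measurement noise $\varepsilon \sim \mathcal N(0, 1^2)$, and planted post
shifts $\delta_i$ in cycles. A positive $\delta$ is downregulation and
maps to an expected $\log_2$FC of $-\delta$ through the sign flip in
$-\Delta CT$. Draws at or above the ceiling are censored to
"undetermined" — hard truncation, chosen over a probabilistic dropout
curve because it makes censoring-rate calibrations analytically checkable
against normal tail probabilities. The spike-in is drawn at
$\mathcal N(22, 0.3^2)$ per sample and never censored. Default cohort and
panel sizes (5 patients, 384 assays) match the study design the package
addresses; planted shifts of 3–7 cycles correspond to the magnitude of
change reported for top candidates in this kind of screen. Planted assays
are kept out of the near-LOD regime by default (`planted_detectable`),
emulating the fact that reported hits are, by construction, assays that
survived the detection filter.

`simulate_targets_and_sets()` adds the annotation side: random target
draws per miRNA from a common gene universe, plus one designated gene set
drawing a controllable fraction (default 0.8) of its members from the
union of planted-down targets — a known GSEA positive — alongside purely
random null sets.

The simulator is deliberately idealised. It does **not** model
amplification-efficiency differences between assays, plate or batch
effects, correlated miRNA co-regulation, heavy-tailed noise, or partial
censoring dynamics near the threshold. Passing recovery tests therefore
demonstrates that the *pipeline* is correct and well calibrated under the
assumed noise model, not that the model captures every property of real
EV-qPCR data.

## Test and verification design

The suite checks each numerical stage against an independent oracle:
the running-sum ES against a literal step-by-step walk over all 385
subsets of sizes 1–4 of a 10-gene list (fixture metrics chosen so no
subset produces a tied maximum deviation); BH q-values against a direct
evaluation of the step-up definition on 1,000 random vectors; the paired
t against `stats::t.test`; ES additionally against an established
independent implementation on a shared fixture. Statistical behaviour is
verified by simulation at fixed seeds: planted shifts of 3–7 cycles are
recovered (nominal $p < 0.05$, correct sign, consistent direction) in at
least 90% of 100 replicates, the nominal test keeps its 5% size under the
null within Monte-Carlo tolerance, the planted gene set ranks first by q
in at least 90% of 20 GSEA replicates, and random sets' permutation
p-values pass a Kolmogorov–Smirnov uniformity check.

Two fixture choices deserve explanation. Shift-invariance of the
normalization is asserted as *bit-identity*, which is only meaningful if
the additions involved are exact; those fixtures therefore draw CTs and
offsets on dyadic grids (multiples of $2^{-8}$ and $2^{-2}$ cycles). And
the recovery studies centre planted baselines in the dynamic range
(28 ± 1 cycles): a planted 3-cycle shift sitting at CT 37 would be
censored at 40 and realised as a smaller effect, so leaving baselines
near the ceiling would test censoring attenuation (covered separately by
the cascade and simulator tests) rather than the recovery property the
fixture is about.

Problem sizes used by the checks — a 134-miRNA retained-scale panel, a
500-gene universe, 21 gene sets of 50 genes, 1,000 permutations, and
20–100 replicates per property — were chosen to keep each property's
Monte-Carlo error comfortably below the margin it is tested against.

## Reproducibility

All randomness flows from explicit integer seeds; `run_pipeline()`
derives fixed per-stage seeds from one root seed, so stages are
individually reproducible and a repeated run writes byte-identical
artifacts (verified by checksum in the manifest). Floating-point values
in interchange files are written with 17 significant digits so re-reading
reproduces the doubles exactly.

## Known limitations

* Inference is the plain paired t-test; no moderated-variance
  (empirical-Bayes) shrinkage, and no nonparametric alternative — at
  $n = 5$ the Wilcoxon signed-rank test cannot reach $p < 0.0625$
  two-sided anyway.
* Censored values enter as the ceiling constant rather than through a
  censoring-aware likelihood (e.g. Tobit); this biases fold-change
  magnitudes toward zero for partially detected miRNAs.
* Target maps are taken as given; no weighting by interaction evidence
  strength, and no predicted (non-validated) targets.
* GSEA significance is relative to the gene-label permutation null, which
  ignores inter-gene correlation induced by shared targeting miRNAs; q
  values should be read as screening-level evidence.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(
  simulate = sim_config(planted_effects = c("1" = 3, "2" = 4,
                                            "3" = 5, "4" = 7)),
  n_perm = 1000, seed = 1)
res <- run_pipeline(cfg)
res$report                                   # the filtering cascade
head(res$de[order(res$de$p_value), ])        # strongest paired changes
significant_pathways(res$enrich)             # GSEA hits at q < 0.2
degree_summary(res$net)                      # miRNA hub degrees
```
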