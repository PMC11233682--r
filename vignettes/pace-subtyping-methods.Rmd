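---
title: "Methods: progression-pace subtyping, molecular modules, and trial emulation"
author: "pacenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progression-pace subtyping, molecular modules, and trial emulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pacenet implements an integrative analysis of Parkinson's disease (PD)
progression: it learns a fixed-length *progression embedding* per
participant from multivariate longitudinal clinical data, clusters the
embeddings into progression-*pace* subtypes, characterises those
subtypes statistically, expands their molecular correlates into
interactome modules, screens drug signatures for module reversal, and
estimates real-world treatment effects by target-trial emulation. Every
stage can be exercised end to end on synthetic cohorts with planted
ground truth, generated by the package itself.

This vignette records the model choices, parameter meanings and
defaults, numerical decisions, and the limits of what the synthetic
validation shows.

## Clinical preprocessing

Input is a participants × visits × variables array with missingness
(`ClinicalPanel`). Repair and scaling follow the standard longitudinal
pipeline:

1. **LOCF then NOCB.** Gaps after the first observation take the last
   observed value; leading gaps take the next observed value. The order
   (forward carry first) preserves the last-known state and uses
   backward fill only for leading gaps. Observed values are never
   modified, and the original observation mask is retained for
   downstream eligibility rules.
2. **Population median.** Series missing entirely for a participant are
   filled with the median of that variable over all observed
   participant-visit cells (no time index — the median is a
   cohort-level constant).
3. **Z-scoring.** Per variable, $\hat x = (x - \mu)/\sigma$ with the
   population (divide-by-$n$) $\sigma$ over all participant-visit
   cells, computed *after* imputation — an ordering chosen so the
   transform is exactly invertible on the stored panel. Zero-variance variables cannot be
   scaled and are dropped with a warning rather than kept as zeros.
4. **Grid assembly.** Sequences are assembled on a regular grid
   (default baseline + 5 annual visits, i.e. 12-month spacing over a
   60-month horizon; the true PPMI visit calendar is not reproduced).
   Participants with less than 12 months of *genuinely observed*
   follow-up are excluded, mirroring the minimum one-year history rule.

The pipeline is idempotent, and `zscorePanel()`/`unscalePanel()` invert
each other to 1e-10.

## The progression embedding (DPPE)

The deep phenotypic progression embedding is an LSTM sequence
autoencoder. The encoder runs a single-layer LSTM over the $T \times V$
sequence; its final hidden state (length 16 by default) *is* the
embedding. The decoder is a mirror LSTM that receives the embedding
repeated at every time step — the simplest faithful "unpacking" scheme
with no teacher forcing — and a linear readout reconstructs the $T
\times V$ input. Training minimises mean squared reconstruction error
with Adam.

Implementation notes:

* The LSTM forward/backward passes (backpropagation through time) and
  the Adam optimizer are implemented natively in R, vectorised over the
  minibatch; the analytic gradients are verified against central finite
  differences (tolerance 1e-7) in the test suite.
* Weights are initialised uniformly in ±0.08 from a seeded generator,
  with the forget-gate bias at +1; no pretrained weights.
* Batch size 1 reproduces the per-patient update scheme of the original
  description and is the config default; minibatches are a supported
  speed option (the validation runs use batch 16, 300 epoch cap,
  learning rate 0.01).
* Training stops early: a 10% validation split is held out and
  training ends after 25 epochs without improvement, keeping the
  best-validation weights.
* Only single-layer encoders/decoders are implemented; stacked variants
  are out of scope.

Embeddings are deterministic given a trained model, invariant to
participant order, and identical inputs yield identical vectors.

## Subtype discovery

Agglomerative hierarchical clustering with Euclidean distance and Ward
linkage (`ward.D2`, the Lance–Williams form appropriate for
non-squared Euclidean input) is cut at $k$ clusters. Merge heights are
monotone; the partition is deterministic and order-invariant.

**Cluster-number selection.** Eight validity indices are computed
natively over a candidate range (default 2–6), each with its own
optimum rule: Silhouette, Dunn, Ratkowsky–Lance and point-biserial
(maximise), Davies–Bouldin and McClain (minimise), Ball (largest drop
between successive hierarchy levels) and TraceW (largest second
difference of the within-cluster sum of squares). The elbow-type rules
difference index values *within* the scanned range only — extending to
$k=1$ would make them degenerate (they would always vote the smallest
candidate). The selected $k$ is the mode of the eight recommendations,
ties broken toward the smaller $k$; dendrogram separation (the largest
relative gap in merge heights) is reported for inspection but never
votes. Clinical interpretation of candidate partitions is left to the
analyst; the package's selection is the majority vote alone.

**2-D inspection.** An exact $O(n^2)$ t-SNE (perplexity calibration by
bisection, early exaggeration, momentum gradient descent) provides
coordinates for visualisation only — suitable for the cohort sizes
(hundreds to a few thousand) this package targets, and never used for
clustering.

**Pace naming.** Clusters are named post hoc by the mean
per-participant OLS slope of a reference clinical variable: slowest =
PD-I (inching), middle = PD-M (moderate), fastest = PD-R (rapid) when
$k=3$.

## Subtype statistics

* **Annual progression rates.** Per variable and subtype, a linear
  mixed model `value ~ time_years + covariates + (1 | participant)`
  (lme4, REML) with a participant random intercept — "individual
  variation" is read as a random intercept; random slopes are not
  fitted by default. The time coefficient is the annual progression
  rate, reported with a Wald 95% CI and normal-approximation p-value.
* **Baseline comparisons.** ANOVA (ANCOVA with age/sex/LEDD-analog
  covariates) for continuous variables with Tukey HSD post hoc when
  significant; chi-square for categorical.
* **Multiplicity.** Benjamini–Hochberg FDR within each analysis family
  (per table), via `p.adjust`.
* **SNP enrichment.** Upper-tail hypergeometric probability
  $P(X \ge k)$ of $k$ subtype carriers among $n$ subtype members given
  $K$ cohort carriers of $N$ — `phyper`, exact.
* **CSF biomarkers.** The standard ratios (Aβ-42/P-tau, Aβ-42/T-tau,
  Aβ-42/α-syn, P-tau/α-syn, T-tau/α-syn, P-tau/T-tau) are computed,
  zero denominators excluded with a warning, and each marker compared
  between groups by a linear model adjusting for age and sex.
* **Imaging.** Per-ROI two-sample t-tests over the 34 Desikan–Killiany
  cortical regions, reported with $-\log_{10} p$ and a 0.05
  significance flag.

## Interactome modules

`buildNetwork()` cleans an edge list (self-loops and duplicates
removed) and keeps the largest connected component. Gene scores are
initialised from the differential-expression table as $z(i) =
|\log_2 FC|$ for genes passing the DEG gate (adjusted $p \le 0.05$),
zero otherwise, then smoothed by a random walk with restart,
$p \leftarrow (1-\gamma) W p + \gamma p_0$ with column-normalised $W$,
restart probability $\gamma = 0.5$ by default (an even weighting of
local and diffused signal; the module tests verify the iteration
against the direct linear solve). Total
score mass is preserved.

A module grows greedily from a seed gene: a neighbouring candidate $i$
joins if its hypergeometric connectivity tail probability satisfies
$P(i) \le 0.01$ *and* the module score

$$S(M) = \frac{\sum_{j \in M} (z(j) - \omega)}{\sqrt{|M|}}$$

strictly increases ($\omega$ = network mean score; $n$ in the score's
denominator is read as $|M|$, the standard normalisation; $m$ in the
connectivity test is the module size *before* adding the candidate).
Among qualifying candidates the one maximising the new score is added
(ties by gene id). Growth stops when no candidate passes both gates,
then restarts from many random seeds; identical modules are
deduplicated and ranked by score.

**Union breadth.** How many top-ranked raw modules should form the
final module is a genuinely open design choice. A fixed count adapts
poorly: depending on the network,
the score landscape has either one dominant raw module or many
overlapping fragments. The final module is therefore the union of all
unique raw modules scoring at least `scoreFraction` (default 0.4) of
the best raw-module score.

**Desk-scale caveat.** The connectivity gate at module size 1 reduces
to $P(i) = d_i/N$, so on a small network it admits only candidates with
$d_i \le 0.01 N$. The synthetic network generator therefore keeps the
degree-to-size ratio near the real interactome's (mean degree ~2 at
$N = 500$, matching $\bar d/N \approx 38/17456$); with realistic
absolute degrees at small $N$ the gate would block all
growth — a property of the algorithm's scaling, not of this
implementation. Single-seed growth remains fragile at this scale, which
is exactly why the procedure restarts from many seeds.

**Genetic modules.** Genetic associated genes keep only those with at
least one interactome edge to a contextual gene (single-nucleus-derived
dopaminergic-neuron markers); the module is the kept genes plus their
contextual neighbours.

## Drug-reversal screening

Drug profiles are amplitude vectors $\alpha = (t - c) / ((t + c)/2)$
(undefined records, $t + c = 0$, are dropped with a warning). Genes are
ranked per drug in ascending amplitude, so rank 1 is the gene most
suppressed by the drug: disease-up genes near rank 1 mean the drug
reverses the disease signature, and a positive enrichment score means
reversal.

For each direction (module-up, module-down genes), with $s$ genes
present among $r$ profiled genes and $V(j)$ their ascending profile
ranks,

$$a = \max_j \left(\frac{j}{s} - \frac{V(j)}{r}\right), \qquad
  b = \max_j \left(\frac{V(j)}{r} - \frac{j-1}{s}\right),$$

the directional score is $a$ if $a > b$, else $-b$, and
$ES = ES_{up} - ES_{down}$ when the two signs differ, 0 otherwise.
Here $r$ is the *total* number of profiled genes (the standard
Kolmogorov–Smirnov form, consistent with the rank normalisation
$V(j)/r$), and module genes absent from a profile are excluded and
counted.

Significance comes from permutation: random gene sets of matched sizes,
$p = (1 + \#\{ES_{perm} \ge ES_{obs}\})/(1 + n_{perm})$ (the +1 avoids
zero p-values), and a normalised ES $=(ES_{obs} -
\mu_{perm})/\sigma_{perm}$. The raw ES is bounded in $[-2, 2]$, so a
selection cutoff of 3 is only meaningful on the normalised scale;
selection therefore applies normalised ES > 3 together with
BH $q < 0.05$ across drugs (both the raw and normalised scores are
reported). The package default is 100 permutations; the validation
screen uses 1000 so that the smallest attainable
p-value ($1/(n_{perm}+1)$) is small enough for BH selection across 500
drugs to be meaningful.

## Target-trial emulation

From EHR-shaped tables (patients, diagnoses, prescriptions):

* **Eligibility:** ≥1 PD code, age ≥50 at first PD code, no
  neurodegenerative code before it.
* **Dates:** PD initiation = first PD code − 183 days (six months);
  index = first dispensing of the tested drug (treated) or an in-class
  alternative (control candidates) on/after initiation; outcomes must
  be strictly after the index; follow-up runs to the first outcome or
  censoring at the last recorded event.
* **Covariates:** binary flags for comorbidity code groups and
  co-prescribed ingredients within the baseline window, plus age, sex,
  race (as coded) and initiation-to-index days — the 267-column layout
  with the default 64 + 199 + 4 schema; the column count is asserted
  against the schema at build time.
* **Matching:** logistic propensity model on all covariates; greedy 1:1
  nearest-neighbour matching on the logit propensity score without
  replacement, treated processed in seeded random order, no caliper by
  default (configurable). Balance: absolute SMD per covariate
  ($|\bar x_T - \bar x_C| / \sqrt{(s_T^2 + s_C^2)/2}$, proportion
  variance for binaries; differing means with zero pooled variance are
  maximally unbalanced); a trial is balanced when at most 2% of
  covariates exceed SMD 0.2.
* **Effect:** Cox partial-likelihood fit of the treatment indicator on
  the matched sample (`survival::coxph`). An emulated trial = a seeded
  subsample of the control candidate pool (size min(pool, 10 ×
  treated)) plus a fresh matching order; 100 trials per drug, drugs
  with <100 treated or <10 balanced trials excluded. The summary is
  the median HR across balanced trials; **the trials act as the
  bootstrap replicates**, so the 95% CI is the percentile range of the
  balanced-trial HRs, and a sign test gives p for median HR ≠ 1.

**Estimand note.** The matched treatment-only Cox fit targets the
*marginal* hazard ratio in the matched population. Hazard ratios are
non-collapsible: with strong unexplained hazard heterogeneity the
marginal HR is attenuated toward 1 relative to the conditional HR even
under perfect covariate balance (we measured ~0.80 marginal for a
planted conditional 0.7 under a frailty of SD 0.8 per confounder unit).
The synthetic EHR generator therefore keeps the outcome-side
confounder effect moderate (0.35 per standardised comorbidity-burden
unit, event fraction ~15%), so the attenuation is ~1% and the planted
HR is effectively the estimand, while treatment-side confounding stays
strong enough to bias the unadjusted HR upward by ~1.4-fold — enough
to mask a planted protective effect of 0.7 entirely. Covariate-adjusted and IPTW variants of the Cox
stage would target the conditional estimand directly.

## Prognostic cascade classifier

Features: baseline and year-1 clinical values, variant carrier flags,
demographics, and 10 principal components of the 34-ROI atrophy block.
The PCA is refit inside each training fold and applied to the held-out
fold, so no test information enters the rotation (verified by a leak
test). The cascade is two seeded random forests (500 trees):
stage 1 separates the rapid subtype from the rest; stage 2, trained
only on non-rapid participants, separates the remaining two. Evaluation
is stratified 5-fold cross-validation; AUCs are reported as mean ± SD
across folds (fold SD, not bootstrap). Class imbalance is handled by
stratification only.

## The synthetic-data generators

Every generator is a pure function of its spec and seed (identical
seeds reproduce outputs bitwise) and emits its ground truth for
recovery tests.

* **Longitudinal cohort.** $x_{itv} = \text{baseline}_{kv} +
  \text{slope}_{kv} t + u_i + \varepsilon_{itv}$ with a shared
  participant intercept $u_i$ (SD 0.6), observation noise (SD 0.5),
  10% completely-at-random missingness (baseline spared), and a
  2%/visit monotone dropout hazard. The default three subtypes combine
  pace multipliers 0.35/1.4/2.4 units/year with subtype-specific domain
  emphasis (a cosine pattern over the variable index). Purely
  proportional (collinear) pace profiles place the three subtype means
  on a line, for which nearly every validity index prefers $k = 2$; the
  domain-emphasis component reflects that real pace subtypes differ in
  *which* domains deteriorate fastest and makes the planted $k = 3$
  geometrically real. Slope separation is kept large relative to the
  within-subtype slope spread ("clear separation"); LOCF flattens the
  trajectories of dropouts, which is the main residual source of
  subtype mixing.
* **Interactome.** Preferential attachment (attach 1 edge/vertex) with
  a planted 30-gene subgraph at internal density 0.15 — degree-to-size
  ratio scaled to the real interactome (see above).
* **DEG table / signatures / genotypes / biomarkers.** Planted DEGs at
  $|\log_2 FC| \approx 2$ with passing q-values; reverser drugs shift
  disease-up genes to amplitude −strength and disease-down genes to
  +strength against N(0,1) null profiles; enriched SNPs multiply
  carrier odds within one subtype; biomarker tables add per-subtype
  Gaussian shifts in SD units. Signatures are generated directly on the
  amplitude scale; `amplitude()` exercises the raw t/c computation.
* **EHR cohort.** Comorbidity flags drive both treatment assignment
  (logit −3.3 + 0.8 × standardised burden ⇒ ~5% treated, so the
  control-pool subsample genuinely varies across trials) and the
  outcome hazard (exponential proportional hazards, baseline 0.05/yr,
  +0.35 per burden unit, planted treatment log-HR), with independent
  censoring (0.25/yr, administrative end at 4 years). Confounding acts
  only through observed flags, so matching can remove it exactly; the
  planted HR is the estimand of the matched Cox stage up to the ~1%
  non-collapsibility attenuation discussed above. Small fractions of
  under-age and prior-neurodegenerative patients exercise the
  eligibility filters.

**What the synthetic validation does and does not show.** Passing tests
demonstrate that the implementation recovers *planted* structure under
the generator's assumptions: linear mean trajectories, Gaussian noise,
MCAR-plus-dropout missingness, exponential hazards, confounding fully
captured by observed covariates. Real cohorts violate all of these
(nonlinear progression, informative missingness, unmeasured
confounding, calendar-time effects), so green tests certify software
correctness and statistical calibration at the stated conditions — not
clinical validity on PPMI-like data.

## Validation scale

The bundled validation (test suite and `scripts/acceptance.R`) uses:
300-participant cohorts (3 × 100, 20 variables, 6 annual visits) with 5
embedding seeds; 100 mixed-model replicates at n = 100; a 500-gene
network with 1000 growth restarts; 500 drugs with 50 planted reversers
at 1000 permutations; a 20,000-patient EHR with 100 emulated trials
(null calibration at 10,000 patients × 20 trials — propensity models
with 267 covariates need several hundred treated patients, and below
that scale the overfit propensity scores reintroduce confounding);
and a 240-participant classifier cohort. These sizes were chosen as the
smallest at which the planted effects are comfortably identifiable.

## Known limitations

* Single-layer LSTMs only; no GPU, no attention variants, no
  hyperparameter search.
* 8 cluster-validity indices (a deliberate subset spanning max-, min-
  and elbow-type criteria); the majority vote is robust to the subset
  but not identical to a wider panel.
* The trial-emulation Cox stage reports the matched marginal HR;
  IPTW-weighted estimation is not the default path.
* The t-SNE is exact (quadratic); it is not intended beyond a few
  thousand points.
* LEDD conversion, ICD code-set curation, RxNorm translation, pathway
  enrichment against external services, and raw-data processing
  (imaging, snRNA-seq, DESeq2) are out of scope; their outputs are
  consumed as inputs.
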