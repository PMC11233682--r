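# pacenet

Progression-**pace** subtyping and network medicine for Parkinson's
disease (PD), as one reusable R pipeline:

1. **Progression embedding.** An LSTM sequence autoencoder (the
   *deep phenotypic progression embedding*, DPPE) maps each
   participant's multivariate clinical time series — imputed by
   LOCF/NOCB + population median and z-scored,
   $\hat x = (x-\mu)/\sigma$ — to a 16-dimensional vector encoding the
   symptom-progression trajectory.
2. **Subtype discovery.** Ward agglomerative clustering (Euclidean
   distance) on the embeddings; the cluster number is the majority vote
   of eight validity indices; clusters are named by pace (PD-I
   inching < PD-M moderate < PD-R rapid).
3. **Subtype statistics.** Annual progression rates from linear mixed
   models (`value ~ time + covariates + (1 | participant)`),
   ANOVA/ANCOVA and chi-square baseline comparisons with Tukey HSD,
   Benjamini–Hochberg FDR, hypergeometric SNP enrichment, CSF-ratio and
   per-ROI atrophy comparisons.
4. **Molecular modules.** On a protein–protein interactome, gene scores
   $z(i)=|\log_2\mathrm{FC}|$ (DEGs at $q \le 0.05$) are smoothed by a
   random walk with restart; modules grow greedily from random seeds,
   admitting a neighbouring gene $i$ when its hypergeometric
   connectivity tail $P(i)\le 0.01$ and the module score
   $S(M)=\sum_{j\in M}(z(j)-\omega)/\sqrt{|M|}$ increases; top raw
   modules are unioned. Genetic modules link risk genes to contextual
   (dopaminergic-neuron) genes on the same interactome.
5. **Drug-reversal screening.** Per drug, genes are ranked by amplitude
   $\alpha=(t-c)/((t+c)/2)$; a signed Kolmogorov–Smirnov enrichment
   score ($ES = ES_{up} - ES_{down}$ when the signs differ) measures
   whether the drug opposes the module's expression signature, with
   permutation p-values, a normalised ES, and selection at
   normalised ES > 3, BH $q<0.05$.
6. **Target-trial emulation.** From EHR-shaped tables: eligibility
   (PD code, age ≥ 50, no prior neurodegeneration), PD initiation =
   first PD code − 183 days, 267-column baseline covariates, logistic
   propensity scores with greedy 1:1 nearest-neighbour matching,
   SMD ≤ 0.2 balance gating (≤ 2% unbalanced), Cox hazard ratios per
   emulated trial, and a median HR with a percentile CI across 100
   trials.
7. **Prognostic cascade.** Two random forests (rapid-vs-rest, then the
   remaining pair) on first-year features including 10 fold-internal
   principal components of 34-region brain atrophy, evaluated by
   stratified 5-fold cross-validation AUC.

The cohorts this kind of analysis targets (PPMI, PDBP, and large
clinical research networks such as INSIGHT and OneFlorida+) are
access-controlled, so the package ships a
**synthetic-data module** that generates every input with planted
ground truth — subtype labels, module genes, reverser drugs, enriched
SNPs, a known hazard ratio — and the test suite validates each stage by
recovering what was planted.

## Worked example

```r
library(pacenet)

sim  <- simulateCohort(cohortSpec(seed = 1))     # 3 x 100 participants
prep <- preprocessPanel(sim$panel)               # impute, z-score, grid
cfg  <- dppeConfig(input_dim = 20, embedding_dim = 16, epochs = 300,
                   batch_size = 16, patience = 25, seed = 1)
model <- trainDppe(buildDppe(cfg), prep$sequences)
emb   <- embedParticipants(model, prep$sequences)

asn <- hierarchicalCluster(emb, k = 3)
vote <- selectClusterNumber(clusterValidityIndices(emb, 2:6))
vote$k
#> [1] 3
ariIndex(asn@labels, sim$labels[participants(prep$sequences)])
#> [1] 0.9694462
nameSubtypesByPace(asn, prep$panel, "var01")
#> SubtypeAssignment: k = 3 over 293 participants
#> cluster
#>   1   2   3
#> 101  95  97
#>   pace naming: PD-I < PD-M < PD-R
```

The vote selects three subtypes and the clustering recovers the planted
labels almost perfectly (adjusted Rand index 0.97; 293 of 300
participants survive the one-year-history rule). Downstream, the same
cohort feeds the module, drug-screen and trial-emulation stages:

```r
net <- simulatePpiNetwork(seed = 2)              # 500 genes, 30 planted
deg <- simulateDegTable(net$network, net$planted, seed = 3)
z   <- rwrSmooth(net$network, initGeneScores(net$network, deg))
mod <- assembleModules(net$network, z, nRestarts = 1000, seed = 4)
mean(moduleGenes(mod) %in% net$planted)          # precision
#> [1] 1
mean(net$planted %in% moduleGenes(mod))          # recall
#> [1] 0.9

ehr <- simulateEhrCohort(ehrSpec(nPatients = 20000, seed = 11))
runEmulation(ehr, nTrials = 100, seed = 12)
#> HazardEstimate [drug_test -> OUTCOME_DEM]: median HR 0.777
#>   (95% CI 0.656-0.885), p = 1.59e-28, 100 balanced trials
```

The matched median hazard ratio (0.78, with a CI excluding 1 and
covering the planted 0.7) recovers the simulated protective effect
that the raw comparison misses entirely: the planted confounding
biases the unadjusted HR up by roughly 1.4-fold, to ~1.03, completely
masking the drug's benefit.

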