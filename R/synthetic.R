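#' @include AllClasses.R utils.R
NULL

#' Specification of a synthetic longitudinal cohort
#'
#' Defines the generative model of [simulateCohort()]: K progression-pace
#' subtypes of multivariate clinical time series with subtype-specific
#' linear annual slopes, participant-level random intercepts, observation
#' noise, completely-at-random missingness and monotone dropout.
#'
#' @param nPerSubtype integer vector, participants per subtype.
#' @param nVariables number of clinical variables.
#' @param nVisits number of scheduled visits (baseline included).
#' @param visitSpacing months between visits.
#' @param subtypeSlopes K x nVariables matrix of annual changes
#'   (variable units per year). NULL = default pace structure: pace
#'   multipliers spaced over 0.35-2.4 units/year combined with
#'   subtype-specific domain emphasis (a cosine pattern over the
#'   variable index), so subtypes differ both in overall pace and in
#'   which clinical domains progress fastest.
#' @param baselineMeans K x nVariables matrix; NULL = shared baselines.
#' @param randomInterceptSd participant-level intercept SD (shared
#'   across variables).
#' @param noiseSd observation noise SD.
#' @param missingRate fraction of cells missing completely at random,
#'   in \[0, 1).
#' @param dropoutHazard per-visit probability of permanent dropout.
#' @param seed integer RNG seed.
#' @return A named list of class `cohortSpec`.
#' @export
cohortSpec <- function(nPerSubtype = c(100, 100, 100), nVariables = 20,
                       nVisits = 6, visitSpacing = 12,
                       subtypeSlopes = NULL, baselineMeans = NULL,
                       randomInterceptSd = 0.6, noiseSd = 0.5,
                       missingRate = 0.1, dropoutHazard = 0.02,
                       seed = 1L) {
  K <- length(nPerSubtype)
  if (is.null(subtypeSlopes)) {
    # most variables progress, a few are flat; each subtype combines an
    # overall pace with its own domain emphasis so mean trajectories
    # are not collinear
    load <- rep(c(1, 0.6, 0.3, 0), length.out = nVariables)
    pace <- seq(0.35, 2.4, length.out = K)
    v <- seq_len(nVariables)
    subtypeSlopes <- t(vapply(seq_len(K), function(k)
      pace[k] * load * (1 + 0.6 * cos(2 * pi * v / nVariables +
                                        2 * pi * k / K)),
      numeric(nVariables)))
  }
  if (is.null(baselineMeans))
    baselineMeans <- matrix(rep(seq(5, 20, length.out = nVariables),
                                each = K), nrow = K)
  stopifnot(identical(dim(subtypeSlopes), c(K, as.integer(nVariables))) ||
            all(dim(subtypeSlopes) == c(K, nVariables)))
  if (!all(dim(baselineMeans) == c(K, nVariables)))
    stop("baselineMeans must be K x nVariables")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  structure(list(nPerSubtype = as.integer(nPerSubtype),
                 nVariables = as.integer(nVariables),
                 nVisits = as.integer(nVisits),
                 visitSpacing = visitSpacing,
                 subtypeSlopes = subtypeSlopes,
                 baselineMeans = baselineMeans,
                 randomInterceptSd = randomInterceptSd,
                 noiseSd = noiseSd, missingRate = missingRate,
                 dropoutHazard = dropoutHazard, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Simulate a K-subtype longitudinal clinical cohort
#'
#' value(i,t,v) = baseline\[k,v\] + slope\[k,v\] * t_years + u_i + eps,
#' with u_i ~ N(0, randomInterceptSd^2) per participant and
#' eps ~ N(0, noiseSd^2) per cell. Cells are then masked missing at
#' `missingRate`, and a per-visit dropout hazard truncates trajectory
#' tails (monotone missingness). The baseline visit is never masked.
#'
#' @param spec a [cohortSpec()].
#' @return list with `panel` (a [ClinicalPanel-class]) and `labels`
#'   (named integer subtype per participant).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  K <- length(spec$nPerSubtype)
  n <- sum(spec$nPerSubtype)
  Tn <- spec$nVisits; V <- spec$nVariables
  visits <- (seq_len(Tn) - 1) * spec$visitSpacing
  tYears <- visits / 12
  ids <- sprintf("S%04d", seq_len(n))
  labels <- rep(seq_len(K), spec$nPerSubtype)
  u <- rnorm(n, 0, spec$randomInterceptSd)
  vals <- array(NA_real_, dim = c(n, Tn, V),
                dimnames = list(ids, visits, sprintf("var%02d", seq_len(V))))
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    for (v in seq_len(V)) {
      mu <- spec$baselineMeans[k, v] + outer(rep(1, length(idx)),
                                             spec$subtypeSlopes[k, v] * tYears)
      vals[idx, , v] <- mu + u[idx] +
        matrix(rnorm(length(idx) * Tn, 0, spec$noiseSd), length(idx))
    }
  }
  # MCAR missingness, sparing baseline
  if (spec$missingRate > 0) {
    drop <- array(runif(n * Tn * V) < spec$missingRate, dim = dim(vals))
    drop[, 1, ] <- FALSE
    vals[drop] <- NA_real_
  }
  # monotone dropout: once out, all later visits missing
  if (spec$dropoutHazard > 0) {
    for (i in seq_len(n)) {
      out <- which(runif(Tn - 1) < spec$dropoutHazard)
      if (length(out)) vals[i, (min(out) + 1L):Tn, ] <- NA_real_
    }
  }
  list(panel = clinicalPanel(vals), labels = setNames(labels, ids))
}

#' Simulate a scale-free interactome with a planted dense module
#'
#' Grows a preferential-attachment graph, then rewires a designated gene
#' set into a dense clique-like subgraph (internal edge probability
#' `plantDensity`). The graph stays connected. Defaults keep the
#' degree-to-size ratio d_i/N near the real interactome's, which is
#' the quantity the hypergeometric connectivity gate of module growth
#' depends on.
#'
#' @param nGenes total gene count (>= 10).
#' @param attachM edges added per new vertex.
#' @param plantedSize size of the planted module (0 = no planting).
#' @param plantDensity internal edge probability among planted genes.
#' @param seed integer seed.
#' @return list with `network` (a [GeneNetwork-class]) and `planted`
#'   (character gene ids).
#' @export
simulatePpiNetwork <- function(nGenes = 500, attachM = 1,
                               plantedSize = 30, plantDensity = 0.15,
                               seed = 1L) {
  if (nGenes < 10) stop("nGenes must be >= 10")
  if (plantedSize >= nGenes) stop("plantedSize must be < nGenes")
  set.seed(seed)
  g <- igraph::sample_pa(nGenes, power = 1, m = attachM,
                         directed = FALSE)
  genes <- sprintf("g%04d", seq_len(nGenes))
  igraph::V(g)$name <- genes
  planted <- character(0)
  if (plantedSize > 0) {
    planted <- sort(sample(genes, plantedSize))
    pairs <- t(combn(planted, 2))
    keep <- runif(nrow(pairs)) < plantDensity
    if (any(keep))
      g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  }
  el <- igraph::as_edgelist(g)
  net <- buildNetwork(data.frame(from = el[, 1], to = el[, 2],
                                 stringsAsFactors = FALSE))
  list(network = net, planted = planted)
}

#' Simulate a differential-expression table with planted module effects
#'
#' Planted genes receive |log2FC| near `effectLog2fc` (random sign) and
#' adjusted p-values passing the DEG gate (q <= 0.05); `nNull` other
#' genes receive small fold changes with q > 0.05. With `effectLog2fc =
#' 0` the planted genes are indistinguishable from nulls.
#'
#' @param network a [GeneNetwork-class].
#' @param planted character planted gene ids (subset of network genes).
#' @param effectLog2fc planted |log2FC| magnitude.
#' @param nNull number of additional null rows.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `log2fc`, `padj`.
#' @export
simulateDegTable <- function(network, planted, effectLog2fc = 2,
                             nNull = 200, seed = 1L) {
  stopifnot(all(planted %in% networkGenes(network)))
  set.seed(seed)
  others <- setdiff(networkGenes(network), planted)
  nulls <- sample(others, min(nNull, length(others)))
  nullRow <- function(gs) data.frame(
    gene = gs, log2fc = rnorm(length(gs), 0, 0.1),
    padj = runif(length(gs), 0.051, 1), stringsAsFactors = FALSE)
  if (effectLog2fc == 0 || length(planted) == 0) {
    out <- rbind(nullRow(planted), nullRow(nulls))
  } else {
    sg <- sample(c(-1, 1), length(planted), replace = TRUE)
    out <- rbind(
      data.frame(gene = planted,
                 log2fc = sg * (effectLog2fc + rnorm(length(planted), 0, 0.1)),
                 padj = 10^runif(length(planted), -6, log10(0.05)),
                 stringsAsFactors = FALSE),
      nullRow(nulls))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a drug x gene signature (amplitude) matrix
#'
#' Null drugs draw amplitudes iid N(0, 1). Designated reverser drugs
#' suppress the disease-up genes (amplitude -strength) and elevate the
#' disease-down genes (+strength), i.e. anti-correlate with the planted
#' disease signature. `strength = 0` makes reversers indistinguishable
#' from nulls.
#'
#' @param genes character profiled gene ids.
#' @param nDrugs drug count.
#' @param reverserIds character ids of planted reversers (must be among
#'   the generated drug ids `drug001`...).
#' @param diseaseUp,diseaseDown disjoint character gene sets.
#' @param strength reversal amplitude shift.
#' @param seed integer seed.
#' @return numeric matrix, drugs as rows, genes as columns.
#' @export
simulateDrugSignatures <- function(genes, nDrugs = 500,
                                   reverserIds = sprintf("drug%03d", 1:50),
                                   diseaseUp, diseaseDown,
                                   strength = 2, seed = 1L) {
  if (length(intersect(diseaseUp, diseaseDown)))
    stop("diseaseUp and diseaseDown must be disjoint")
  set.seed(seed)
  drugs <- sprintf("drug%03d", seq_len(nDrugs))
  stopifnot(all(reverserIds %in% drugs))
  m <- matrix(rnorm(nDrugs * length(genes)), nrow = nDrugs,
              dimnames = list(drugs, genes))
  if (strength > 0) {
    up <- intersect(diseaseUp, genes); dn <- intersect(diseaseDown, genes)
    for (d in reverserIds) {
      m[d, up] <- -strength + rnorm(length(up), 0, 0.5)
      m[d, dn] <-  strength + rnorm(length(dn), 0, 0.5)
    }
  }
  m
}

#' Simulate genotypes with subtype-enriched variants
#'
#' Carrier status per SNP is Bernoulli with baseline probability
#' `baseProb`; for (SNP, subtype) pairs listed in `enrichedPairs` the
#' carrier odds are multiplied by `odds` within that subtype. Each SNP
#' maps to 1-3 candidate genes.
#'
#' @param nSnps SNP count.
#' @param subtypeLabels named integer subtype per participant.
#' @param enrichedPairs data.frame with columns `snp` (index or id) and
#'   `subtype` (integer), or NULL for a pure null.
#' @param odds carrier odds multiplier in the enriched subtype.
#' @param genePool character genes to draw the SNP-to-gene map from.
#' @param baseProb baseline carrier probability.
#' @param seed integer seed.
#' @return list with `genotypes` (participants x SNPs 0/1 matrix) and
#'   `snpGeneMap` (data.frame snp, gene).
#' @export
simulateGenotypes <- function(nSnps = 90, subtypeLabels,
                              enrichedPairs = NULL, odds = 8,
                              genePool = sprintf("g%04d", 1:500),
                              baseProb = 0.2, seed = 1L) {
  set.seed(seed)
  n <- length(subtypeLabels)
  snps <- sprintf("rs%04d", seq_len(nSnps))
  p <- matrix(baseProb, n, nSnps, dimnames = list(names(subtypeLabels), snps))
  if (!is.null(enrichedPairs)) {
    for (r in seq_len(nrow(enrichedPairs))) {
      s <- enrichedPairs$snp[r]
      if (is.character(s)) s <- match(s, snps)
      if (is.na(s) || s < 1 || s > nSnps) stop("enrichedPairs references an unknown SNP")
      k <- enrichedPairs$subtype[r]
      if (!k %in% subtypeLabels) stop("enrichedPairs references an unknown subtype")
      o <- baseProb / (1 - baseProb) * odds
      p[subtypeLabels == k, s] <- o / (1 + o)
    }
  }
  geno <- matrix(rbinom(n * nSnps, 1, as.vector(p)), n,
                 dimnames = dimnames(p))
  nMap <- sample(1:3, nSnps, replace = TRUE)
  snpGeneMap <- data.frame(
    snp = rep(snps, nMap),
    gene = unlist(lapply(nMap, function(m) sample(genePool, m))),
    stringsAsFactors = FALSE)
  list(genotypes = geno, snpGeneMap = snpGeneMap)
}

dkRoiNames <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
  "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
  "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
  "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
  "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
  "superiorfrontal", "superiorparietal", "superiortemporal",
  "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
  "insula")

#' Simulate CSF, ROI-atrophy and contextual-gene inputs
#'
#' CSF biomarkers (alpha-synuclein, A-beta 42, P-tau, T-tau) and 1-year
#' atrophy in the 34 Desikan-Killiany cortical regions are drawn
#' Gaussian per participant; `effects` plants per-subtype mean shifts
#' (in SD units) on designated columns. A contextual-gene list is
#' sampled from `genePool`.
#'
#' @param subtypeLabels named integer subtype per participant.
#' @param effects list of entries `list(table = "csf"|"roi", column =
#'   name, subtype = k, shift = SD units)`; NULL = no planted effect.
#' @param genePool character genes to sample contextual genes from.
#' @param nContextual contextual-gene list size.
#' @param seed integer seed.
#' @return list with `csf` (data.frame incl. age/sex covariates), `roi`
#'   (data.frame with 34 ROI columns), `contextualGenes` (character).
#' @export
simulateBiomarkers <- function(subtypeLabels, effects = NULL,
                               genePool = sprintf("g%04d", 1:500),
                               nContextual = 50, seed = 1L) {
  set.seed(seed)
  n <- length(subtypeLabels)
  ids <- names(subtypeLabels)
  base <- data.frame(participant_id = ids,
                     subtype = as.integer(subtypeLabels),
                     age = round(runif(n, 45, 80), 1),
                     sex = rbinom(n, 1, 0.4), stringsAsFactors = FALSE)
  csfCols <- c("alpha_syn", "abeta42", "ptau", "ttau")
  csfMeans <- c(alpha_syn = 1800, abeta42 = 900, ptau = 15, ttau = 170)
  csfSds <- c(alpha_syn = 600, abeta42 = 300, ptau = 5, ttau = 60)
  csf <- base
  for (cc in csfCols)
    csf[[cc]] <- rnorm(n, csfMeans[[cc]], csfSds[[cc]])
  roi <- base
  for (cc in dkRoiNames) roi[[cc]] <- rnorm(n, 0, 1)
  if (!is.null(effects)) {
    for (e in effects) {
      tgt <- if (identical(e$table, "csf")) "csf" else "roi"
      sdv <- if (tgt == "csf") csfSds[[e$column]] else 1
      sel <- subtypeLabels == e$subtype
      if (tgt == "csf") csf[[e$column]][sel] <- csf[[e$column]][sel] + e$shift * sdv
      else roi[[e$column]][sel] <- roi[[e$column]][sel] + e$shift * sdv
    }
  }
  list(csf = csf, roi = roi,
       contextualGenes = sort(sample(genePool, nContextual)))
}

#' Specification of a synthetic EHR cohort
#'
#' @param nPatients patient count.
#' @param nComorbidities comorbidity code groups (first
#'   `nConfounders` of them drive confounding).
#' @param nCoingredients co-prescribed ingredient count. The covariate
#'   layout is nComorbidities + nCoingredients + 4 (age, sex, race,
#'   initiation-to-index days); the defaults give the 267-column layout.
#' @param nConfounders number of comorbidities acting as true
#'   confounders.
#' @param confounderEffects named numeric: `treatment` log-odds and
#'   `outcome` log-hazard per unit of the standardized confounder score.
#' @param treatmentLogHr planted log hazard ratio of the tested drug.
#' @param baseHazard baseline outcome hazard per year.
#' @param censorRate independent censoring hazard per year.
#' @param adminYears administrative end of follow-up (years post index).
#' @param seed integer seed.
#' @return named list of class `ehrSpec`.
#' @export
ehrSpec <- function(nPatients = 20000, nComorbidities = 64,
                    nCoingredients = 199, nConfounders = 8,
                    confounderEffects = c(treatment = 0.8, outcome = 0.35),
                    treatmentLogHr = log(0.7), baseHazard = 0.05,
                    censorRate = 0.25, adminYears = 4, seed = 1L) {
  structure(list(nPatients = as.integer(nPatients),
                 nComorbidities = as.integer(nComorbidities),
                 nCoingredients = as.integer(nCoingredients),
                 nConfounders = as.integer(nConfounders),
                 confounderEffects = confounderEffects,
                 treatmentLogHr = treatmentLogHr,
                 baseHazard = baseHazard, censorRate = censorRate,
                 adminYears = adminYears, seed = as.integer(seed)),
            class = "ehrSpec")
}

#' Simulate an EHR cohort with confounded treatment and survival outcome
#'
#' Emits patients / diagnoses / prescriptions tables shaped like a
#' claims extract. Treatment with the tested ingredient (`drug_test`)
#' versus an in-class alternative (`alt1`..`alt5`) is assigned with
#' log-odds increasing in a standardized comorbidity-burden score; the
#' outcome (`OUTCOME_DEM` diagnosis) follows an exponential
#' proportional-hazards model whose log hazard adds the same score and
#' the planted treatment log-HR, so the planted HR is the exact estimand
#' of the downstream Cox stage. A `LAST_CONTACT` diagnosis marks end of
#' follow-up for censoring. A small fraction of patients violate
#' eligibility (age < 50, prior neurodegenerative code `G30`) to
#' exercise the filters.
#'
#' @param spec an [ehrSpec()].
#' @return list with `patients`, `diagnoses`, `prescriptions`
#'   data.frames (ISO-8601 dates) and `truth` (treated ids, confounder
#'   score, planted log-HR).
#' @export
simulateEhrCohort <- function(spec) {
  stopifnot(inherits(spec, "ehrSpec"))
  set.seed(spec$seed)
  n <- spec$nPatients
  ids <- sprintf("P%06d", seq_len(n))
  age <- runif(n, 50, 85)
  young <- runif(n) < 0.02           # eligibility violators
  age[young] <- runif(sum(young), 42, 49.5)
  sex <- rbinom(n, 1, 0.45)
  race <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  firstPd <- as.Date("2013-01-01") + round(runif(n, 0, 1800))
  birth <- firstPd - round(age * 365.25)
  initiation <- firstPd - 183L
  indexDate <- initiation + round(runif(n, 60, 540))

  # comorbidity flags; the first nConfounders drive everything
  nCom <- spec$nComorbidities
  flags <- matrix(rbinom(n * nCom, 1, 0.25), n, nCom)
  z <- as.vector(scale(flags[, seq_len(spec$nConfounders), drop = FALSE] %*%
                         rep(1, spec$nConfounders)))
  treatLogit <- -3.3 + spec$confounderEffects[["treatment"]] * z
  treated <- rbinom(n, 1, plogis(treatLogit)) == 1

  # outcome model (years from index)
  lh <- log(spec$baseHazard) + spec$confounderEffects[["outcome"]] * z +
    spec$treatmentLogHr * treated
  tEvent <- rexp(n, exp(lh))
  tCens <- pmin(rexp(n, spec$censorRate), spec$adminYears)
  event <- tEvent <= tCens
  tEnd <- pmin(tEvent, tCens)

  patients <- data.frame(patient_id = ids,
                         birth_date = format(birth),
                         sex = sex, race = race, stringsAsFactors = FALSE)

  dxList <- list(
    data.frame(patient_id = ids, code = "G20", date = format(firstPd),
               stringsAsFactors = FALSE))
  prior <- runif(n) < 0.02          # prior neurodegenerative diagnosis
  if (any(prior))
    dxList[[length(dxList) + 1L]] <- data.frame(
      patient_id = ids[prior], code = "G30",
      date = format(firstPd[prior] - round(runif(sum(prior), 30, 400))),
      stringsAsFactors = FALSE)
  comIdx <- which(flags == 1, arr.ind = TRUE)
  if (nrow(comIdx)) {
    i <- comIdx[, 1]
    gap <- as.numeric(indexDate[i] - initiation[i])
    dxList[[length(dxList) + 1L]] <- data.frame(
      patient_id = ids[i],
      code = sprintf("COM%02d", comIdx[, 2]),
      date = format(initiation[i] + round(runif(length(i)) * gap)),
      stringsAsFactors = FALSE)
  }
  outDate <- indexDate + round(tEvent * 365.25)
  dxList[[length(dxList) + 1L]] <- data.frame(
    patient_id = ids[event], code = "OUTCOME_DEM",
    date = format(outDate[event]), stringsAsFactors = FALSE)
  dxList[[length(dxList) + 1L]] <- data.frame(
    patient_id = ids, code = "LAST_CONTACT",
    date = format(indexDate + round(tEnd * 365.25) + 1L),
    stringsAsFactors = FALSE)
  diagnoses <- do.call(rbind, dxList)

  rxMain <- data.frame(
    patient_id = ids,
    ingredient = ifelse(treated, "drug_test",
                        sample(sprintf("alt%d", 1:5), n, replace = TRUE)),
    date = format(indexDate), stringsAsFactors = FALSE)
  nCo <- rpois(n, 3)
  ci <- rep(seq_len(n), nCo)
  rxCo <- data.frame(
    patient_id = ids[ci],
    ingredient = sprintf("coing%03d",
                         sample.int(spec$nCoingredients, length(ci),
                                    replace = TRUE)),
    date = format(initiation[ci] +
                    round(runif(length(ci)) *
                            as.numeric(indexDate[ci] - initiation[ci]))),
    stringsAsFactors = FALSE)
  prescriptions <- rbind(rxMain, rxCo)

  ord <- order(diagnoses$patient_id, diagnoses$date)
  diagnoses <- diagnoses[ord, ]
  rownames(diagnoses) <- NULL
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$date), ]
  rownames(prescriptions) <- NULL

  list(patients = patients, diagnoses = diagnoses,
       prescriptions = prescriptions,
       truth = list(treated = ids[treated], confounder = setNames(z, ids),
                    treatmentLogHr = spec$treatmentLogHr))
}
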