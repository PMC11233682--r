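#' @include AllClasses.R utils.R
NULL

firstDateByPatient <- function(df, codes, codeCol = "code") {
  sel <- df[df[[codeCol]] %in% codes, ]
  if (!nrow(sel))
    return(setNames(as.Date(character(0)), character(0)))
  d <- as.Date(sel$date)
  agg <- tapply(d, sel$patient_id, min)
  setNames(as.Date(agg, origin = "1970-01-01"), names(agg))
}

#' Apply trial eligibility criteria
#'
#' Keeps patients with at least one PD diagnosis code, age >= `minAge`
#' at the first PD code, and no neurodegenerative code strictly before
#' the first PD code. With `probablePdr = TRUE` additionally requires a
#' cognitive-deficit code within one year after PD initiation (first PD
#' code minus 183 days) and strictly before the patient's drug index
#' date.
#'
#' @param patients data.frame: patient_id, birth_date, sex, race.
#' @param diagnoses data.frame: patient_id, code, date.
#' @param pdCodes,neuroCodes nonempty character code sets.
#' @param minAge minimum age at first PD diagnosis, default 50.
#' @param probablePdr logical; restrict to the probable rapid-subtype
#'   phenotype.
#' @param cognitiveCodes code set for cognitive deficits (required when
#'   `probablePdr`).
#' @param indexDates named Date vector of drug index dates (required
#'   when `probablePdr`).
#' @return character vector of eligible patient ids.
#' @export
applyEligibility <- function(patients, diagnoses, pdCodes = "G20",
                             neuroCodes = "G30", minAge = 50,
                             probablePdr = FALSE,
                             cognitiveCodes = character(0),
                             indexDates = NULL) {
  if (!length(pdCodes) || !length(neuroCodes))
    stop("code sets must be nonempty")
  firstPd <- firstDateByPatient(diagnoses, pdCodes)
  ids <- names(firstPd)
  birth <- as.Date(patients$birth_date[match(ids, patients$patient_id)])
  age <- as.numeric(firstPd - birth) / 365.25
  keep <- !is.na(age) & age >= minAge
  firstNeuro <- firstDateByPatient(diagnoses, neuroCodes)
  hasPrior <- ids %in% names(firstNeuro) &
    firstNeuro[ids] < firstPd
  hasPrior[is.na(hasPrior)] <- FALSE
  keep <- keep & !hasPrior
  elig <- ids[keep]
  if (probablePdr) {
    if (!length(cognitiveCodes) || is.null(indexDates))
      stop("probablePdr requires cognitiveCodes and indexDates")
    firstCog <- firstDateByPatient(diagnoses, cognitiveCodes)
    initiation <- firstPd - 183
    ok <- vapply(elig, function(id) {
      if (!id %in% names(firstCog) || !id %in% names(indexDates))
        return(FALSE)
      cg <- firstCog[[id]]
      cg > initiation[[id]] && cg <= initiation[[id]] + 365 &&
        cg < indexDates[[id]]
    }, logical(1))
    elig <- elig[ok]
  }
  elig
}

#' Define initiation and index dates for an emulated trial
#'
#' PD initiation = first PD code date minus 183 days (six months).
#' Index = first dispensing of the tested drug (treated arm) or of an
#' alternative-class drug (control candidates) on/after initiation.
#' Patients whose qualifying dispensing precedes initiation, or whose
#' first outcome is not strictly later than the index, are rejected.
#' Patients exposed to the tested drug are assigned to the treated arm
#' regardless of alternative use.
#'
#' @param eligible character eligible patient ids.
#' @param diagnoses,prescriptions EHR tables.
#' @param testedDrug ingredient name of the tested drug.
#' @param alternativeSet ingredient names of the in-class alternatives.
#' @param pdCodes PD diagnosis code set.
#' @param outcomeCodes outcome diagnosis code set.
#' @return data.frame: patient_id, arm ("treated"/"control"),
#'   initiation, index (Date columns).
#' @export
defineDates <- function(eligible, diagnoses, prescriptions,
                        testedDrug, alternativeSet,
                        pdCodes = "G20", outcomeCodes = "OUTCOME_DEM") {
  firstPd <- firstDateByPatient(diagnoses, pdCodes)[eligible]
  initiation <- firstPd - 183
  rx <- prescriptions[prescriptions$patient_id %in% eligible, ]
  rx$date <- as.Date(rx$date)
  pick <- function(drugs) {
    sel <- rx[rx$ingredient %in% drugs, ]
    sel <- sel[sel$date >= initiation[sel$patient_id], ]
    if (!nrow(sel)) return(setNames(as.Date(character(0)), character(0)))
    agg <- tapply(sel$date, sel$patient_id, min)
    setNames(as.Date(agg, origin = "1970-01-01"), names(agg))
  }
  idxT <- pick(testedDrug)
  idxC <- pick(alternativeSet)
  idxC <- idxC[setdiff(names(idxC), names(idxT))]
  out <- rbind(
    data.frame(patient_id = names(idxT), arm = "treated",
               index = unname(idxT), stringsAsFactors = FALSE),
    data.frame(patient_id = names(idxC), arm = "control",
               index = unname(idxC), stringsAsFactors = FALSE))
  if (!nrow(out)) return(out)
  out$initiation <- initiation[out$patient_id]
  firstOut <- firstDateByPatient(diagnoses, outcomeCodes)
  fo <- firstOut[out$patient_id]
  reject <- !is.na(fo) & fo <= out$index
  out <- out[!reject & out$index >= out$initiation, ]
  rownames(out) <- NULL
  out[, c("patient_id", "arm", "initiation", "index")]
}

#' Build the covariate matrix for propensity modeling
#'
#' Binary flags for each comorbidity code group and each co-prescribed
#' ingredient observed within the baseline window (initiation to index,
#' inclusive), plus age at index, sex, race (as coded), and days from
#' initiation to index. Events after the index date never contribute.
#' The column count is asserted against the schema.
#'
#' @param dates data.frame from [defineDates()].
#' @param patients,diagnoses,prescriptions EHR tables.
#' @param comorbidityCodes character comorbidity code groups.
#' @param topIngredients character co-ingredient names.
#' @return numeric matrix (patients x covariates) with a `schema`
#'   attribute; rownames are patient ids.
#' @export
buildCovariates <- function(dates, patients, diagnoses, prescriptions,
                            comorbidityCodes, topIngredients) {
  ids <- dates$patient_id
  n <- length(ids)
  w <- match(diagnoses$patient_id, ids)
  dd <- as.Date(diagnoses$date)
  inWin <- !is.na(w) & diagnoses$code %in% comorbidityCodes &
    dd >= dates$initiation[w] & dd <= dates$index[w]
  comFlags <- matrix(0, n, length(comorbidityCodes),
                     dimnames = list(ids, comorbidityCodes))
  if (any(inWin)) {
    tb <- unique(data.frame(i = w[inWin], j = match(
      diagnoses$code[inWin], comorbidityCodes)))
    comFlags[cbind(tb$i, tb$j)] <- 1
  }
  wp <- match(prescriptions$patient_id, ids)
  pd <- as.Date(prescriptions$date)
  inWinP <- !is.na(wp) & prescriptions$ingredient %in% topIngredients &
    pd >= dates$initiation[wp] & pd <= dates$index[wp]
  ingFlags <- matrix(0, n, length(topIngredients),
                     dimnames = list(ids, topIngredients))
  if (any(inWinP)) {
    tb <- unique(data.frame(i = wp[inWinP], j = match(
      prescriptions$ingredient[inWinP], topIngredients)))
    ingFlags[cbind(tb$i, tb$j)] <- 1
  }
  pm <- match(ids, patients$patient_id)
  demo <- cbind(
    age = as.numeric(dates$index - as.Date(patients$birth_date[pm])) / 365.25,
    sex = patients$sex[pm],
    race = patients$race[pm],
    init_to_index_days = as.numeric(dates$index - dates$initiation))
  rownames(demo) <- ids
  out <- cbind(comFlags, ingFlags, demo)
  schema <- colnames(out)
  stopifnot(ncol(out) ==
              length(comorbidityCodes) + length(topIngredients) + 4L)
  attr(out, "schema") <- schema
  out
}

#' Balance diagnostics for a matched trial
#'
#' Absolute SMD per covariate between the treated and control sets;
#' the trial is balanced if the fraction of covariates with SMD above
#' `smdThreshold` is at most `maxUnbalancedFrac`.
#'
#' @param covariates covariate matrix (rownames = patient ids).
#' @param treatedIds,controlIds character id vectors.
#' @param smdThreshold per-covariate balance cutoff, default 0.2.
#' @param maxUnbalancedFrac tolerated unbalanced fraction, default 0.02.
#' @return list: smd (named numeric), balanced (logical),
#'   unbalancedFrac.
#' @export
assessBalance <- function(covariates, treatedIds, controlIds,
                          smdThreshold = 0.2, maxUnbalancedFrac = 0.02) {
  xT <- covariates[treatedIds, , drop = FALSE]
  xC <- covariates[controlIds, , drop = FALSE]
  smd <- vapply(seq_len(ncol(covariates)), function(j)
    smdValue(xT[, j], xC[, j]), numeric(1))
  names(smd) <- colnames(covariates)
  frac <- mean(smd > smdThreshold)
  list(smd = smd, balanced = frac <= maxUnbalancedFrac,
       unbalancedFrac = frac)
}

fitPropensity <- function(covariates, treated) {
  X <- covariates
  keep <- apply(X, 2, function(x) var(x) > 0)
  X <- cbind(1, X[, keep, drop = FALSE])
  fit <- suppressWarnings(
    glm.fit(X, as.integer(treated), family = binomial()))
  ps <- pmin(pmax(fit$fitted.values, 1e-6), 1 - 1e-6)
  setNames(ps, rownames(covariates))
}

#' Propensity-score match one emulated trial
#'
#' Fits a logistic propensity model of treatment on the covariates,
#' then greedily 1:1 nearest-neighbor matches on the logit propensity
#' score without replacement, processing treated patients in a seeded
#' random order. Optionally discards pairs further apart than `caliper`
#' (in logit-PS units).
#'
#' @param covariates covariate matrix over treated + control-pool rows.
#' @param treatedIds,controlPool character id vectors
#'   (pool >= treated).
#' @param seed integer seed for the matching order.
#' @param caliper optional max |logit PS| distance.
#' @param smdThreshold,maxUnbalancedFrac balance settings.
#' @return An [EmulatedTrialSet-class].
#' @export
matchTrial <- function(covariates, treatedIds, controlPool, seed = 1L,
                       caliper = NULL, smdThreshold = 0.2,
                       maxUnbalancedFrac = 0.02) {
  if (length(controlPool) < length(treatedIds))
    stop("control pool smaller than treated set")
  all <- c(treatedIds, controlPool)
  cov <- covariates[all, , drop = FALSE]
  ps <- fitPropensity(cov, all %in% treatedIds)
  lps <- qlogis(ps)
  set.seed(seed)
  ord <- sample(treatedIds)
  avail <- rep(TRUE, length(controlPool))
  ctrlL <- lps[controlPool]
  pairC <- character(length(ord)); pairT <- character(length(ord))
  nPair <- 0L
  for (tid in ord) {
    d <- abs(ctrlL - lps[[tid]])
    d[!avail] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) next
    if (!is.null(caliper) && d[j] > caliper) next
    nPair <- nPair + 1L
    pairT[nPair] <- tid
    pairC[nPair] <- controlPool[j]
    avail[j] <- FALSE
  }
  pairT <- pairT[seq_len(nPair)]; pairC <- pairC[seq_len(nPair)]
  smdPre <- assessBalance(covariates, treatedIds, controlPool,
                          smdThreshold, maxUnbalancedFrac)
  bal <- assessBalance(covariates, pairT, pairC, smdThreshold,
                       maxUnbalancedFrac)
  new("EmulatedTrialSet", treated = pairT, controls = pairC,
      propensity = ps, smd = bal$smd, smdPre = smdPre$smd,
      balanced = bal$balanced)
}

#' Time-to-event outcomes from the EHR tables
#'
#' Follow-up runs from the index date to the first outcome diagnosis or
#' censoring at the last recorded event for the patient, whichever
#' comes first.
#'
#' @param dates data.frame from [defineDates()].
#' @param diagnoses EHR diagnoses.
#' @param outcomeCodes outcome code set.
#' @return data.frame: patient_id, time (years), event (0/1).
#' @export
survivalFromTables <- function(dates, diagnoses, outcomeCodes) {
  firstOut <- firstDateByPatient(diagnoses, outcomeCodes)
  dd <- as.Date(diagnoses$date)
  lastAny <- tapply(dd[diagnoses$patient_id %in% dates$patient_id],
                    diagnoses$patient_id[diagnoses$patient_id %in%
                                           dates$patient_id], max)
  lastAny <- setNames(as.Date(lastAny, origin = "1970-01-01"),
                      names(lastAny))
  fo <- firstOut[dates$patient_id]
  la <- lastAny[dates$patient_id]
  event <- !is.na(fo) & fo > dates$index & fo <= la
  end <- ifelse(event, fo, la)
  end <- as.Date(end, origin = "1970-01-01")
  data.frame(patient_id = dates$patient_id,
             time = pmax(as.numeric(end - dates$index), 0.5) / 365.25,
             event = as.integer(event), stringsAsFactors = FALSE)
}

#' Cox hazard ratio of treatment in one matched trial
#'
#' Partial-likelihood Cox fit of the treatment indicator on the
#' matched sample.
#'
#' @param surv data.frame from [survivalFromTables()].
#' @param treatedIds,controlIds matched id sets.
#' @return list: hr, se (log scale), ciLow, ciHigh, nEvents; NULL if an
#'   arm has no events.
#' @export
estimateCoxHr <- function(surv, treatedIds, controlIds) {
  d <- surv[surv$patient_id %in% c(treatedIds, controlIds), ]
  d$treated <- as.integer(d$patient_id %in% treatedIds)
  if (sum(d$event[d$treated == 1]) == 0 ||
      sum(d$event[d$treated == 0]) == 0) {
    warning("no events in one arm; HR undefined")
    return(NULL)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ treated, data = d)
  beta <- unname(coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  list(hr = exp(beta), se = se, ciLow = exp(beta - 1.96 * se),
       ciHigh = exp(beta + 1.96 * se), nEvents = sum(d$event))
}

#' Run a full repeated trial emulation for one drug
#'
#' Eligibility, index dating, covariate assembly, then `nTrials`
#' emulated trials: each trial draws a seeded subsample of the control
#' candidate pool (size min(pool, poolFactor x treated)) and a fresh
#' matching order, matches 1:1 on the propensity score, keeps the trial
#' if covariate balance is reached, and fits the Cox treatment HR.
#' Drugs with fewer than `minTreated` treated patients are skipped;
#' drugs with fewer than `minBalanced` balanced trials are excluded.
#' The summary is the median HR across balanced trials with a
#' percentile-bootstrap 95% CI (the trials serve as bootstrap
#' replicates of the control sampling and matching; the CI is the
#' percentile range of their HRs) and a sign-test p for median
#' HR != 1.
#'
#' @param ehr list with `patients`, `diagnoses`, `prescriptions`.
#' @param testedDrug,alternativeSet ingredient names.
#' @param outcomeCodes outcome diagnosis code set.
#' @param comorbidityCodes,topIngredients covariate code sets.
#' @param nTrials number of emulated trials, default 100.
#' @param seed master seed.
#' @param minTreated,minBalanced inclusion gates (100 / 10).
#' @param poolFactor control-pool subsample factor, default 10.
#' @param nBoot bootstrap draws for the CI, default 1000.
#' @param pdCodes,neuroCodes eligibility code sets.
#' @return A [HazardEstimate-class], or NULL (with a message) when a
#'   gate fails. The per-trial table is attached as attribute
#'   `trials`; mean post-match balanced-covariate fraction as
#'   `balanceFrac`.
#' @export
runEmulation <- function(ehr, testedDrug = "drug_test",
                         alternativeSet = sprintf("alt%d", 1:5),
                         outcomeCodes = "OUTCOME_DEM",
                         comorbidityCodes = sprintf("COM%02d", 1:64),
                         topIngredients = sprintf("coing%03d", 1:199),
                         nTrials = 100, seed = 1L, minTreated = 100,
                         minBalanced = 10, poolFactor = 10,
                         nBoot = 1000, pdCodes = "G20",
                         neuroCodes = "G30") {
  elig <- applyEligibility(ehr$patients, ehr$diagnoses, pdCodes,
                           neuroCodes)
  dates <- defineDates(elig, ehr$diagnoses, ehr$prescriptions,
                       testedDrug, alternativeSet, pdCodes,
                       outcomeCodes)
  treatedIds <- dates$patient_id[dates$arm == "treated"]
  controlIds <- dates$patient_id[dates$arm == "control"]
  if (length(treatedIds) < minTreated) {
    message("drug skipped: insufficient patients (",
            length(treatedIds), " treated)")
    return(NULL)
  }
  cov <- buildCovariates(dates, ehr$patients, ehr$diagnoses,
                         ehr$prescriptions, comorbidityCodes,
                         topIngredients)
  surv <- survivalFromTables(dates, ehr$diagnoses, outcomeCodes)
  nPool <- min(length(controlIds), poolFactor * length(treatedIds))
  hrs <- numeric(0)
  trials <- list()
  balFracs <- numeric(0)
  for (tr in seq_len(nTrials)) {
    s <- childSeed(seed, tr)
    set.seed(s)
    pool <- sample(controlIds, nPool)
    trial <- matchTrial(cov, treatedIds, pool, seed = childSeed(s, 1))
    balFracs <- c(balFracs, mean(trial@smd <= 0.2))
    cx <- if (trial@balanced)
      estimateCoxHr(surv, trial@treated, trial@controls) else NULL
    if (!is.null(cx)) hrs <- c(hrs, cx$hr)
    trials[[tr]] <- data.frame(
      trial = tr, balanced = trial@balanced,
      unbalanced = sum(trial@smd > 0.2),
      hr = if (is.null(cx)) NA_real_ else cx$hr)
  }
  trialTab <- do.call(rbind, trials)
  if (length(hrs) < minBalanced) {
    message("drug excluded: only ", length(hrs), " balanced trials")
    return(NULL)
  }
  # the emulated trials are the bootstrap replicates (each resamples
  # the control pool and matching); the CI is the percentile range of
  # the balanced-trial HRs, smoothed by nBoot resampling draws
  set.seed(childSeed(seed, 999983L))
  boot <- sample(hrs, nBoot, replace = TRUE)
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  p <- binom.test(sum(hrs < 1), length(hrs))$p.value
  est <- new("HazardEstimate", drug = testedDrug,
             outcome = paste(outcomeCodes, collapse = ","),
             hrs = hrs, medianHR = median(hrs), ciLow = ci[1],
             ciHigh = ci[2], p = p, nBalanced = length(hrs))
  attr(est, "trials") <- trialTab
  attr(est, "balanceFrac") <- mean(balFracs)
  est
}
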