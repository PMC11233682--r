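#' @include AllClasses.R utils.R
NULL

#' Annual progression rate from a linear mixed model
#'
#' Fits `value ~ time_years + covariates + (1 | participant)` by REML
#' (lme4) on the long-format records of one variable within one subtype
#' and reports the time coefficient as the annual progression rate with
#' a Wald 95% CI and normal-approximation p-value. Falls back to an
#' ordinary linear model (with a warning) if the random-intercept fit
#' is singular in a degenerate way (zero residual variance).
#'
#' @param data data.frame with columns `participant`, `time_years`,
#'   `value`, plus any covariate columns.
#' @param covariates character covariate column names (e.g. age, sex,
#'   LEDD analog); may be empty.
#' @return data.frame row: beta, ciLow, ciHigh, p.
#' @export
fitProgressionRate <- function(data, covariates = character(0)) {
  stopifnot(all(c("participant", "time_years", "value") %in% names(data)))
  nVisits <- table(data$participant)
  if (any(nVisits < 2))
    data <- data[data$participant %in% names(nVisits)[nVisits >= 2], ]
  rhs <- paste(c("time_years", covariates, "(1 | participant)"),
               collapse = " + ")
  fit <- tryCatch(
    lme4::lmer(as.formula(paste("value ~", rhs)), data = data,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed-model fit failed; falling back to a fixed-effects model")
    f2 <- lm(as.formula(paste("value ~",
                              paste(c("time_years", covariates),
                                    collapse = " + "))), data = data)
    s <- summary(f2)$coefficients["time_years", ]
    return(data.frame(beta = s[1], ciLow = s[1] - 1.96 * s[2],
                      ciHigh = s[1] + 1.96 * s[2], p = s[4]))
  }
  cf <- lme4::fixef(fit)["time_years"]
  se <- sqrt(diag(as.matrix(vcov(fit))))[["time_years"]]
  z <- cf / se
  data.frame(beta = unname(cf), ciLow = unname(cf - 1.96 * se),
             ciHigh = unname(cf + 1.96 * se),
             p = unname(2 * pnorm(-abs(z))))
}

#' Progression rates for every variable and subtype
#'
#' Convenience wrapper running [fitProgressionRate()] per (subtype,
#' variable) on a [ClinicalPanel-class], with BH correction within each
#' subtype's family of variables.
#'
#' @param panel an imputed [ClinicalPanel-class] (original scale or
#'   z-scored).
#' @param labels named integer subtype per participant.
#' @param covariateTable optional data.frame keyed by `participant`
#'   with covariate columns.
#' @param covariates character covariate names in `covariateTable`.
#' @return data.frame: subtype, variable, beta, ciLow, ciHigh, p, q.
#' @export
progressionRateTable <- function(panel, labels,
                                 covariateTable = NULL,
                                 covariates = character(0)) {
  out <- list()
  tY <- panel@visits / 12
  for (k in sort(unique(labels))) {
    ids <- names(labels)[labels == k]
    idx <- match(ids, panel@participants)
    rows <- list()
    for (v in seq_along(panel@variables)) {
      long <- do.call(rbind, lapply(idx, function(i) {
        ok <- panel@mask[i, , v]
        data.frame(participant = panel@participants[i],
                   time_years = tY[ok], value = panel@values[i, ok, v],
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(covariateTable))
        long <- merge(long, covariateTable, by = "participant")
      r <- fitProgressionRate(long, covariates)
      rows[[v]] <- cbind(data.frame(subtype = k,
                                    variable = panel@variables[v],
                                    stringsAsFactors = FALSE), r)
    }
    tab <- do.call(rbind, rows)
    tab$q <- adjustFdr(tab$p)
    out[[length(out) + 1L]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Baseline group comparison (ANOVA / chi-square, optional ANCOVA)
#'
#' Continuous variables: one-way ANOVA across groups (ANCOVA when
#' covariates are supplied), with Tukey HSD pairwise contrasts when the
#' group effect is significant at 0.05. Categorical variables:
#' chi-square test on the contingency table.
#'
#' @param values vector of the variable (numeric, or factor/character
#'   for categorical).
#' @param groups group labels, >= 2 groups with >= 2 observations each.
#' @param covariateTable optional data.frame of covariates (same row
#'   order as `values`).
#' @return list with `type`, `statistic`, `p`, and `tukey` (data.frame
#'   or NULL).
#' @export
compareGroupsBaseline <- function(values, groups, covariateTable = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  if (is.numeric(values)) {
    df <- data.frame(y = values, g = groups)
    if (!is.null(covariateTable)) df <- cbind(df, covariateTable)
    rhs <- paste(c(setdiff(names(df), c("y", "g")), "g"), collapse = " + ")
    fit <- aov(as.formula(paste("y ~", rhs)), data = df)
    at <- anova(fit)
    p <- at["g", "Pr(>F)"]
    stat <- at["g", "F value"]
    tk <- NULL
    if (!is.na(p) && p < 0.05) {
      tt <- TukeyHSD(fit, which = "g")$g
      tk <- data.frame(contrast = rownames(tt), diff = tt[, "diff"],
                       pAdj = tt[, "p adj"], row.names = NULL,
                       stringsAsFactors = FALSE)
    }
    list(type = if (is.null(covariateTable)) "anova" else "ancova",
         statistic = stat, p = p, tukey = tk)
  } else {
    tab <- table(values, groups)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(type = "chisq", statistic = unname(ct$statistic),
         p = ct$p.value, tukey = NULL)
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values; q is monotone in p.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
adjustFdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Hypergeometric SNP-subtype enrichment
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing k
#' carriers of a SNP among the n subtype members, given K carriers in
#' the PD cohort of size N.
#'
#' @param N cohort size.
#' @param K carriers in the cohort.
#' @param n subtype size.
#' @param k carriers in the subtype.
#' @return p-value in (0, 1].
#' @export
snpEnrichment <- function(N, K, n, k) {
  if (k > min(K, n) || K > N || n > N || k < 0)
    stop("impossible hypergeometric configuration")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of every SNP in every subtype
#'
#' @param genotypes participants x SNPs 0/1 matrix.
#' @param labels named integer subtype per participant (same ids).
#' @return data.frame: snp, subtype, N, K, n, k, p.
#' @export
snpEnrichmentTable <- function(genotypes, labels) {
  labels <- labels[rownames(genotypes)]
  N <- nrow(genotypes)
  out <- list()
  for (s in colnames(genotypes)) {
    K <- sum(genotypes[, s])
    for (st in sort(unique(labels))) {
      sel <- labels == st
      k <- sum(genotypes[sel, s])
      out[[length(out) + 1L]] <- data.frame(
        snp = s, subtype = st, N = N, K = K, n = sum(sel), k = k,
        p = snpEnrichment(N, K, sum(sel), k), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

csfRatioDefs <- list(
  abeta42_ptau = c("abeta42", "ptau"),
  abeta42_ttau = c("abeta42", "ttau"),
  abeta42_asyn = c("abeta42", "alpha_syn"),
  ptau_asyn = c("ptau", "alpha_syn"),
  ttau_asyn = c("ttau", "alpha_syn"),
  ptau_ttau = c("ptau", "ttau"))

#' Compare CSF biomarkers (and their ratios) between two groups
#'
#' Adds the standard biomarker ratios (A-beta-42/P-tau, P-tau/alpha-syn,
#' ...), then fits a linear model per biomarker with group membership
#' as the explanatory variable, adjusting for baseline age and sex.
#' Records with a zero ratio denominator are excluded with a warning.
#'
#' @param csf data.frame with `subtype`, `age`, `sex` and raw biomarker
#'   columns `alpha_syn`, `abeta42`, `ptau`, `ttau`.
#' @param groupPair length-2 vector of subtype codes to compare.
#' @return data.frame: biomarker, beta (second vs first group), p.
#' @export
compareBiomarker <- function(csf, groupPair) {
  d <- csf[csf$subtype %in% groupPair, ]
  for (nm in names(csfRatioDefs)) {
    num <- d[[csfRatioDefs[[nm]][1]]]
    den <- d[[csfRatioDefs[[nm]][2]]]
    bad <- den == 0
    if (any(bad)) {
      warning(sum(bad), " record(s) with zero denominator excluded for ", nm)
      num[bad] <- NA
    }
    d[[nm]] <- num / den
  }
  marks <- c("alpha_syn", "abeta42", "ptau", "ttau", names(csfRatioDefs))
  d$grp <- factor(d$subtype, levels = groupPair)
  out <- lapply(marks, function(m) {
    dd <- d[!is.na(d[[m]]), ]
    fit <- lm(dd[[m]] ~ grp + age + sex, data = dd)
    s <- summary(fit)$coefficients
    r <- grep("^grp", rownames(s))
    data.frame(biomarker = m, beta = s[r, 1], p = s[r, 4],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-ROI two-sample t-tests of brain atrophy
#'
#' Student's t-test per Desikan-Killiany region between two groups,
#' with -log10(p) and a significance flag at p < 0.05.
#'
#' @param roi data.frame with `subtype` and ROI columns.
#' @param groupPair length-2 vector of subtype codes.
#' @param roiColumns character ROI column names (default: the 34
#'   Desikan-Killiany regions present in the table).
#' @return data.frame: roi, t, p, negLog10P, significant.
#' @export
compareRoiAtrophy <- function(roi, groupPair,
                              roiColumns = intersect(dkRoiNames, names(roi))) {
  a <- roi[roi$subtype == groupPair[1], ]
  b <- roi[roi$subtype == groupPair[2], ]
  out <- lapply(roiColumns, function(cc) {
    tt <- t.test(a[[cc]], b[[cc]])
    data.frame(roi = cc, t = unname(tt$statistic), p = tt$p.value,
               negLog10P = -log10(tt$p.value),
               significant = tt$p.value < 0.05, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
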