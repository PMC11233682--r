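#' @include AllClasses.R
NULL

# derive a child seed from a master seed; kept below 2^31
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009) %% 2147483647)
}

#' Construct a ClinicalPanel
#'
#' @param values participants x visits x variables numeric array; NA
#'   marks missing cells.
#' @param participants,visits,variables dimension labels; taken from
#'   `dimnames(values)` when omitted.
#' @return A [ClinicalPanel-class] object whose `observed` slot records
#'   the non-NA cells.
#' @export
clinicalPanel <- function(values, participants = NULL, visits = NULL,
                          variables = NULL) {
  dn <- dimnames(values)
  if (is.null(participants)) participants <- dn[[1]]
  if (is.null(visits)) visits <- as.numeric(dn[[2]])
  if (is.null(variables)) variables <- dn[[3]]
  mask <- !is.na(values)
  new("ClinicalPanel", participants = as.character(participants),
      visits = as.numeric(visits), variables = as.character(variables),
      values = values, mask = mask, observed = mask, scaling = NULL)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
ariIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score against binary labels.
#'
#' @param score numeric predictions, larger = more positive.
#' @param label binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(score, label) {
  label <- as.integer(as.logical(label))
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Absolute standardized mean difference
#'
#' SMD = |mean_T - mean_C| / sqrt((var_T + var_C)/2). Binary covariates
#' use the proportion variance p(1-p). A covariate constant at the same
#' value in both arms has SMD 0 by convention; differing means with zero
#' pooled variance give Inf (maximally unbalanced).
#'
#' @param xT,xC numeric covariate values in the treated / control arm.
#' @return nonnegative SMD.
#' @export
smdValue <- function(xT, xC) {
  binary <- all(xT %in% c(0, 1)) && all(xC %in% c(0, 1))
  mT <- mean(xT); mC <- mean(xC)
  if (binary) {
    vT <- mT * (1 - mT); vC <- mC * (1 - mC)
  } else {
    vT <- var(xT); vC <- var(xC)
    if (is.na(vT)) vT <- 0
    if (is.na(vC)) vC <- 0
  }
  pool <- sqrt((vT + vC) / 2)
  if (pool == 0) return(if (mT == mC) 0 else Inf)
  abs(mT - mC) / pool
}

# stratified fold assignment: each class split as evenly as possible
stratifiedFolds <- function(labels, nFolds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}
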