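#' @include AllClasses.R utils.R
NULL

#' Impute with last-observation-carried-forward then
#' next-observation-carried-backward
#'
#' Per participant-variable series, a LOCF pass fills every gap after
#' the first observation with the most recent observed value, then a
#' NOCB pass fills leading gaps from the first observed value. Series
#' with at least one observation become complete; all-missing series are
#' left untouched (they are handled by [imputePopulationMedian()]).
#' Observed values are never altered.
#'
#' @param panel a [ClinicalPanel-class].
#' @return The panel with gaps filled and `mask` updated.
#' @export
imputeLocfNocb <- function(panel) {
  stopifnot(is(panel, "ClinicalPanel"))
  vals <- panel@values
  d <- dim(vals)
  for (i in seq_len(d[1])) for (v in seq_len(d[3])) {
    x <- vals[i, , v]
    obs <- which(!is.na(x))
    if (length(obs) == 0L || length(obs) == d[2]) next
    # LOCF
    last <- NA_real_
    for (t in seq_len(d[2])) {
      if (!is.na(x[t])) last <- x[t] else if (!is.na(last)) x[t] <- last
    }
    # NOCB on whatever leading gap remains
    first <- which(!is.na(x))[1]
    if (first > 1L) x[seq_len(first - 1L)] <- x[first]
    vals[i, , v] <- x
  }
  panel@values <- vals
  panel@mask <- !is.na(vals)
  validObject(panel)
  panel
}

#' Impute remaining gaps with the population median
#'
#' Any cell still missing (i.e. all-missing participant series) is
#' replaced by the median of that variable over all currently observed
#' participant-visit cells. Intended to run after [imputeLocfNocb()].
#'
#' @param panel a [ClinicalPanel-class].
#' @return Fully imputed panel (`mask` all TRUE).
#' @export
imputePopulationMedian <- function(panel) {
  stopifnot(is(panel, "ClinicalPanel"))
  vals <- panel@values
  for (v in seq_along(panel@variables)) {
    slab <- vals[, , v, drop = FALSE]
    if (!anyNA(slab)) next
    obs <- slab[!is.na(slab)]
    if (length(obs) == 0L)
      stop("variable '", panel@variables[v],
           "' is observed in zero participants")
    slab[is.na(slab)] <- median(obs)
    vals[, , v] <- slab
  }
  panel@values <- vals
  panel@mask <- !is.na(vals)
  validObject(panel)
  panel
}

#' Z-score a fully imputed panel
#'
#' Per variable, computes mu and sigma over all participant-visit cells
#' (population sigma, divide by n) and stores (x - mu) / sigma. The
#' scaling parameters are retained for the inverse transform. A
#' zero-variance variable cannot be scaled and is dropped with a
#' warning.
#'
#' @param panel fully imputed [ClinicalPanel-class].
#' @return Z-scored panel with the `scaling` slot populated.
#' @export
zscorePanel <- function(panel) {
  stopifnot(is(panel, "ClinicalPanel"))
  if (!all(panel@mask)) stop("panel must be fully imputed before scaling")
  vals <- panel@values
  V <- length(panel@variables)
  mu <- sigma <- numeric(V)
  for (v in seq_len(V)) {
    x <- vals[, , v]
    mu[v] <- mean(x)
    sigma[v] <- sqrt(mean((x - mu[v])^2))
  }
  keep <- sigma > 0
  if (!all(keep))
    warning("dropping zero-variance variable(s): ",
            paste(panel@variables[!keep], collapse = ", "))
  scl <- data.frame(variable = panel@variables[keep], mu = mu[keep],
                    sigma = sigma[keep], stringsAsFactors = FALSE)
  out <- vals[, , keep, drop = FALSE]
  for (j in seq_len(sum(keep)))
    out[, , j] <- (out[, , j] - scl$mu[j]) / scl$sigma[j]
  panel@values <- out
  panel@variables <- panel@variables[keep]
  panel@mask <- panel@mask[, , keep, drop = FALSE]
  panel@observed <- panel@observed[, , keep, drop = FALSE]
  panel@scaling <- scl
  validObject(panel)
  panel
}

#' Invert the z-score transform
#'
#' @param panel a z-scored [ClinicalPanel-class].
#' @return Panel on the original scale (scaling slot cleared).
#' @export
unscalePanel <- function(panel) {
  stopifnot(is(panel, "ClinicalPanel"), !is.null(panel@scaling))
  vals <- panel@values
  for (j in seq_len(nrow(panel@scaling)))
    vals[, , j] <- vals[, , j] * panel@scaling$sigma[j] + panel@scaling$mu[j]
  panel@values <- vals
  panel@scaling <- NULL
  panel
}

#' Assemble fixed-grid sequences for the embedding model
#'
#' Maps each participant to a T x V array on the regular visit grid
#' `seq(0, horizonMonths, spacingMonths)`. Participants whose genuinely
#' observed history (frozen `observed` slot) spans less than
#' `minHistoryMonths` are excluded, mirroring the minimum one-year
#' follow-up requirement.
#'
#' @param panel z-scored, fully imputed [ClinicalPanel-class].
#' @param horizonMonths last grid time (months), default 60.
#' @param spacingMonths grid spacing (months), default 12.
#' @param minHistoryMonths minimum observed follow-up, default 12.
#' @return A [SequenceSet-class].
#' @export
assembleSequences <- function(panel, horizonMonths = 60,
                              spacingMonths = 12, minHistoryMonths = 12) {
  stopifnot(is(panel, "ClinicalPanel"))
  if (!all(panel@mask)) stop("panel must be fully imputed")
  grid <- seq(0, horizonMonths, by = spacingMonths)
  sel <- match(grid, panel@visits)
  if (anyNA(sel))
    stop("panel visits do not cover the requested grid: ",
         paste(grid[is.na(sel)], collapse = ", "))
  obsAny <- apply(panel@observed, c(1, 2), any)
  lastObs <- apply(obsAny, 1, function(r)
    if (any(r)) max(panel@visits[r]) else -Inf)
  keep <- lastObs >= minHistoryMonths
  if (!any(keep)) stop("no participants retained")
  dat <- panel@values[keep, sel, , drop = FALSE]
  dimnames(dat) <- list(panel@participants[keep], grid, panel@variables)
  new("SequenceSet", data = dat,
      participants = panel@participants[keep],
      times = as.numeric(grid), variables = panel@variables,
      excluded = panel@participants[!keep])
}

#' Run the full preprocessing pipeline
#'
#' LOCF/NOCB imputation, population-median fill, z-scoring and grid
#' assembly in one call, returning the sequence set plus a report.
#'
#' @inheritParams assembleSequences
#' @return list with `sequences` (a [SequenceSet-class]), `panel` (the
#'   processed panel) and `report` (dropped variables, exclusion counts,
#'   scaling table).
#' @export
preprocessPanel <- function(panel, horizonMonths = 60,
                            spacingMonths = 12, minHistoryMonths = 12) {
  varsIn <- panel@variables
  p <- imputeLocfNocb(panel)
  p <- imputePopulationMedian(p)
  p <- withCallingHandlers(zscorePanel(p),
                           warning = function(w) invokeRestart("muffleWarning"))
  seqs <- assembleSequences(p, horizonMonths, spacingMonths,
                            minHistoryMonths)
  list(sequences = seqs, panel = p,
       report = list(droppedVariables = setdiff(varsIn, p@variables),
                     nExcluded = length(seqs@excluded),
                     nRetained = length(seqs@participants),
                     scaling = p@scaling))
}
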