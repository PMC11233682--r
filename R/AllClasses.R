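#' @import methods
#' @importFrom stats median sd var quantile rnorm runif rbinom rexp
#'   rpois setNames phyper p.adjust aov anova chisq.test TukeyHSD t.test
#'   lm coef confint vcov as.formula pnorm qnorm binom.test as.dist
#'   hclust cutree dist prcomp predict glm.fit binomial plogis qlogis
#' @importFrom utils head tail read.delim write.table combn
NULL

setClassUnion("DataFrameOrNULL", c("data.frame", "NULL"))
setOldClass(c("dppeConfig", "list"))

#' ClinicalPanel: a longitudinal clinical data cube
#'
#' Holds a participants x visits x variables array of clinical
#' measurements together with an observation mask. `mask` tracks which
#' cells currently hold a value (observed or imputed); `observed` is
#' frozen at construction and records which cells were genuinely
#' measured, so downstream eligibility rules (e.g. the minimum follow-up
#' requirement) can be applied after imputation.
#'
#' @slot participants character vector of participant identifiers.
#' @slot visits numeric vector of visit times in months from baseline,
#'   strictly increasing.
#' @slot variables character vector of variable names.
#' @slot values 3-d numeric array, participants x visits x variables.
#' @slot mask logical array of the same shape; TRUE where `values` holds
#'   a usable number.
#' @slot observed logical array of the same shape, frozen at
#'   construction: TRUE where the value was measured rather than imputed.
#' @slot scaling data.frame with columns `variable`, `mu`, `sigma` once
#'   the panel has been z-scored, otherwise NULL.
#' @export
setClass("ClinicalPanel",
  representation(
    participants = "character",
    visits       = "numeric",
    variables    = "character",
    values       = "array",
    mask         = "array",
    observed     = "array",
    scaling      = "DataFrameOrNULL"
  )
)

setValidity("ClinicalPanel", function(object) {
  d <- dim(object@values)
  msg <- character(0)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-d array")
  else {
    if (d[1] != length(object@participants))
      msg <- c(msg, "dim 1 of values must match participants")
    if (d[2] != length(object@visits))
      msg <- c(msg, "dim 2 of values must match visits")
    if (d[3] != length(object@variables))
      msg <- c(msg, "dim 3 of values must match variables")
    if (!identical(dim(object@mask), d))
      msg <- c(msg, "mask must have the same shape as values")
    if (!identical(dim(object@observed), d))
      msg <- c(msg, "observed must have the same shape as values")
    if (any(!is.finite(object@values[object@mask])))
      msg <- c(msg, "values must be finite wherever mask is TRUE")
  }
  if (length(object@visits) > 1 && any(diff(object@visits) <= 0))
    msg <- c(msg, "visits must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' SequenceSet: fixed-grid multivariate sequences ready for embedding
#'
#' @slot data 3-d array, participants x time points x variables, fully
#'   observed (no NA).
#' @slot participants character participant ids (one per row of `data`).
#' @slot times numeric grid times in months.
#' @slot variables character variable names.
#' @slot excluded character ids of participants dropped by the
#'   minimum-history rule.
#' @export
setClass("SequenceSet",
  representation(
    data = "array", participants = "character",
    times = "numeric", variables = "character", excluded = "character"
  )
)

setValidity("SequenceSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array")
  if (d[1] != length(object@participants))
    return("dim 1 must match participants")
  if (d[2] != length(object@times)) return("dim 2 must match times")
  if (d[3] != length(object@variables))
    return("dim 3 must match variables")
  if (anyNA(object@data)) return("data must contain no NA")
  TRUE
})

#' DppeModel: LSTM sequence-autoencoder for progression embedding
#'
#' The deep phenotypic progression embedding model: an LSTM encoder whose
#' final hidden state is the embedding, and a mirror LSTM decoder that
#' reconstructs the input sequence from the embedding repeated at every
#' time step.
#'
#' @slot params named list of weight matrices/vectors.
#' @slot config named list (see [dppeConfig()]).
#' @slot lossHistory numeric per-epoch mean training loss (empty before
#'   training).
#' @slot trained logical.
#' @export
setClass("DppeModel",
  representation(params = "list", config = "list",
                 lossHistory = "numeric", trained = "logical")
)

#' SubtypeAssignment: clustering result on progression embeddings
#'
#' @slot participants character ids.
#' @slot labels integer cluster labels in 1..k.
#' @slot k integer chosen cluster count.
#' @slot merge matrix, hclust-style merge history.
#' @slot height numeric merge heights (non-decreasing under Ward).
#' @slot subtypeNames optional character names per cluster (pace order).
#' @export
setClass("SubtypeAssignment",
  representation(participants = "character", labels = "integer",
                 k = "integer", merge = "matrix", height = "numeric",
                 subtypeNames = "character")
)

setValidity("SubtypeAssignment", function(object) {
  if (length(object@labels) != length(object@participants))
    return("labels must match participants")
  if (any(object@labels < 1L | object@labels > object@k))
    return("labels must lie in 1..k")
  TRUE
})

#' GeneNetwork: cleaned protein-protein interactome
#'
#' An undirected interactome restricted to its largest connected
#' component, with self-loops and duplicate edges removed.
#'
#' @slot graph igraph object.
#' @slot genes character gene identifiers (vertex order).
#' @slot degree integer degrees, named by gene.
#' @slot N integer gene count of the largest connected component.
#' @export
setClass("GeneNetwork",
  representation(graph = "ANY", genes = "character",
                 degree = "integer", N = "integer")
)

setValidity("GeneNetwork", function(object) {
  if (object@N != length(object@genes))
    return("N must equal the number of genes")
  if (any(object@degree < 1L))
    return("all retained genes must have degree >= 1")
  TRUE
})

#' GeneModule: a scored, connected gene set grown on the interactome
#'
#' @slot genes character genes in the module.
#' @slot score numeric module score S(M).
#' @slot seedGene character seed the growth started from ("" for
#'   assembled/genetic modules).
#' @slot trace data.frame growth trace (gene added, score after, P(i)).
#' @export
setClass("GeneModule",
  representation(genes = "character", score = "numeric",
                 seedGene = "character", trace = "DataFrameOrNULL")
)

#' EmulatedTrialSet: one emulated trial (matched treated/control sets)
#'
#' @slot treated character treated patient ids.
#' @slot controls character matched control ids (same length, pairwise).
#' @slot propensity numeric propensity scores named by patient id.
#' @slot smd numeric absolute standardized mean difference per covariate
#'   (post-match).
#' @slot smdPre numeric pre-match SMDs.
#' @slot balanced logical: unbalanced fraction <= the threshold?
#' @export
setClass("EmulatedTrialSet",
  representation(treated = "character", controls = "character",
                 propensity = "numeric", smd = "numeric",
                 smdPre = "numeric", balanced = "logical")
)

setValidity("EmulatedTrialSet", function(object) {
  if (length(object@treated) != length(object@controls))
    return("matched controls must equal treated in number")
  if (anyDuplicated(object@controls))
    return("no control may be reused within a trial")
  TRUE
})

#' HazardEstimate: summary treatment-effect estimate across trials
#'
#' @slot drug character tested drug.
#' @slot outcome character outcome label.
#' @slot hrs numeric per-trial hazard ratios (balanced trials only).
#' @slot medianHR numeric.
#' @slot ciLow,ciHigh numeric bootstrap 95% CI bounds.
#' @slot p numeric sign-test p for median HR != 1.
#' @slot nBalanced integer balanced trial count.
#' @export
setClass("HazardEstimate",
  representation(drug = "character", outcome = "character",
                 hrs = "numeric", medianHR = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 p = "numeric", nBalanced = "integer")
)

setValidity("HazardEstimate", function(object) {
  if (length(object@hrs) && any(object@hrs <= 0))
    return("hazard ratios must be positive")
  if (length(object@medianHR) == 1L && length(object@ciLow) == 1L &&
      (object@ciLow > object@medianHR || object@medianHR > object@ciHigh))
    return("CI must bracket the median HR")
  TRUE
})
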