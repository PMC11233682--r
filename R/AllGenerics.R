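#' @include AllClasses.R
NULL

#' Accessors for pacenet classes
#'
#' Small accessor generics: `participants()`, `visitMonths()`,
#' `panelValues()`, `panelMask()`, `variableNames()`, `moduleGenes()`,
#' `moduleScore()` (on a GeneModule), `networkGenes()`, `subtypeLabels()`.
#'
#' @param object a pacenet S4 object.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("participants", function(object) standardGeneric("participants"))
#' @rdname accessors
#' @export
setGeneric("visitMonths", function(object) standardGeneric("visitMonths"))
#' @rdname accessors
#' @export
setGeneric("panelValues", function(object) standardGeneric("panelValues"))
#' @rdname accessors
#' @export
setGeneric("panelMask", function(object) standardGeneric("panelMask"))
#' @rdname accessors
#' @export
setGeneric("variableNames", function(object) standardGeneric("variableNames"))
#' @rdname accessors
#' @export
setGeneric("networkGenes", function(object) standardGeneric("networkGenes"))
#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(object) standardGeneric("moduleGenes"))
#' @rdname accessors
#' @export
setGeneric("subtypeLabels", function(object) standardGeneric("subtypeLabels"))

#' @rdname accessors
setMethod("participants", "ClinicalPanel", function(object) object@participants)
#' @rdname accessors
setMethod("participants", "SequenceSet", function(object) object@participants)
#' @rdname accessors
setMethod("participants", "SubtypeAssignment", function(object) object@participants)
#' @rdname accessors
setMethod("visitMonths", "ClinicalPanel", function(object) object@visits)
#' @rdname accessors
setMethod("panelValues", "ClinicalPanel", function(object) object@values)
#' @rdname accessors
setMethod("panelMask", "ClinicalPanel", function(object) object@mask)
#' @rdname accessors
setMethod("variableNames", "ClinicalPanel", function(object) object@variables)
#' @rdname accessors
setMethod("variableNames", "SequenceSet", function(object) object@variables)
#' @rdname accessors
setMethod("networkGenes", "GeneNetwork", function(object) object@genes)
#' @rdname accessors
setMethod("moduleGenes", "GeneModule", function(object) object@genes)
#' @rdname accessors
setMethod("subtypeLabels", "SubtypeAssignment", function(object) {
  setNames(object@labels, object@participants)
})

setMethod("show", "ClinicalPanel", function(object) {
  d <- dim(object@values)
  cat("ClinicalPanel:", d[1], "participants x", d[2], "visits x",
      d[3], "variables\n")
  cat("  observed cells:",
      sprintf("%.1f%%", 100 * mean(object@observed)), "\n")
  cat("  imputed:", if (all(object@mask)) "complete" else "incomplete",
      "| z-scored:", if (is.null(object@scaling)) "no" else "yes", "\n")
})

setMethod("show", "SequenceSet", function(object) {
  d <- dim(object@data)
  cat("SequenceSet:", d[1], "participants x", d[2], "time points x",
      d[3], "variables (", length(object@excluded), "excluded )\n")
})

setMethod("show", "DppeModel", function(object) {
  cfg <- object@config
  cat("DppeModel (LSTM autoencoder):", cfg$input_dim, "vars ->",
      cfg$embedding_dim, "dim embedding;",
      if (object@trained) sprintf("trained, final loss %.4g",
                                  tail(object@lossHistory, 1))
      else "untrained", "\n")
})

setMethod("show", "SubtypeAssignment", function(object) {
  cat("SubtypeAssignment: k =", object@k, "over",
      length(object@participants), "participants\n")
  print(table(cluster = object@labels))
  if (length(object@subtypeNames))
    cat("  pace naming:", paste(object@subtypeNames, collapse = " < "), "\n")
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", object@N, "genes,",
      igraph::ecount(object@graph), "edges (largest component)\n")
})

setMethod("show", "GeneModule", function(object) {
  cat("GeneModule:", length(object@genes), "genes, S(M) =",
      format(object@score, digits = 4),
      if (nzchar(object@seedGene)) paste("(seed", object@seedGene, ")")
      else "", "\n")
})

setMethod("show", "EmulatedTrialSet", function(object) {
  cat("EmulatedTrialSet:", length(object@treated), "matched pairs;",
      sum(object@smd > 0.2), "covariates unbalanced;",
      if (object@balanced) "balanced" else "NOT balanced", "\n")
})

setMethod("show", "HazardEstimate", function(object) {
  cat(sprintf("HazardEstimate [%s -> %s]: median HR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d balanced trials\n",
              object@drug, object@outcome, object@medianHR,
              object@ciLow, object@ciHigh, object@p, object@nBalanced))
})
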