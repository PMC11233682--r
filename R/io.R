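#' @include AllClasses.R utils.R
NULL

#' Write / read a clinical panel as a long-format TSV
#'
#' Columns: participant_id, visit_month, variable, value. Only cells
#' currently masked observed are written.
#'
#' @param panel a [ClinicalPanel-class].
#' @param path TSV file path.
#' @return `writePanelTsv`: the path, invisibly. `readPanelTsv`: a
#'   [ClinicalPanel-class].
#' @export
writePanelTsv <- function(panel, path) {
  idx <- which(panel@mask, arr.ind = TRUE)
  df <- data.frame(
    participant_id = panel@participants[idx[, 1]],
    visit_month = panel@visits[idx[, 2]],
    variable = panel@variables[idx[, 3]],
    value = panel@values[idx])
  df <- df[order(df$participant_id, df$visit_month, df$variable), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePanelTsv
#' @param path TSV file path.
#' @export
readPanelTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "visit_month", "variable", "value")
  if (!all(need %in% names(df)))
    stop("panel TSV must have columns: ", paste(need, collapse = ", "))
  ids <- sort(unique(df$participant_id))
  visits <- sort(unique(df$visit_month))
  vars <- sort(unique(df$variable))
  vals <- array(NA_real_, dim = c(length(ids), length(visits),
                                  length(vars)),
                dimnames = list(ids, visits, vars))
  vals[cbind(match(df$participant_id, ids),
             match(df$visit_month, visits),
             match(df$variable, vars))] <- df$value
  clinicalPanel(vals)
}

#' Write gene modules in GMT format
#'
#' One line per module: name, description, then the gene ids.
#'
#' @param modules named list of [GeneModule-class] objects (or
#'   character vectors).
#' @param path output file.
#' @param descriptions optional character descriptions per module.
#' @return the path, invisibly.
#' @export
writeGmt <- function(modules, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(modules))
  lines <- vapply(seq_along(modules), function(i) {
    g <- modules[[i]]
    if (is(g, "GeneModule")) g <- moduleGenes(g)
    paste(c(names(modules)[i], descriptions[i], g), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file
#' @param path GMT file.
#' @return named list of character gene vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) p[-(1:2)])
  names(out) <- vapply(parts, `[`, character(1), 1)
  out
}

#' Write an edge list / results table as TSV
#' @param df data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
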