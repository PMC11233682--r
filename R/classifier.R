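#' @include AllClasses.R utils.R
NULL

#' Assemble the prognostic feature blocks
#'
#' Joins demographics, raw imaging (ROI atrophy), variant carrier flags
#' and baseline + year-1 clinical values by participant, keeping only
#' participants present in every block. The imaging block is kept raw
#' here; [cascadeFitEvaluate()] reduces it to principal components
#' inside each training fold so no test-fold information leaks into the
#' rotation.
#'
#' @param clinical data.frame keyed by `participant_id` with baseline /
#'   year-1 clinical columns.
#' @param imaging data.frame keyed by `participant_id` with ROI
#'   columns.
#' @param genotypes 0/1 matrix, rownames = participant ids.
#' @param demographics data.frame keyed by `participant_id`.
#' @param labels named integer subtype per participant.
#' @return list with `blocks` (named list of numeric matrices, common
#'   row order), `labels` (integer vector), `ids`, and `nDropped`.
#' @export
buildFeatureMatrix <- function(clinical, imaging, genotypes,
                               demographics, labels) {
  ids <- Reduce(intersect, list(clinical$participant_id,
                                imaging$participant_id,
                                rownames(genotypes),
                                demographics$participant_id,
                                names(labels)))
  if (!length(ids)) stop("no participants present in all blocks")
  asMat <- function(df) {
    m <- as.matrix(df[match(ids, df$participant_id),
                      setdiff(names(df), "participant_id"), drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
    m
  }
  blocks <- list(clinical = asMat(clinical), imaging = asMat(imaging),
                 genotypes = {
                   g <- genotypes[ids, , drop = FALSE]
                   storage.mode(g) <- "double"; g
                 },
                 demographics = asMat(demographics))
  nDropped <- length(labels) - length(ids)
  list(blocks = blocks, labels = unname(labels[ids]), ids = ids,
       nDropped = nDropped)
}

pcaReduce <- function(trainX, testX, nComp = 10) {
  nComp <- min(nComp, ncol(trainX), nrow(trainX) - 1L)
  pc <- prcomp(trainX, center = TRUE, scale. = FALSE)
  list(train = pc$x[, seq_len(nComp), drop = FALSE],
       test = predict(pc, testX)[, seq_len(nComp), drop = FALSE])
}

#' Cascade random-forest classification of pace subtypes
#'
#' Two-stage cascade evaluated by stratified k-fold cross-validation:
#' stage 1 separates the rapid subtype from the rest; stage 2, trained
#' only on non-rapid participants, separates the remaining two
#' subtypes. The imaging block is reduced to `nComp` principal
#' components fit on each training fold. Reports the AUC per stage as
#' mean and SD across folds.
#'
#' @param features result of [buildFeatureMatrix()].
#' @param rapidClass integer label of the rapid subtype.
#' @param nFolds folds, default 5.
#' @param nTrees random-forest trees, default 500.
#' @param nComp imaging principal components, default 10.
#' @param seed integer seed (fold splits and forests).
#' @return list: aucStage1/aucStage2 (mean), sdStage1/sdStage2,
#'   perFold (data.frame).
#' @export
cascadeFitEvaluate <- function(features, rapidClass, nFolds = 5,
                               nTrees = 500, nComp = 10, seed = 1L) {
  labels <- features$labels
  if (length(unique(labels)) < 3)
    stop("need at least 3 classes for the cascade")
  fold <- stratifiedFolds(labels, nFolds, childSeed(seed, 0L))
  a1 <- a2 <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    tr <- fold != f; te <- !tr
    img <- pcaReduce(features$blocks$imaging[tr, , drop = FALSE],
                     features$blocks$imaging[te, , drop = FALSE], nComp)
    join <- function(rows, pcs) cbind(
      features$blocks$clinical[rows, , drop = FALSE],
      pcs,
      features$blocks$genotypes[rows, , drop = FALSE],
      features$blocks$demographics[rows, , drop = FALSE])
    Xtr <- join(tr, img$train); Xte <- join(te, img$test)
    y1tr <- factor(labels[tr] == rapidClass)
    set.seed(childSeed(seed, f))
    rf1 <- randomForest::randomForest(Xtr, y1tr, ntree = nTrees)
    p1 <- predict(rf1, Xte, type = "prob")[, "TRUE"]
    a1[f] <- aucScore(p1, labels[te] == rapidClass)
    sub <- labels[tr] != rapidClass
    y2tr <- factor(labels[tr][sub])
    rf2 <- randomForest::randomForest(Xtr[sub, , drop = FALSE], y2tr,
                                      ntree = nTrees)
    teSub <- labels[te] != rapidClass
    pos <- levels(y2tr)[2]
    p2 <- predict(rf2, Xte[teSub, , drop = FALSE],
                  type = "prob")[, pos]
    a2[f] <- aucScore(p2, labels[te][teSub] == as.integer(pos))
  }
  list(aucStage1 = mean(a1), aucStage2 = mean(a2),
       sdStage1 = sd(a1), sdStage2 = sd(a2),
       perFold = data.frame(fold = seq_len(nFolds), aucStage1 = a1,
                            aucStage2 = a2))
}
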