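#' @include AllClasses.R utils.R stats.R
NULL

#' Drug-treatment amplitude
#'
#' alpha = (t - c) / ((t + c) / 2), where t is the (scaled, thresholded)
#' average expression under drug treatment and c under control.
#' alpha > 0 means elevated expression after treatment. Records with
#' t + c = 0 are undefined and returned as NA with a warning.
#'
#' @param t,c numeric vectors (recycled).
#' @return numeric amplitudes; antisymmetric in (t, c).
#' @export
amplitude <- function(t, c) {
  out <- (t - c) / ((t + c) / 2)
  bad <- (t + c) == 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with t + c = 0 dropped (undefined amplitude)")
    out[bad] <- NA_real_
  }
  out
}

#' Per-drug gene ranking from an amplitude matrix
#'
#' Ranks genes in ascending amplitude per drug: rank 1 = the gene most
#' down-regulated by the drug. Disease-up genes near rank 1 are being
#' suppressed, so a positive enrichment score means signature reversal.
#'
#' @param signatures drugs x genes amplitude matrix.
#' @return integer matrix of the same shape: rank of each gene within
#'   its drug profile.
#' @export
drugGeneRanks <- function(signatures) {
  t(apply(signatures, 1, rank, ties.method = "first"))
}

esOneSide <- function(ranks, r) {
  # ranks: profile ranks of the gene set, any order
  s <- length(ranks)
  V <- sort(ranks)
  j <- seq_len(s)
  a <- max(j / s - V / r)
  b <- max(V / r - (j - 1) / s)
  if (a > b) a else -b
}

#' Signature-reversal enrichment score of one drug
#'
#' Kolmogorov-Smirnov style statistic of where the disease module's
#' up- and down-regulated genes fall in the drug's expression ranking:
#' for each direction, with s genes present among the r profiled genes
#' and V(j) their ascending profile ranks, a = max_j(j/s - V(j)/r) and
#' b = max_j(V(j)/r - (j-1)/s); the directional score is a if a > b,
#' else -b. ES = ES_up - ES_down when the two have opposite signs, and
#' 0 otherwise. Genes absent from the profile are excluded and counted.
#'
#' @param drugRanking named integer vector: profile rank per gene for
#'   one drug (1 = most down-regulated), e.g. one row of
#'   [drugGeneRanks()].
#' @param upGenes,downGenes disjoint character gene sets.
#' @return list: es, esUp, esDown, nUp, nDown, nMissing.
#' @export
enrichmentScore <- function(drugRanking, upGenes, downGenes) {
  if (length(intersect(upGenes, downGenes)))
    stop("up and down gene sets must be disjoint")
  r <- length(drugRanking)
  up <- drugRanking[intersect(upGenes, names(drugRanking))]
  dn <- drugRanking[intersect(downGenes, names(drugRanking))]
  nMissing <- length(setdiff(c(upGenes, downGenes), names(drugRanking)))
  if (!length(up) || !length(dn))
    return(list(es = NA_real_, esUp = NA_real_, esDown = NA_real_,
                nUp = length(up), nDown = length(dn),
                nMissing = nMissing))
  esUp <- esOneSide(up, r)
  esDown <- esOneSide(dn, r)
  es <- if (sign(esUp) != sign(esDown)) esUp - esDown else 0
  list(es = es, esUp = esUp, esDown = esDown,
       nUp = length(up), nDown = length(dn), nMissing = nMissing)
}

#' Permutation significance of an enrichment score
#'
#' Recomputes ES for `nPerm` random gene lists of the same up/down
#' sizes drawn from the profiled genes. p = (1 + #\{ES_perm >=
#' ES_obs\}) / (1 + nPerm); the normalized ES is (ES_obs - mean_perm) /
#' sd_perm.
#'
#' @param drugRanking named rank vector for one drug.
#' @param upGenes,downGenes the observed gene sets.
#' @param nPerm permutation count, default 100.
#' @param seed integer seed.
#' @return list: es, p, nes, permMean, permSd.
#' @export
permutationSignificance <- function(drugRanking, upGenes, downGenes,
                                    nPerm = 100, seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  obs <- enrichmentScore(drugRanking, upGenes, downGenes)
  if (is.na(obs$es))
    return(list(es = NA_real_, p = NA_real_, nes = NA_real_,
                permMean = NA_real_, permSd = NA_real_))
  set.seed(seed)
  genes <- names(drugRanking)
  r <- length(genes)
  sUp <- obs$nUp; sDn <- obs$nDown
  perm <- vapply(seq_len(nPerm), function(i) {
    pick <- sample.int(r, sUp + sDn)
    u <- drugRanking[pick[seq_len(sUp)]]
    d <- drugRanking[pick[sUp + seq_len(sDn)]]
    eu <- esOneSide(u, r); ed <- esOneSide(d, r)
    if (sign(eu) != sign(ed)) eu - ed else 0
  }, numeric(1))
  p <- (1 + sum(perm >= obs$es)) / (1 + nPerm)
  sdP <- sd(perm)
  nes <- if (is.na(sdP) || sdP == 0) NA_real_ else
    (obs$es - mean(perm)) / sdP
  list(es = obs$es, p = p, nes = nes,
       permMean = mean(perm), permSd = sdP)
}

#' Screen a signature matrix for reversal of a disease module
#'
#' Computes ES, permutation p and normalized ES for every drug against
#' the module's up/down gene sets.
#'
#' @param signatures drugs x genes amplitude matrix.
#' @param upGenes,downGenes disease-module genes up-/down-regulated in
#'   the subtype.
#' @param nPerm permutations per drug.
#' @param seed master seed (per-drug seeds derived from it).
#' @return data.frame: drug, es, esUp, esDown, nes, p.
#' @export
screenDrugs <- function(signatures, upGenes, downGenes, nPerm = 100,
                        seed = 1L) {
  ranks <- drugGeneRanks(signatures)
  out <- lapply(seq_len(nrow(ranks)), function(i) {
    rk <- setNames(ranks[i, ], colnames(ranks))
    es <- enrichmentScore(rk, upGenes, downGenes)
    ps <- permutationSignificance(rk, upGenes, downGenes, nPerm,
                                  seed = childSeed(seed, i))
    data.frame(drug = rownames(signatures)[i], es = es$es,
               esUp = es$esUp, esDown = es$esDown, nes = ps$nes,
               p = ps$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prioritize drug candidates
#'
#' BH-adjusts the permutation p-values across drugs, selects drugs with
#' normalized ES above `esThreshold` and q below `qThreshold` (the raw
#' ES is bounded in \[-2, 2\], so the selection cutoff applies to the
#' permutation-normalized score), and ranks the selection by normalized
#' ES descending.
#'
#' @param results data.frame from [screenDrugs()].
#' @param esThreshold normalized-ES cutoff, default 3.
#' @param qThreshold BH q cutoff, default 0.05.
#' @return `results` with added `q` and `selected` columns, selected
#'   rows first (by decreasing nes).
#' @export
prioritizeDrugs <- function(results, esThreshold = 3, qThreshold = 0.05) {
  if (!nrow(results)) stop("empty results")
  results$q <- NA_real_
  ok <- !is.na(results$p)
  results$q[ok] <- adjustFdr(results$p[ok])
  results$selected <- !is.na(results$nes) & !is.na(results$q) &
    results$nes > esThreshold & results$q < qThreshold
  results[order(-results$selected, -pmin(results$nes, Inf),
                na.last = TRUE), , drop = FALSE]
}
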