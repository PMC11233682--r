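#' @include AllClasses.R utils.R
NULL

#' Agglomerative hierarchical clustering of progression embeddings
#'
#' Ward-linkage agglomeration on Euclidean distances (Lance-Williams
#' update, `ward.D2`), cut at `k` clusters. Deterministic; permuting
#' the input order yields the same partition up to label renaming.
#'
#' @param embeddings numeric matrix, participants x dims (rownames =
#'   ids).
#' @param k number of clusters (2 <= k <= n).
#' @return A [SubtypeAssignment-class].
#' @export
hierarchicalCluster <- function(embeddings, k) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  hc <- hclust(dist(embeddings), method = "ward.D2")
  labels <- cutree(hc, k = k)
  ids <- rownames(embeddings)
  if (is.null(ids)) ids <- sprintf("obs%04d", seq_len(n))
  new("SubtypeAssignment", participants = ids,
      labels = as.integer(labels), k = as.integer(k),
      merge = hc$merge, height = hc$height, subtypeNames = character(0))
}

withinSS <- function(X, labels) {
  tot <- 0
  for (cl in unique(labels)) {
    xs <- X[labels == cl, , drop = FALSE]
    ctr <- colMeans(xs)
    tot <- tot + sum(sweep(xs, 2, ctr)^2)
  }
  tot
}

silhouetteMean <- function(D, labels) {
  n <- length(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    nOwn <- sum(own) - 1L
    a <- if (nOwn == 0L) 0 else sum(D[i, own]) / nOwn
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (nOwn == 0L) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

daviesBouldin <- function(X, labels) {
  cls <- sort(unique(labels))
  ctr <- t(vapply(cls, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  S <- vapply(seq_along(cls), function(j) {
    xs <- X[labels == cls[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, ctr[j, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(ctr))
  mean(vapply(seq_along(cls), function(i) {
    r <- (S[i] + S[-i]) / M[i, -i]
    max(r[is.finite(r)])
  }, numeric(1)))
}

dunnIndex <- function(D, labels) {
  cls <- sort(unique(labels))
  minBetween <- Inf; maxDiam <- 0
  for (a in seq_along(cls)) {
    ia <- labels == cls[a]
    da <- D[ia, ia, drop = FALSE]
    if (sum(ia) > 1) maxDiam <- max(maxDiam, max(da))
    for (b in seq_along(cls)) if (b > a) {
      ib <- labels == cls[b]
      minBetween <- min(minBetween, min(D[ia, ib, drop = FALSE]))
    }
  }
  if (maxDiam == 0) return(Inf)
  minBetween / maxDiam
}

ratkowskyIndex <- function(X, labels) {
  k <- length(unique(labels))
  grand <- colMeans(X)
  bg <- numeric(ncol(X)); ts <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    ts[j] <- sum((X[, j] - grand[j])^2)
    for (cl in unique(labels)) {
      sel <- labels == cl
      bg[j] <- bg[j] + sum(sel) * (mean(X[sel, j]) - grand[j])^2
    }
  }
  mean(sqrt(bg / pmax(ts, .Machine$double.eps))) / sqrt(k)
}

ptBiserialMcClain <- function(D, labels) {
  dv <- D[lower.tri(D)]
  same <- outer(labels, labels, "==")[lower.tri(D)]
  sw <- dv[same]; sb <- dv[!same]
  pb <- if (sd(dv) == 0) 0 else
    (mean(sb) - mean(sw)) * sqrt(length(sw) * length(sb)) /
      length(dv) / sd(dv)
  list(ptbiserial = pb, mcclain = mean(sw) / mean(sb))
}

#' Cluster-validity index panel over candidate cluster numbers
#'
#' Computes eight validity indices for Ward partitions at each k in
#' `kRange` and derives each index's recommended k under its own
#' optimum rule: Silhouette, Dunn, Ratkowsky and PtBiserial (maximum),
#' Davies-Bouldin and McClain (minimum), Ball (maximum successive
#' drop) and TraceW (maximum second difference, elbow).
#'
#' @param embeddings numeric matrix participants x dims.
#' @param kRange integer candidate cluster numbers (within \[2, n-1\]).
#' @return list with `values` (data.frame index x k) and
#'   `recommended` (named integer per index).
#' @export
clusterValidityIndices <- function(embeddings, kRange = 2:6) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (any(kRange < 2) || any(kRange > n - 1))
    stop("kRange must lie within [2, n-1]")
  kRange <- sort(unique(as.integer(kRange)))
  D <- as.matrix(dist(X))
  hc <- hclust(as.dist(D), method = "ward.D2")
  cuts <- lapply(kRange, function(k) cutree(hc, k = k))
  names(cuts) <- kRange
  W <- vapply(cuts, function(l) withinSS(X, l), numeric(1))

  vals <- data.frame(k = kRange)
  for (nm in c("silhouette", "db", "dunn", "ball", "ratkowsky",
               "ptbiserial", "mcclain", "tracew"))
    vals[[nm]] <- NA_real_
  for (r in seq_along(kRange)) {
    k <- kRange[r]
    l <- cuts[[as.character(k)]]
    vals$silhouette[r] <- silhouetteMean(D, l)
    vals$db[r] <- daviesBouldin(X, l)
    vals$dunn[r] <- dunnIndex(D, l)
    vals$ball[r] <- W[as.character(k)] / k
    vals$ratkowsky[r] <- ratkowskyIndex(X, l)
    pm <- ptBiserialMcClain(D, l)
    vals$ptbiserial[r] <- pm$ptbiserial
    vals$mcclain[r] <- pm$mcclain
    vals$tracew[r] <- W[as.character(k)]
  }

  rec <- c(
    silhouette = kRange[which.max(vals$silhouette)],
    db = kRange[which.min(vals$db)],
    dunn = kRange[which.max(vals$dunn)],
    ratkowsky = kRange[which.max(vals$ratkowsky)],
    ptbiserial = kRange[which.max(vals$ptbiserial)],
    mcclain = kRange[which.min(vals$mcclain)])
  # Ball: largest drop between successive hierarchy levels, differenced
  # within the scanned range only (so the recommendation lies in
  # kmin+1..kmax)
  ball <- vals$ball
  if (length(kRange) >= 2) {
    drops <- ball[-length(ball)] - ball[-1]
    rec["ball"] <- kRange[-1][which.max(drops)]
  } else rec["ball"] <- kRange[1]
  # TraceW elbow: largest second difference of W within the range
  if (length(kRange) >= 3) {
    sec <- diff(vals$tracew, differences = 2)   # W[k-1]-2W[k]+W[k+1]
    rec["tracew"] <- kRange[-c(1, length(kRange))][which.max(sec)]
  } else rec["tracew"] <- kRange[1]
  list(values = vals, recommended = rec)
}

#' Select the cluster number by majority vote
#'
#' The chosen k is the mode of the per-index recommendations; ties are
#' broken toward the smaller k.
#'
#' @param indexPanel result of [clusterValidityIndices()].
#' @return list with `k` (integer) and `votes` (table of all votes).
#' @export
selectClusterNumber <- function(indexPanel) {
  rec <- indexPanel$recommended
  if (!length(rec)) stop("empty index panel")
  tab <- table(rec)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), votes = tab)
}

#' Largest relative gap in Ward merge heights
#'
#' Operationalizes "clusters clearly separated in the dendrogram": the
#' number of clusters just before the largest relative jump between
#' successive merge heights. Reported for inspection, not used by
#' [selectClusterNumber()].
#'
#' @param assignment a [SubtypeAssignment-class].
#' @return list with `k` and `gapRatio`.
#' @export
dendrogramGap <- function(assignment) {
  h <- assignment@height
  n <- length(h) + 1L
  ratios <- h[-1] / pmax(h[-length(h)], .Machine$double.eps)
  j <- which.max(ratios)            # merge j+1 starts the big jump
  list(k = n - j, gapRatio = ratios[j])
}

#' 2-D t-SNE projection for visual inspection
#'
#' Exact (O(n^2)) t-distributed stochastic neighbor embedding with
#' per-point perplexity calibration, gradient descent with momentum and
#' early exaggeration. For visualization only; never used for
#' clustering.
#'
#' @param embeddings numeric matrix participants x dims (n >= 5).
#' @param seed integer seed.
#' @param perplexity target perplexity (capped at (n-1)/3).
#' @param maxIter gradient-descent iterations.
#' @return n x 2 coordinate matrix with the input rownames.
#' @export
projectTsne <- function(embeddings, seed = 1L, perplexity = 30,
                        maxIter = 400) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 points")
  perplexity <- min(perplexity, (n - 1) / 3)
  set.seed(seed)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n)
  dY <- matrix(0, n, 2)
  momentum <- 0.5
  exag <- 4
  for (iter in seq_len(maxIter)) {
    Pe <- if (iter <= 100) P * exag else P
    sq <- as.matrix(dist(Y))^2
    Qn <- 1 / (1 + sq); diag(Qn) <- 0
    Z <- sum(Qn)
    grad <- matrix(0, n, 2)
    Wg <- (Pe - Qn / Z) * Qn
    grad <- 4 * (diag(rowSums(Wg)) %*% Y - Wg %*% Y)
    if (iter == 250) momentum <- 0.8
    dY <- momentum * dY - 100 * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Name clusters by progression pace
#'
#' Orders clusters by the mean per-participant OLS slope of a reference
#' clinical variable and names them from slowest to fastest
#' progression: for k = 3 the names are PD-I (inching), PD-M
#' (moderate), PD-R (rapid); otherwise pace1..paceK.
#'
#' @param assignment a [SubtypeAssignment-class].
#' @param panel the (imputed) [ClinicalPanel-class] the embeddings came
#'   from.
#' @param variable reference variable name (e.g. the motor score).
#' @return The assignment with `subtypeNames` filled (names ordered by
#'   cluster label) and an attribute-free mapping available via
#'   `subtypeLabels()`.
#' @export
nameSubtypesByPace <- function(assignment, panel, variable) {
  v <- match(variable, panel@variables)
  if (is.na(v)) stop("unknown variable: ", variable)
  idx <- match(assignment@participants, panel@participants)
  tY <- panel@visits / 12
  slopes <- vapply(idx, function(i) {
    y <- panel@values[i, , v]
    ok <- panel@mask[i, , v] & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    coef(lm(y[ok] ~ tY[ok]))[2]
  }, numeric(1))
  ms <- vapply(seq_len(assignment@k), function(cl)
    mean(slopes[assignment@labels == cl], na.rm = TRUE), numeric(1))
  ord <- order(ms)                 # slowest first
  nms <- if (assignment@k == 3) c("PD-I", "PD-M", "PD-R")
         else sprintf("pace%d", seq_len(assignment@k))
  out <- character(assignment@k)
  out[ord] <- nms
  assignment@subtypeNames <- out
  assignment
}
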