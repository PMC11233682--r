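# shared fixtures, all generated in code

tinyPanel <- function(vals) {
  # vals: participants x visits x variables array (dimnames optional)
  if (is.null(dimnames(vals)))
    dimnames(vals) <- list(sprintf("P%02d", seq_len(dim(vals)[1])),
                           (seq_len(dim(vals)[2]) - 1) * 12,
                           sprintf("v%02d", seq_len(dim(vals)[3])))
  clinicalPanel(vals)
}

smallCohort <- function(seed = 1L, nPer = 30) {
  simulateCohort(cohortSpec(nPerSubtype = rep(nPer, 3), seed = seed))
}

# independent brute-force hypergeometric upper tail by term summation
bruteHyperTail <- function(N, K, n, k) {
  d <- k:min(K, n)
  sum(choose(K, d) * choose(N - K, n - d)) / choose(N, n)
}

# independent running-sum implementation of the directional KS score
bruteEsSide <- function(ranks, r) {
  s <- length(ranks)
  inSet <- logical(r); inSet[ranks] <- TRUE
  cnt <- 0; a <- -Inf; b <- -Inf
  for (x in seq_len(r)) {
    if (inSet[x]) {
      b <- max(b, x / r - cnt / s)
      cnt <- cnt + 1
      a <- max(a, cnt / s - x / r)
    }
  }
  if (a > b) a else -b
}

bruteEs <- function(ranking, up, dn) {
  r <- length(ranking)
  eu <- bruteEsSide(unname(ranking[intersect(up, names(ranking))]), r)
  ed <- bruteEsSide(unname(ranking[intersect(dn, names(ranking))]), r)
  if (sign(eu) != sign(ed)) eu - ed else 0
}

# exhaustive greedy Ward agglomeration oracle on tiny n: at each step
# merge the pair of clusters whose union minimally increases total
# within-cluster sum of squares
bruteWard <- function(X, k) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  ess <- function(idx) {
    xs <- X[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }
  while (length(clusters) > k) {
    best <- NULL; bestCost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      cost <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (cost < bestCost) { bestCost <- cost; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(nrow(X))
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

samePartition <- function(a, b) ariIndex(a, b) == 1

mkFeatures <- function(n = 240, sep = 1, seed = 40) {
  set.seed(seed)
  labels <- setNames(rep(1:3, each = n / 3), sprintf("S%04d", 1:n))
  ids <- names(labels)
  clin <- data.frame(participant_id = ids,
                     base = rnorm(n, sep * labels),
                     year1 = rnorm(n, sep * labels^1.5))
  img <- data.frame(participant_id = ids)
  for (r in pacenet:::dkRoiNames) img[[r]] <- rnorm(n, 0.4 * sep * labels)
  gen <- matrix(rbinom(n * 15, 1, 0.3), n,
                dimnames = list(ids, sprintf("rs%02d", 1:15)))
  demo <- data.frame(participant_id = ids, age = rnorm(n, 65),
                     sex = rbinom(n, 1, 0.5))
  buildFeatureMatrix(clin, img, gen, demo, labels)
}
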