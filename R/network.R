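#' @include AllClasses.R utils.R
NULL

#' Build a cleaned gene network from an edge list
#'
#' Removes self-loops and duplicate edges, restricts to the largest
#' connected component, and computes degrees.
#'
#' @param edgeList data.frame whose first two columns are gene ids.
#' @return A [GeneNetwork-class].
#' @export
buildNetwork <- function(edgeList) {
  if (!nrow(edgeList)) stop("empty edge list")
  g <- igraph::graph_from_data_frame(edgeList[, 1:2], directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  if (igraph::vcount(g) == 0) stop("network empty after cleaning")
  genes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  new("GeneNetwork", graph = g, genes = genes,
      degree = setNames(as.integer(deg), genes),
      N = as.integer(igraph::vcount(g)))
}

#' Initialize gene scores from a differential-expression table
#'
#' DEGs passing the gate (adjusted p <= `qThreshold`) get
#' z(i) = |log2FC|; all other network genes get 0.
#'
#' @param network a [GeneNetwork-class].
#' @param degTable data.frame with columns `gene`, `log2fc`, `padj`.
#' @param qThreshold DEG gate, default 0.05.
#' @return named nonnegative numeric vector over all network genes.
#' @export
initGeneScores <- function(network, degTable, qThreshold = 0.05) {
  z <- setNames(numeric(network@N), network@genes)
  hit <- degTable$padj <= qThreshold & degTable$gene %in% network@genes
  z[degTable$gene[hit]] <- abs(degTable$log2fc[hit])
  z
}

#' Random-walk-with-restart score smoothing
#'
#' Iterates p <- (1 - gamma) W p + gamma p0 with W the column-normalized
#' adjacency matrix and p0 the initial scores normalized to sum 1,
#' until the max change is below `tol`. The output is rescaled to
#' preserve the total score mass of the input.
#'
#' @param network a [GeneNetwork-class].
#' @param scores named nonnegative scores over the network genes.
#' @param restartProb restart probability gamma in (0, 1\], default 0.5.
#' @param tol convergence tolerance on the max absolute change.
#' @param maxIter iteration cap.
#' @return named smoothed scores with the same total mass.
#' @export
rwrSmooth <- function(network, scores, restartProb = 0.5, tol = 1e-10,
                      maxIter = 10000) {
  if (restartProb <= 0 || restartProb > 1)
    stop("restartProb must lie in (0, 1]")
  scores <- scores[network@genes]
  total <- sum(scores)
  if (total <= 0) stop("scores must have positive total mass")
  A <- igraph::as_adjacency_matrix(network@graph, sparse = TRUE)
  W <- A %*% Matrix::Diagonal(x = 1 / Matrix::colSums(A))
  p0 <- scores / total
  p <- p0
  for (it in seq_len(maxIter)) {
    pNew <- (1 - restartProb) * as.vector(W %*% p) + restartProb * p0
    delta <- max(abs(pNew - p))
    p <- pNew
    if (delta < tol)
      return(setNames(as.vector(p) * total, network@genes))
  }
  stop("RWR did not converge in ", maxIter,
       " iterations (residual ", format(delta), ")")
}

#' Hypergeometric connectivity p-value of a candidate gene
#'
#' P(i) = sum over d from d_n to d_i of
#' C(m, d) C(N - m, d_i - d) / C(N, d_i): the probability that a gene
#' of degree d_i has at least d_n of its links inside the size-m module
#' by chance. Computed via the exact hypergeometric upper tail.
#'
#' @param N network gene count.
#' @param m module size (before adding the candidate).
#' @param di candidate degree.
#' @param dn candidate links into the module.
#' @return P(i) in \[0, 1\].
#' @export
connectivityPvalue <- function(N, m, di, dn) {
  if (any(dn > di)) stop("dn cannot exceed di")
  phyper(dn - 1, m, N - m, di, lower.tail = FALSE)
}

#' Module-level gene score
#'
#' S(M) = sum over j in M of (z(j) - omega) / sqrt(|M|), where omega is
#' the mean score over all network genes.
#'
#' @param scores named gene scores over the whole network.
#' @param module character gene set.
#' @param omega network mean score; computed from `scores` if missing.
#' @return numeric S(M).
#' @export
geneModuleScore <- function(scores, module, omega = mean(scores)) {
  if (!length(module)) stop("module must be nonempty")
  sum(scores[module] - omega) / sqrt(length(module))
}

#' Grow one module from a seed gene
#'
#' Starting from M = \{seed\}, repeatedly considers the genes adjacent
#' to M; among candidates whose connectivity p-value P(i) is at most
#' `pThreshold` and whose inclusion strictly increases S(M), adds the
#' one maximizing S(M union i) (ties broken by lexicographic gene id).
#' Stops when no candidate qualifies.
#'
#' @param network a [GeneNetwork-class].
#' @param scores named (smoothed) gene scores.
#' @param seedGene gene to start from.
#' @param pThreshold connectivity gate, default 0.01.
#' @param maxSize safety cap on module size.
#' @return A [GeneModule-class] with a growth trace.
#' @export
growModule <- function(network, scores, seedGene, pThreshold = 0.01,
                       maxSize = 500) {
  if (!seedGene %in% network@genes) stop("seed gene not in network")
  scores <- scores[network@genes]
  omega <- mean(scores)
  N <- network@N
  adj <- igraph::adjacent_vertices(network@graph,
                                   igraph::V(network@graph))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- network@genes
  inMod <- setNames(logical(N), network@genes)
  dn <- setNames(integer(N), network@genes)
  module <- seedGene
  inMod[seedGene] <- TRUE
  for (nb in adj[[seedGene]]) dn[nb] <- dn[nb] + 1L
  zSum <- scores[[seedGene]]
  S <- (zSum - omega) / 1
  trace <- list(data.frame(gene = seedGene, score = S, p = NA_real_,
                           stringsAsFactors = FALSE))
  while (length(module) < maxSize) {
    cand <- names(dn)[dn > 0L & !inMod]
    if (!length(cand)) break
    m <- length(module)
    pv <- connectivityPvalue(N, m, network@degree[cand], dn[cand])
    cand <- cand[pv <= pThreshold]
    pv <- pv[pv <= pThreshold]
    if (!length(cand)) break
    sNew <- (zSum + scores[cand] - omega * (m + 1)) / sqrt(m + 1)
    gain <- sNew > S
    if (!any(gain)) break
    cand <- cand[gain]; sNew <- sNew[gain]; pv <- pv[gain]
    best <- order(-sNew, cand)[1]
    gBest <- cand[best]
    module <- c(module, gBest)
    inMod[gBest] <- TRUE
    zSum <- zSum + scores[[gBest]]
    S <- sNew[best]
    for (nb in adj[[gBest]]) dn[nb] <- dn[nb] + 1L
    trace[[length(trace) + 1L]] <- data.frame(gene = gBest, score = S,
                                              p = unname(pv[best]),
                                              stringsAsFactors = FALSE)
  }
  new("GeneModule", genes = module, score = unname(S),
      seedGene = seedGene, trace = do.call(rbind, trace))
}

#' Assemble a final module from many seeded growths
#'
#' Runs [growModule()] from `nRestarts` random seed genes (seeded RNG),
#' deduplicates identical modules, ranks unique modules by S(M)
#' descending, and returns the union of the top-ranked modules: those
#' whose score is at least `scoreFraction` of the best raw-module
#' score. A relative-score cutoff adapts the union breadth to how
#' concentrated the score landscape is (one dominant module, or many
#' overlapping high-score fragments), which a fixed count cannot.
#'
#' @param network a [GeneNetwork-class].
#' @param scores named (smoothed) gene scores.
#' @param nRestarts number of seeded growths, default 1000.
#' @param scoreFraction union every unique raw module scoring at least
#'   this fraction of the top score, default 0.4.
#' @param pThreshold connectivity gate passed to [growModule()].
#' @param seed integer RNG seed for the seed-gene draws.
#' @param seedPool optional character vector restricting seed genes
#'   (default: genes with positive score, falling back to all genes).
#' @return A [GeneModule-class] (trace = ranked raw-module table).
#' @export
assembleModules <- function(network, scores, nRestarts = 1000,
                            scoreFraction = 0.4,
                            pThreshold = 0.01, seed = 1L,
                            seedPool = NULL) {
  if (nRestarts < 1) stop("nRestarts must be >= 1")
  set.seed(seed)
  if (is.null(seedPool)) {
    seedPool <- names(scores)[scores > 0]
    if (!length(seedPool)) seedPool <- network@genes
  }
  seeds <- sample(seedPool, nRestarts, replace = TRUE)
  mods <- lapply(seeds, function(s)
    growModule(network, scores, s, pThreshold))
  keys <- vapply(mods, function(m) paste(sort(m@genes), collapse = "|"),
                 character(1))
  uniq <- mods[!duplicated(keys)]
  sc <- vapply(uniq, function(m) m@score, numeric(1))
  ord <- order(-sc)
  thr <- if (max(sc) > 0) scoreFraction * max(sc) else max(sc)
  top <- uniq[sc >= thr]
  genes <- sort(unique(unlist(lapply(top, function(m) m@genes))))
  rank <- data.frame(rank = seq_along(ord),
                     score = sc[ord],
                     size = vapply(uniq[ord], function(m)
                       length(m@genes), integer(1)))
  new("GeneModule", genes = genes,
      score = geneModuleScore(scores, genes), seedGene = "",
      trace = rank)
}

#' Build a genetic molecular module via contextual-gene linkage
#'
#' Keeps the genetic associated genes that have at least one interactome
#' edge to a contextual gene; the module is those kept genes plus their
#' contextual neighbors. Genes absent from the network are logged.
#'
#' @param network a [GeneNetwork-class].
#' @param geneticGenes character genetic associated genes.
#' @param contextualGenes character contextual genes.
#' @return A [GeneModule-class] (possibly empty, with a warning).
#' @export
buildGeneticModule <- function(network, geneticGenes, contextualGenes) {
  gIn <- intersect(geneticGenes, network@genes)
  cIn <- intersect(contextualGenes, network@genes)
  unmapped <- setdiff(c(geneticGenes, contextualGenes), network@genes)
  if (length(unmapped))
    message(length(unmapped), " gene(s) not in the network were skipped")
  kept <- character(0); partners <- character(0)
  ctxSet <- setdiff(cIn, gIn)
  for (g in gIn) {
    nb <- igraph::neighbors(network@graph, g)$name
    link <- intersect(nb, ctxSet)
    if (length(link)) {
      kept <- c(kept, g)
      partners <- union(partners, link)
    }
  }
  genes <- sort(union(kept, partners))
  if (!length(genes)) {
    warning("no genetic gene links to any contextual gene; empty module")
    return(new("GeneModule", genes = character(0), score = 0,
               seedGene = "", trace = NULL))
  }
  new("GeneModule", genes = genes, score = NA_real_, seedGene = "",
      trace = data.frame(gene = kept, role = "genetic",
                         stringsAsFactors = FALSE))
}
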