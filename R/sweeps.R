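## Detection of positively selected subclones: greedy breadth-first search
## from the root over clades of at least minCladeSize leaves, scoring each
## clade's internal SFS with Fay & Wu's H against a constant-size neutral
## null matched to the clade's leaf count and segregating sites. Descent
## stops at the first significant clade (greedy pruning), so reported
## subclones are never nested. The per-clade threshold is calibrated on
## neutral simulations to a 1% lineage-level false discovery rate.

#' Shipped per-clade significance threshold
#'
#' Calibrated once with [calibrateAlpha()] on neutrally simulated lineages at
#' the default configuration (1,000-leaf Kingman genealogies, theta = 10,
#' minCladeSize = 50, 2,000-replicate per-clade nulls) so that the fraction
#' of neutral lineages with at least one detection is at most the 1% target
#' false discovery rate. See the methods vignette.
#'
#' @return A single number.
#' @export
defaultPerCladeAlpha <- function() 5e-4

#' Sweep-detection configuration
#'
#' @param minCladeSize smallest clade (leaves) tested; default 50, which
#'   keeps the per-clade H null nondegenerate.
#' @param perCladeAlpha per-clade significance threshold; default the shipped
#'   calibrated value [defaultPerCladeAlpha()].
#' @param nullModel neutral null for clade scoring (\code{"kingman"}).
#' @param replicates per-clade null replicates (default 2,000, the smallest
#'   count at which the calibrated threshold is achievable; the
#'   lineage-level FDR is controlled by calibration, not per-clade
#'   precision).
#' @param targetFdr lineage-level false-discovery target used by
#'   [calibrateAlpha()] (default 0.01).
#' @return A list of class \code{sweep_config}.
#' @export
sweepConfig <- function(minCladeSize = 50,
                        perCladeAlpha = defaultPerCladeAlpha(),
                        nullModel = "kingman", replicates = 2000,
                        targetFdr = 0.01) {
  if (perCladeAlpha <= 0 || perCladeAlpha >= 1)
    stop("perCladeAlpha must be in (0, 1)")
  if (minCladeSize < 10) stop("minCladeSize must be >= 10")
  structure(list(minCladeSize = as.integer(minCladeSize),
                 perCladeAlpha = perCladeAlpha,
                 nullModel = match.arg(nullModel, "kingman"),
                 replicates = as.integer(replicates),
                 targetFdr = targetFdr),
            class = "sweep_config")
}

## children list and clade bookkeeping for a rooted phylo
.treeIndex <- function(phy) {
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  edgeOfChild <- integer(length(phy$tip.label) + phy$Nnode)
  edgeOfChild[phy$edge[, 2L]] <- seq_len(nrow(phy$edge))
  list(kids = kids, edgeOfChild = edgeOfChild,
       leafCount = .subtreeLeafCounts(phy))
}

## edge rows strictly inside the subtree rooted at node (stem edge excluded)
.subtreeEdges <- function(idx, node) {
  nmax <- length(idx$edgeOfChild)
  out <- integer(nmax)
  stack <- integer(nmax)
  ch0 <- idx$kids[[as.character(node)]]
  stack[seq_along(ch0)] <- ch0
  sp <- length(ch0)
  no <- 0L
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    no <- no + 1L
    out[no] <- idx$edgeOfChild[v]
    ch <- idx$kids[[as.character(v)]]
    if (!is.null(ch)) {
      stack[sp + seq_along(ch)] <- ch
      sp <- sp + length(ch)
    }
  }
  out[seq_len(no)]
}

## H, H* and S of the SFS restricted to the clade below `node`: derived
## counts are subtree leaf counts of internal edges; mutations on the stem
## are clade-fixed and excluded
.cladeH <- function(phy, idx, node) {
  ed <- .subtreeEdges(idx, node)
  sub <- idx$leafCount[phy$edge[ed, 2L]]
  counts <- phy$mut_counts[ed]
  n <- idx$leafCount[node]
  seg <- sub < n & counts > 0L
  S <- sum(counts[seg])
  i <- sub[seg]
  C2 <- choose(n, 2)
  tp <- sum(counts[seg] * i * (n - i)) / C2
  th <- sum(counts[seg] * i^2) / C2
  list(n = n, S = S, H = tp - th,
       hstar = if (tp + th == 0) 0 else (tp - th) / (tp + th))
}

#' Detect positively selected subclones in a lineage phylogeny
#'
#' Breadth-first search from the root's children: each visited clade with at
#' least \code{minCladeSize} leaves is scored by Fay & Wu's H of its
#' clade-restricted SFS against a fixed-S Kingman null matched to the clade
#' leaf count; a clade with empirical p below the per-clade threshold is
#' flagged selected and its descendants are not visited, otherwise its
#' children are enqueued. The whole-lineage test at the root is the job of
#' [testSelection()], so the search starts below the root.
#'
#' @param genealogy rooted \code{phylo} carrying per-branch mutation counts
#'   (\code{mut_counts} from [dropMutations()] or
#'   [mapMutationsToBranches()]). A \code{"germline"} outgroup leaf, if
#'   present, is ignored for clade sizes.
#' @param config a [sweepConfig()].
#' @param collectP also return, for every clade of sufficient size reachable
#'   ignoring pruning, its p-value (used by [calibrateAlpha()]; default
#'   FALSE).
#' @return data.frame of visited clades: \code{node, clade_size, S, H, p,
#'   selected}. Selected clades are mutually non-nested by construction.
#' @export
detectSelectedSubclones <- function(genealogy, config = sweepConfig(),
                                    collectP = FALSE) {
  phy <- genealogy
  if (!.hasSingleRoot(phy)) stop("genealogy must be rooted")
  if (is.null(phy$mut_counts))
    stop("genealogy carries no mutations; run dropMutations() or ",
         "mapMutationsToBranches() first")
  ntip <- length(phy$tip.label)
  idx <- .treeIndex(phy)
  root <- ntip + 1L
  queue <- idx$kids[[as.character(root)]]
  queue <- queue[queue > ntip & idx$leafCount[queue] >= config$minCladeSize]
  rows <- list()
  while (length(queue)) {
    node <- queue[1L]
    queue <- queue[-1L]
    st <- .cladeH(phy, idx, node)
    if (st$S > 0L) {
      null <- nullDistribution("Hstar", config$nullModel, st$n, st$S,
                               config$replicates)
      p <- empiricalP(st$hstar, null, "lower")
    } else p <- 1
    selected <- p < config$perCladeAlpha
    rows[[length(rows) + 1L]] <- data.frame(
      node = node, clade_size = st$n, S = st$S, H = st$H,
      h_star = st$hstar, p = p, selected = selected)
    if (!selected || collectP) {
      ch <- idx$kids[[as.character(node)]]
      ch <- ch[ch > ntip & idx$leafCount[ch] >= config$minCladeSize]
      queue <- c(queue, ch)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), clade_size = integer(0), S = integer(0),
               H = numeric(0), h_star = numeric(0), p = numeric(0),
               selected = logical(0))
  if (collectP) return(out)
  ## structural invariant: greedy pruning makes selected clades non-nested
  sel <- out$node[out$selected]
  if (length(sel) > 1L) {
    for (v in sel) {
      inside <- phy$edge[.subtreeEdges(idx, v), 2L]
      if (any(sel %in% inside))
        stop("internal error: nested selected subclones")
    }
  }
  out
}

#' Count distinct selected subclones
#'
#' @param calls output of [detectSelectedSubclones()].
#' @return Number of selected (mutually non-nested) clades.
#' @export
countSweeps <- function(calls) sum(calls$selected)

#' Calibrate the per-clade threshold to a lineage-level FDR
#'
#' Simulates neutral (Kingman) lineages with the given sizes, collects every
#' qualifying clade's p-value, and returns the largest grid alpha at which
#' the fraction of neutral lineages with at least one detection is at most
#' \code{config$targetFdr}. Detection under greedy pruning occurs iff any
#' qualifying clade's p falls below alpha, so calibration can grid over
#' alphas from one set of simulations.
#'
#' @param sizeDistribution integer vector of lineage sizes to emulate
#'   (sampled with replacement).
#' @param nLineages neutral lineages to simulate (default 200).
#' @param theta mutation rate for the simulated lineages (default 10).
#' @param config a [sweepConfig()]; \code{targetFdr}, \code{minCladeSize} and
#'   \code{replicates} are honored.
#' @param alphaGrid candidate thresholds, decreasing order not required.
#' @return The calibrated alpha (attribute \code{fdr_hat}: the realized
#'   fraction; attribute \code{minp}: per-lineage minimum p-values). When no
#'   grid value meets the target, the smallest is returned with a warning.
#' @export
calibrateAlpha <- function(sizeDistribution, nLineages = 200, theta = 10,
                           config = sweepConfig(),
                           alphaGrid = c(0.05, 0.02, 0.01, 0.005, 0.002,
                                         0.001, 5e-4)) {
  minp <- vapply(seq_len(nLineages), function(i) {
    n <- sample(sizeDistribution, 1L)
    phy <- dropMutations(simulateKingman(n), theta = theta, mode = "rate")
    calls <- detectSelectedSubclones(phy, config, collectP = TRUE)
    if (nrow(calls)) min(calls$p) else Inf
  }, numeric(1))
  grid <- sort(alphaGrid, decreasing = TRUE)
  for (a in grid) {
    fdr <- mean(minp < a)
    if (fdr <= config$targetFdr) {
      out <- a
      attr(out, "fdr_hat") <- fdr
      attr(out, "minp") <- minp
      return(out)
    }
  }
  warning("no grid alpha met the FDR target; returning the smallest")
  out <- min(alphaGrid)
  attr(out, "fdr_hat") <- mean(minp < out)
  attr(out, "minp") <- minp
  out
}

#' Correlation between sweep count and lineage size
#'
#' @param counts number of selected subclones per lineage.
#' @param sizes lineage sizes (leaves), same order.
#' @return List with \code{r} (Pearson) and \code{p}; both NA with a warning
#'   when either vector has zero variance.
#' @export
sweepSizeCorrelation <- function(counts, sizes) {
  if (length(counts) < 3L) stop("need at least 3 lineages")
  if (stats::sd(counts) == 0 || stats::sd(sizes) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(counts, sizes, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
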