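## Genealogy simulators for the three evolutionary models compared against
## observed lineages: neutral constant-size (Kingman coalescent), neutral
## exponential expansion (time-rescaled Kingman), and continuous adaptation
## (Bolthausen-Sznitman multiple-merger coalescent). Time is in scaled
## coalescent units (N = 1). Mutations follow the infinite-sites model.

.MODEL_CODE <- c(kingman = 0L, expanding = 1L, bsz = 2L)

## convert the C engine output (parent/time over creation-order ids) to an
## ape phylo; internal ids are renumbered so the root is n + 1
.asPhylo <- function(sim, tipLabels = NULL) {
  n <- sim$n
  m <- sim$nInternal
  maxid <- n + m
  parent <- sim$parent + 1L            # 1-based; root's parent is NA
  newid <- function(id) ifelse(id <= n, id, n + (maxid - id) + 1L)
  child <- setdiff(seq_len(maxid), maxid)  # root (creation id maxid) has no edge
  edge <- cbind(newid(parent[child]), newid(child))
  len <- sim$time[parent[child]] - sim$time[child]
  if (is.null(tipLabels)) tipLabels <- paste0("s", seq_len(n))
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = tipLabels, Nnode = m),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a coalescent genealogy
#'
#' \code{simulateKingman}: the standard n-coalescent (with k lineages,
#' pairwise mergers at rate k(k-1)/2, the pair uniform). \code{simulateExpanding}:
#' Kingman time-rescaled for exponential growth, with backward-time merger
#' intensity \eqn{\binom{k}{2} e^{g t}} (population size
#' \eqn{N(t) = N_0 e^{-g t}} looking back), sampled by inverse-CDF time
#' transformation. \code{simulateBSZ}: the Bolthausen-Sznitman multiple-merger
#' coalescent, in which b of k lineages (2 <= b <= k) merge at total rate
#' \eqn{k / (b(b-1))} (overall merger rate k - 1, \eqn{P(b) \propto 1/(b(b-1))}),
#' participants uniform.
#'
#' @param n sample size (leaves), \code{n >= 2}.
#' @param growthRate exponential growth rate g > 0 (expanding model only);
#'   default [defaultGrowthRate()].
#' @param tipLabels optional leaf labels (default \code{s1..sn}).
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   first so the tree is reproducible.
#' @return An \pkg{ape} \code{phylo}, rooted, with branch lengths in
#'   coalescent time units.
#' @export
simulateKingman <- function(n, tipLabels = NULL, seed = NULL) {
  .simulateCoalescent(n, "kingman", 0, tipLabels, seed)
}

#' @rdname simulateKingman
#' @export
simulateExpanding <- function(n, growthRate = defaultGrowthRate(),
                              tipLabels = NULL, seed = NULL) {
  if (growthRate <= 0) stop("growthRate must be > 0")
  .simulateCoalescent(n, "expanding", growthRate, tipLabels, seed)
}

#' @rdname simulateKingman
#' @export
simulateBSZ <- function(n, tipLabels = NULL, seed = NULL) {
  .simulateCoalescent(n, "bsz", 0, tipLabels, seed)
}

.simulateCoalescent <- function(n, model, growthRate, tipLabels = NULL,
                                seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  .asPhylo(.coal_sim_cpp(n, .MODEL_CODE[[model]], growthRate), tipLabels)
}

#' Default growth rate for the expanding-population model
#'
#' The study does not print its expansion parameterization; the shipped
#' default is calibrated once so that the expected singleton fraction of the
#' SFS at n = 100 sits roughly midway between the Kingman and
#' Bolthausen-Sznitman values (see the methods vignette).
#'
#' @return A positive scalar (per-coalescent-time exponential rate).
#' @export
defaultGrowthRate <- function() 25

#' Drop infinite-sites mutations onto a genealogy
#'
#' Under \code{mode = "rate"}, each branch receives a Poisson(theta/2 x
#' length) number of mutations; under \code{mode = "fixed_S"} exactly
#' \code{S} mutations are placed on branches with probability proportional to
#' branch length (the conditioning used for null distributions). Every
#' mutation is a new site carried by all leaves below its branch.
#'
#' @param genealogy a rooted \code{phylo} with branch lengths.
#' @param theta population-scaled mutation rate (> 0; \code{mode = "rate"}).
#' @param mode \code{"rate"} or \code{"fixed_S"}.
#' @param S number of segregating sites for \code{mode = "fixed_S"}.
#' @return The genealogy with two extra elements: \code{mut_counts} (integer
#'   per edge row) and \code{site_edges} (integer vector, one entry per
#'   mutation site giving its edge row).
#' @export
dropMutations <- function(genealogy, theta = NULL,
                          mode = c("rate", "fixed_S"), S = NULL) {
  mode <- match.arg(mode)
  len <- genealogy$edge.length
  if (mode == "rate") {
    if (is.null(theta) || theta <= 0) stop("theta must be > 0")
    counts <- stats::rpois(length(len), theta / 2 * len)
  } else {
    if (is.null(S) || S < 0) stop("S must be a nonnegative count")
    counts <- if (sum(len) > 0)
      as.integer(stats::rmultinom(1L, S, prob = len))
    else integer(length(len)) # zero-length tree: no mutations possible
  }
  genealogy$mut_counts <- as.integer(counts)
  genealogy$site_edges <- rep(seq_along(counts), counts)
  genealogy
}

## subtree leaf count for every node (tips first, then internal nodes)
.subtreeLeafCounts <- function(phy) {
  n <- length(phy$tip.label)
  cnt <- c(rep(1L, n), integer(phy$Nnode))
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge)))
    cnt[po$edge[e, 1L]] <- cnt[po$edge[e, 1L]] + cnt[po$edge[e, 2L]]
  cnt
}

#' Read the site frequency spectrum off a mutated genealogy
#'
#' \eqn{\xi_i} counts the mutations on branches subtending exactly i leaves.
#' Mutations on branches subtending all n leaves (possible only below a
#' unifurcating root) are reported as fixed.
#'
#' @param genealogy a \code{phylo} carrying \code{mut_counts} from
#'   [dropMutations()].
#' @return An [SFS-class].
#' @export
genealogyToSFS <- function(genealogy) {
  if (is.null(genealogy$mut_counts))
    stop("genealogy has no mutations; run dropMutations() first")
  n <- length(genealogy$tip.label)
  cnt <- .subtreeLeafCounts(genealogy)
  sub <- cnt[genealogy$edge[, 2L]]
  xi <- numeric(n - 1L)
  seg <- sub < n
  if (any(seg)) {
    agg <- rowsum(genealogy$mut_counts[seg], group = sub[seg])
    xi[as.integer(rownames(agg))] <- agg[, 1L]
  }
  SFS(n, xi, fixed = sum(genealogy$mut_counts[!seg]))
}

#' Fast fixed-S null site classes
#'
#' Simulates \code{reps} genealogies under a model, places exactly \code{S}
#' mutations on each proportional to branch length, and returns each
#' mutation's derived-allele count. Implemented from per-frequency-class
#' branch-length totals in C, which is distributionally identical to the
#' tree-based route ([dropMutations()] + [genealogyToSFS()]).
#'
#' @param model \code{"kingman"}, \code{"expanding"} or \code{"bsz"}.
#' @param n sample size.
#' @param S segregating sites per replicate.
#' @param reps number of replicates.
#' @param growthRate growth rate for \code{model = "expanding"}.
#' @return Integer matrix (\code{S} x \code{reps}) of derived-allele counts
#'   in 1..n-1.
#' @export
nullSiteClasses <- function(model, n, S, reps,
                            growthRate = defaultGrowthRate()) {
  model <- match.arg(model, names(.MODEL_CODE))
  if (n < 2L) stop("n must be >= 2")
  .coal_null_sites_cpp(as.integer(n), as.integer(S), as.integer(reps),
                       .MODEL_CODE[[model]], growthRate)
}

#' Expected branch-length profile by frequency class
#'
#' Total branch length subtending exactly i leaves, per replicate; the
#' building block of fixed-S conditioning and of model spectra.
#'
#' @inheritParams nullSiteClasses
#' @return Numeric matrix ((n-1) x reps).
#' @export
classLengths <- function(model, n, reps, growthRate = defaultGrowthRate()) {
  model <- match.arg(model, names(.MODEL_CODE))
  .coal_class_lengths_cpp(as.integer(n), as.integer(reps),
                          .MODEL_CODE[[model]], growthRate)
}
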