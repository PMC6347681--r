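## Fay & Wu's H and the SFS-nonmonotonicity statistic, scored against
## simulated coalescent nulls conditioned on the observed number of
## segregating sites (fixed-S) with matched sample size.

#' SFS summary statistics: theta_pi, theta_H and Fay & Wu's H
#'
#' \deqn{\theta_\pi = \sum_i \xi_i \, i(n-i) / \binom{n}{2}, \qquad
#'       \theta_H  = \sum_i \xi_i \, i^2    / \binom{n}{2}, \qquad
#'       H = \theta_\pi - \theta_H.}
#' H is negative when high-frequency derived variants are in excess -- the
#' hitchhiking signature of selective sweeps (unnormalized form; significance
#' is assessed empirically against simulated nulls, never asymptotically).
#'
#' @param sfs an [SFS-class].
#' @return A single number.
#' @export
thetaPi <- function(sfs) {
  n <- sampleSize(sfs)
  i <- seq_len(n - 1L)
  sum(xiCounts(sfs) * i * (n - i)) / choose(n, 2)
}

#' @rdname thetaPi
#' @export
thetaH <- function(sfs) {
  n <- sampleSize(sfs)
  i <- seq_len(n - 1L)
  sum(xiCounts(sfs) * i^2) / choose(n, 2)
}

#' @rdname thetaPi
#' @export
fayWuH <- function(sfs) thetaPi(sfs) - thetaH(sfs)

#' Diversity-normalized Fay & Wu's H
#'
#' \deqn{H^* = (\theta_\pi - \theta_H) / (\theta_\pi + \theta_H) \in [-1, 1].}
#' The raw H statistic scales with the diversity level, so under genealogy
#' nulls conditioned on the number of segregating sites its distribution is
#' dominated by deep-branch fluctuations of the null trees and the test has
#' essentially no power against multiple-merger (adaptive) genealogies.
#' Normalizing by total diversity removes that scale and restores power (see
#' the methods vignette); the sign convention matches H. This is the default
#' test statistic of [testSelection()] and the subclone sweep detector.
#'
#' @param sfs an [SFS-class].
#' @return H* in \[-1, 1\]; 0 for an empty spectrum.
#' @export
fayWuHStar <- function(sfs) {
  tp <- thetaPi(sfs)
  th <- thetaH(sfs)
  if (tp + th == 0) return(0)
  (tp - th) / (tp + th)
}

#' Nonmonotonicity of a binned SFS
#'
#' A neutral spectrum decays with frequency; recurrent sweeps produce a
#' high-frequency uptick. The statistic is the largest increase between
#' adjacent bins of the width-normalized (density) spectrum over the bins
#' lying above \code{minFreq}, rescaled to sum 1 over that range (0 for
#' monotonically nonincreasing spectra, and 0 when no site lies above
#' \code{minFreq}). Restricting to the upper frequency range keeps the
#' singleton-dominated low end -- where neutral and adaptive spectra both
#' concentrate their mass -- from drowning the uptick; dividing by bin width
#' stops wide mid-frequency bins from faking rises under log-spaced edges.
#' This max-uptick form is this package's definition of the statistic.
#'
#' @param sfs an [SFS-class].
#' @param binEdges interior bin edges, as in [binSFS()].
#' @param minFreq only bins entirely above this frequency enter the
#'   statistic (default 0.2).
#' @return Nonnegative number in \[0, 1\]; larger = more nonmonotone.
#' @export
sfsNonmonotonicity <- function(sfs, binEdges = defaultBinEdges(),
                               minFreq = 0.2) {
  mass <- binSFS(sfs, binEdges, normalize = FALSE)
  lower <- c(0, binEdges)
  keep <- lower >= minFreq
  if (sum(keep) < 2L || sum(mass[keep]) == 0) return(0)
  width <- diff(c(0, binEdges, 1))
  dens <- mass[keep] / width[keep]
  dens <- dens / sum(dens)
  max(c(0, diff(dens)))
}

.statFun <- function(statistic, binEdges) {
  if (is.function(statistic)) return(statistic)
  switch(match.arg(statistic, c("H", "Hstar", "nonmonotonicity")),
    H = fayWuH,
    Hstar = fayWuHStar,
    nonmonotonicity = function(s) sfsNonmonotonicity(s, binEdges))
}

#' Null distribution of an SFS statistic under a coalescent model
#'
#' Simulates \code{replicates} genealogies with sample size \code{n} under
#' the model, drops exactly \code{S} mutations on each (fixed-S
#' conditioning), and evaluates the statistic. The default engine computes
#' the site placement from per-frequency-class branch lengths in C (see
#' [nullSiteClasses()]); \code{engine = "tree"} takes the explicit
#' genealogy + mutation-dropping route, and the two are distributionally
#' identical.
#'
#' @param statistic \code{"Hstar"} (the default test statistic, see
#'   [fayWuHStar()]), \code{"H"}, \code{"nonmonotonicity"}, or a function of
#'   an [SFS-class].
#' @param model \code{"kingman"}, \code{"expanding"} or \code{"bsz"}.
#' @param n sample size to match.
#' @param S segregating sites to condition on.
#' @param replicates number of null replicates (>= 100 recommended; the
#'   study's convention is 10,000).
#' @param growthRate growth rate for the expanding model.
#' @param binEdges bin edges for binned statistics.
#' @param engine \code{"lengths"} (fast, default) or \code{"tree"}.
#' @return Sorted numeric vector of \code{replicates} null statistic values.
#' @export
nullDistribution <- function(statistic = "Hstar", model = "kingman", n, S,
                             replicates = 10000,
                             growthRate = defaultGrowthRate(),
                             binEdges = defaultBinEdges(),
                             engine = c("lengths", "tree")) {
  engine <- match.arg(engine)
  model <- match.arg(model, c("kingman", "expanding", "bsz"))
  if (n < 2L) stop("n must be >= 2")
  fn <- .statFun(statistic, binEdges)
  fastH <- !is.function(statistic) &&
    statistic %in% c("H", "Hstar") && engine == "lengths"
  if (S == 0L) return(rep(fn(SFS(n)), replicates))
  if (engine == "lengths") {
    classes <- nullSiteClasses(model, n, S, replicates, growthRate)
    if (fastH) {
      i <- seq_len(n - 1L)
      C2 <- choose(n, 2)
      if (identical(statistic, "H")) {
        w <- (i * (n - i) - i^2) / C2
        vals <- colSums(matrix(w[classes], nrow = S))
      } else {
        tp <- colSums(matrix((i * (n - i) / C2)[classes], nrow = S))
        th <- colSums(matrix((i^2 / C2)[classes], nrow = S))
        vals <- ifelse(tp + th == 0, 0, (tp - th) / (tp + th))
      }
    } else {
      vals <- apply(classes, 2L, function(cl)
        fn(SFS(n, tabulate(cl, nbins = n - 1L))))
    }
  } else {
    simfun <- switch(model,
      kingman = function() simulateKingman(n),
      expanding = function() simulateExpanding(n, growthRate),
      bsz = function() simulateBSZ(n))
    vals <- replicate(replicates, {
      fn(genealogyToSFS(dropMutations(simfun(), mode = "fixed_S", S = S)))
    })
  }
  sort(vals)
}

#' Empirical p-value with add-one correction
#'
#' \code{p = (1 + #(null at or beyond observed)) / (R + 1)}; lower tail for H
#' (sweeps push H negative), upper tail for nonmonotonicity.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistic values.
#' @param tail \code{"lower"} or \code{"upper"}.
#' @return p in \[1/(R+1), 1\].
#' @export
empiricalP <- function(observed, null, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (!length(null)) stop("null distribution is empty")
  hits <- if (tail == "lower") sum(null <= observed) else sum(null >= observed)
  (1 + hits) / (length(null) + 1)
}

#' Signed significance score
#'
#' \code{sign(H) * -log10(p)}: large negative scores flag lineages whose
#' excess of high-frequency derived alleles is unlikely under the null.
#'
#' @param H observed Fay & Wu's H.
#' @param p empirical p-value.
#' @return Signed score (0 when H = 0).
#' @export
significanceScore <- function(H, p) sign(H) * -log10(p)

#' Score selection on one lineage
#'
#' Computes theta_pi, theta_H, Fay & Wu's H, its diversity-normalized form
#' H* (the test statistic) and the nonmonotonicity statistic from a
#' lineage's SFS, then one-sided empirical p-values against the requested
#' null models with matched n and S (H*: lower tail; nonmonotonicity: upper
#' tail).
#'
#' @param x a [Lineage-class] or an [SFS-class].
#' @param nulls models to test against (subset of \code{c("kingman",
#'   "expanding")}).
#' @param replicates null replicates per model (default 10,000; reduce for
#'   interactive use).
#' @param growthRate expanding-model growth rate.
#' @param binEdges bin edges for the nonmonotonicity statistic.
#' @param lineage_id label for the output row (taken from the lineage when
#'   given).
#' @return One-row data.frame: \code{lineage_id, n, S, theta_pi, theta_H, H,
#'   h_star, nonmono}, then per null model \code{p_vs_<model>} (for H*),
#'   \code{p_nonmono_vs_<model>} and \code{score_vs_<model>} (the signed
#'   significance score). Model names in columns: \code{constant} (Kingman)
#'   and \code{expanding}.
#' @export
testSelection <- function(x, nulls = c("kingman", "expanding"),
                          replicates = 10000,
                          growthRate = defaultGrowthRate(),
                          binEdges = defaultBinEdges(),
                          lineage_id = NA_character_) {
  sfs <- if (is(x, "Lineage")) {
    if (is.na(lineage_id)) lineage_id <- lineageId(x)
    buildSFS(x)
  } else x
  stopifnot(is(sfs, "SFS"))
  n <- sampleSize(sfs)
  S <- segSites(sfs)
  H <- fayWuH(sfs)
  hs <- fayWuHStar(sfs)
  nm <- sfsNonmonotonicity(sfs, binEdges)
  out <- data.frame(lineage_id = lineage_id, n = n, S = S,
                    theta_pi = thetaPi(sfs), theta_H = thetaH(sfs),
                    H = H, h_star = hs, nonmono = nm, stringsAsFactors = FALSE)
  for (model in nulls) {
    tag <- if (model == "kingman") "constant" else model
    nullH <- nullDistribution("Hstar", model, n, S, replicates, growthRate)
    nullNm <- nullDistribution("nonmonotonicity", model, n, S, replicates,
                               growthRate, binEdges)
    pH <- empiricalP(hs, nullH, "lower")
    out[[paste0("p_vs_", tag)]] <- pH
    out[[paste0("p_nonmono_vs_", tag)]] <- empiricalP(nm, nullNm, "upper")
    out[[paste0("score_vs_", tag)]] <- significanceScore(hs, pH)
  }
  out
}
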