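## Somatic mutation calling against the personalized germline and site
## frequency spectra. Mutations are called on germline V and J positions
## only; CDR3 polymorphisms are excluded because the ancestral state of the
## junction is not known with confidence. Multiple derived bases at one
## position are independent sites (infinite-sites reading); indels ignored.

#' Call somatic point mutations for every lineage member
#'
#' Compares each aligned member to the germline at callable positions
#' (germline-covered V and J, excluding CDR3). N bases on either side are
#' ignored. Members covering fewer than half of the callable positions with
#' non-N bases are excluded.
#'
#' @param lineage a [Lineage-class].
#' @param alignment optional precomputed [alignToGermline()] result.
#' @param minCoverage minimum fraction of callable positions with a non-N
#'   base (default 0.5).
#' @return data.frame with one row per mismatch: \code{sequence_id,
#'   position} (0-based germline axis), \code{germline_base, derived_base,
#'   region}; attribute \code{"n"} gives the number of members screened
#'   (included), attribute \code{"excluded"} the dropped ids.
#' @export
callSomaticMutations <- function(lineage, alignment = NULL,
                                 minCoverage = 0.5) {
  if (is.null(alignment)) alignment <- alignToGermline(lineage)
  mat <- alignment$matrix
  call_idx <- which(alignment$callable)
  germ <- mat["germline", call_idx]
  memberIds <- setdiff(rownames(mat), "germline")
  cov <- vapply(memberIds, function(id)
    mean(mat[id, call_idx] != "N"), numeric(1))
  excluded <- memberIds[cov < minCoverage]
  kept <- setdiff(memberIds, excluded)
  if (length(excluded))
    warning(length(excluded), " member(s) excluded: < ", minCoverage * 100,
            "% coverage of callable germline positions")
  rows <- lapply(kept, function(id) {
    s <- mat[id, call_idx]
    mm <- which(s != germ & s != "N" & germ != "N")
    if (!length(mm)) return(NULL)
    data.frame(sequence_id = id,
               position = alignment$coords[call_idx[mm]],
               germline_base = unname(germ[mm]), derived_base = unname(s[mm]),
               region = alignment$regions[call_idx[mm]],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(0), position = integer(0),
               germline_base = character(0), derived_base = character(0),
               region = character(0), stringsAsFactors = FALSE)
  attr(out, "n") <- length(kept)
  attr(out, "excluded") <- excluded
  out
}

#' Build the site frequency spectrum of a lineage
#'
#' Each segregating site is a (position, derived base) pair; its derived
#' count i is the number of unique member sequences carrying it. Sites
#' carried by all n members are fixed differences, recorded in the SFS's
#' \code{fixed} slot rather than in \eqn{\xi}.
#'
#' @inheritParams callSomaticMutations
#' @param mutations optional precomputed [callSomaticMutations()] table.
#' @return An [SFS-class]; the site table is attached as attribute
#'   \code{"sites"} (\code{position, derived_base, count, frequency,
#'   region}).
#' @export
buildSFS <- function(lineage, alignment = NULL, mutations = NULL) {
  if (is.null(mutations))
    mutations <- callSomaticMutations(lineage, alignment)
  n <- attr(mutations, "n")
  if (is.null(n)) stop("mutation table lacks the 'n' attribute")
  if (n < 2L) stop("SFS undefined for fewer than 2 member sequences")
  if (!nrow(mutations)) {
    sfs <- SFS(n)
    attr(sfs, "sites") <- data.frame(position = integer(0),
                                     derived_base = character(0),
                                     count = integer(0), frequency = numeric(0),
                                     region = character(0),
                                     stringsAsFactors = FALSE)
    return(sfs)
  }
  key <- paste(mutations$position, mutations$derived_base, sep = ":")
  counts <- table(key)
  first <- mutations[!duplicated(key), , drop = FALSE]
  ord <- order(first$position, first$derived_base)
  first <- first[ord, , drop = FALSE]
  cnt <- as.integer(counts[paste(first$position, first$derived_base,
                                 sep = ":")])
  xi <- numeric(n - 1L)
  seg <- cnt < n
  tab <- tabulate(cnt[seg], nbins = n - 1L)
  xi[seq_along(tab)] <- tab
  sfs <- SFS(n, xi, fixed = sum(!seg))
  attr(sfs, "sites") <- data.frame(
    position = first$position, derived_base = first$derived_base,
    count = cnt, frequency = cnt / n, region = first$region,
    stringsAsFactors = FALSE)
  sfs
}

#' Default frequency bin edges
#'
#' Log-spaced interior edges over (0, 1) with a terminal (0.99, 1) bin, so
#' high-frequency mass (the sweep signature) is resolved.
#'
#' @return Increasing numeric vector of interior edges.
#' @export
defaultBinEdges <- function()
  c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 0.75, 0.9, 0.99)

#' Bin a site frequency spectrum
#'
#' Assigns the mass \eqn{\xi_i} to frequency bins by i/n. Interior edges
#' \code{e1 < ... < ek} define bins (0, e1], (e1, e2], ..., (ek, 1).
#'
#' @param sfs an [SFS-class].
#' @param binEdges increasing interior edges in (0, 1).
#' @param normalize divide by S so the bins sum to 1 (default TRUE; an empty
#'   spectrum returns all zeros with attribute \code{empty = TRUE}).
#' @return Numeric vector of bin masses, names giving the bin intervals.
#' @export
binSFS <- function(sfs, binEdges = defaultBinEdges(), normalize = TRUE) {
  stopifnot(is(sfs, "SFS"))
  if (is.unsorted(binEdges, strictly = TRUE) ||
      any(binEdges <= 0) || any(binEdges >= 1))
    stop("binEdges must be strictly increasing within (0, 1)")
  n <- sampleSize(sfs)
  freq <- seq_len(n - 1L) / n
  ## bin index: number of edges strictly below the frequency (left-open bins)
  idx <- vapply(freq, function(f) sum(binEdges < f) + 1L, integer(1))
  nb <- length(binEdges) + 1L
  mass <- vapply(seq_len(nb), function(b) sum(xiCounts(sfs)[idx == b]),
                 numeric(1))
  names(mass) <- paste0("(", c(0, binEdges), ",", c(binEdges, 1),
                        c(rep("]", nb - 1L), ")"))
  S <- sum(mass)
  if (normalize) {
    if (S == 0) {
      attr(mass, "empty") <- TRUE
      return(mass)
    }
    mass <- mass / S
  }
  mass
}

#' Average binned spectra across lineages
#'
#' Each lineage's SFS is binned and normalized to sum 1, then averaged
#' without weighting; the SEM per bin is sd/sqrt(k) across the k lineages
#' contributing a nonempty spectrum.
#'
#' @param sfsList list of [SFS-class] objects (>= 2).
#' @param binEdges interior bin edges, as in [binSFS()].
#' @return List with \code{mean}, \code{sem} (numeric per bin) and \code{k}
#'   (spectra averaged).
#' @export
averageSFS <- function(sfsList, binEdges = defaultBinEdges()) {
  if (length(sfsList) < 2L) stop("need at least 2 lineages to average")
  binned <- lapply(sfsList, binSFS, binEdges = binEdges)
  keep <- !vapply(binned, function(b) isTRUE(attr(b, "empty")), logical(1))
  mat <- do.call(rbind, binned[keep])
  k <- nrow(mat)
  list(mean = colMeans(mat),
       sem = apply(mat, 2L, stats::sd) / sqrt(k),
       k = k)
}

#' Model-averaged spectrum
#'
#' Simulates \code{reps} lineages under a coalescent model (rate-mode
#' mutations at \code{theta}), builds each SFS off the genealogy, and
#' averages the binned spectra -- the simulated curves observed lineage
#' spectra are compared against.
#'
#' @inheritParams nullSiteClasses
#' @param theta population-scaled mutation rate.
#' @param binEdges interior bin edges.
#' @return As [averageSFS()].
#' @export
modelAverageSpectrum <- function(model, n, theta, reps = 100,
                                 binEdges = defaultBinEdges(),
                                 growthRate = defaultGrowthRate()) {
  model <- match.arg(model, c("kingman", "expanding", "bsz"))
  simfun <- switch(model,
    kingman = function() simulateKingman(n),
    expanding = function() simulateExpanding(n, growthRate),
    bsz = function() simulateBSZ(n))
  sfss <- replicate(reps, {
    genealogyToSFS(dropMutations(simfun(), theta = theta, mode = "rate"))
  }, simplify = FALSE)
  averageSFS(sfss, binEdges)
}
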