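#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib repevol, .registration = TRUE
NULL

VALID_REGIONS <- c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3", "FWR4")
VALID_ISOTYPES <- c("IgM", "IgD", "IgG", "IgA", "IgE", "unknown")

#' GermlineReference: personalized germline V/J coordinate system
#'
#' Holds the germline V and J gene sequences for one (V, J) pair together
#' with a per-position region annotation (FWR1..FWR3 plus an optional CDR3
#' tail on V; an optional CDR3 head plus FWR4 on J) and the reading frame of
#' position 0. All coordinates in the package are 0-based, half-open, on the
#' germline axis \code{V ++ CDR3-junction ++ J}; junction positions between
#' the annotated V and J segments belong to CDR3 and are excluded from
#' somatic mutation calling because their ancestral state is not known.
#'
#' @slot vGene,jGene germline gene labels.
#' @slot vSeq,jSeq germline nucleotide sequences (A/C/G/T).
#' @slot vRegions,jRegions character vectors of region labels, one per
#'   position of \code{vSeq}/\code{jSeq}.
#' @slot readingFrame integer in 0:2, codon offset of V position 0.
#' @exportClass GermlineReference
setClass("GermlineReference",
  representation(
    vGene = "character", jGene = "character",
    vSeq = "character", jSeq = "character",
    vRegions = "character", jRegions = "character",
    readingFrame = "integer"
  )
)

setValidity("GermlineReference", function(object) {
  msg <- character(0)
  if (nchar(object@vSeq) != length(object@vRegions))
    msg <- c(msg, "vRegions must annotate every position of vSeq")
  if (nchar(object@jSeq) != length(object@jRegions))
    msg <- c(msg, "jRegions must annotate every position of jSeq")
  if (!all(object@vRegions %in% VALID_REGIONS) ||
      !all(object@jRegions %in% VALID_REGIONS))
    msg <- c(msg, "region labels must be FWR1..FWR4 / CDR1..CDR3")
  ## regions must tile contiguously in IMGT order
  vord <- match(rle(object@vRegions)$values, VALID_REGIONS)
  jord <- match(rle(object@jRegions)$values, VALID_REGIONS)
  if (is.unsorted(vord, strictly = TRUE) || is.unsorted(jord, strictly = TRUE))
    msg <- c(msg, "regions must tile contiguously in order FWR1..FWR4")
  if (length(jord) && any(jord < 6))
    msg <- c(msg, "J gene regions must be within {CDR3, FWR4}")
  if (!object@readingFrame %in% 0:2)
    msg <- c(msg, "readingFrame must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct a GermlineReference
#'
#' @param vGene,jGene gene labels.
#' @param vSeq,jSeq germline nucleotide sequences.
#' @param vRegions,jRegions per-position region labels (see
#'   [GermlineReference-class]).
#' @param readingFrame codon offset (0, 1 or 2) of V position 0.
#' @return A [GermlineReference-class] object.
#' @export
GermlineReference <- function(vGene, jGene, vSeq, jSeq, vRegions, jRegions,
                              readingFrame = 0L) {
  new("GermlineReference",
    vGene = as.character(vGene), jGene = as.character(jGene),
    vSeq = toupper(as.character(vSeq)), jSeq = toupper(as.character(jSeq)),
    vRegions = as.character(vRegions), jRegions = as.character(jRegions),
    readingFrame = as.integer(readingFrame)
  )
}

#' Lineage: one clonal B-cell family
#'
#' A clonal lineage is a set of receptor sequences inferred to descend from a
#' single naive B-cell ancestor: all members share V gene, J gene and CDR3
#' length, and were linked by single-linkage clustering at the configured
#' identity cutoff. \code{members} is a repertoire-style data.frame (columns
#' \code{sequence_id, subject, timepoint, sequence, v_gene, j_gene, cdr3,
#' isotype}).
#'
#' @slot lineageId lineage identifier.
#' @slot subject subject identifier (lineages never span subjects).
#' @slot members data.frame of member sequence records.
#' @slot germline the [GermlineReference-class] for the lineage's V/J pair.
#' @slot cdr3Length CDR3 nucleotide length shared by all members.
#' @exportClass Lineage
setClass("Lineage",
  representation(
    lineageId = "character", subject = "character",
    members = "data.frame", germline = "GermlineReference",
    cdr3Length = "integer"
  )
)

setValidity("Lineage", function(object) {
  msg <- character(0)
  m <- object@members
  need <- c("sequence_id", "subject", "timepoint", "sequence",
            "v_gene", "j_gene", "cdr3", "isotype")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("members must have columns:",
                        paste(setdiff(need, names(m)), collapse = ", ")))
  else {
    if (nrow(m) == 0L) msg <- c(msg, "lineage must have at least one member")
    if (nrow(m) > 0L) {
      if (length(unique(m$v_gene)) > 1L || length(unique(m$j_gene)) > 1L)
        msg <- c(msg, "all members must share v_gene and j_gene")
      if (any(nchar(m$cdr3) != object@cdr3Length))
        msg <- c(msg, "all members must share the lineage CDR3 length")
      if (!all(m$subject == object@subject))
        msg <- c(msg, "members must belong to the lineage's subject")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Lineage
#'
#' @param lineageId lineage identifier.
#' @param members data.frame of sequence records (see [Lineage-class]).
#' @param germline a [GermlineReference-class].
#' @param subject subject id; defaults to the members' (unique) subject.
#' @return A [Lineage-class] object.
#' @export
Lineage <- function(lineageId, members, germline,
                    subject = unique(members$subject)) {
  new("Lineage",
    lineageId = as.character(lineageId), subject = as.character(subject),
    members = as.data.frame(members, stringsAsFactors = FALSE),
    germline = germline,
    cdr3Length = as.integer(nchar(members$cdr3[1]))
  )
}

#' SFS: site frequency spectrum of derived somatic mutations
#'
#' Counts \eqn{\xi_i} of segregating sites whose derived allele is carried by
#' exactly \eqn{i} of the \eqn{n} sampled unique sequences, \eqn{i = 1, ...,
#' n-1}. Sites carried by all \eqn{n} members are fixed differences and are
#' stored separately in \code{fixed}, not in \code{xi}.
#'
#' @slot n integer sample size (unique sequences).
#' @slot xi numeric vector of length \code{n - 1}; \code{xi[i]} is the number
#'   of sites at derived-allele count \code{i}.
#' @slot fixed number of fixed derived sites (carried by all \code{n}).
#' @exportClass SFS
setClass("SFS",
  representation(n = "integer", xi = "numeric", fixed = "numeric")
)

setValidity("SFS", function(object) {
  msg <- character(0)
  if (object@n < 2L) msg <- c(msg, "SFS requires n >= 2")
  if (length(object@xi) != object@n - 1L)
    msg <- c(msg, "xi must have length n - 1")
  if (any(object@xi < 0) || object@fixed < 0)
    msg <- c(msg, "site counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct an SFS
#'
#' @param n sample size (number of unique sequences), \code{n >= 2}.
#' @param xi either a full numeric vector of length \code{n - 1}, or a named
#'   vector/list mapping derived-allele counts to site counts (e.g.
#'   \code{c("3" = 1)}).
#' @param fixed number of fixed derived sites.
#' @return An [SFS-class] object.
#' @export
SFS <- function(n, xi = numeric(n - 1), fixed = 0) {
  n <- as.integer(n)
  if (!is.null(names(xi)) || length(xi) != n - 1L) {
    idx <- as.integer(names(xi))
    if (is.null(names(xi)) || anyNA(idx) || any(idx < 1L) || any(idx >= n))
      stop("xi must be length n-1 or named by derived-allele counts in 1..n-1")
    full <- numeric(n - 1L)
    full[idx] <- as.numeric(xi)
    xi <- full
  }
  new("SFS", n = n, xi = as.numeric(xi), fixed = as.numeric(fixed))
}
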