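#' @name accessors
#' @title Accessors for repevol classes
#'
#' @description
#' \code{sampleSize(x)}: number of unique sequences behind an [SFS-class].
#' \code{xiCounts(x)}: the vector \eqn{\xi_1..\xi_{n-1}}.
#' \code{segSites(x)}: total segregating sites \eqn{S = \sum_i \xi_i}.
#' \code{fixedSites(x)}: derived sites carried by all \eqn{n} members.
#' \code{lineageId(x)}, \code{subjectId(x)}, \code{members(x)},
#' \code{germline(x)}, \code{cdr3Length(x)}: slots of a [Lineage-class].
#' \code{germlineAxis(x, cdr3Length)}: germline sequence, region labels and
#' callable mask on the V ++ CDR3 ++ J axis of a [GermlineReference-class].
#'
#' @param x the object.
#' @param ... unused.
#' @return The slot value (see Description).
NULL

#' @rdname accessors
#' @export
setGeneric("sampleSize", function(x, ...) standardGeneric("sampleSize"))
#' @rdname accessors
#' @export
setGeneric("xiCounts", function(x, ...) standardGeneric("xiCounts"))
#' @rdname accessors
#' @export
setGeneric("segSites", function(x, ...) standardGeneric("segSites"))
#' @rdname accessors
#' @export
setGeneric("fixedSites", function(x, ...) standardGeneric("fixedSites"))
#' @rdname accessors
#' @export
setGeneric("lineageId", function(x, ...) standardGeneric("lineageId"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x, ...) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("members", function(x, ...) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("germline", function(x, ...) standardGeneric("germline"))
#' @rdname accessors
#' @export
setGeneric("cdr3Length", function(x, ...) standardGeneric("cdr3Length"))
#' @rdname accessors
#' @export
setGeneric("germlineAxis", function(x, ...) standardGeneric("germlineAxis"))

#' @rdname accessors
setMethod("sampleSize", "SFS", function(x, ...) x@n)
#' @rdname accessors
setMethod("xiCounts", "SFS", function(x, ...) x@xi)
#' @rdname accessors
setMethod("segSites", "SFS", function(x, ...) sum(x@xi))
#' @rdname accessors
setMethod("fixedSites", "SFS", function(x, ...) x@fixed)
#' @rdname accessors
setMethod("lineageId", "Lineage", function(x, ...) x@lineageId)
#' @rdname accessors
setMethod("subjectId", "Lineage", function(x, ...) x@subject)
#' @rdname accessors
setMethod("members", "Lineage", function(x, ...) x@members)
#' @rdname accessors
setMethod("germline", "Lineage", function(x, ...) x@germline)
#' @rdname accessors
setMethod("cdr3Length", "Lineage", function(x, ...) x@cdr3Length)

#' @rdname accessors
#' @param cdr3Length CDR3 junction length (nt) to place between the annotated
#'   V and J segments.
setMethod("germlineAxis", "GermlineReference", function(x, cdr3Length, ...) {
  cdr3Length <- as.integer(cdr3Length)
  vcdr3 <- sum(x@vRegions == "CDR3")
  jcdr3 <- sum(x@jRegions == "CDR3")
  insert <- cdr3Length - vcdr3 - jcdr3
  if (insert < 0L)
    stop("cdr3Length shorter than the germline-annotated CDR3 flanks")
  vlen <- nchar(x@vSeq)
  seq <- paste0(x@vSeq, strrep("N", insert), x@jSeq)
  regions <- c(x@vRegions, rep("CDR3", insert), x@jRegions)
  ## callable: germline-covered (V or J) positions outside CDR3
  callable <- regions != "CDR3" &
    seq_along(regions) %in% c(seq_len(vlen), vlen + insert + seq_len(nchar(x@jSeq)))
  list(
    seq = seq, regions = regions, callable = callable,
    length = nchar(seq), vLength = vlen, insertLength = insert,
    cdr3Start = vlen - vcdr3,            # 0-based start of CDR3 on the axis
    cdr3End = vlen + insert + jcdr3      # 0-based half-open end
  )
})

setMethod("show", "GermlineReference", function(object) {
  cat("GermlineReference:", object@vGene, "/", object@jGene, "\n")
  cat("  V:", nchar(object@vSeq), "nt [",
      paste(rle(object@vRegions)$values, collapse = " "), "]\n")
  cat("  J:", nchar(object@jSeq), "nt [",
      paste(rle(object@jRegions)$values, collapse = " "), "]\n")
  cat("  reading frame:", object@readingFrame, "\n")
})

setMethod("show", "Lineage", function(object) {
  m <- object@members
  cat("Lineage", object@lineageId, "(subject ", object@subject, ")\n", sep = "")
  cat("  ", nrow(m), " unique sequences | ", object@germline@vGene, "/",
      object@germline@jGene, " | CDR3 ", object@cdr3Length, " nt\n", sep = "")
  tp <- table(m$timepoint)
  cat("  timepoints:", paste(names(tp), tp, sep = ":", collapse = " "), "\n")
})

setMethod("show", "SFS", function(object) {
  cat("SFS: n =", object@n, "| S =", sum(object@xi),
      "segregating sites |", object@fixed, "fixed\n")
  nz <- which(object@xi > 0)
  if (length(nz)) {
    head_nz <- utils::head(nz, 8L)
    cat("  xi:", paste0("[", head_nz, "]=", object@xi[head_nz], collapse = " "),
        if (length(nz) > 8L) "..." else "", "\n")
  }
})
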