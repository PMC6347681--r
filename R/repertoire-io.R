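## Readers/writers for the tabular and sequence formats the pipeline consumes:
## AIRR-style rearrangement TSV, germline FASTA + region BED, lineage FASTA,
## Newick trees, plain results TSV.

REPERTOIRE_COLUMNS <- c("sequence_id", "subject", "timepoint", "sequence",
                        "v_gene", "j_gene", "cdr3", "isotype")

#' Default column aliases for AIRR-style rearrangement tables
#'
#' Maps the package's canonical record fields to the column names accepted in
#' input TSVs (first present alias wins). AIRR-Rearrangement names
#' (\code{v_call}, \code{junction}, \code{c_call}, ...) are included.
#'
#' @return Named list: canonical field -> character vector of aliases.
#' @export
repertoireColumnConfig <- function() {
  list(
    sequence_id = c("sequence_id", "seq_id"),
    subject     = c("subject", "subject_id", "patient"),
    timepoint   = c("timepoint", "time_point", "sample_time"),
    sequence    = c("sequence", "nucleotide_seq", "sequence_nt"),
    v_gene      = c("v_gene", "v_call"),
    j_gene      = c("j_gene", "j_call"),
    cdr3        = c("cdr3", "cdr3_nt", "junction"),
    isotype     = c("isotype", "c_call", "c_gene")
  )
}

.normalizeIsotype <- function(x) {
  x <- as.character(x)
  map <- c(IGHM = "IgM", IGHD = "IgD", IGHG = "IgG", IGHA = "IgA",
           IGHE = "IgE", IGM = "IgM", IGD = "IgD", IGG = "IgG",
           IGA = "IgA", IGE = "IgE")
  up <- toupper(sub("[0-9]+$", "", x))   # IGHG1 -> IGHG
  out <- ifelse(x %in% VALID_ISOTYPES, x,
                ifelse(up %in% names(map), map[up], "unknown"))
  out[is.na(x) | x == ""] <- "unknown"
  unname(out)
}

#' Read an annotated repertoire table
#'
#' Reads an AIRR-Rearrangement-style TSV (one row per unique sequence) into
#' the canonical record data.frame used throughout the package. Rows missing
#' a V call, J call or CDR3 are dropped and counted in the skip report;
#' identical (subject, timepoint, sequence) rows are collapsed to one unique
#' sequence.
#'
#' @param path TSV file with a header.
#' @param columnConfig alias map as from [repertoireColumnConfig()].
#' @param collapseDuplicates collapse identical (subject, timepoint,
#'   sequence) rows before returning (default TRUE).
#' @return List with \code{records} (data.frame with columns
#'   \code{sequence_id, subject, timepoint, sequence, v_gene, j_gene, cdr3,
#'   isotype}) and \code{skipped} (named integer: \code{missing_v},
#'   \code{missing_j}, \code{missing_cdr3}, \code{duplicate}).
#' @export
readRepertoire <- function(path, columnConfig = repertoireColumnConfig(),
                           collapseDuplicates = TRUE) {
  if (!file.exists(path)) stop("cannot read repertoire table: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  asRecords(tab, columnConfig = columnConfig,
            collapseDuplicates = collapseDuplicates)
}

#' Coerce an annotated table to canonical sequence records
#'
#' Same contract as [readRepertoire()] but starting from an in-memory
#' data.frame.
#'
#' @param tab data.frame with (aliased) record columns.
#' @inheritParams readRepertoire
#' @return See [readRepertoire()].
#' @export
asRecords <- function(tab, columnConfig = repertoireColumnConfig(),
                      collapseDuplicates = TRUE) {
  cols <- lapply(names(columnConfig), function(field) {
    hit <- intersect(columnConfig[[field]], names(tab))
    if (!length(hit)) {
      if (field == "isotype") return(rep("unknown", nrow(tab)))
      stop("required column missing from table: ", field,
           " (accepted names: ", paste(columnConfig[[field]], collapse = ", "),
           ")")
    }
    as.character(tab[[hit[1]]])
  })
  names(cols) <- names(columnConfig)
  rec <- as.data.frame(cols, stringsAsFactors = FALSE)
  rec$isotype <- .normalizeIsotype(rec$isotype)
  rec$sequence <- toupper(rec$sequence)
  rec$cdr3 <- toupper(rec$cdr3)

  blank <- function(x) is.na(x) | x == ""
  skipped <- c(missing_v = 0L, missing_j = 0L, missing_cdr3 = 0L,
               duplicate = 0L)
  bad_v <- blank(rec$v_gene)
  bad_j <- !bad_v & blank(rec$j_gene)
  bad_c <- !bad_v & !bad_j & blank(rec$cdr3)
  skipped["missing_v"] <- sum(bad_v)
  skipped["missing_j"] <- sum(bad_j)
  skipped["missing_cdr3"] <- sum(bad_c)
  rec <- rec[!(bad_v | bad_j | bad_c), , drop = FALSE]

  if (collapseDuplicates && nrow(rec)) {
    key <- paste(rec$subject, rec$timepoint, rec$sequence, sep = "\r")
    dup <- duplicated(key)
    skipped["duplicate"] <- sum(dup)
    rec <- rec[!dup, , drop = FALSE]
  }
  rownames(rec) <- NULL
  list(records = rec, skipped = skipped)
}

## ---- germline database ----------------------------------------------------

.readRegionBed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L)
    stop("region annotation must have columns: gene, start, end, region")
  names(bed)[1:4] <- c("gene", "start", "end", "region")
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  bed
}

.regionMapFor <- function(gene, len, bed) {
  iv <- bed[bed$gene == gene, , drop = FALSE]
  if (!nrow(iv)) stop("gene missing region annotation: ", gene)
  iv <- iv[order(iv$start), , drop = FALSE]
  if (iv$start[1] != 0L || iv$end[nrow(iv)] != len ||
      (nrow(iv) > 1L && any(iv$start[-1] != iv$end[-nrow(iv)])))
    stop("region intervals for gene ", gene,
         " must tile [0, ", len, ") without gaps or overlaps")
  rep(iv$region, iv$end - iv$start)
}

#' Read a germline V/J reference database
#'
#' Reads germline V and J gene FASTA files (headers are gene labels) plus a
#' BED-like region annotation (columns \code{gene, start, end, region};
#' 0-based half-open) into a database from which per-lineage
#' [GermlineReference-class] objects are drawn with [germlineFor()]. Every
#' reference position must be covered by exactly one region interval.
#'
#' @param vFasta,jFasta FASTA paths.
#' @param regionBed region annotation path.
#' @param readingFrame codon offset of V position 0 (single value or vector
#'   named by V gene); default 0.
#' @return An object of class \code{germline_db}.
#' @export
readGermlineDb <- function(vFasta, jFasta, regionBed, readingFrame = 0L) {
  vset <- Biostrings::readDNAStringSet(vFasta)
  jset <- Biostrings::readDNAStringSet(jFasta)
  bed <- .readRegionBed(regionBed)
  vSeqs <- stats::setNames(as.character(vset), names(vset))
  jSeqs <- stats::setNames(as.character(jset), names(jset))
  vRegions <- lapply(names(vSeqs), function(g)
    .regionMapFor(g, nchar(vSeqs[[g]]), bed))
  names(vRegions) <- names(vSeqs)
  jRegions <- lapply(names(jSeqs), function(g)
    .regionMapFor(g, nchar(jSeqs[[g]]), bed))
  names(jRegions) <- names(jSeqs)
  frames <- if (length(readingFrame) == 1L)
    stats::setNames(rep(as.integer(readingFrame), length(vSeqs)), names(vSeqs))
  else stats::setNames(as.integer(readingFrame[names(vSeqs)]), names(vSeqs))
  db <- list(vSeqs = vSeqs, jSeqs = jSeqs, vRegions = vRegions,
             jRegions = jRegions, frames = frames)
  class(db) <- "germline_db"
  ## construct every reference once so invalid annotations fail at read time
  for (v in names(vSeqs)) for (j in names(jSeqs)) germlineFor(db, v, j)
  db
}

#' Look up the GermlineReference for a (V, J) pair
#'
#' @param db a \code{germline_db} from [readGermlineDb()] or
#'   [generateGermlineDb()].
#' @param vGene,jGene gene labels.
#' @return A [GermlineReference-class].
#' @export
germlineFor <- function(db, vGene, jGene) {
  if (!vGene %in% names(db$vSeqs)) stop("unknown V gene: ", vGene)
  if (!jGene %in% names(db$jSeqs)) stop("unknown J gene: ", jGene)
  GermlineReference(vGene, jGene, db$vSeqs[[vGene]], db$jSeqs[[jGene]],
                    db$vRegions[[vGene]], db$jRegions[[jGene]],
                    db$frames[[vGene]])
}

#' Write a germline database to FASTA + region BED
#'
#' Inverse of [readGermlineDb()].
#'
#' @inheritParams germlineFor
#' @param vFasta,jFasta,regionBed output paths.
#' @return Invisibly, the three paths.
#' @export
writeGermlineDb <- function(db, vFasta, jFasta, regionBed) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(db$vSeqs), vFasta)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(db$jSeqs), jFasta)
  bedOne <- function(gene, regions) {
    r <- rle(regions)
    end <- cumsum(r$lengths)
    data.frame(gene = gene, start = end - r$lengths, end = end,
               region = r$values, stringsAsFactors = FALSE)
  }
  bed <- rbind(
    do.call(rbind, lapply(names(db$vRegions), function(g)
      bedOne(g, db$vRegions[[g]]))),
    do.call(rbind, lapply(names(db$jRegions), function(g)
      bedOne(g, db$jRegions[[g]])))
  )
  utils::write.table(bed, regionBed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(vFasta, jFasta, regionBed))
}

## ---- lineage / tree / results export -------------------------------------

#' Write a lineage to FASTA
#'
#' The germline axis sequence (id \code{"germline"}, junction positions as N)
#' is always the first record, followed by the members in table order.
#'
#' @param lineage a [Lineage-class].
#' @param path output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
writeLineageFasta <- function(lineage, path) {
  axis <- germlineAxis(germline(lineage), cdr3Length(lineage))
  m <- members(lineage)
  seqs <- c(axis$seq, m$sequence)
  names(seqs) <- c("germline", m$sequence_id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write / read a genealogy as Newick
#'
#' Thin wrappers over \pkg{ape} keeping at least 10 significant digits of
#' branch length.
#'
#' @param genealogy an \code{ape} \code{phylo}.
#' @param path Newick file path.
#' @return \code{writeNewickTree}: invisibly \code{path};
#'   \code{readNewickTree}: a \code{phylo}.
#' @export
writeNewickTree <- function(genealogy, path) {
  ape::write.tree(genealogy, file = path, digits = 10)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) ape::read.tree(path)

#' Write / read a results table (TSV)
#'
#' @param rows data.frame of results.
#' @param path TSV path.
#' @return \code{writeResultsTable}: invisibly \code{path};
#'   \code{readResultsTable}: the data.frame.
#' @export
writeResultsTable <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
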