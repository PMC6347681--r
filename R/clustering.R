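## Clonal lineage identification: sequences sharing V gene, J gene and CDR3
## length are grouped, then single-linkage clustered at >= 90% nucleotide
## identity, so that a lineage is a connected component of the identity graph.

#' Clustering configuration
#'
#' @param identityCutoff single-linkage identity threshold in (0, 1];
#'   default 0.90. Pairs at exactly the cutoff count as linked.
#' @param scope \code{"cdr3_plus_variable"} (default): identity computed
#'   across both the CDR3 and the rest of the variable region, implemented as
#'   identity over the concatenation when member sequences are column-
#'   comparable (equal length; the package assumes point mutations only), and
#'   falling back to CDR3-only identity for a pair of unequal-length
#'   sequences. \code{"cdr3_only"}: identity on the CDR3 alone.
#' @return A list of class \code{cluster_config}.
#' @export
clusterConfig <- function(identityCutoff = 0.90,
                          scope = c("cdr3_plus_variable", "cdr3_only")) {
  scope <- match.arg(scope)
  if (!is.numeric(identityCutoff) || identityCutoff <= 0 || identityCutoff > 1)
    stop("identityCutoff must be in (0, 1]")
  structure(list(identityCutoff = identityCutoff, scope = scope),
            class = "cluster_config")
}

#' Group records by germline key
#'
#' Partitions records into equivalence classes of (subject, V gene, J gene,
#' CDR3 length), the candidate pools within which single-linkage clustering
#' runs. Lineages never span subjects.
#'
#' @param records canonical record data.frame (see [readRepertoire()]).
#' @param bySubject include subject in the key (default TRUE).
#' @return Named list of record data.frames; the union of the groups is the
#'   input and groups are disjoint.
#' @export
partitionByVJCdr3 <- function(records, bySubject = TRUE) {
  if (!nrow(records)) return(list())
  key <- paste(records$v_gene, records$j_gene, nchar(records$cdr3), sep = "|")
  if (bySubject) key <- paste(records$subject, key, sep = "|")
  unname(split(records, key)) |> stats::setNames(sort(unique(key)))
}

#' Pairwise nucleotide identity of two equal-length sequences
#'
#' @param a,b DNA strings of equal length.
#' @return Fraction of matching positions; 1.0 iff \code{a == b}.
#' @export
pairwiseIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("pairwiseIdentity requires equal-length sequences")
  if (nchar(a) == 0L) stop("pairwiseIdentity requires nonempty sequences")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

## identity matrix for a character matrix of sequences (rows = sequences)
.identityMatrix <- function(mat) {
  n <- nrow(mat)
  idm <- diag(1, n)
  if (n < 2L) return(idm)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    eq <- mat[rest, , drop = FALSE] == matrix(mat[i, ], nrow = length(rest),
                                              ncol = ncol(mat), byrow = TRUE)
    idm[i, rest] <- idm[rest, i] <- rowMeans(eq)
  }
  idm
}

.clusterStrings <- function(strings, cutoff) {
  n <- length(strings)
  if (n == 1L) return(1L)
  mat <- do.call(rbind, strsplit(strings, ""))
  idm <- .identityMatrix(mat)
  linked <- idm >= cutoff
  comp <- seq_len(n)
  repeat {                      # label propagation to connected components
    new <- apply(linked, 1L, function(row) min(comp[row]))
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

#' Single-linkage clustering of one germline group
#'
#' Two sequences end up in the same cluster iff they are connected by a chain
#' of pairs each with identity at or above the cutoff on the configured
#' scope.
#'
#' @param group record data.frame from [partitionByVJCdr3()] (members share
#'   V, J and CDR3 length).
#' @param config a [clusterConfig()].
#' @return Integer cluster membership vector (1-based, dense labels), one
#'   entry per row of \code{group}.
#' @export
singleLinkageCluster <- function(group, config = clusterConfig()) {
  n <- nrow(group)
  if (!n) return(integer(0))
  if (config$scope == "cdr3_only") {
    return(.clusterStrings(group$cdr3, config$identityCutoff))
  }
  ## cdr3_plus_variable: whole-sequence identity where column-comparable;
  ## length-bucketed so only equal-length sequences are compared on the full
  ## sequence, with CDR3-only identity linking across length buckets
  lens <- nchar(group$sequence)
  if (length(unique(lens)) == 1L) {
    return(.clusterStrings(group$sequence, config$identityCutoff))
  }
  cdr3Comp <- .clusterStrings(group$cdr3, config$identityCutoff)
  comp <- seq_len(n)
  for (len in unique(lens)) {
    idx <- which(lens == len)
    sub <- .clusterStrings(group$sequence[idx], config$identityCutoff)
    for (s in unique(sub)) {
      ids <- idx[sub == s]
      comp[comp %in% comp[ids]] <- min(comp[ids])
    }
  }
  for (s in unique(cdr3Comp)) {
    ids <- which(cdr3Comp == s)
    comp[comp %in% comp[ids]] <- min(comp[ids])
  }
  match(comp, unique(comp))
}

#' Identify clonal lineages in a repertoire
#'
#' Full lineage identification: group by (subject, V, J, CDR3 length), then
#' single-linkage cluster each group at the configured identity cutoff.
#'
#' @param records canonical record data.frame.
#' @param germlineDb a \code{germline_db} (see [readGermlineDb()]); used to
#'   attach the personalized [GermlineReference-class] to each lineage.
#' @param config a [clusterConfig()].
#' @return List with \code{lineages} (list of [Lineage-class], ids
#'   \code{<subject>-L<k>}) and \code{assignments} (data.frame
#'   \code{sequence_id, subject, timepoint, lineage_id}).
#' @export
clusterLineages <- function(records, germlineDb, config = clusterConfig()) {
  groups <- partitionByVJCdr3(records)
  lineages <- list()
  assign_rows <- list()
  counters <- new.env(parent = emptyenv())
  for (g in groups) {
    memb <- singleLinkageCluster(g, config)
    for (k in sort(unique(memb))) {
      rows <- g[memb == k, , drop = FALSE]
      subj <- rows$subject[1]
      cnt <- get0(subj, envir = counters, ifnotfound = 0L) + 1L
      assign(subj, cnt, envir = counters)
      lid <- sprintf("%s-L%04d", subj, cnt)
      germ <- germlineFor(germlineDb, rows$v_gene[1], rows$j_gene[1])
      lineages[[lid]] <- Lineage(lid, rows, germ)
      assign_rows[[lid]] <- data.frame(
        sequence_id = rows$sequence_id, subject = rows$subject,
        timepoint = rows$timepoint, lineage_id = lid,
        stringsAsFactors = FALSE)
    }
  }
  list(lineages = lineages,
       assignments = if (length(assign_rows))
         do.call(rbind, c(assign_rows, list(make.row.names = FALSE)))
       else data.frame(sequence_id = character(0), subject = character(0),
                       timepoint = character(0), lineage_id = character(0)))
}
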