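## Per-lineage abundance trajectories over the vaccination time course and
## classification into vaccine-responsive (> 50-fold fractional-abundance
## expansion D0 -> D7, typically undetectable before vaccination), persistent
## (< 2-fold change and > 0.1% of the repertoire at D7), or other.

#' Study timepoint labels
#'
#' The default sampling design: 5 and 3 days before vaccination, vaccination
#' day, and 1, 4, 7, 9 and 11 days after.
#' @return Character vector of ordered timepoint labels.
#' @export
studyTimepoints <- function() c("D-5", "D-3", "D0", "D1", "D4", "D7", "D9", "D11")

#' Per-lineage abundance trajectories
#'
#' Counts unique sequences per lineage and timepoint and divides by the total
#' number of unique sequences in the subject's repertoire at that timepoint
#' (fractional abundance). Totals are computed over all assigned records.
#'
#' @param assignments data.frame with columns \code{sequence_id, subject,
#'   timepoint, lineage_id} (from [clusterLineages()]).
#' @param timepoints ordered timepoint labels; defaults to the labels present,
#'   ordered as in [studyTimepoints()] when they match.
#' @return Long data.frame (class \code{abundance_trajectories}): columns
#'   \code{lineage_id, subject, timepoint, count, fraction}, one row per
#'   lineage x timepoint. Fractions at a timepoint sum to 1 across each
#'   subject's lineages (NaN when the subject has no sequences then).
#' @export
abundanceTrajectories <- function(assignments, timepoints = NULL) {
  if (is.null(timepoints)) {
    seen <- unique(assignments$timepoint)
    timepoints <- if (all(seen %in% studyTimepoints()))
      intersect(studyTimepoints(), seen) else sort(seen)
  }
  bad <- setdiff(unique(assignments$timepoint), timepoints)
  if (length(bad))
    stop("timepoints absent from the declared order: ",
         paste(bad, collapse = ", "))
  lins <- unique(assignments[, c("lineage_id", "subject")])
  counts <- table(factor(assignments$lineage_id, levels = lins$lineage_id),
                  factor(assignments$timepoint, levels = timepoints))
  totals <- table(factor(assignments$subject, levels = unique(lins$subject)),
                  factor(assignments$timepoint, levels = timepoints))
  out <- data.frame(
    lineage_id = rep(lins$lineage_id, times = length(timepoints)),
    subject = rep(lins$subject, times = length(timepoints)),
    timepoint = rep(timepoints, each = nrow(lins)),
    count = as.vector(counts[cbind(rep(seq_len(nrow(lins)), length(timepoints)),
                                   rep(seq_along(timepoints), each = nrow(lins)))]),
    stringsAsFactors = FALSE)
  tot <- as.vector(totals[cbind(match(out$subject, rownames(totals)),
                                match(out$timepoint, colnames(totals)))])
  out$fraction <- ifelse(tot > 0, out$count / tot, NaN)
  attr(out, "timepoints") <- timepoints
  class(out) <- c("abundance_trajectories", class(out))
  out
}

#' Fractional abundance of a lineage at a timepoint
#'
#' @param trajectories an [abundanceTrajectories()] table.
#' @param lineage lineage id.
#' @param timepoint timepoint label.
#' @return Unique sequences in the lineage divided by all unique sequences of
#'   the subject at that timepoint; 0 when unobserved, NaN when the subject
#'   total is 0.
#' @export
fractionalAbundance <- function(trajectories, lineage, timepoint) {
  if (!timepoint %in% attr(trajectories, "timepoints"))
    stop("timepoint not in trajectory table: ", timepoint)
  hit <- trajectories$lineage_id == lineage &
    trajectories$timepoint == timepoint
  if (!any(hit)) return(0)
  trajectories$fraction[hit][1]
}

#' Fold change of fractional abundance between two timepoints
#'
#' Follows the study's convention: lineages detected at \code{t1} but not at
#' \code{t0} have infinite fold change; both-zero is undefined (NaN).
#'
#' @inheritParams fractionalAbundance
#' @param t0,t1 timepoint labels (defaults \code{"D0"}, \code{"D7"}).
#' @return \code{f(t1)/f(t0)}; \code{Inf} when \code{f(t0) = 0 < f(t1)};
#'   0 when \code{f(t1) = 0 < f(t0)}; \code{NaN} when both are 0.
#' @export
foldChange <- function(trajectories, lineage, t0 = "D0", t1 = "D7") {
  f0 <- fractionalAbundance(trajectories, lineage, t0)
  f1 <- fractionalAbundance(trajectories, lineage, t1)
  if (f0 == 0 && f1 == 0) return(NaN)
  if (f0 == 0) return(Inf)
  f1 / f0
}

#' Classify lineage dynamics
#'
#' Labels each lineage \code{vaccine_responsive} when its fractional
#' abundance expanded more than \code{responsiveFc}-fold from \code{t0} to
#' \code{t1} (infinite fold change qualifies), \code{persistent} when the
#' fold change is below \code{persistentFc} and the \code{t1} fractional
#' abundance exceeds \code{persistentFrac}, and \code{other} otherwise. The
#' three labels are mutually exclusive and exhaustive.
#'
#' @inheritParams foldChange
#' @param responsiveFc expansion threshold (default 50).
#' @param persistentFc stability threshold (default 2).
#' @param persistentFrac minimum fractional abundance at \code{t1} for
#'   persistent lineages (default 0.001, i.e. 0.1%).
#' @return data.frame: \code{lineage_id, subject, fold_change, d7_fraction,
#'   d7_count, label}. \code{d7_*} columns refer to \code{t1}.
#' @export
classifyLineages <- function(trajectories, responsiveFc = 50,
                             persistentFc = 2, persistentFrac = 0.001,
                             t0 = "D0", t1 = "D7") {
  tps <- attr(trajectories, "timepoints")
  if (!all(c(t0, t1) %in% tps))
    stop("trajectories must cover ", t0, " and ", t1)
  lins <- unique(trajectories[, c("lineage_id", "subject")])
  fc <- vapply(lins$lineage_id, function(l)
    foldChange(trajectories, l, t0, t1), numeric(1))
  f1 <- vapply(lins$lineage_id, function(l)
    fractionalAbundance(trajectories, l, t1), numeric(1))
  c1 <- vapply(lins$lineage_id, function(l) {
    hit <- trajectories$lineage_id == l & trajectories$timepoint == t1
    if (any(hit)) trajectories$count[hit][1] else 0L
  }, numeric(1))
  label <- ifelse(!is.nan(fc) & fc > responsiveFc, "vaccine_responsive",
           ifelse(!is.nan(fc) & fc < persistentFc & f1 > persistentFrac,
                  "persistent", "other"))
  data.frame(lineage_id = lins$lineage_id, subject = lins$subject,
             fold_change = unname(fc), d7_fraction = unname(f1),
             d7_count = as.integer(c1), label = unname(label),
             stringsAsFactors = FALSE)
}

#' Germline gene usage enrichment
#'
#' For each germline gene, builds the lineage-level 2x2 table (in-set vs
#' background lineages) x (uses the gene vs not) and reports fold enrichment
#' of the usage fraction together with a two-sided Fisher exact p-value.
#'
#' @param lineageGenes data.frame with columns \code{lineage_id}, the gene
#'   column named by \code{gene}, and a logical column \code{in_set} marking
#'   the focal lineage set (e.g. vaccine-responsive).
#' @param gene \code{"v_gene"} or \code{"j_gene"}.
#' @param bonferroni also report Bonferroni-adjusted p-values (default FALSE;
#'   the study reports raw p-values).
#' @return data.frame: \code{gene, in_count, in_total, bg_count, bg_total,
#'   fold_enrichment, p_value} (plus \code{p_bonferroni}), one row per gene
#'   used by at least one lineage. Fold enrichment is \code{Inf} when the
#'   background usage is zero.
#' @export
geneUsageEnrichment <- function(lineageGenes, gene = c("v_gene", "j_gene"),
                                bonferroni = FALSE) {
  gene <- match.arg(gene)
  if (sum(lineageGenes$in_set) < 2L || sum(!lineageGenes$in_set) < 2L)
    stop("need at least 2 lineages in the focal set and in the background")
  g <- lineageGenes[[gene]]
  inset <- lineageGenes$in_set
  nIn <- sum(inset); nBg <- sum(!inset)
  rows <- lapply(sort(unique(g)), function(gg) {
    a <- sum(inset & g == gg); b <- nIn - a
    c_ <- sum(!inset & g == gg); d <- nBg - c_
    if (a + c_ == 0L) return(NULL)   # gene absent from both sets
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "two.sided")$p.value
    fold <- if (c_ == 0L) Inf else (a / nIn) / (c_ / nBg)
    data.frame(gene = gg, in_count = a, in_total = nIn, bg_count = c_,
               bg_total = nBg, fold_enrichment = fold, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

#' Somatic mutation density within the V gene
#'
#' Mismatch fraction between a sequence and the germline over V-gene
#' positions, by positional comparison on the germline axis. N bases and
#' positions beyond either sequence are excluded from both numerator and
#' denominator.
#'
#' @param sequence member nucleotide sequence (germline-axis coordinates).
#' @param germ a [GermlineReference-class].
#' @return Mismatches / compared V positions, in \[0, 1\]; NaN when no V
#'   position is comparable.
#' @export
mutationDensity <- function(sequence, germ) {
  vlen <- nchar(germ@vSeq)
  upto <- min(vlen, nchar(sequence))
  if (upto == 0L) return(NaN)
  sv <- strsplit(toupper(substr(sequence, 1L, upto)), "")[[1]]
  gv <- strsplit(substr(germ@vSeq, 1L, upto), "")[[1]]
  ok <- sv != "N" & gv != "N"
  if (!any(ok)) return(NaN)
  mean(sv[ok] != gv[ok])
}
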