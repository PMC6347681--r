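## Phylogenetic fitness inference via the local branching index (LBI): the
## total tree length surrounding a node, exponentially discounted with
## distance at timescale tau. Dense neighborhoods (recent rapid branching)
## mark high-fitness sequences. Branches with the largest parent-to-child
## LBI change carry candidate affinity-enhancing mutations, summarized by
## regional dN/dS.

#' Local branching index
#'
#' Two-pass message passing: for each node, the integral of tree length
#' around it discounted by exp(-distance/tau). Deterministic given the tree.
#'
#' @param genealogy a rooted \code{phylo} with branch lengths.
#' @param tau neighborhood timescale in branch-length units, or
#'   \code{"auto"} (default): 0.0625 x the average root-to-leaf distance,
#'   the published LBI convention.
#' @return List of class \code{lbi_annotation}: \code{lbi} (numeric per node,
#'   tips then internal, names = tip labels for tips), \code{delta} (per edge
#'   row: child LBI - parent LBI), \code{tau}.
#' @export
localBranchingIndex <- function(genealogy, tau = "auto") {
  phy <- genealogy
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (identical(tau, "auto")) {
    depths <- ape::node.depth.edgelength(phy)
    tau <- 0.0625 * mean(depths[seq_len(ntip)])
    if (tau <= 0) tau <- 1e-8   # degenerate zero-length tree
  }
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  po <- ape::reorder.phylo(phy, "postorder")
  nn <- ntip + nnode
  root <- ntip + 1L
  ## up-messages: contribution of each subtree through its stem edge
  up <- numeric(nn)            # up[v]: message from v to its parent
  childSum <- numeric(nn)      # sum of up-messages arriving at v
  att <- tau * (1 - exp(-po$edge.length / tau))
  dec <- exp(-po$edge.length / tau)
  for (e in seq_len(nrow(po$edge))) {  # postorder: children before parents
    v <- po$edge[e, 2L]
    up[v] <- att[e] + dec[e] * childSum[v]
    childSum[po$edge[e, 1L]] <- childSum[po$edge[e, 1L]] + up[v]
  }
  ## down-messages, parents before children
  down <- numeric(nn)
  pre <- rev(seq_len(nrow(po$edge)))
  for (e in pre) {
    u <- po$edge[e, 1L]; v <- po$edge[e, 2L]
    down[v] <- att[e] + dec[e] * (down[u] + childSum[u] - up[v])
  }
  lbi <- down + childSum
  names(lbi) <- c(phy$tip.label, rep("", nnode))
  delta <- lbi[phy$edge[, 2L]] - lbi[phy$edge[, 1L]]
  structure(list(lbi = lbi, delta = unname(delta), tau = tau),
            class = "lbi_annotation")
}

#' Rank branches by fitness change
#'
#' Sorts branches by the parent-to-child LBI change and returns the top k
#' (strongest fitness enhancements) and bottom k (strongest diminishments).
#' Ties are broken by clade size (larger first) then child node id, so the
#' ranking is deterministic.
#'
#' @param annotation an \code{lbi_annotation} from [localBranchingIndex()].
#' @param genealogy the same tree the annotation was computed on.
#' @param k branches per tail (default 3, the study's convention).
#' @param excludeGermline drop the germline terminal branch from the ranking
#'   (default TRUE; the outgroup's LBI change is not a fitness signal).
#' @return List with \code{top} and \code{bottom}: data.frames \code{edge,
#'   parent, child, delta, clade_size}, k rows each (fewer, with attribute
#'   \code{short = TRUE}, when the tree has fewer than 2k rankable branches).
#' @export
rankBranchesByFitnessChange <- function(annotation, genealogy, k = 3,
                                        excludeGermline = TRUE) {
  phy <- genealogy
  cnt <- .subtreeLeafCounts(phy)
  edges <- seq_len(nrow(phy$edge))
  if (excludeGermline && "germline" %in% phy$tip.label) {
    gtip <- which(phy$tip.label == "germline")
    edges <- edges[phy$edge[, 2L] != gtip]
  }
  df <- data.frame(edge = edges,
                   parent = phy$edge[edges, 1L], child = phy$edge[edges, 2L],
                   delta = annotation$delta[edges],
                   clade_size = cnt[phy$edge[edges, 2L]])
  ord <- order(-df$delta, -df$clade_size, df$child)
  df <- df[ord, , drop = FALSE]
  short <- nrow(df) < 2L * k
  kk <- min(k, nrow(df))
  top <- utils::head(df, kk)
  bottom <- utils::tail(df, kk)[rev(seq_len(kk)), , drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  out <- list(top = top, bottom = bottom)
  if (short) attr(out, "short") <- TRUE
  out
}

#' Classify a mutation's codon effect
#'
#' Translates the parent-haplotype codon with and without the mutation.
#' Codons containing N or spanning the CDR3 junction boundary are
#' \code{"unknown"}.
#'
#' @param position 0-based germline-axis position of the mutation.
#' @param to derived base.
#' @param parentSeq character vector of the parent haplotype's bases on the
#'   germline axis (provides the other two codon positions).
#' @param regions per-position region labels for the axis.
#' @param readingFrame codon offset of position 0.
#' @return \code{"synonymous"}, \code{"nonsynonymous"} or \code{"unknown"}.
#' @export
classifyCodonEffect <- function(position, to, parentSeq, regions,
                                readingFrame = 0L) {
  p <- as.integer(position)
  within <- (p + readingFrame) %% 3L
  codonPos <- (p - within) + 0:2          # 0-based axis positions of the codon
  if (any(codonPos < 0L) || any(codonPos >= length(parentSeq)))
    return("unknown")
  codon <- parentSeq[codonPos + 1L]
  reg <- regions[codonPos + 1L]
  if (any(codon == "N") || length(unique(reg == "CDR3")) > 1L)
    return("unknown")
  mut <- codon
  mut[within + 1L] <- to
  code <- Biostrings::GENETIC_CODE
  aa0 <- code[paste(codon, collapse = "")]
  aa1 <- code[paste(mut, collapse = "")]
  if (is.na(aa0) || is.na(aa1)) return("unknown")
  if (aa0 == aa1) "synonymous" else "nonsynonymous"
}

#' Annotate branch mutations with codon effects
#'
#' For every mutation mapped by [mapMutationsToBranches()], reconstructs the
#' parent haplotype (germline axis overlaid with the parent node's inferred
#' states at variable columns) and classifies the change.
#'
#' @param genealogy tree with \code{branch_mutations} / \code{anc_states}.
#' @param alignment the \code{lineage_alignment} used for the mapping.
#' @return The \code{branch_mutations} data.frame with an \code{effect}
#'   column.
#' @export
classifyBranchMutations <- function(genealogy, alignment) {
  bm <- genealogy$branch_mutations
  if (is.null(bm)) stop("run mapMutationsToBranches() first")
  if (!nrow(bm)) { bm$effect <- character(0); return(bm) }
  germRow <- alignment$matrix["germline", ]
  frame <- alignment$germ@readingFrame
  colAt <- match(bm$position, genealogy$anc_columns)
  parents <- genealogy$edge[bm$edge, 1L]
  bm$effect <- vapply(seq_len(nrow(bm)), function(i) {
    parentSeq <- germRow
    anc <- genealogy$anc_states[parents[i], ]
    parentSeq[genealogy$anc_columns + 1L] <- anc
    classifyCodonEffect(bm$position[i], bm$to[i], parentSeq,
                        alignment$regions, frame)
  }, character(1))
  bm
}

#' Regional dN/dS enrichment of a branch set
#'
#' For mutations pooled over a branch set (e.g. the top-3 fitness-change
#' branches of each lineage), computes per region r the nonsynonymous /
#' synonymous ratio normalized to the same branch set overall:
#' \deqn{enrichment_r = (N_r / S_r) / (N_{tot} / S_{tot}),}
#' an SD by bootstrap over lineages (respecting within-lineage correlation),
#' and a two-sided Fisher exact p on the (region vs elsewhere) x (nonsyn vs
#' syn) table.
#'
#' @param mutations data.frame with columns \code{lineage_id, region,
#'   effect} (\code{"unknown"} rows are ignored), pooled over the branch
#'   set.
#' @param bootstrapReps bootstrap replicates (default 100).
#' @param regions regions to report (default all seven).
#' @return data.frame per region: \code{region, n_nonsyn, n_syn, enrichment,
#'   bootstrap_sd, fisher_p}. Enrichment is NA when the region (or the pool)
#'   has no synonymous mutations.
#' @export
#' Pooled CDR vs FWR dN/dS enrichment
#'
#' Same normalization as [regionalDndsEnrichment()] but with the three CDRs
#' (respectively four FWRs) pooled, the aggregate contrast between the
#' binding interface and the structural scaffold.
#'
#' @inheritParams regionalDndsEnrichment
#' @return Named numeric: \code{CDR} and \code{FWR} enrichment (NA when a
#'   pool has no synonymous mutations).
#' @export
cdrFwrEnrichment <- function(mutations) {
  mut <- mutations[mutations$effect %in% c("synonymous", "nonsynonymous"), ,
                   drop = FALSE]
  cdr <- mut$region %in% c("CDR1", "CDR2", "CDR3")
  Nt <- sum(mut$effect == "nonsynonymous")
  St <- sum(mut$effect == "synonymous")
  one <- function(sel) {
    Nr <- sum(mut$effect == "nonsynonymous" & sel)
    Sr <- sum(mut$effect == "synonymous" & sel)
    if (Sr == 0L || St == 0L || Nt == 0L) return(NA_real_)
    (Nr / Sr) / (Nt / St)
  }
  c(CDR = one(cdr), FWR = one(!cdr))
}

regionalDndsEnrichment <- function(mutations, bootstrapReps = 100,
                                   regions = VALID_REGIONS) {
  mut <- mutations[mutations$effect %in% c("synonymous", "nonsynonymous"), ,
                   drop = FALSE]
  enrich <- function(m) {
    Nt <- sum(m$effect == "nonsynonymous")
    St <- sum(m$effect == "synonymous")
    vapply(regions, function(r) {
      Nr <- sum(m$effect == "nonsynonymous" & m$region == r)
      Sr <- sum(m$effect == "synonymous" & m$region == r)
      if (Sr == 0L || St == 0L || Nt == 0L) return(NA_real_)
      (Nr / Sr) / (Nt / St)
    }, numeric(1))
  }
  point <- enrich(mut)
  lins <- unique(mut$lineage_id)
  boot <- replicate(bootstrapReps, {
    pick <- sample(lins, length(lins), replace = TRUE)
    enrich(do.call(rbind, lapply(pick, function(l)
      mut[mut$lineage_id == l, , drop = FALSE])))
  })
  boot <- matrix(boot, nrow = length(regions))
  sds <- apply(boot, 1L, function(x) stats::sd(x[is.finite(x)]))
  fp <- vapply(regions, function(r) {
    a <- sum(mut$effect == "nonsynonymous" & mut$region == r)
    b <- sum(mut$effect == "synonymous" & mut$region == r)
    c_ <- sum(mut$effect == "nonsynonymous" & mut$region != r)
    d <- sum(mut$effect == "synonymous" & mut$region != r)
    if (a + b == 0L) return(NA_real_)
    stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
  }, numeric(1))
  data.frame(region = regions,
             n_nonsyn = vapply(regions, function(r)
               sum(mut$effect == "nonsynonymous" & mut$region == r), integer(1)),
             n_syn = vapply(regions, function(r)
               sum(mut$effect == "synonymous" & mut$region == r), integer(1)),
             enrichment = unname(point), bootstrap_sd = unname(sds),
             fisher_p = unname(fp), row.names = NULL,
             stringsAsFactors = FALSE)
}
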