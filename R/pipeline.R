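## End-to-end orchestration: cluster -> dynamics -> SFS -> selection ->
## trees -> sweeps -> fitness/dN/dS, with per-stage outputs, a run manifest,
## and the cross-stage selection-vs-expansion summary.

#' Pipeline run configuration
#'
#' @param seed global seed; all stage randomness derives from it.
#' @param minD7Count lineages feeding selection analyses need at least this
#'   many unique sequences at the peak timepoint (default 100, the study's
#'   convention; lower it for tiny synthetic runs).
#' @param selectionReplicates null replicates per lineage and model.
#' @param cluster a [clusterConfig()].
#' @param sweep a [sweepConfig()].
#' @param responsiveFc,persistentFc,persistentFrac dynamics thresholds (see
#'   [classifyLineages()]).
#' @param t0,t1 baseline and peak timepoints.
#' @param tau LBI timescale (\code{"auto"} or a number).
#' @param topK branches per fitness tail (default 3).
#' @param bootstrapReps dN/dS bootstrap replicates (default 100).
#' @param growthRate expanding-null growth rate.
#' @param binEdges frequency bin edges.
#' @param stages stages to run, in order; downstream stages stop with an
#'   informative error when an upstream stage they need was toggled off.
#' @return A list of class \code{run_config}.
#' @export
runConfig <- function(seed = 1L, minD7Count = 100,
                      selectionReplicates = 10000,
                      cluster = clusterConfig(), sweep = sweepConfig(),
                      responsiveFc = 50, persistentFc = 2,
                      persistentFrac = 0.001, t0 = "D0", t1 = "D7",
                      tau = "auto", topK = 3, bootstrapReps = 100,
                      growthRate = defaultGrowthRate(),
                      binEdges = defaultBinEdges(),
                      stages = c("cluster", "dynamics", "sfs", "selection",
                                 "trees", "sweeps", "fitness")) {
  structure(list(seed = as.integer(seed), minD7Count = minD7Count,
                 selectionReplicates = selectionReplicates,
                 cluster = cluster, sweep = sweep,
                 responsiveFc = responsiveFc, persistentFc = persistentFc,
                 persistentFrac = persistentFrac, t0 = t0, t1 = t1,
                 tau = tau, topK = topK, bootstrapReps = bootstrapReps,
                 growthRate = growthRate, binEdges = binEdges,
                 stages = stages),
            class = "run_config")
}

.needStage <- function(results, stage, needed,
                       producer = c(assignments = "cluster",
                                    lineages = "cluster",
                                    labels = "dynamics", sfs = "sfs",
                                    trees = "trees")[needed]) {
  if (is.null(results[[needed]]))
    stop("stage '", stage, "' requires '", needed, "' from stage '",
         producer, "', which did not run")
}

#' Run the full analysis
#'
#' Executes the configured stages on an annotated repertoire and returns a
#' results bundle; when \code{outDir} is given, each table is written as TSV
#' together with a run manifest. Deterministic under a fixed seed.
#'
#' @param records canonical record data.frame (see [readRepertoire()]).
#' @param germlineDb a \code{germline_db}.
#' @param config a [runConfig()].
#' @param outDir optional output directory.
#' @return List with (depending on stages) \code{lineages},
#'   \code{assignments}, \code{trajectories}, \code{labels}, \code{sfs},
#'   \code{selection}, \code{trees}, \code{sweeps}, \code{fitness},
#'   \code{dnds}, \code{selection_vs_expansion}, \code{manifest}.
#' @export
runFullAnalysis <- function(records, germlineDb, config = runConfig(),
                            outDir = NULL) {
  set.seed(config$seed)
  res <- list()
  st <- config$stages

  if ("cluster" %in% st) {
    cl <- clusterLineages(records, germlineDb, config$cluster)
    res$lineages <- cl$lineages
    res$assignments <- cl$assignments
  }
  if ("dynamics" %in% st) {
    .needStage(res, "dynamics", "assignments")
    res$trajectories <- abundanceTrajectories(res$assignments)
    res$labels <- classifyLineages(res$trajectories, config$responsiveFc,
                                   config$persistentFc, config$persistentFrac,
                                   config$t0, config$t1)
  }
  eligible <- NULL
  if (any(c("sfs", "selection", "trees") %in% st)) {
    .needStage(res, "sfs", "lineages")
    sizes <- vapply(res$lineages, function(l)
      length(unique(members(l)$sequence)), integer(1))
    eligible <- names(res$lineages)[sizes >= 2L]
  }
  if ("sfs" %in% st) {
    res$sfs <- lapply(res$lineages[eligible], function(l) buildSFS(l))
  }
  if ("selection" %in% st) {
    .needStage(res, "selection", "sfs")
    .needStage(res, "selection", "labels")
    d7 <- res$labels$d7_count[match(eligible, res$labels$lineage_id)]
    feed <- eligible[d7 >= config$minD7Count]
    rows <- lapply(feed, function(lid)
      testSelection(res$sfs[[lid]], replicates = config$selectionReplicates,
                    growthRate = config$growthRate,
                    binEdges = config$binEdges, lineage_id = lid))
    res$selection <- if (length(rows))
      do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  }
  if ("trees" %in% st) {
    treeable <- eligible[vapply(res$lineages[eligible], function(l)
      length(unique(members(l)$sequence)) >= 3L, logical(1))]
    res$trees <- lapply(res$lineages[treeable], function(l) {
      aln <- alignToGermline(l)
      phy <- buildLineageTree(aln)
      phy <- mapMutationsToBranches(phy, aln)
      list(tree = phy, alignment = aln)
    })
  }
  if ("sweeps" %in% st) {
    .needStage(res, "sweeps", "trees")
    big <- names(res$trees)[vapply(res$trees, function(t)
      sum(t$tree$tip.label != "germline") >= config$sweep$minCladeSize,
      logical(1))]
    calls <- lapply(res$trees[big], function(t)
      detectSelectedSubclones(t$tree, config$sweep))
    res$sweeps <- if (length(calls)) data.frame(
      lineage_id = names(calls),
      n_leaves = vapply(res$trees[big], function(t)
        sum(t$tree$tip.label != "germline"), integer(1)),
      n_sweeps = vapply(calls, countSweeps, integer(1)),
      row.names = NULL, stringsAsFactors = FALSE) else NULL
    res$sweep_calls <- calls
  }
  if ("fitness" %in% st) {
    .needStage(res, "fitness", "trees")
    fitRows <- list(); mutTop <- list(); mutBottom <- list()
    for (lid in names(res$trees)) {
      t <- res$trees[[lid]]
      ann <- localBranchingIndex(t$tree, config$tau)
      rk <- rankBranchesByFitnessChange(ann, t$tree, k = config$topK)
      ntip <- length(t$tree$tip.label)
      fitRows[[lid]] <- data.frame(
        lineage_id = lid,
        sequence_id = t$tree$tip.label,
        lbi = unname(ann$lbi[seq_len(ntip)]),
        stringsAsFactors = FALSE)
      bm <- classifyBranchMutations(t$tree, t$alignment)
      tag <- function(sub) {
        sub$lineage_id <- rep(lid, nrow(sub))
        sub
      }
      mutTop[[lid]] <- tag(bm[bm$edge %in% rk$top$edge, , drop = FALSE])
      mutBottom[[lid]] <- tag(bm[bm$edge %in% rk$bottom$edge, , drop = FALSE])
    }
    res$fitness <- if (length(fitRows))
      do.call(rbind, c(fitRows, list(make.row.names = FALSE))) else NULL
    topMut <- do.call(rbind, c(mutTop, list(make.row.names = FALSE)))
    botMut <- do.call(rbind, c(mutBottom, list(make.row.names = FALSE)))
    res$dnds <- list(
      top = if (!is.null(topMut) && nrow(topMut))
        regionalDndsEnrichment(topMut, config$bootstrapReps) else NULL,
      bottom = if (!is.null(botMut) && nrow(botMut))
        regionalDndsEnrichment(botMut, config$bootstrapReps) else NULL)
    res$branch_mutations <- list(top = topMut, bottom = botMut)
  }
  if (!is.null(res$selection) && !is.null(res$labels) &&
      nrow(res$selection) >= 3L) {
    res$selection_vs_expansion <-
      selectionVsExpansion(res$selection, res$labels)
  }
  res$manifest <- data.frame(
    key = c("seed", "n_records", "n_lineages", "stages"),
    value = c(config$seed, nrow(records),
              length(res$lineages), paste(st, collapse = ",")),
    stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x) && is.data.frame(x))
      writeResultsTable(x, file.path(outDir, f))
    w(res$assignments, "lineages.tsv")
    w(res$labels, "labels.tsv")
    w(res$selection, "selection.tsv")
    w(res$sweeps, "sweeps.tsv")
    w(res$fitness, "fitness.tsv")
    w(res$dnds$top, "dnds_top.tsv")
    w(res$dnds$bottom, "dnds_bottom.tsv")
    w(res$manifest, "manifest.tsv")
  }
  res
}

#' Selection versus clonal expansion
#'
#' Joins per-lineage selection scores with dynamics: Spearman correlation
#' between the Fay & Wu significance score (vs the constant-size null) and
#' fold change (infinite fold changes mapped to the top shared rank),
#' two-sided Mann-Whitney U comparing fold changes of selected (p < alpha)
#' vs nonselected lineages, and the fraction of each group exceeding a range
#' of fold-change cutoffs.
#'
#' @param selection output rows of [testSelection()] (column
#'   \code{p_vs_constant}, \code{score_vs_constant}).
#' @param labels output of [classifyLineages()].
#' @param alpha significance cutoff defining the selected group (default
#'   0.05).
#' @param fcCutoffs fold-change cutoffs for the sweep table.
#' @return List: \code{rho}, \code{rho_p}, \code{abs_rho}, \code{mw_p},
#'   \code{median_fc} (named: selected, nonselected), \code{cutoff_table}
#'   (data.frame \code{cutoff, frac_selected, frac_nonselected}), \code{n}.
#' @export
selectionVsExpansion <- function(selection, labels, alpha = 0.05,
                                 fcCutoffs = c(1, 2, 5, 10, 20, 50, 100)) {
  merged <- merge(selection, labels, by = "lineage_id")
  if (nrow(merged) < 3L) {
    warning("fewer than 3 lineages; selection-vs-expansion undefined")
    return(list(rho = NA_real_, rho_p = NA_real_, abs_rho = NA_real_,
                mw_p = NA_real_, median_fc = c(selected = NA_real_,
                                               nonselected = NA_real_),
                cutoff_table = NULL, n = nrow(merged)))
  }
  fc <- merged$fold_change
  fcRank <- fc
  if (any(is.finite(fc)) && any(is.infinite(fc)))
    fcRank[is.infinite(fc)] <- max(fc[is.finite(fc)]) + 1
  ct <- suppressWarnings(
    stats::cor.test(merged$score_vs_constant, fcRank, method = "spearman",
                    exact = FALSE))
  sel <- merged$p_vs_constant < alpha
  mw <- if (any(sel) && any(!sel))
    suppressWarnings(stats::wilcox.test(fc[sel], fc[!sel],
                                        alternative = "two.sided"))$p.value
  else NA_real_
  cutoff_table <- data.frame(
    cutoff = fcCutoffs,
    frac_selected = vapply(fcCutoffs, function(k)
      if (any(sel)) mean(fc[sel] > k) else NA_real_, numeric(1)),
    frac_nonselected = vapply(fcCutoffs, function(k)
      if (any(!sel)) mean(fc[!sel] > k) else NA_real_, numeric(1)))
  list(rho = unname(ct$estimate), rho_p = ct$p.value,
       abs_rho = abs(unname(ct$estimate)), mw_p = mw,
       median_fc = c(selected = stats::median(fc[sel]),
                     nonselected = stats::median(fc[!sel])),
       cutoff_table = cutoff_table, n = nrow(merged))
}
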