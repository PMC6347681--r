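## Synthetic repertoires with known ground truth: germline V/J references,
## single lineages simulated under a chosen coalescent regime, and full
## multi-subject, multi-timepoint repertoires emulating the study design
## (5 subjects, 8 timepoints; vaccine-responsive lineages drawn from the
## Bolthausen-Sznitman coalescent with high mutation load, persistent
## lineages from the Kingman coalescent with low mutation load).

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.randomOrf <- function(nCodons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, .STOP_CODONS)
  paste(sample(codons, nCodons, replace = TRUE), collapse = "")
}

#' Generate a synthetic germline V/J database
#'
#' Random in-frame V genes (294 nt: FWR1 75, CDR1 24, FWR2 51, CDR2 24,
#' FWR3 114, then 6 nt of CDR3) and J genes (45 nt: 9 nt of CDR3 then FWR4
#' 36), IMGT-style region tiling, reading frame 0, no stop codons anywhere in
#' frame. Region lengths are multiples of 3 so codons never straddle region
#' boundaries.
#'
#' @param nV,nJ number of V and J genes (>= 1).
#' @param seed optional integer seed.
#' @return A \code{germline_db} (as from [readGermlineDb()]), genes named
#'   \code{V1..}, \code{J1..}.
#' @export
generateGermlineDb <- function(nV = 3, nJ = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vlens <- c(FWR1 = 75L, CDR1 = 24L, FWR2 = 51L, CDR2 = 24L, FWR3 = 114L,
             CDR3 = 6L)
  jlens <- c(CDR3 = 9L, FWR4 = 36L)
  vSeqs <- stats::setNames(
    vapply(seq_len(nV), function(i) .randomOrf(sum(vlens) / 3L), character(1)),
    paste0("V", seq_len(nV)))
  jSeqs <- stats::setNames(
    vapply(seq_len(nJ), function(i) .randomOrf(sum(jlens) / 3L), character(1)),
    paste0("J", seq_len(nJ)))
  db <- list(
    vSeqs = vSeqs, jSeqs = jSeqs,
    vRegions = stats::setNames(rep(list(rep(names(vlens), vlens)), nV),
                               names(vSeqs)),
    jRegions = stats::setNames(rep(list(rep(names(jlens), jlens)), nJ),
                               names(jSeqs)),
    frames = stats::setNames(rep(0L, nV), names(vSeqs)))
  class(db) <- "germline_db"
  db
}

## largest-remainder allocation of n items over weights
.allocateCounts <- function(n, w) {
  raw <- n * w / sum(w)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

## choose a derived base at axis position p; forceNonsyn tries to change the
## amino acid given the (gap-free) lineage germline sequence
.pickDerivedBase <- function(p, germSeq, readingFrame, forceNonsyn = FALSE) {
  bases <- c("A", "C", "G", "T")
  ref <- substr(germSeq, p + 1L, p + 1L)
  alts <- setdiff(bases, ref)
  if (!forceNonsyn) return(sample(alts, 1L))
  within <- (p + readingFrame) %% 3L
  start <- p - within
  codon <- strsplit(substr(germSeq, start + 1L, start + 3L), "")[[1]]
  code <- Biostrings::GENETIC_CODE
  aa0 <- code[paste(codon, collapse = "")]
  nonsyn <- alts[vapply(alts, function(b) {
    mut <- codon; mut[within + 1L] <- b
    !identical(unname(code[paste(mut, collapse = "")]), unname(aa0))
  }, logical(1))]
  if (length(nonsyn)) sample(nonsyn, 1L) else sample(alts, 1L)
}

## leaf ids below each edge's child, as a list over edges with mutations
.tipSets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Generate one synthetic lineage
#'
#' Simulates a genealogy of \code{nCells} cells under the chosen regime,
#' drops infinite-sites mutations at rate \code{theta}, assigns each mutation
#' a distinct germline-axis position and derived base, emits the leaf
#' sequences, and collapses identical genotypes so the emitted records are
#' unique sequences. The returned ground-truth SFS is computed on the
#' collapsed sample over callable (non-CDR3) positions, so
#' [buildSFS()] on the emitted records reproduces it exactly.
#'
#' With \code{cdrBias > 0}, every "backbone" branch (an internal branch
#' subtending at least \code{biasCladeFrac} of the leaves -- the stem of an
#' expanded clade, which fitness ranking picks up) additionally carries a
#' Poisson(\code{cdrBias}) number of driver mutations: CDR changes at second
#' codon positions, nonsynonymous in every haplotype context, emulating the
#' affinity-enhancing mutations that drove the expansion. All other
#' mutations are uniform over callable positions with a random derived base.
#'
#' @param regime \code{"kingman"}, \code{"expanding"} or \code{"bsz"}.
#' @param nCells number of sampled cells (leaves before collapsing).
#' @param theta population-scaled mutation rate.
#' @param germ a [GermlineReference-class].
#' @param cdr3Insert junction sequence inserted between the annotated V and J
#'   CDR3 flanks (defines the lineage's CDR3).
#' @param lineageId,subject identifiers for the emitted records.
#' @param timepointWeights named nonnegative weights over timepoint labels;
#'   genotype observations are allocated by largest remainder (default: all
#'   at \code{"D7"}).
#' @param observationsPerGenotype \code{1} (default): each unique genotype is
#'   observed at a single timepoint drawn from the weights -- the pattern of
#'   a transient expansion; \code{"all"}: every genotype is observed at every
#'   weighted timepoint -- the stable pattern of persistent lineages.
#' @param isotypeProbs named probability vector over isotypes (default all
#'   IgM).
#' @param fixedMutations number of derived mutations fixed in the lineage
#'   before the sampled diversification (carried by every member; the
#'   affinity-maturation history of a memory lineage). They raise mutation
#'   density but not within-lineage diversity (default 0).
#' @param cdrBias expected number of driver mutations -- forced
#'   CDR-nonsynonymous changes attached to each backbone branch (the stem of
#'   an expanded clade), emulating the affinity-enhancing mutations that
#'   drove the expansion. Poisson per stem; 0 (default) disables drivers.
#' @param biasCladeFrac minimum subtree fraction defining backbone branches
#'   (default 0.05).
#' @param growthRate expanding-model growth rate.
#' @param seed optional integer seed.
#' @return List: \code{records} (canonical record data.frame of unique
#'   sequences), \code{genealogy} (the uncollapsed simulated \code{phylo}
#'   with \code{mut_counts} and \code{leaf_map}: leaf -> emitted
#'   sequence_id), \code{sfs} (ground-truth [SFS-class] on the collapsed
#'   sample, NULL when fewer than 2 unique genotypes), \code{sites}
#'   (data.frame \code{site, position, derived_base, region, edge, count}),
#'   \code{nUnique}.
#' @export
generateLineage <- function(regime, nCells, theta, germ, cdr3Insert,
                            lineageId = "L1", subject = "S1",
                            timepointWeights = c(D7 = 1),
                            observationsPerGenotype = 1,
                            isotypeProbs = c(IgM = 1),
                            fixedMutations = 0,
                            cdrBias = 0, biasCladeFrac = 0.05,
                            growthRate = defaultGrowthRate(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regime <- match.arg(regime, c("kingman", "expanding", "bsz"))
  axis <- germlineAxis(germ, nchar(cdr3Insert) +
                         sum(germ@vRegions == "CDR3") +
                         sum(germ@jRegions == "CDR3"))
  germSeq <- paste0(germ@vSeq, cdr3Insert, germ@jSeq)  # gap-free lineage germline
  phy <- switch(regime,
    kingman = simulateKingman(nCells),
    expanding = simulateExpanding(nCells, growthRate),
    bsz = simulateBSZ(nCells))
  if (theta > 0) phy <- dropMutations(phy, theta = theta, mode = "rate")
  else { phy$mut_counts <- integer(nrow(phy$edge)); phy$site_edges <- integer(0) }

  callable <- which(axis$callable) - 1L               # 0-based positions
  fixedPos <- integer(0); fixedBase <- character(0)
  if (fixedMutations > 0) {
    fixedPos <- sample(callable, min(fixedMutations, length(callable) %/% 2))
    fixedBase <- vapply(fixedPos, function(p)
      .pickDerivedBase(p, germSeq, germ@readingFrame), character(1))
    callable <- setdiff(callable, fixedPos)
  }
  ## driver sites live at second codon positions of the CDRs: a change there
  ## is nonsynonymous in every haplotype context (no synonymous codon pair
  ## differs only at its second position)
  cdrPos <- which(axis$regions %in% c("CDR1", "CDR2", "CDR3")) - 1L
  cdrPos <- setdiff(cdrPos, fixedPos)
  cdrPos <- cdrPos[(cdrPos + germ@readingFrame) %% 3L == 1L]
  M <- sum(phy$mut_counts)
  budget <- length(callable) - length(cdrPos)   # reserve CDR driver capacity
  if (M > budget) {             # finite amplicon: thin to the site budget
    drop <- sample(rep(seq_along(phy$mut_counts), phy$mut_counts),
                   M - budget)
    for (d in drop) phy$mut_counts[d] <- phy$mut_counts[d] - 1L
    phy$site_edges <- rep(seq_along(phy$mut_counts), phy$mut_counts)
    M <- sum(phy$mut_counts)
  }
  siteEdge <- phy$site_edges
  cnt <- .subtreeLeafCounts(phy)
  backbone <- which(
    cnt[phy$edge[, 2L]] >= max(3L, ceiling(biasCladeFrac * nCells)) &
    phy$edge[, 2L] > length(phy$tip.label))
  ## driver mutations: each backbone branch (the stem of an expanded clade)
  ## carries, with probability cdrBias, a CDR nonsynonymous change -- the
  ## affinity-enhancing mutation that drove the clade's expansion
  biased <- logical(M)
  if (cdrBias > 0 && length(backbone)) {
    drivers <- rep(backbone, stats::rpois(length(backbone), cdrBias))
    if (length(drivers)) {
      phy$mut_counts[drivers] <- phy$mut_counts[drivers] + 1L
      siteEdge <- c(siteEdge, drivers)
      biased <- c(biased, rep(TRUE, length(drivers)))
      M <- M + length(drivers)
      phy$site_edges <- siteEdge
    }
  }
  if (sum(biased) > length(cdrPos)) {   # finite CDRs can fill up
    keep <- sample(which(biased), length(cdrPos))
    biased[] <- FALSE
    biased[keep] <- TRUE
  }
  excess <- M - length(callable)
  if (excess > 0) {   # drivers can push past the amplicon site budget
    dropIdx <- sample(which(!biased), excess)
    for (d in siteEdge[dropIdx])
      phy$mut_counts[d] <- phy$mut_counts[d] - 1L
    keep <- setdiff(seq_len(M), dropIdx)
    siteEdge <- siteEdge[keep]
    biased <- biased[keep]
    M <- M - excess
    phy$site_edges <- siteEdge
  }
  nb <- sum(biased)
  pos <- integer(M)
  if (nb > 0) pos[biased] <- sample(cdrPos, nb)
  if (M - nb > 0)
    pos[!biased] <- sample(setdiff(callable, pos[biased]), M - nb)
  base <- character(M)
  for (s in seq_len(M))
    base[s] <- .pickDerivedBase(pos[s], germSeq, germ@readingFrame,
                                forceNonsyn = biased[s])

  ## leaf genotypes: sites on the root -> leaf path
  tips <- .tipSets(phy)
  inc <- matrix(FALSE, nrow = nCells, ncol = M)
  for (s in seq_len(M)) {
    below <- tips[[phy$edge[siteEdge[s], 2L]]]
    inc[below, s] <- TRUE
  }
  key <- apply(inc, 1L, function(r) paste(which(r), collapse = ","))
  firstLeaf <- which(!duplicated(key))
  nU <- length(firstLeaf)
  uinc <- inc[firstLeaf, , drop = FALSE]
  memberIds <- sprintf("%s.u%03d", lineageId, seq_len(nU))
  leafMap <- memberIds[match(key, key[firstLeaf])]

  ## ground-truth SFS on the collapsed sample, callable positions only
  regionOf <- axis$regions[pos + 1L]
  inSfs <- regionOf != "CDR3"
  ucounts <- colSums(uinc)
  sfs <- NULL
  if (nU >= 2L) {
    cc <- ucounts[inSfs]
    xi <- numeric(nU - 1L)
    tab <- tabulate(cc[cc >= 1L & cc < nU], nbins = nU - 1L)
    xi[seq_along(tab)] <- tab
    sfs <- SFS(nU, xi, fixed = sum(cc == nU) + length(fixedPos))
  }

  seqs <- vapply(seq_len(nU), function(u) {
    sv <- strsplit(germSeq, "")[[1]]
    sv[fixedPos + 1L] <- fixedBase
    on <- which(uinc[u, ])
    sv[pos[on] + 1L] <- base[on]
    paste(sv, collapse = "")
  }, character(1))
  cdr3 <- substr(seqs, axis$cdr3Start + 1L, axis$cdr3End)
  tpw <- timepointWeights[timepointWeights > 0]
  if (identical(observationsPerGenotype, "all")) {
    idx <- rep(seq_len(nU), times = length(tpw))
    tp <- rep(names(tpw), each = nU)
  } else if (identical(as.integer(observationsPerGenotype), 1L)) {
    tpCounts <- .allocateCounts(nU, tpw)
    idx <- seq_len(nU)
    tp <- rep(names(tpw), tpCounts)[sample.int(nU)]
  } else stop("observationsPerGenotype must be 1 or 'all'")
  isotype <- sample(names(isotypeProbs), nU, replace = TRUE,
                    prob = isotypeProbs)
  records <- data.frame(
    sequence_id = memberIds[idx], subject = subject, timepoint = tp,
    sequence = seqs[idx], v_gene = germ@vGene, j_gene = germ@jGene,
    cdr3 = cdr3[idx], isotype = isotype[idx],
    stringsAsFactors = FALSE)
  phy$leaf_map <- leafMap
  sites <- data.frame(site = seq_len(M), position = pos,
                      derived_base = base, region = regionOf,
                      edge = siteEdge, count = ucounts,
                      stringsAsFactors = FALSE)
  if (length(fixedPos))
    sites <- rbind(sites, data.frame(
      site = M + seq_along(fixedPos), position = fixedPos,
      derived_base = fixedBase, region = axis$regions[fixedPos + 1L],
      edge = NA_integer_, count = nU, stringsAsFactors = FALSE))
  list(records = records, genealogy = phy, sfs = sfs, sites = sites,
       nUnique = nU)
}

#' Repertoire design
#'
#' The stated world of the synthetic generator. The \code{"study"} profile
#' mirrors the study scale (5 subjects, 8 timepoints, ~36 vaccine-responsive
#' and ~83 persistent lineages per subject); \code{"tiny"} (the default, used
#' by the test suite) keeps 2 subjects with 5 lineages each. Responsive
#' lineages draw Bolthausen-Sznitman genealogies with high mutation load and
#' class-switched isotypes and are absent before vaccination with a D7 peak;
#' persistent lineages draw Kingman genealogies with low mutation load,
#' mostly-IgM isotypes and flat trajectories; \code{other} lineages expand
#' moderately (between the 2- and 50-fold thresholds).
#'
#' @param profile \code{"tiny"} or \code{"study"}.
#' @param subjects,nResponsive,nPersistent,nOther scalar overrides.
#' @param seed integer seed fixing all randomness of the repertoire.
#' @return A list of class \code{repertoire_design}.
#' @export
repertoireDesign <- function(profile = c("tiny", "study"), subjects = NULL,
                             nResponsive = NULL, nPersistent = NULL,
                             nOther = NULL, seed = 1L) {
  profile <- match.arg(profile)
  base <- switch(profile,
    tiny = list(subjects = 2L, nResponsive = 2L, nPersistent = 2L,
                nOther = 1L,
                sizeRange = list(responsive = c(60L, 120L),
                                 persistent = c(150L, 250L),
                                 other = c(100L, 180L))),
    study = list(subjects = 5L, nResponsive = 36L, nPersistent = 83L,
                 nOther = 10L,
                 sizeRange = list(responsive = c(120L, 1000L),
                                  persistent = c(300L, 800L),
                                  other = c(150L, 400L))))
  if (!is.null(subjects)) base$subjects <- as.integer(subjects)
  if (!is.null(nResponsive)) base$nResponsive <- as.integer(nResponsive)
  if (!is.null(nPersistent)) base$nPersistent <- as.integer(nPersistent)
  if (!is.null(nOther)) base$nOther <- as.integer(nOther)
  design <- c(base, list(
    timepoints = studyTimepoints(),
    regimes = c(responsive = "bsz", persistent = "kingman",
                other = "kingman"),
    observations = list(responsive = 1, persistent = "all", other = 1),
    theta = c(responsive = 6, persistent = 4, other = 8),
    fixedMutations = c(responsive = 12, persistent = 0, other = 4),
    cdrBias = c(responsive = 0.5, persistent = 0, other = 0),
    trajectories = list(
      responsive = c("D-5" = 0, "D-3" = 0, D0 = 0, D1 = 0.02, D4 = 0.18,
                     D7 = 0.50, D9 = 0.20, D11 = 0.10),
      persistent = stats::setNames(rep(1 / 8, 8), studyTimepoints()),
      ## 'other' lineages surface as a single sequence at D0 (enforced in
      ## generateRepertoire), so their count fold change is c(D7)/1
      other = c("D-5" = 0, "D-3" = 0, D0 = 0, D1 = 0.05, D4 = 0.15,
                D7 = 0.60, D9 = 0.12, D11 = 0.08)),
    isotypes = list(
      responsive = c(IgG = 0.75, IgA = 0.20, IgM = 0.05),
      persistent = c(IgM = 0.80, IgD = 0.05, IgA = 0.15),
      other = c(IgM = 0.40, IgG = 0.40, IgA = 0.20)),
    cdr3InsertLengths = c(9L, 12L, 15L, 18L, 21L, 24L),
    seed = as.integer(seed)))
  class(design) <- "repertoire_design"
  design
}

#' Generate a full synthetic repertoire with ground truth
#'
#' Builds every subject's lineages per the design: each lineage gets a
#' distinct (V gene, J gene, CDR3 length) key within its subject (so the
#' generating partition is recoverable by clustering), a genealogy from its
#' regime, and members allocated over timepoints by its class trajectory
#' (largest-remainder, so the designed fold-change thresholds are met
#' exactly: responsive absent before D0, persistent flat, other in between).
#'
#' @param design a [repertoireDesign()].
#' @return List: \code{records} (canonical record data.frame over all
#'   subjects/timepoints), \code{truth} (data.frame \code{lineage_id,
#'   subject, class, regime, theta, n_unique}), \code{membership}
#'   (\code{sequence_id -> true lineage}), \code{lineageData} (per-lineage
#'   output of [generateLineage()]), \code{db} (the \code{germline_db}).
#' @export
generateRepertoire <- function(design = repertoireDesign()) {
  set.seed(design$seed)
  perSubject <- design$nResponsive + design$nPersistent + design$nOther
  lengths_ <- design$cdr3InsertLengths
  nV <- max(3L, ceiling(sqrt(perSubject / length(lengths_))))
  nJ <- max(2L, ceiling(perSubject / (nV * length(lengths_))))
  db <- generateGermlineDb(nV = nV, nJ = nJ)
  keys <- expand.grid(v = names(db$vSeqs), j = names(db$jSeqs),
                      len = lengths_, stringsAsFactors = FALSE)
  records <- list(); truth <- list(); lineageData <- list()
  for (si in seq_len(design$subjects)) {
    subj <- paste0("S", si)
    classes <- rep(c("responsive", "persistent", "other"),
                   c(design$nResponsive, design$nPersistent, design$nOther))
    keyIdx <- sample.int(nrow(keys), length(classes))
    for (li in seq_along(classes)) {
      cls <- classes[li]
      key <- keys[keyIdx[li], ]
      lid <- sprintf("%s-true%03d", subj, li)
      germ <- germlineFor(db, key$v, key$j)
      ## key$len is the junction-insert length; total CDR3 length adds the
      ## germline-annotated V and J flanks
      insert <- paste(sample(c("A", "C", "G", "T"), key$len, replace = TRUE),
                      collapse = "")
      size <- sample(seq(design$sizeRange[[cls]][1],
                         design$sizeRange[[cls]][2]), 1L)
      gen <- generateLineage(
        regime = design$regimes[[cls]], nCells = size,
        theta = design$theta[[cls]], germ = germ, cdr3Insert = insert,
        lineageId = lid, subject = subj,
        timepointWeights = design$trajectories[[cls]],
        observationsPerGenotype = design$observations[[cls]],
        isotypeProbs = design$isotypes[[cls]],
        fixedMutations = design$fixedMutations[[cls]],
        cdrBias = design$cdrBias[[cls]])
      ## guarantee the 'other'/persistent classes are observed at D0
      if (cls != "responsive" &&
          !any(gen$records$timepoint == "D0") && gen$nUnique > 1L) {
        donor <- which(gen$records$timepoint ==
                         names(which.max(table(gen$records$timepoint))))[1L]
        gen$records$timepoint[donor] <- "D0"
      }
      records[[lid]] <- gen$records
      truth[[lid]] <- data.frame(lineage_id = lid, subject = subj,
                                 class = cls,
                                 regime = design$regimes[[cls]],
                                 theta = design$theta[[cls]],
                                 n_unique = gen$nUnique,
                                 stringsAsFactors = FALSE)
      lineageData[[lid]] <- gen
    }
  }
  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  truthDf <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  membership <- unique(data.frame(sequence_id = records$sequence_id,
                                  lineage_id = sub("\\.u[0-9]+$", "",
                                                   records$sequence_id),
                                  stringsAsFactors = FALSE))
  rownames(membership) <- NULL
  list(records = records, truth = truthDf, membership = membership,
       lineageData = lineageData, db = db)
}
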