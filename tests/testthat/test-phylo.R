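test_that("germline-anchored alignment reproduces mutations in place", {
  germ <- fixtureGermline()
  alt <- function(p, axis) setdiff(c("A", "C", "G", "T"),
                                   substr(axis, p + 1, p + 1))[1]
  axis <- germlineAxis(germ, 18)
  lin <- fixtureLineage(mutations = list(
    "2" = list(pos = c(7L, 40L), base = c(alt(7, axis$seq), alt(40, axis$seq)))))
  aln <- alignToGermline(lin)
  expect_equal(rownames(aln$matrix)[1], "germline")
  expect_equal(ncol(aln$matrix), axis$length)
  mm <- which(aln$matrix["m2", ] != aln$matrix["germline", ] &
                aln$matrix["germline", ] != "N")
  expect_equal(aln$coords[mm], c(7L, 40L))
  ## identical members collapse to one row
  expect_equal(nrow(aln$matrix), 1 + 2)  # germline + m1 (=m3 collapsed) + m2
  ## garbage member excluded with warning
  bad <- members(lin)
  bad$sequence[1] <- paste(rep("T", nchar(bad$sequence[1])), collapse = "")
  lin2 <- Lineage("LF2", bad, germ)
  expect_warning(aln2 <- alignToGermline(lin2), "anchor identity")
  expect_false("m1" %in% rownames(aln2$matrix))
})

test_that("NJ recovers the topology of an additive distance matrix", {
  ## build a 4-taxon additive tree ((A,B),(C,D)) in sequence space
  germ <- fixtureGermline()
  axis <- germlineAxis(germ, 18)
  base <- sub("NNNNNN", "AAATTT", axis$seq, fixed = TRUE)
  sv <- strsplit(base, "")[[1]]
  flip <- function(s, pos) {
    s[pos] <- vapply(s[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
    s
  }
  ab <- flip(sv, 1:6)          # shared by A and B
  a <- flip(ab, 10:11); b2 <- flip(ab, 13:14)
  c_ <- flip(sv, 20:21); d <- flip(sv, 23:24)
  rec <- data.frame(
    sequence_id = c("A", "B", "C", "D"), subject = "S1", timepoint = "D7",
    sequence = vapply(list(a, b2, c_, d), paste, character(1), collapse = ""),
    v_gene = "V1", j_gene = "J1",
    cdr3 = substr(base, axis$cdr3Start + 1, axis$cdr3End), isotype = "IgM",
    stringsAsFactors = FALSE)
  lin <- Lineage("L4", rec, germ)
  phy <- buildLineageTree(alignToGermline(lin))
  expect_true(ape::is.rooted(phy))
  ## A and B must be siblings (their MRCA excludes C, D)
  mrca <- ape::getMRCA(phy, c("A", "B"))
  tipsBelow <- ape::extract.clade(phy, mrca)$tip.label
  expect_setequal(tipsBelow, c("A", "B"))
  expect_true(all(phy$edge.length >= 0))
})

test_that("rooting on the germline is idempotent and conserves leaves", {
  lin <- fixtureLineage(nMembers = 3, mutations = list(
    "1" = list(pos = 3L, base = "T"), "2" = list(pos = 9L, base = "C")))
  phy <- buildLineageTree(alignToGermline(lin))
  again <- rootOnGermline(phy)
  expect_equal(again$edge, phy$edge)
  expect_setequal(phy$tip.label, c("germline", "m1", "m2", "m3"))
  ## germline's parent is the root
  root <- length(phy$tip.label) + 1L
  gedge <- phy$edge[phy$edge[, 2] == which(phy$tip.label == "germline"), 1]
  expect_equal(gedge, root)
  expect_error(rootOnGermline(ape::rtree(4)), "germline")
})

test_that("Fitch placement puts mutations on the right branches", {
  germ <- fixtureGermline()
  axis <- germlineAxis(germ, 18)
  alt <- function(p) setdiff(c("A", "C", "G", "T"),
                             substr(axis$seq, p + 1, p + 1))[1]
  ## 6 leaves: clade {m1,m2,m3} shares a mutation at 12; m5 private at 30
  shared <- list(pos = 12L, base = alt(12))
  lin <- fixtureLineage(nMembers = 6, mutations = list(
    "1" = shared,
    "2" = list(pos = c(12L, 22L), base = c(alt(12), alt(22))),
    "3" = list(pos = c(12L, 18L), base = c(alt(12), alt(18))),
    "5" = list(pos = 30L, base = alt(30))))
  aln <- alignToGermline(lin)
  phy <- mapMutationsToBranches(buildLineageTree(aln), aln)
  bm <- phy$branch_mutations
  ## private mutation sits on m5's terminal branch
  m5edge <- which(phy$edge[, 2] == which(phy$tip.label == "m5"))
  expect_equal(bm$edge[bm$position == 30], m5edge)
  ## shared mutation: single change on the clade stem
  expect_equal(sum(bm$position == 12), 1L)
  stem <- bm$edge[bm$position == 12]
  below <- ape::extract.clade(phy, phy$edge[stem, 2])$tip.label
  expect_setequal(below, c("m1", "m2", "m3"))
  ## parsimony optimality per column against exhaustive Sankoff
  for (pos in c(12L, 18L, 30L)) {
    col <- match(pos, aln$coords)
    tipStates <- aln$matrix[phy$tip.label, col]
    best <- oracleParsimonyChanges(phy, tipStates,
                                   aln$matrix["germline", col])
    expect_equal(sum(bm$position == pos), unname(best))
  }
  ## polymorphic columns need at least one change
  expect_true(all(table(bm$position) >= 1))
})

test_that("parsimony counts reproduce SFS site counts on single-origin trees", {
  set.seed(41)
  db <- generateGermlineDb(2, 1, seed = 5)
  germ <- germlineFor(db, "V1", "J1")
  gen <- generateLineage("kingman", 30, 6, germ, cdr3Insert = "ACGTACGTACGT")
  lin <- Lineage("LP", gen$records, germ)
  aln <- alignToGermline(lin)
  sfs <- buildSFS(lin, alignment = aln)
  phy <- mapMutationsToBranches(buildLineageTree(aln), aln)
  ## every called site appears at least once among branch mutations; total
  ## parsimony changes >= number of sites (equality when single-origin)
  called <- attr(sfs, "sites")
  mapped <- phy$branch_mutations
  mapped <- mapped[mapped$region != "CDR3", ]
  expect_true(all(paste(called$position, called$derived_base) %in%
                    paste(mapped$position, mapped$to)))
  expect_gte(nrow(mapped), nrow(called))
})

test_that("Newick import demands matching labels", {
  lin <- fixtureLineage(nMembers = 3, mutations = list(
    "1" = list(pos = 3L, base = "T"), "2" = list(pos = 9L, base = "C")))
  aln <- alignToGermline(lin)
  nw <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((m1:1,m2:1):1,(m3:1,germline:1):1);", nw)
  phy <- buildLineageTree(aln, method = "import", newick = nw)
  expect_setequal(phy$tip.label, c("m1", "m2", "m3", "germline"))
  writeLines("((m1:1,zzz:1):1,(m3:1,germline:1):1);", nw)
  expect_error(buildLineageTree(aln, method = "import", newick = nw), "zzz")
})
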