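test_that("LBI matches the closed form on a two-leaf tree and quadrature
           on random trees", {
  tau <- 0.4; b <- 0.7
  phy <- ape::read.tree(text = sprintf("(A:%f,B:%f);", b, b))
  ann <- localBranchingIndex(phy, tau)
  closed <- tau * (1 - exp(-b / tau)) +
    exp(-b / tau) * tau * (1 - exp(-b / tau))
  expect_equal(unname(ann$lbi["A"]), closed, tolerance = 1e-10)
  expect_equal(unname(ann$lbi["A"]), unname(ann$lbi["B"]))
  ## quadrature oracle on small random trees
  set.seed(51)
  for (i in 1:3) {
    phy <- simulateKingman(6)
    tau <- 0.3
    ann <- localBranchingIndex(phy, tau)
    orc <- oracleLBI(phy, tau)
    expect_equal(unname(ann$lbi), orc, tolerance = 1e-3)
  }
})

test_that("LBI is symmetric on star trees and ranks bushy regions highest", {
  phy <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  ann <- localBranchingIndex(phy, 0.5)
  expect_equal(length(unique(round(ann$lbi[1:5], 12))), 1L)
  ## caterpillar with a dense clade: the node adjacent to the bushy region
  ## has maximal LBI
  cat6 <- ape::read.tree(
    text = "(((A:0.05,B:0.05,C:0.05,D:0.05):0.3,E:1):0.5,F:1.5);")
  ann2 <- localBranchingIndex(cat6, 0.25)
  bushy <- ape::getMRCA(cat6, c("A", "B"))
  parentOfBushy <- cat6$edge[cat6$edge[, 2] == bushy, 1]
  expect_true(unname(which.max(ann2$lbi)) %in% c(bushy, parentOfBushy))
})

test_that("branch ranking is deterministic, disjoint and flags short trees", {
  set.seed(52)
  phy <- simulateKingman(12)
  ann <- localBranchingIndex(phy)
  rk1 <- rankBranchesByFitnessChange(ann, phy, k = 3)
  rk2 <- rankBranchesByFitnessChange(ann, phy, k = 3)
  expect_identical(rk1, rk2)
  expect_length(intersect(rk1$top$edge, rk1$bottom$edge), 0)
  ## all-equal deltas: stable tie-broken order
  ann0 <- ann; ann0$delta[] <- 0
  t1 <- rankBranchesByFitnessChange(ann0, phy, k = 3)
  t2 <- rankBranchesByFitnessChange(ann0, phy, k = 3)
  expect_identical(t1$top$edge, t2$top$edge)
  ## fewer than 2k branches: returns all, flagged
  tiny <- ape::read.tree(text = "(A:1,B:1);")
  annT <- localBranchingIndex(tiny, 0.5)
  rkT <- rankBranchesByFitnessChange(annT, tiny, k = 3,
                                     excludeGermline = FALSE)
  expect_true(isTRUE(attr(rkT, "short")))
})

test_that("the stem of a dominant expanding clade is top-ranked", {
  ## one big recent clade vs scattered singles
  txt <- "(((A:.02,B:.02,C:.02,D:.02,E:.02,F:.02):.02,G:1):.5,(H:1,I:1):.5);"
  phy <- ape::read.tree(text = txt)
  ann <- localBranchingIndex(phy, 0.1)
  rk <- rankBranchesByFitnessChange(ann, phy, k = 1, excludeGermline = FALSE)
  stemChild <- phy$edge[rk$top$edge, 2]
  tips <- ape::extract.clade(phy, stemChild)$tip.label
  ## the top branch leads into the expanding region (A-F), away from H, I
  expect_true(all(c("A", "B", "C", "D", "E", "F") %in% tips))
  expect_false(any(c("H", "I") %in% tips))
})

test_that("codon effects follow the genetic code and unknown conventions", {
  parent <- strsplit("GCTAAA", "")[[1]]
  regions <- rep("FWR1", 6)
  expect_equal(classifyCodonEffect(2, "C", parent, regions), "synonymous")  # GCT->GCC Ala
  expect_equal(classifyCodonEffect(1, "T", parent, regions), "nonsynonymous") # GCT->GTT Val
  parentN <- parent; parentN[1] <- "N"
  expect_equal(classifyCodonEffect(2, "C", parentN, regions), "unknown")
  ## codon spanning the CDR3 boundary
  regB <- c("FWR3", "FWR3", "CDR3", "CDR3", "CDR3", "CDR3")
  expect_equal(classifyCodonEffect(1, "T", parent, regB), "unknown")
})

test_that("regional dN/dS normalization and Fisher tests behave", {
  ## proportional distribution: enrichment 1 everywhere measurable
  mut <- rbind(
    data.frame(lineage_id = "L1", region = rep(c("CDR1", "FWR1"), each = 8),
               effect = rep(rep(c("nonsynonymous", "synonymous"), c(6, 2)), 2)),
    data.frame(lineage_id = "L2", region = rep(c("CDR1", "FWR1"), each = 8),
               effect = rep(rep(c("nonsynonymous", "synonymous"), c(6, 2)), 2)))
  out <- regionalDndsEnrichment(mut, bootstrapReps = 20)
  expect_equal(out$enrichment[out$region == "CDR1"], 1)
  expect_equal(out$enrichment[out$region == "FWR1"], 1)
  expect_true(all(is.na(out$enrichment[out$region == "CDR2"])))
  ## all nonsyn concentrated in CDR3, syn uniform: CDR3 > 1, FWRs < 1
  mut2 <- data.frame(
    lineage_id = "L1",
    region = c(rep("CDR3", 12), rep(c("FWR1", "FWR2", "FWR3"), each = 4)),
    effect = c(rep("nonsynonymous", 12),
               rep(c("nonsynonymous", "synonymous"), 6)))
  mut2$effect[mut2$region == "CDR3"][1:2] <- "synonymous"
  out2 <- regionalDndsEnrichment(mut2, bootstrapReps = 20)
  expect_gt(out2$enrichment[out2$region == "CDR3"], 1)
  expect_lt(out2$enrichment[out2$region == "FWR1"], 1)
  pooled <- cdrFwrEnrichment(mut2)
  expect_gt(pooled["CDR"], 1)
  expect_lt(pooled["FWR"], 1)
  ## unknown effects are ignored
  mut3 <- rbind(mut, data.frame(lineage_id = "L1", region = "CDR1",
                                effect = "unknown"))
  expect_equal(regionalDndsEnrichment(mut3, bootstrapReps = 5)$n_nonsyn,
               regionalDndsEnrichment(mut, bootstrapReps = 5)$n_nonsyn)
})

test_that("bootstrap SD shrinks as lineages accumulate", {
  set.seed(53)
  mkMut <- function(k) do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(lineage_id = paste0("L", i),
               region = sample(c("CDR1", "FWR1"), 12, TRUE),
               effect = sample(c("nonsynonymous", "synonymous"), 12, TRUE,
                               prob = c(0.7, 0.3)))))
  sdSmall <- regionalDndsEnrichment(mkMut(8), bootstrapReps = 60)
  sdBig <- regionalDndsEnrichment(mkMut(80), bootstrapReps = 60)
  i <- which(sdSmall$region == "CDR1")
  expect_lt(sdBig$bootstrap_sd[i], sdSmall$bootstrap_sd[i])
})
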