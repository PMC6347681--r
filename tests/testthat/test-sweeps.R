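## Build a "hard sweep" clade as Newick: a dominant subclade (90% of the
## leaves) hanging off a heavy stem, plus minority outsiders -- the classic
## post-sweep genealogy.
sweptCladeNewick <- function(m, label) {
  nBig <- round(0.98 * m); nSmall <- m - nBig
  big <- paste0("(", paste0(label, "b", seq_len(nBig), ":0.05",
                            collapse = ","), "):0.6")
  small <- paste0(label, "s", seq_len(nSmall), ":0.65")
  paste0("(", big, ",", paste(small, collapse = ","), "):0.3")
}

## chimeric lineage: two independently swept clades on a shared stem
chimericFixture <- function(m = 300, sharedMut = 5L, stemMut = 30L) {
  txt <- paste0("((", sweptCladeNewick(m, "A"), ",",
                sweptCladeNewick(m, "B"), "):0.2,germline:1.0);")
  phy <- ape::read.tree(text = txt)
  phy$mut_counts <- integer(nrow(phy$edge))
  ntip <- length(phy$tip.label)
  ## shared stem: edge above the MRCA of everything
  all_mrca <- ape::getMRCA(phy, grep("germline", phy$tip.label,
                                     invert = TRUE, value = TRUE))
  phy$mut_counts[phy$edge[, 2] == all_mrca] <- sharedMut
  for (lab in c("A", "B")) {
    big <- grep(paste0("^", lab, "b"), phy$tip.label)
    stemNode <- ape::getMRCA(phy, phy$tip.label[big])
    phy$mut_counts[phy$edge[, 2] == stemNode] <- stemMut
    ## a singleton on every 20th big leaf keeps the spectrum realistic
    leafEdges <- which(phy$edge[, 2] %in% big[seq(1, length(big), by = 20)])
    phy$mut_counts[leafEdges] <- 1L
  }
  phy$site_edges <- rep(seq_along(phy$mut_counts), phy$mut_counts)
  phy
}

test_that("countSweeps counts selected calls and empty input gives zero", {
  calls <- data.frame(node = 1:3, clade_size = c(60, 55, 80),
                      S = c(5, 8, 2), H = 0, h_star = 0,
                      p = c(0.5, 1e-4, 0.9),
                      selected = c(FALSE, TRUE, FALSE))
  expect_equal(countSweeps(calls), 1L)
  expect_equal(countSweeps(calls[0, ]), 0L)
})

test_that("chimeric two-sweep lineage yields exactly two non-nested calls
           sharing stem mutations", {
  set.seed(61)
  phy <- chimericFixture()
  calls <- detectSelectedSubclones(phy, sweepConfig())
  expect_equal(countSweeps(calls), 2L)
  sel <- calls[calls$selected, ]
  ## the two calls are the A and B sweep clades (non-nested by construction;
  ## detectSelectedSubclones asserts non-nesting internally)
  tipsOf <- function(node) ape::extract.clade(phy, node)$tip.label
  labs <- vapply(sel$node, function(nd)
    unique(substr(tipsOf(nd), 1, 1)), character(1))
  expect_setequal(labs, c("A", "B"))
  ## both selected clades sit below the mutation-bearing shared stem:
  ## they share those mutations, acquired before branching
  all_mrca <- ape::getMRCA(phy, grep("germline", phy$tip.label,
                                     invert = TRUE, value = TRUE))
  expect_true(all(phy$mut_counts[phy$edge[, 2] == all_mrca] > 0))
})

test_that("a single swept lineage is detected and a mutation-free one is not", {
  set.seed(62)
  txt <- paste0("(", sweptCladeNewick(400, "A"), ",germline:1.0);")
  phy <- ape::read.tree(text = txt)
  phy$mut_counts <- integer(nrow(phy$edge))
  big <- grep("^Ab", phy$tip.label)
  stemNode <- ape::getMRCA(phy, phy$tip.label[big])
  phy$mut_counts[phy$edge[, 2] == stemNode] <- 30L
  phy$mut_counts[which(phy$edge[, 2] %in% big[1:20])] <- 1L
  calls <- detectSelectedSubclones(phy, sweepConfig())
  expect_gte(countSweeps(calls), 1L)
  ## without mutations every clade is p = 1
  phy$mut_counts[] <- 0L
  calls0 <- detectSelectedSubclones(phy, sweepConfig(replicates = 100))
  expect_equal(countSweeps(calls0), 0L)
})

test_that("calibration is vacuous at target 1 and monotone in the target", {
  set.seed(63)
  cfgTest <- sweepConfig(replicates = 150)
  cfgTest$targetFdr <- 1
  a1 <- calibrateAlpha(c(150L, 250L), nLineages = 12, theta = 8,
                       config = cfgTest,
                       alphaGrid = c(0.05, 0.01, 0.001))
  expect_equal(as.numeric(a1), 0.05)
  ## reuse the same minp draw logic: smaller target cannot raise alpha
  minp <- attr(a1, "minp")
  rateAt <- function(a) mean(minp < a)
  expect_true(rateAt(0.001) <= rateAt(0.01))
})

test_that("sweep-size correlation equals the direct moment formula", {
  set.seed(64)
  counts <- c(0, 1, 1, 2, 3, 5)
  sizes <- c(120, 300, 350, 800, 1500, 2600)
  out <- sweepSizeCorrelation(counts, sizes)
  expect_equal(out$r, oraclePearson(counts, sizes), tolerance = 1e-12)
  ## perfectly linear: r = 1
  expect_equal(sweepSizeCorrelation(1:5, (1:5) * 10)$r, 1)
  ## zero variance: undefined with warning
  expect_warning(und <- sweepSizeCorrelation(c(1, 1, 1), c(5, 6, 7)))
  expect_true(is.na(und$r))
  ## random fixtures against the oracle
  for (i in 1:5) {
    x <- rpois(10, 2); y <- rnorm(10, 100, 20)
    if (sd(x) == 0) next
    expect_equal(sweepSizeCorrelation(x, y)$r, oraclePearson(x, y),
                 tolerance = 1e-12)
  }
})
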