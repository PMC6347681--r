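test_that("somatic mutation calling excludes CDR3 and N and flags low coverage", {
  germ <- fixtureGermline()
  vlen <- nchar(germ@vSeq)
  ## member 2: V mutation at position 30 (A->G forced); member 3: CDR3 change
  axis <- germlineAxis(germ, 18)
  ref30 <- substr(axis$seq, 31, 31)
  alt30 <- setdiff(c("A", "C", "G", "T"), ref30)[1]
  cdr3pos <- vlen - 3L       # inside the V CDR3 flank
  altc <- setdiff(c("A", "C", "G", "T"), substr(axis$seq, cdr3pos + 1, cdr3pos + 1))[1]
  lin <- fixtureLineage(mutations = list(
    "2" = list(pos = 30L, base = alt30),
    "3" = list(pos = cdr3pos, base = altc)))
  muts <- callSomaticMutations(lin)
  expect_equal(attr(muts, "n"), 3L)
  expect_equal(nrow(muts), 1L)            # CDR3 change not reported
  expect_equal(muts$position, 30L)
  expect_equal(muts$germline_base, ref30)
  expect_equal(muts$derived_base, alt30)
  ## member identical to germline contributes no rows
  expect_false("m1" %in% muts$sequence_id)
})

test_that("buildSFS counts derived alleles over unique sequences", {
  germ <- fixtureGermline()
  ## members carry private CDR3-junction changes (positions 61-63 of the
  ## axis) so each is a distinct unique sequence without touching callable
  ## positions -- the junctional uniqueness of real repertoires
  alt <- function(p) setdiff(c("A", "C", "G", "T"),
                             substr(germ@vSeq, p + 1, p + 1))[1]
  ## n = 4; one mutation shared by 3 members -> xi = {3: 1}
  lin <- fixtureLineage(nMembers = 4, mutations = list(
    "1" = list(pos = 10L, base = alt(10)),
    "2" = list(pos = c(10L, 61L), base = c(alt(10), "C")),
    "3" = list(pos = c(10L, 62L), base = c(alt(10), "C")),
    "4" = list(pos = 63L, base = "C")))
  sfs <- buildSFS(lin)
  expect_s4_class(sfs, "SFS")
  expect_equal(sampleSize(sfs), 4L)
  expect_equal(xiCounts(sfs), c(0, 0, 1))
  expect_equal(segSites(sfs), 1)
  ## two derived bases at one position in disjoint member sets: two sites
  b <- setdiff(c("A", "C", "G", "T"), substr(germ@vSeq, 11, 11))
  lin2 <- fixtureLineage(nMembers = 4, mutations = list(
    "1" = list(pos = 10L, base = b[1]),
    "2" = list(pos = c(10L, 61L), base = c(b[1], "C")),
    "3" = list(pos = c(10L, 62L), base = c(b[2], "C")),
    "4" = list(pos = 63L, base = "C")))
  sfs2 <- buildSFS(lin2)
  expect_equal(segSites(sfs2), 2)
  expect_equal(xiCounts(sfs2), c(1, 1, 0))
  sites <- attr(sfs2, "sites")
  expect_equal(nrow(sites), 2L)
  expect_setequal(sites$count, c(1L, 2L))
  ## mutation in all members: excluded from xi, listed as fixed
  lin3 <- fixtureLineage(nMembers = 3, mutations = list(
    "1" = list(pos = 5L, base = alt(5)),
    "2" = list(pos = c(5L, 61L), base = c(alt(5), "C")),
    "3" = list(pos = c(5L, 62L), base = c(alt(5), "C"))))
  sfs3 <- buildSFS(lin3)
  expect_equal(segSites(sfs3), 0)
  expect_equal(fixedSites(sfs3), 1)
})

test_that("binSFS assigns mass by frequency and conserves it", {
  ## all mass at i/n = 0.75 with edges (0.5, 0.9): middle bin gets 1
  sfs <- SFS(4, xi = c("3" = 5))
  m <- binSFS(sfs, c(0.5, 0.9))
  expect_equal(unname(m), c(0, 1, 0))
  expect_equal(sum(m), 1)
  ## raw mode: uniform xi -> bin masses proportional to counts in bins
  sfs2 <- SFS(11, xi = rep(1, 10))
  m2 <- binSFS(sfs2, c(0.25, 0.5, 0.75), normalize = FALSE)
  ## freqs i/11: bins (0,.25]: i=1,2 ; (.25,.5]: 3,4,5 ; (.5,.75]: 6,7,8 ; rest 9,10
  expect_equal(unname(m2), c(2, 3, 3, 2))
  ## empty spectrum flagged
  m3 <- binSFS(SFS(5), c(0.5))
  expect_true(isTRUE(attr(m3, "empty")))
  expect_error(binSFS(sfs, c(0.9, 0.5)), "increasing")
})

test_that("averaged spectra have correct mean and SEM", {
  a <- SFS(10, xi = c("1" = 4))          # all mass in lowest bin
  b <- SFS(10, xi = c("9" = 4))          # all mass at 0.9
  avg <- averageSFS(list(a, b), binEdges = c(0.5))
  expect_equal(unname(avg$mean), c(0.5, 0.5))
  expect_equal(avg$k, 2L)
  avg2 <- averageSFS(list(a, a, a), binEdges = c(0.5))
  expect_equal(unname(avg2$sem), c(0, 0))
})

test_that("generator SFS round-trips through mutation calling exactly", {
  set.seed(14)
  db <- generateGermlineDb(2, 1, seed = 3)
  germ <- germlineFor(db, "V1", "J1")
  for (regime in c("kingman", "bsz")) {
    gen <- generateLineage(regime, 60, 6, germ, cdr3Insert = "ACGTACGTACGT",
                           fixedMutations = 5, cdrBias = 1)
    lin <- Lineage("L1", gen$records, germ)
    sfs <- buildSFS(lin)
    expect_equal(sampleSize(sfs), sampleSize(gen$sfs))
    expect_equal(xiCounts(sfs), xiCounts(gen$sfs))
    expect_equal(fixedSites(sfs), fixedSites(gen$sfs))
  }
})
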