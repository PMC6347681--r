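test_that("synthetic germline databases are deterministic, in frame and tiled", {
  db1 <- generateGermlineDb(3, 2, seed = 71)
  db2 <- generateGermlineDb(3, 2, seed = 71)
  expect_identical(db1, db2)
  expect_equal(length(db1$vSeqs), 3L)
  for (g in names(db1$vSeqs)) {
    v <- db1$vSeqs[[g]]
    expect_equal(nchar(v), length(db1$vRegions[[g]]))
    ## region order and 7-region map ending mid-CDR3
    expect_equal(unique(db1$vRegions[[g]]),
                 c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3"))
    ## no stop codons anywhere in frame 0
    codons <- substring(v, seq(1, nchar(v) - 2, 3), seq(3, nchar(v), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
  ## FASTA bytes identical under the same seed
  d <- withr::local_tempdir()
  writeGermlineDb(db1, file.path(d, "v1.fa"), file.path(d, "j1.fa"),
                  file.path(d, "r1.bed"))
  writeGermlineDb(db2, file.path(d, "v2.fa"), file.path(d, "j2.fa"),
                  file.path(d, "r2.bed"))
  expect_identical(readLines(file.path(d, "v1.fa")),
                   readLines(file.path(d, "v2.fa")))
})

test_that("zero mutation rate reproduces the germline plus lineage CDR3", {
  db <- generateGermlineDb(2, 1, seed = 72)
  germ <- germlineFor(db, "V1", "J1")
  gen <- generateLineage("kingman", 12, theta = 0, germ,
                         cdr3Insert = "ACGTACGTACGT")
  expect_equal(gen$nUnique, 1L)      # all cells identical
  expect_equal(unique(gen$records$sequence),
               paste0(germ@vSeq, "ACGTACGTACGT", germ@jSeq))
  expect_equal(unique(nchar(gen$records$cdr3)),
               12L + sum(germ@vRegions == "CDR3") + sum(germ@jRegions == "CDR3"))
})

test_that("same-key lineages with separated CDR3s are recovered by clustering", {
  ## ten lineages sharing V/J and CDR3 length, inserts >= 3 mismatches apart
  set.seed(73)
  db <- generateGermlineDb(2, 1, seed = 73)
  germ <- germlineFor(db, "V1", "J1")
  inserts <- c("AAAAAAAAA", "AAATTTAAA", "CCCAAACCC", "GGGGGGGGG",
               "TTTTTTTTT", "ACACACACA", "GTGTGTGTG", "CAGCAGCAG",
               "TTCTTCTTC", "GAAGAAGAA")
  recs <- do.call(rbind, lapply(seq_along(inserts), function(i) {
    generateLineage("kingman", 25, 3, germ, cdr3Insert = inserts[i],
                    lineageId = paste0("T", i))$records
  }))
  memb <- singleLinkageCluster(recs, clusterConfig(scope = "cdr3_only"))
  truth <- sub("\\.u.*$", "", recs$sequence_id)
  expect_equal(length(unique(memb)), 10L)
  expect_true(all(tapply(truth, memb, function(x) length(unique(x))) == 1))
})

test_that("generated repertoires are deterministic and internally consistent", {
  rep1 <- generateRepertoire(repertoireDesign("tiny", seed = 5))
  rep2 <- generateRepertoire(repertoireDesign("tiny", seed = 5))
  expect_identical(rep1$records, rep2$records)
  expect_identical(rep1$truth, rep2$truth)
  ## responsive lineages are absent before vaccination
  respIds <- rep1$truth$lineage_id[rep1$truth$class == "responsive"]
  respRows <- rep1$records[sub("\\.u[0-9]+$", "",
                               rep1$records$sequence_id) %in% respIds, ]
  expect_false(any(respRows$timepoint %in% c("D-5", "D-3", "D0")))
  ## per-timepoint fractional abundances sum to 1
  mem <- rep1$records
  mem$lineage_id <- sub("\\.u[0-9]+$", "", mem$sequence_id)
  tr <- abundanceTrajectories(mem[, c("sequence_id", "subject", "timepoint",
                                      "lineage_id")])
  sums <- tapply(tr$fraction, paste(tr$subject, tr$timepoint), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ## isotype profiles: responsive mostly class-switched, persistent mostly IgM
  persIds <- rep1$truth$lineage_id[rep1$truth$class == "persistent"]
  persRows <- rep1$records[mem$lineage_id %in% persIds, ]
  expect_gt(mean(persRows$isotype %in% c("IgM", "IgD")), 0.5)
  expect_gt(mean(respRows$isotype %in% c("IgG", "IgA", "IgE")), 0.5)
})

test_that("mutation densities contrast responsive vs persistent classes", {
  rep <- generateRepertoire(repertoireDesign("tiny", seed = 6))
  mem <- rep$records
  mem$lineage_id <- sub("\\.u[0-9]+$", "", mem$sequence_id)
  dens <- function(cls) {
    ids <- rep$truth$lineage_id[rep$truth$class == cls]
    rows <- mem[mem$lineage_id %in% ids, ]
    rows <- rows[!duplicated(rows$sequence_id), ]
    mean(vapply(seq_len(nrow(rows)), function(i) {
      lid <- rows$lineage_id[i]
      germ <- germline(Lineage(lid, rows[i, , drop = FALSE],
                               germlineFor(rep$db, rows$v_gene[i],
                                           rows$j_gene[i])))
      mutationDensity(rows$sequence[i], germ)
    }, numeric(1)))
  }
  expect_gt(dens("responsive"), 2 * dens("persistent"))
})
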