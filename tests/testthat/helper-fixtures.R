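## Shared fixtures and independent oracles for the test suite.

## tiny deterministic germline database (fixed, not random)
fixtureGermlineDb <- function() {
  v <- paste0(
    strrep("ATG", 5),              # FWR1 15
    strrep("GCT", 2),              # CDR1 6
    strrep("CTG", 4),              # FWR2 12
    strrep("AGC", 2),              # CDR2 6
    strrep("ACC", 5),              # FWR3 15
    "TGTGCG")                      # CDR3 flank 6
  j <- paste0("GATTAC", strrep("GGC", 4))  # CDR3 6 + FWR4 12
  db <- list(
    vSeqs = c(V1 = v), jSeqs = c(J1 = j),
    vRegions = list(V1 = rep(c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3"),
                             c(15, 6, 12, 6, 15, 6))),
    jRegions = list(J1 = rep(c("CDR3", "FWR4"), c(6, 12))),
    frames = c(V1 = 0L))
  class(db) <- "germline_db"
  db
}

fixtureGermline <- function() germlineFor(fixtureGermlineDb(), "V1", "J1")

## a small lineage built by mutating the germline axis at given positions
fixtureLineage <- function(mutations = list(), nMembers = 3,
                           insert = "AAATTT", timepoint = "D7",
                           germ = fixtureGermline()) {
  axis <- germlineAxis(germ, nchar(insert) + sum(germ@vRegions == "CDR3") +
                         sum(germ@jRegions == "CDR3"))
  base <- sub(strrep("N", nchar(insert)), insert, axis$seq, fixed = TRUE)
  seqs <- vapply(seq_len(nMembers), function(m) {
    sv <- strsplit(base, "")[[1]]
    mm <- mutations[[as.character(m)]]
    if (!is.null(mm)) sv[mm$pos + 1L] <- mm$base
    paste(sv, collapse = "")
  }, character(1))
  rec <- data.frame(
    sequence_id = paste0("m", seq_len(nMembers)), subject = "S1",
    timepoint = timepoint, sequence = seqs, v_gene = "V1", j_gene = "J1",
    cdr3 = substr(seqs, axis$cdr3Start + 1L, axis$cdr3End),
    isotype = "IgM", stringsAsFactors = FALSE)
  Lineage("LF1", rec, germ)
}

## ---- independent oracles --------------------------------------------------

## brute-force single-linkage: connected components over the full threshold
## graph via repeated closure (no union-find, no bucketing)
oracleSingleLinkage <- function(strings, cutoff) {
  n <- length(strings)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- strsplit(strings[i], "")[[1]]
    b <- strsplit(strings[j], "")[[1]]
    adj[i, j] <- mean(a == b) >= cutoff
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cur
      frontier <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                          is.na(comp))
    }
  }
  comp
}

## two-sided Fisher exact p by exhaustive hypergeometric enumeration
oracleFisherP <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  lo <- max(0L, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)),
    numeric(1))
  pObs <- probs[a - lo + 1L]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Spearman/Pearson by the direct formulas (ties via midranks)
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## LBI by numeric quadrature: integrate exp(-d(u, node)/tau) along every
## edge of the tree, distances computed on the tree metric
oracleLBI <- function(phy, tau, nSteps = 4000) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  ## node-to-node distance matrix via ape
  D <- ape::dist.nodes(phy)
  out <- numeric(nn)
  for (v in seq_len(nn)) {
    total <- 0
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      len <- phy$edge.length[e]
      if (len == 0) next
      ## point u at distance s from child along the edge; d(v,u) piecewise
      s <- (seq_len(nSteps) - 0.5) / nSteps * len
      dv <- pmin(D[v, ch] + s, D[v, p] + (len - s))
      total <- total + sum(exp(-dv / tau)) * (len / nSteps)
    }
    out[v] <- total
  }
  out
}

## exhaustive small-parsimony: minimum number of changes for one column over
## all root-state assignments consistent with a fixed root state
oracleParsimonyChanges <- function(phy, tipStates, rootState) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  bases <- c("A", "C", "G", "T")
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  cost <- matrix(Inf, nn, 4, dimnames = list(NULL, bases))
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(ntip))
    cost[i, ] <- if (tipStates[i] == "N") 0 else
      ifelse(bases == tipStates[i], 0, Inf)
  for (nd in unique(po$edge[, 1L])) {
    for (b in 1:4) {
      tot <- 0
      for (ch in kids[[as.character(nd)]])
        tot <- tot + min(cost[ch, ] + (bases != bases[b]))
      cost[nd, b] <- tot
    }
  }
  cost[ntip + 1L, rootState]
}
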