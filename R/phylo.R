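## Lineage phylogenetics: germline-anchored alignment, a neighbor-joining
## tree builder (with Newick import for externally built trees), germline
## rooting, and parsimony mapping of mutations onto branches.

#' Align lineage members to the germline axis
#'
#' Members of a lineage share V gene, J gene and CDR3 length by construction,
#' so each member is anchored to the germline axis (V ++ CDR3 junction ++ J)
#' by ungapped positional alignment: the package assumes point mutations only
#' (indels are out of scope). Members whose V+J anchor identity to the
#' germline falls below \code{minAnchorIdentity}, or whose length does not
#' match the axis, are excluded with a warning.
#'
#' The same sequence observed at several timepoints is one unique sequence:
#' rows are collapsed to distinct nucleotide sequences (the convention used
#' for site frequency spectra and phylogenies, which pool a lineage's unique
#' sequences across timepoints).
#'
#' @param lineage a [Lineage-class].
#' @param minAnchorIdentity minimum V+J identity to the germline (default
#'   0.5).
#' @param collapseIdentical collapse members with identical sequences to one
#'   row (default TRUE), keeping the first member's id as representative.
#' @return A \code{lineage_alignment}: list with \code{matrix} (character
#'   matrix, rows = \code{"germline"} then member ids, columns = axis
#'   positions), \code{coords} (0-based germline axis coordinate per column),
#'   \code{regions}, \code{callable} (positions usable for mutation calling:
#'   germline-covered, non-CDR3), \code{germ}, \code{excluded} and
#'   \code{representative} (member id -> alignment row id).
#' @export
alignToGermline <- function(lineage, minAnchorIdentity = 0.5,
                            collapseIdentical = TRUE) {
  germ <- germline(lineage)
  axis <- germlineAxis(germ, cdr3Length(lineage))
  m <- members(lineage)
  repMap <- stats::setNames(m$sequence_id[match(m$sequence, m$sequence)],
                            m$sequence_id)
  if (collapseIdentical) m <- m[!duplicated(m$sequence), , drop = FALSE]
  ok <- nchar(m$sequence) == axis$length
  if (any(!ok))
    warning(sum(!ok), " member(s) excluded: length differs from the ",
            "germline axis (indels are not modeled)")
  rows <- strsplit(toupper(m$sequence[ok]), "")
  germRow <- strsplit(axis$seq, "")[[1]]
  anchor <- axis$callable | (axis$regions == "CDR3" & germRow != "N")
  anchorId <- vapply(rows, function(s) {
    cmp <- anchor & s != "N"
    if (!any(cmp)) return(0)
    mean(s[cmp] == germRow[cmp])
  }, numeric(1))
  low <- anchorId < minAnchorIdentity
  if (any(low))
    warning(sum(low), " member(s) excluded: V/J anchor identity below ",
            minAnchorIdentity)
  keep <- which(ok)[!low]
  mat <- do.call(rbind, c(list(germRow), rows[!low]))
  rownames(mat) <- c("germline", m$sequence_id[keep])
  structure(list(matrix = mat, coords = seq_len(ncol(mat)) - 1L,
                 regions = axis$regions, callable = axis$callable,
                 germ = germ, cdr3Start = axis$cdr3Start,
                 cdr3End = axis$cdr3End,
                 excluded = setdiff(m$sequence_id, m$sequence_id[keep]),
                 representative = repMap),
            class = "lineage_alignment")
}

## pairwise Hamming distance fraction over non-N columns
.hammingDist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  isN <- mat == "N"
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      use <- !isN[i, ] & !isN[j, ]
      d[i, j] <- d[j, i] <- if (any(use)) mean(mat[i, use] != mat[j, use]) else 0
    }
  }
  d
}

#' Build a lineage phylogeny
#'
#' \code{method = "nj"}: neighbor-joining (\pkg{ape}) on pairwise Hamming
#' distances over alignment columns (N treated as missing), negative branch
#' lengths clamped to 0, then rooted on the germline. \code{method =
#' "import"}: parse a user-provided Newick tree whose leaf labels match the
#' alignment rows (a documented entry point for externally built
#' maximum-likelihood trees).
#'
#' @param alignment a \code{lineage_alignment} from [alignToGermline()].
#' @param method \code{"nj"} or \code{"import"}.
#' @param newick path to a Newick file (\code{method = "import"}).
#' @return A rooted \code{phylo} whose leaves are the member ids plus
#'   \code{"germline"}.
#' @export
buildLineageTree <- function(alignment, method = c("nj", "import"),
                             newick = NULL) {
  method <- match.arg(method)
  if (method == "import") {
    if (is.null(newick)) stop("method = 'import' requires a newick path")
    phy <- readNewickTree(newick)
    orphans <- setdiff(phy$tip.label, rownames(alignment$matrix))
    missing <- setdiff(rownames(alignment$matrix), phy$tip.label)
    if (length(orphans) || length(missing))
      stop("imported tree labels do not match the alignment; orphans: ",
           paste(orphans, collapse = ", "), "; missing: ",
           paste(missing, collapse = ", "))
    return(rootOnGermline(phy))
  }
  if (nrow(alignment$matrix) < 3L)
    stop("need at least 3 rows (germline + 2 members) to build a tree")
  d <- .hammingDist(alignment$matrix)
  phy <- ape::nj(stats::as.dist(d))
  phy$edge.length[phy$edge.length < 0] <- 0
  rootOnGermline(phy)
}

#' Root a genealogy on its germline leaf
#'
#' Re-roots the tree on the edge adjacent to the \code{"germline"} leaf so
#' the germline becomes the outgroup; the ancestral state at the root is then
#' the germline sequence. Idempotent on trees already rooted this way.
#'
#' @param genealogy a \code{phylo} containing a leaf labeled
#'   \code{"germline"}.
#' @return A rooted \code{phylo} with the same leaf set.
#' @export
rootOnGermline <- function(genealogy) {
  if (!"germline" %in% genealogy$tip.label)
    stop("tree has no 'germline' leaf")
  if (ape::is.rooted(genealogy)) {
    root <- length(genealogy$tip.label) + 1L
    gtip <- which(genealogy$tip.label == "germline")
    already <- any(genealogy$edge[, 1L] == root & genealogy$edge[, 2L] == gtip)
    if (already) return(genealogy)
  }
  ape::root(genealogy, outgroup = "germline", resolve.root = TRUE)
}

## rooted in the structural sense: exactly one basal node (ape::is.rooted
## additionally requires a binary root, which coalescent trees with a
## multifurcating root legitimately violate)
.hasSingleRoot <- function(phy) {
  length(setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])) == 1L
}

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L)
.BIT_BASE <- c("A", "C", "G", "T")   # lowest set bit 1,2,4,8 -> base

## lowest set bit -> base index (1..4); x in 1..15
.lowBase <- function(x) {
  ifelse(bitwAnd(x, 1L) > 0L, 1L,
  ifelse(bitwAnd(x, 2L) > 0L, 2L,
  ifelse(bitwAnd(x, 4L) > 0L, 3L, 4L)))
}

#' Map mutations onto branches by parsimony
#'
#' Fitch parsimony per alignment column with the root state fixed to the
#' germline base (when compatible with the column's most-parsimonious sets):
#' ancestral states are reconstructed bottom-up, then assigned top-down
#' preferring the parent's state, which breaks ties toward the germline and
#' minimizes early changes. Each state change is assigned to the branch where
#' it occurs. N is treated as missing, never as a change.
#'
#' @param genealogy a rooted \code{phylo} from [buildLineageTree()] /
#'   [rootOnGermline()] (germline leaf present), or any rooted tree whose
#'   tips match the alignment rows.
#' @param alignment a \code{lineage_alignment}.
#' @param columns columns to map (default: all columns with germline-known or
#'   polymorphic states).
#' @return The genealogy with \code{branch_mutations} (a data.frame:
#'   \code{edge, position, from, to, region}) and \code{mut_counts} (integer
#'   per edge row).
#' @export
mapMutationsToBranches <- function(genealogy, alignment, columns = NULL) {
  phy <- genealogy
  if (!.hasSingleRoot(phy)) stop("genealogy must be rooted")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  mat <- alignment$matrix[phy$tip.label, , drop = FALSE]
  if (is.null(columns)) {
    poly <- apply(mat, 2L, function(col) {
      b <- unique(col[col != "N"])
      length(b) > 1L
    })
    columns <- which(poly)
  }
  if (!length(columns)) {
    phy$branch_mutations <- data.frame(edge = integer(0), position = integer(0),
                                       from = character(0), to = character(0),
                                       region = character(0),
                                       stringsAsFactors = FALSE)
    phy$mut_counts <- integer(nrow(phy$edge))
    return(phy)
  }
  germRow <- which(phy$tip.label == "germline")
  bits <- matrix(.BASE_BITS[mat[, columns, drop = FALSE]],
                 nrow = ntip)             # tips x columns
  ## bottom-up Fitch over the (possibly multifurcating) tree
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- matrix(0L, nrow = ntip + nnode, ncol = length(columns))
  sets[seq_len(ntip), ] <- bits
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  ordNodes <- unique(po$edge[, 1L])       # postorder: children before parents
  for (nd in ordNodes) {
    ch <- kids[[as.character(nd)]]
    s <- sets[ch[1L], ]
    for (c2 in ch[-1L]) {
      inter <- bitwAnd(s, sets[c2, ])
      s <- ifelse(inter > 0L, inter, bitwOr(s, sets[c2, ]))
    }
    sets[nd, ] <- s
  }
  ## top-down assignment, root fixed toward germline where compatible
  root <- ntip + 1L
  state <- matrix(0L, nrow = ntip + nnode, ncol = length(columns))
  germBits <- if (length(germRow)) bits[germRow, ] else rep(15L, length(columns))
  rootSet <- sets[root, ]
  germOk <- bitwAnd(rootSet, germBits)
  state[root, ] <- ifelse(germOk > 0L & germBits != 15L,
                          bitwShiftL(1L, .lowBase(germOk) - 1L),
                          bitwShiftL(1L, .lowBase(rootSet) - 1L))
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # parents first
  changeEdge <- integer(0); changeCol <- integer(0)
  changeFrom <- integer(0); changeTo <- integer(0)
  edgeKey <- paste(phy$edge[, 1L], phy$edge[, 2L])
  for (e in seq_len(nrow(pre))) {
    par <- pre[e, 1L]; ch <- pre[e, 2L]
    pst <- state[par, ]
    s <- sets[ch, ]
    keep <- bitwAnd(s, pst)
    st <- ifelse(keep > 0L, pst, bitwShiftL(1L, .lowBase(s) - 1L))
    missing <- s == 15L & ch <= ntip      # N leaf: inherit, no change
    st[missing] <- pst[missing]
    state[ch, ] <- st
    chg <- which(st != pst)
    if (length(chg)) {
      row <- match(paste(par, ch), edgeKey)
      changeEdge <- c(changeEdge, rep(row, length(chg)))
      changeCol <- c(changeCol, chg)
      changeFrom <- c(changeFrom, .lowBase(pst[chg]))
      changeTo <- c(changeTo, .lowBase(st[chg]))
    }
  }
  pos <- alignment$coords[columns][changeCol]
  phy$branch_mutations <- data.frame(
    edge = changeEdge, position = pos,
    from = .BIT_BASE[changeFrom], to = .BIT_BASE[changeTo],
    region = alignment$regions[columns][changeCol],
    stringsAsFactors = FALSE)
  phy$mut_counts <- tabulate(changeEdge, nbins = nrow(phy$edge))
  ## reconstructed ancestral bases at the mapped columns (single-bit states)
  phy$anc_columns <- alignment$coords[columns]
  phy$anc_states <- matrix(.BIT_BASE[.lowBase(state)],
                           nrow = nrow(state), ncol = ncol(state))
  phy
}
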