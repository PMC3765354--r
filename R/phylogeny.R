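#' p-distance matrix with pairwise deletion
#'
#' For each pair of aligned sequences, distance = mismatches / number of
#' columns where both sequences are non-gap; columns with a gap in either
#' member of the pair are skipped (pairwise deletion).  A pair sharing no
#' non-gap column is an explicit error, not an infinite distance.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (gap character `-`), length >= 2.
#' @return symmetric numeric matrix with zero diagonal; the per-pair
#'   effective site counts are attached as attribute `"sites"`.
#' @export
pdistance_matrix <- function(alignment) {
  n <- length(alignment)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: unequal sequence lengths", call. = FALSE)
  ids <- names(alignment)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(n))
  chm <- do.call(rbind, strsplit(toupper(alignment), ""))
  gap <- chm == "-"
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  S <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      m <- sum(ok)
      if (m == 0)
        stop(sprintf("pair %s / %s shares no non-gap columns",
                     ids[i], ids[j]), call. = FALSE)
      d <- sum(chm[i, ok] != chm[j, ok]) / m
      D[i, j] <- D[j, i] <- d
      S[i, j] <- S[j, i] <- m
    }
  }
  attr(D, "sites") <- S
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: Q-criterion join selection with
#' Studier-Keppler distance updates.  Join ties are broken by the smallest
#' (i, j) index pair in the current matrix; negative branch-length
#' estimates are clamped to zero (total clamped deficit is attached as
#' attribute `"clamped"`).  The returned tree is unrooted (basal
#' trichotomy).
#'
#' @param D symmetric distance matrix with >= 3 taxa (row names are taxon
#'   labels).
#' @return an `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(!is.finite(D))) stop("non-finite distances", call. = FALSE)
  labs <- rownames(D)
  if (is.null(labs)) labs <- sprintf("t%d", seq_len(n))
  nodes <- labs
  clamped <- 0
  clamp <- function(x) {
    clamped <<- clamped + sum(pmax(-x, 0))
    pmax(x, 0)
  }
  fmt <- function(x) formatC(x, format = "g", digits = 12)
  while (nrow(D) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))))
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li),
                       nodes[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], newnode)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- clamp((d12 + d13 - d23) / 2)
  l2 <- clamp((d12 + d23 - d13) / 2)
  l3 <- clamp((d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(l1),
                 nodes[2], fmt(l2), nodes[3], fmt(l3))
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped") <- clamped
  tree
}

# canonical keys for the non-trivial bipartitions of an unrooted tree:
# each bipartition is written as the sorted leaf set on the side that does
# not contain the alphabetically first taxon
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (part in pp) {
    set <- tips[part]
    if (ref %in% set) set <- setdiff(tips, set)
    if (length(set) < 2 || length(set) > length(tips) - 2) next
    keys <- c(keys, paste(sort(set), collapse = "|"))
  }
  unique(keys)
}

# per-internal-node bipartition key (NA for trivial/root), aligned with the
# tree's internal node numbering, used to attach supports as node labels
node_bipartition_keys <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  vapply(pp, function(part) {
    set <- tips[part]
    if (ref %in% set) set <- setdiff(tips, set)
    if (length(set) < 2 || length(set) > length(tips) - 2)
      return(NA_character_)
    paste(sort(set), collapse = "|")
  }, character(1))
}

#' Bootstrap support for the bipartitions of an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' neighbor-joining tree per replicate, and reports each original-tree
#' bipartition's replicate frequency as an integer percentage.  Supports
#' at or below `display_floor` (default 50, the usual display rule) are
#' flagged, not dropped.
#'
#' @param alignment named aligned sequences, >= 4.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param display_floor flagging floor (percent).
#' @return list with `tree` (original NJ tree, supports as node labels)
#'   and `supports` (data.frame bipartition, support, flagged).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              display_floor = 50) {
  if (length(alignment) < 4)
    stop("need at least 4 sequences", call. = FALSE)
  D0 <- pdistance_matrix(alignment)
  tree <- neighbor_joining(D0)
  keys <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(keys)), keys)
  L <- nchar(alignment[[1]])
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot <- vapply(alignment, function(s)
        paste(strsplit(s, "")[[1]][cols], collapse = ""), character(1))
      bt <- tryCatch(neighbor_joining(pdistance_matrix(boot)),
                     error = function(e) NULL)
      if (is.null(bt)) next
      bk <- tree_bipartitions(bt)
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- as.integer(round(100 * counts / n_replicates))
  node_keys <- node_bipartition_keys(tree)
  tree$node.label <- ifelse(is.na(node_keys), "",
                            as.character(support[match(node_keys, keys)]))
  list(tree = tree,
       supports = data.frame(bipartition = keys, support = support,
                             flagged = support <= display_floor,
                             stringsAsFactors = FALSE))
}

#' Simulate pairwise distances from a tree (additive matrix)
#'
#' Patristic distances of a phylo tree; used to test neighbor joining's
#' consistency on additive data.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric distance matrix over the tip labels.
#' @export
additive_distances <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  D[sort(rownames(D)), sort(rownames(D))]
}
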