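# Distance-based phylogenetics at desk scale: Poisson-corrected protein
# distances, neighbor joining (Saitou-Nei) with a deterministic tie-break,
# column-resampling bootstrap supports, and the two statistics a lateral-
# gene-transfer argument needs -- monophyly of a labeled leaf set, and the
# Fitch small-parsimony change count used as an interspersion index.
# Maximum-likelihood inference is deliberately not implemented; NJ on
# Poisson-corrected distances is the documented surrogate.

#' Poisson-corrected distance between two aligned protein rows
#'
#' p is the mismatch fraction over shared non-gap columns; the corrected
#' distance is `-ln(1 - p)`. At `p >= 0.95` the correction is saturated
#' and capped at 3.0 (attribute `saturated`).
#'
#' @param a,b Aligned residue strings (equal length, gaps `-`).
#' @return A nonnegative distance; attribute `saturated` when capped.
#' @export
protein_distance <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) stop("aligned rows differ in length")
  shared <- av != "-" & bv != "-"
  if (!any(shared)) stop("incomparable pair: no shared non-gap columns")
  p <- mean(av[shared] != bv[shared])
  if (p >= 0.95) {
    return(structure(3.0, saturated = TRUE))
  }
  -log(1 - p)
}

aln_char_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$seqs, "", fixed = TRUE))
  rownames(m) <- block$ids
  m
}

dist_from_char_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(shared)) {
        stop("incomparable pair: no shared non-gap columns between '",
             rownames(m)[i], "' and '", rownames(m)[j], "'")
      }
      p <- mean(m[i, shared] != m[j, shared])
      d[i, j] <- d[j, i] <- if (p >= 0.95) 3.0 else -log(1 - p)
    }
  }
  d
}

#' Pairwise Poisson-corrected distance matrix from an alignment
#'
#' @param block An `alignment_block`.
#' @return A symmetric numeric matrix with taxon dimnames.
#' @export
dist_from_alignment <- function(block) {
  stopifnot(inherits(block, "alignment_block"))
  dist_from_char_matrix(aln_char_matrix(block))
}

#' Validate a distance matrix
#'
#' Checks symmetry (within 1e-12), a zero diagonal and nonnegativity.
#' Triangle-inequality violations are tolerated (NJ handles them) but
#' counted in the returned attribute `triangle_violations`.
#'
#' @param d A square numeric matrix with dimnames.
#' @return `d`, invisibly, with attribute `triangle_violations`.
#' @export
validate_distance_matrix <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix needs taxon dimnames")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distance matrix has negative entries")
  viol <- 0L
  n <- nrow(d)
  if (n <= 30) {  # O(n^3) check only at desk scale
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (d[i, j] > d[i, k] + d[k, j] + 1e-12) viol <- viol + 1L
    }
  }
  attr(d, "triangle_violations") <- viol
  invisible(d)
}

fmt_bl <- function(x) sprintf("%.12g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration. Ties on Q are broken
#' deterministically by the lexicographically smallest pair of cluster
#' identifiers (a cluster is identified by its smallest member taxon), so
#' the result does not depend on input order. Additive matrices are
#' recovered exactly. Negative branch lengths are clamped to zero with a
#' warning (standard practice; count in attribute `n_clamped`).
#'
#' @param d Symmetric distance matrix with taxon dimnames, n >= 3.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  validate_distance_matrix(d)
  n0 <- nrow(d)
  if (n0 < 3) stop("size error: neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  frag <- labels                       # newick fragment per cluster
  ids <- labels                        # tie-break identifier per cluster
  D <- d
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) n_clamped <<- n_clamped + 1L
    max(x, 0)
  }
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_ids <- cbind(pmin(ids[cand[, 1]], ids[cand[, 2]]),
                      pmax(ids[cand[, 1]], ids[cand[, 2]]))
    pick <- order(pair_ids[, 1], pair_ids[, 2], method = "radix")[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(D[i, j] - li)
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_bl(li),
                        frag[j], fmt_bl(lj))
    new_id <- min(ids[i], ids[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    ids <- c(ids[keep], new_id)
    rownames(D) <- colnames(D) <- ids
  }
  # resolve the final three clusters around one internal node
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt_bl(la),
                 frag[2], fmt_bl(lb), frag[3], fmt_bl(lc))
  tree <- ape::read.tree(text = nwk)
  if (n_clamped > 0) {
    warning(n_clamped, " negative branch length(s) clamped to zero")
  }
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree per replicate and reports, for every internal
#' edge of the full-alignment tree, the percentage of replicate trees
#' containing the same bipartition. Reproducible given `seed`.
#'
#' @param block An `alignment_block` with at least 2 columns.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return The full-alignment [ape::phylo] tree with `node.label` set to
#'   integer support percentages (root label empty).
#' @export
bootstrap_support <- function(block, replicates = 100L, seed = 1L) {
  stopifnot(inherits(block, "alignment_block"), replicates >= 1)
  if (block$length < 2) stop("alignment must have at least 2 columns")
  m <- aln_char_matrix(block)
  main <- nj_tree(dist_from_char_matrix(m))
  set.seed(seed)
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    # per-replicate negative-length clamps are routine; stay quiet here
    boots[[b]] <- suppressWarnings(
      nj_tree(dist_from_char_matrix(m[, cols, drop = FALSE])))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates)
  main$node.label <- as.character(support)
  main$node.label[1] <- ""   # basal node of the stored representation
  attr(main, "replicates") <- replicates
  main
}

# tip-label set below the child node of every edge
edge_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  list(tree = tree, sets = sets)
}

#' Test monophyly of a leaf set
#'
#' TRUE iff removing some single edge bipartitions the leaves into exactly
#' `taxa` and its complement.
#'
#' @param tree An [ape::phylo] tree.
#' @param taxa Nonempty proper subset of the tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (length(taxa) == 0 || length(taxa) >= length(tips)) {
    stop("taxa must be a nonempty proper subset of the leaves")
  }
  ets <- edge_tip_sets(tree)
  target <- sort(unique(taxa))
  complement <- sort(setdiff(tips, target))
  for (e in seq_len(nrow(ets$tree$edge))) {
    below <- sort(ets$sets[[ets$tree$edge[e, 2]]])
    if (identical(below, target) || identical(below, complement)) return(TRUE)
  }
  FALSE
}

#' Fitch small-parsimony change count for a binary character
#'
#' The minimum number of state changes of a two-state leaf character on
#' the tree, computed by the Fitch downpass on an arbitrary rooting (the
#' root choice does not affect the count on an unrooted binary tree).
#' Used as an interspersion index for lateral-gene-transfer signal: the
#' count is 1 iff either state's leaf set is monophyletic, and grows with
#' the number of separate clusters the focal leaves fall into.
#'
#' @param tree An unrooted binary [ape::phylo] tree.
#' @param labels Named vector (tip label -> state); exactly the tree's
#'   tips must be labeled; any two states (e.g. `"in"`/`"out"`).
#' @return Integer change count (>= 1 when both states occur).
#' @export
fitch_changes <- function(tree, labels) {
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(labels))
  if (length(missing_tips)) {
    stop("unlabeled leaf: ", paste(missing_tips, collapse = ", "))
  }
  labels <- as.character(labels[tips])
  states <- sort(unique(labels))
  if (length(states) > 2) stop("fitch_changes expects a binary character")
  if (length(states) == 1) return(0L)
  rooted <- if (!ape::is.rooted(tree)) {
    ape::root(tree, outgroup = tips[1], resolve.root = TRUE)
  } else {
    tree
  }
  if (!ape::is.binary(rooted)) {
    stop("fitch_changes expects a (unrooted) binary tree")
  }
  rooted <- ape::reorder.phylo(rooted, "postorder")
  ntip <- length(rooted$tip.label)
  mask <- integer(ntip + rooted$Nnode)
  mask[seq_len(ntip)] <- ifelse(labels[match(rooted$tip.label, tips)] ==
                                  states[1], 1L, 2L)
  changes <- 0L
  # postorder guarantees a child's mask is final before its edge is visited;
  # combine children into the parent pairwise (Fitch union/intersection)
  for (e in seq_len(nrow(rooted$edge))) {
    parent <- rooted$edge[e, 1]
    child <- rooted$edge[e, 2]
    if (mask[parent] == 0L) {
      mask[parent] <- mask[child]
    } else {
      inter <- bitwAnd(mask[parent], mask[child])
      if (inter > 0L) {
        mask[parent] <- inter
      } else {
        mask[parent] <- bitwOr(mask[parent], mask[child])
        changes <- changes + 1L
      }
    }
  }
  changes
}
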