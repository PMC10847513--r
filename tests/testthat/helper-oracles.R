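# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the scan oracle walks windows one by one, the
# Fitch oracle enumerates every ancestral state assignment, the monophyly
# oracle reads bipartitions off phangorn's split enumeration.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "eddscreen")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", name)
  path
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# per-window oracle for fixed-length patterns given as a list of allowed
# sets (NULL = wildcard), sequence as a character string
oracle_scan_best <- function(residues, sets) {
  s <- strsplit(residues, "", fixed = TRUE)[[1]]
  plen <- length(sets)
  scored <- which(!vapply(sets, is.null, TRUE))
  if (length(s) < plen) return(NULL)
  best <- NULL
  for (start in seq_len(length(s) - plen + 1L)) {
    matched <- 0L
    for (k in scored) {
      ch <- s[start + k - 1L]
      if (ch == "X" || ch %in% sets[[k]]) matched <- matched + 1L
    }
    score <- matched / length(scored)
    if (is.null(best) || score > best$score) {
      best <- list(start = start, end = start + plen - 1L, score = score,
                   matched = matched)
    }
  }
  best
}

# expand a package pattern into the oracle's set-list representation
# (fixed-length patterns only)
pattern_sets <- function(pattern) {
  out <- list()
  for (e in pattern$elements) {
    if (e$kind == "wild") {
      stopifnot(e$min == e$max)
      out <- c(out, rep(list(NULL), e$min))
    } else {
      out <- c(out, list(e$set))
    }
  }
  out
}

# exhaustive small-parsimony minimum: try every assignment of the two
# states to internal nodes of a rooted binary resolution of the tree
oracle_fitch <- function(tree, labels) {
  rooted <- if (!ape::is.rooted(tree)) {
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  } else {
    tree
  }
  ntip <- length(rooted$tip.label)
  nint <- rooted$Nnode
  tip_state <- ifelse(labels[rooted$tip.label] ==
                        sort(unique(as.character(labels)))[1], 0L, 1L)
  best <- Inf
  for (code in 0:(2^nint - 1)) {
    internal <- as.integer(intToBits(code))[seq_len(nint)]
    state <- c(tip_state, internal)
    changes <- sum(state[rooted$edge[, 1]] != state[rooted$edge[, 2]])
    best <- min(best, changes)
  }
  as.integer(best)
}

# bipartition-based monophyly via phangorn's split enumeration
oracle_monophyletic <- function(tree, taxa) {
  splits <- phangorn::as.splits(tree)
  tips <- tree$tip.label
  target <- sort(unique(taxa))
  complement <- sort(setdiff(tips, target))
  for (s in splits) {
    side <- sort(attr(splits, "labels")[s])
    if (identical(side, target) || identical(side, complement)) return(TRUE)
  }
  FALSE
}

# random additive distance matrix with its generating tree
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
  d <- ape::cophenetic.phylo(tr)
  ord <- order(rownames(d))
  list(tree = tr, d = d[ord, ord])
}
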