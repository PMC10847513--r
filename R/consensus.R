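# Per-column similarity classification and consensus-pattern derivation.
# This reproduces the alignment-shading logic used to define the diagnostic
# dehydratase motifs: columns are "dark" at >= 80% similarity, "light" at
# >= 60%, under a configurable amino-acid similarity grouping.

#' Default amino-acid similarity scheme
#'
#' A Dayhoff-like partition of the 20 amino acids into physicochemical
#' classes: \{A,G\}, \{I,L,M,V\}, \{F,W,Y\}, \{H,K,R\}, \{D,E\}, \{N,Q\},
#' \{S,T\}, \{C\}, \{P\}. Group names are the sorted concatenation of their
#' members. The grouping behind published 60/80% shading conventions varies
#' between alignment viewers; the scheme is therefore configurable and is
#' recorded in every consensus report.
#'
#' @return A named list of character vectors partitioning the 20 amino
#'   acids.
#' @export
default_similarity_scheme <- function() {
  groups <- list(c("A", "G"), c("I", "L", "M", "V"), c("F", "W", "Y"),
                 c("H", "K", "R"), c("D", "E"), c("N", "Q"), c("S", "T"),
                 "C", "P")
  names(groups) <- vapply(groups, function(g) paste(sort(g), collapse = ""), "")
  validate_similarity_scheme(groups)
}

#' @rdname default_similarity_scheme
#' @param scheme A named list of character vectors.
#' @export
validate_similarity_scheme <- function(scheme) {
  all_aa <- sort(unlist(scheme, use.names = FALSE))
  if (!identical(all_aa, sort(AA20))) {
    stop("similarity scheme must partition the 20 amino acids exactly once")
  }
  scheme
}

#' Classify one alignment column by residue similarity
#'
#' The dominant set is the similarity group or single residue with the
#' highest coverage of the column's non-gap rows. Ties are broken in favour
#' of the smaller (more specific) set, then by lexicographically smallest
#' set name, so an invariant column always yields its single residue rather
#' than the residue's whole similarity group. Gap rows are excluded from
#' the denominator; `X` residues count in the denominator but belong to no
#' set.
#'
#' @param residues Character vector of one column's residues (may contain
#'   `-` gaps).
#' @param scheme A similarity scheme, see [default_similarity_scheme()].
#' @param cutoffs Numeric pair `c(light, dark)` with `light < dark`, both
#'   in (0, 1]. Defaults to the 60%/80% shading convention.
#' @return A list with elements `class` (`"dark"`, `"light"` or `"none"`),
#'   `dominant_set`, `dominant_name` and `fraction`.
#' @export
classify_column <- function(residues, scheme = default_similarity_scheme(),
                            cutoffs = c(0.6, 0.8)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2],
            all(cutoffs > 0), all(cutoffs <= 1))
  obs <- residues[residues != "-"]
  if (length(obs) == 0) stop("undefined column: all rows are gaps")
  n <- length(obs)

  singles <- sort(unique(obs[obs %in% AA20]))
  cands <- c(as.list(singles), scheme)
  names(cands) <- c(singles, names(scheme))
  if (length(cands) == 0) {   # column of pure X
    return(list(class = "none", dominant_set = character(0),
                dominant_name = NA_character_, fraction = 0))
  }
  cover <- vapply(cands, function(set) sum(obs %in% set) / n, 0)
  size <- vapply(cands, length, 0L)
  ord <- order(-cover, size, names(cands), method = "radix")
  best <- ord[1]
  frac <- cover[best]
  cls <- if (frac >= cutoffs[2]) "dark" else if (frac >= cutoffs[1]) "light" else "none"
  list(class = cls, dominant_set = sort(cands[[best]]),
       dominant_name = names(cands)[best], fraction = unname(frac))
}

#' Derive a consensus motif pattern from an alignment span
#'
#' Reproduces how a diagnostic motif is read off a shaded alignment of one
#' sequence class: dark columns with a single observed residue become
#' literals; dark group columns become residue alternative sets (the
#' observed members of the dominant group); light columns become
#' alternative sets flagged low-confidence; unconserved columns are merged
#' into wildcard runs `x{n}`. Columns that are majority gap are dropped
#' from the pattern and reported in `dropped_columns`.
#'
#' @param block An `alignment_block` containing only sequences of one
#'   class (the caller's responsibility).
#' @param span Integer pair `c(first, last)` of alignment columns
#'   (1-based, inclusive).
#' @param scheme,cutoffs See [classify_column()].
#' @param name Name for the resulting pattern.
#' @param max_gap_fraction Columns with a gap fraction above this value are
#'   dropped from the pattern.
#' @return A `motif_pattern` (see [parse_pattern()]) with extra fields
#'   `source_columns`, `dropped_columns`, `low_confidence` (per-element
#'   flags) and `scheme_used`.
#' @export
derive_consensus <- function(block, span, scheme = default_similarity_scheme(),
                             cutoffs = c(0.6, 0.8), name = "consensus",
                             max_gap_fraction = 0.5) {
  stopifnot(inherits(block, "alignment_block"))
  if (length(span) != 2 || span[1] > span[2]) stop("span error: empty span")
  if (span[1] < 1 || span[2] > block$length) {
    stop("span error: span [", span[1], ",", span[2],
         "] outside alignment of length ", block$length)
  }
  nrow <- length(block$ids)
  elements <- list()
  low_conf <- logical(0)
  dropped <- integer(0)
  per_column <- list()
  for (j in seq(span[1], span[2])) {
    col <- aln_column(block, j)
    gap_frac <- sum(col == "-") / nrow
    if (gap_frac > max_gap_fraction) {
      dropped <- c(dropped, j)
      per_column[[as.character(j)]] <- list(column = j, class = "dropped",
                                            fraction = NA_real_)
      next
    }
    cc <- classify_column(col, scheme, cutoffs)
    per_column[[as.character(j)]] <- c(list(column = j), cc)
    observed <- sort(unique(col[col %in% AA20]))
    el <- switch(cc$class,
      dark = {
        set <- intersect(cc$dominant_set, observed)
        list(kind = "res", set = set)
      },
      light = list(kind = "res", set = intersect(cc$dominant_set, observed)),
      none = list(kind = "wild", min = 1L, max = 1L))
    elements[[length(elements) + 1L]] <- el
    low_conf <- c(low_conf, identical(cc$class, "light"))
  }
  if (length(elements) == 0) stop("span error: all columns dropped")
  merged <- merge_wildcard_runs(elements, low_conf)
  pat <- new_motif_pattern(merged$elements, name = name)
  pat$low_confidence <- merged$low_conf
  pat$source_columns <- span
  pat$dropped_columns <- dropped
  pat$column_classes <- per_column
  pat$scheme_used <- scheme
  pat$cutoffs_used <- cutoffs
  pat
}

merge_wildcard_runs <- function(elements, low_conf) {
  out <- list(); lc <- logical(0)
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    last <- if (length(out)) out[[length(out)]] else NULL
    if (identical(el$kind, "wild") && !is.null(last) &&
        identical(last$kind, "wild")) {
      out[[length(out)]]$min <- last$min + el$min
      out[[length(out)]]$max <- last$max + el$max
    } else {
      out[[length(out) + 1L]] <- el
      lc <- c(lc, low_conf[i])
    }
  }
  list(elements = out, low_conf = lc)
}

#' Per-column consensus report as a data.frame
#'
#' @param pattern A pattern produced by [derive_consensus()].
#' @return A data.frame with one row per inspected column: `column`,
#'   `class`, `dominant`, `fraction`.
#' @export
consensus_report <- function(pattern) {
  stopifnot(!is.null(pattern$column_classes))
  rows <- lapply(pattern$column_classes, function(x) {
    data.frame(column = x$column, class = x$class,
               dominant = if (is.null(x$dominant_set)) NA_character_
                          else paste(x$dominant_set, collapse = ""),
               fraction = if (is.null(x$fraction)) NA_real_ else x$fraction)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
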