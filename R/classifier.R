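# Motif-pattern parsing, approximate sequence scanning, and the central
# EDD / DHAD / unknown call. Patterns use the field's consensus notation:
# literal residues, [ABC] alternative sets, x{n} or x{n,m} wildcard runs.
#
# The two built-in diagnostic patterns describe the N-terminal domains that
# separate 6-phosphogluconate dehydratases from dihydroxy-acid
# dehydratases: domain 1 "LAHGFAAx{4}[DE]Kx{3}" (residues 42-57 of the
# E. coli EDD) and domain 2 "KxK[VI]RQLYAx{2}K" (within residues 185-218).
# DHAD is never called from a positive motif -- its domain-2 region carries
# no conserved consensus -- only by similarity to a DHAD reference.

new_motif_pattern <- function(elements, name = "pattern") {
  scored <- vapply(elements, function(e) identical(e$kind, "res"), TRUE)
  mins <- vapply(elements, function(e) if (e$kind == "wild") e$min else 1L, 0L)
  maxs <- vapply(elements, function(e) if (e$kind == "wild") e$max else 1L, 0L)
  structure(list(name = name, elements = elements,
                 n_scored = sum(scored),
                 min_length = sum(mins), max_length = sum(maxs)),
            class = "motif_pattern")
}

#' Parse a motif pattern string
#'
#' Grammar: upper-case amino-acid letters are literals; `[ABC]` is an
#' alternative set; `x{n}` or `x{n,m}` (lower-case x, also accepted bare
#' as `x`) is a wildcard run matching any residues. Wildcards carry no
#' score mass; the scored positions are the literals and alternative sets.
#'
#' @param text Pattern string, e.g. `"LAHGFAAx{4}[DE]Kx{3}"`.
#' @param name Optional pattern name.
#' @return A `motif_pattern` with fields `elements`, `n_scored`,
#'   `min_length`, `max_length`.
#' @export
parse_pattern <- function(text, name = text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  elements <- list()
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% AA20) {
      elements[[length(elements) + 1L]] <- list(kind = "res", set = ch)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= n && chars[j] != "]") {
        if (!chars[j] %in% AA20) {
          stop("pattern syntax error at offset ", j, ": '", chars[j],
               "' is not an amino-acid letter inside [...]")
        }
        set <- c(set, chars[j]); j <- j + 1L
      }
      if (j > n) stop("pattern syntax error at offset ", i, ": unclosed '['")
      if (length(set) == 0) {
        stop("pattern syntax error at offset ", i, ": empty alternative set")
      }
      elements[[length(elements) + 1L]] <- list(kind = "res",
                                                set = sort(unique(set)))
      i <- j + 1L
    } else if (ch %in% c("x", "X")) {
      run <- c(1L, 1L)
      i <- i + 1L
      if (i <= n && chars[i] == "{") {
        j <- i + 1L
        while (j <= n && chars[j] != "}") j <- j + 1L
        if (j > n) stop("pattern syntax error at offset ", i, ": unclosed '{'")
        body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
        if (!grepl("^[0-9]+(,[0-9]+)?$", body)) {
          stop("pattern syntax error at offset ", i + 1L,
               ": bad run count '", body, "'")
        }
        parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
        run <- if (length(parts) == 1) c(parts, parts) else parts
        if (run[1] > run[2] || run[1] < 0) {
          stop("pattern syntax error at offset ", i + 1L,
               ": bad run bounds ", body)
        }
        i <- j + 1L
      }
      elements[[length(elements) + 1L]] <- list(kind = "wild",
                                                min = run[1], max = run[2])
    } else {
      stop("pattern syntax error at offset ", i, ": unexpected character '",
           ch, "'")
    }
  }
  if (length(elements) == 0) stop("pattern syntax error: empty pattern")
  new_motif_pattern(elements, name = name)
}

#' Serialize a motif pattern back to its string syntax
#' @param pattern A `motif_pattern`.
#' @return A pattern string.
#' @export
pattern_to_string <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    if (e$kind == "wild") {
      if (e$min == 1L && e$max == 1L) "x"
      else if (e$min == e$max) sprintf("x{%d}", e$min)
      else sprintf("x{%d,%d}", e$min, e$max)
    } else if (length(e$set) == 1) e$set
    else paste0("[", paste(e$set, collapse = ""), "]")
  }, ""), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s = %s (%d scored positions, length %d%s)\n",
              x$name, pattern_to_string(x), x$n_scored, x$min_length,
              if (x$max_length != x$min_length)
                paste0("-", x$max_length) else ""))
  invisible(x)
}

# expand a pattern into fixed-length variants: list of (offsets, sets) for
# scored positions; variable wildcard runs are enumerated over their bounds.
expand_pattern <- function(pattern) {
  wild_idx <- which(vapply(pattern$elements,
                           function(e) e$kind == "wild" && e$min != e$max, TRUE))
  choices <- lapply(wild_idx, function(i) {
    seq(pattern$elements[[i]]$min, pattern$elements[[i]]$max)
  })
  grids <- if (length(choices)) expand.grid(choices) else data.frame(row.names = 1)
  lapply(seq_len(nrow(grids)), function(g) {
    pos <- 0L; offsets <- integer(0); sets <- list()
    for (i in seq_along(pattern$elements)) {
      e <- pattern$elements[[i]]
      if (e$kind == "wild") {
        len <- if (i %in% wild_idx) grids[g, match(i, wild_idx)] else e$min
        pos <- pos + len
      } else {
        pos <- pos + 1L
        offsets <- c(offsets, pos)
        sets[[length(sets) + 1L]] <- e$set
      }
    }
    list(length = pos, offsets = offsets, sets = sets)
  })
}

#' Scan a protein for approximate matches to a motif pattern
#'
#' Slides every window of the pattern's length across the sequence and
#' counts satisfied scored positions (`X` in the sequence satisfies any
#' element; wildcards always match). Returns every window with at most
#' `max_mismatch` mismatches, and always includes the single best-scoring
#' window even when it exceeds the budget (flagged `sub_threshold`). Ties
#' on score are broken by the smallest start. Coordinates are 1-based and
#' inclusive on the ungapped protein.
#'
#' @param protein A [protein_record()] (or plain residue string).
#' @param pattern A `motif_pattern`.
#' @param max_mismatch Mismatch budget (default 2).
#' @return A data.frame of matches: `pattern_name`, `start`, `end`,
#'   `matched_literals`, `max_literals`, `score`, `mismatches`,
#'   `sub_threshold`; zero rows with attribute `no_window = TRUE` when the
#'   sequence is shorter than the pattern.
#' @export
scan_sequence <- function(protein, pattern, max_mismatch = 2L) {
  if (is.character(protein)) protein <- protein_record("seq", protein)
  stopifnot(inherits(pattern, "motif_pattern"))
  if (pattern$n_scored == 0) {
    stop("pattern '", pattern$name,
         "' has zero scored positions; its score is undefined")
  }
  s <- strsplit(protein$residues, "", fixed = TRUE)[[1]]
  L <- length(s)
  empty <- data.frame(pattern_name = character(0), start = integer(0),
                      end = integer(0), matched_literals = integer(0),
                      max_literals = integer(0), score = numeric(0),
                      mismatches = integer(0), sub_threshold = logical(0))
  if (L < pattern$min_length) {
    attr(empty, "no_window") <- TRUE
    return(empty)
  }
  best <- NULL
  rows <- list()
  for (variant in expand_pattern(pattern)) {
    plen <- variant$length
    if (L < plen) next
    starts <- seq_len(L - plen + 1L)
    matched <- integer(length(starts))
    for (k in seq_along(variant$offsets)) {
      res <- s[starts + variant$offsets[k] - 1L]
      matched <- matched + (res %in% variant$sets[[k]] | res == "X")
    }
    mism <- pattern$n_scored - matched
    df <- data.frame(pattern_name = pattern$name, start = starts,
                     end = starts + plen - 1L, matched_literals = matched,
                     max_literals = pattern$n_scored,
                     score = matched / pattern$n_scored,
                     mismatches = mism, sub_threshold = FALSE)
    rows[[length(rows) + 1L]] <- df[mism <= max_mismatch, , drop = FALSE]
    top <- df[order(-df$score, df$start), , drop = FALSE][1, , drop = FALSE]
    if (is.null(best) || top$score > best$score ||
        (top$score == best$score && top$start < best$start)) {
      best <- top
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    best$sub_threshold <- best$mismatches > max_mismatch
    out <- best
  } else if (!any(out$start == best$start & out$end == best$end)) {
    best$sub_threshold <- TRUE
    out <- rbind(out, best)
  }
  out <- out[order(-out$score, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- Motif library ----------------------------------------------------------

#' Motif libraries for dehydratase classification
#'
#' A motif library is a named set of patterns with class tags
#' (`"EDD-diagnostic"` or `"auxiliary-EDD"`) and weights. The default
#' library ships the two printed diagnostic domains of the EDD class:
#' `domain1 = "LAHGFAAx{4}[DE]Kx{3}"` and `domain2 = "KxK[VI]RQLYAx{2}K"`.
#' Auxiliary short motifs (2-4 residues, individually uninformative) can
#' be added with a down-weighted default weight of 0.25.
#'
#' @return A `motif_library`.
#' @export
default_motif_library <- function() {
  lib <- motif_library(
    patterns = list(domain1 = parse_pattern("LAHGFAAx{4}[DE]Kx{3}", "domain1"),
                    domain2 = parse_pattern("KxK[VI]RQLYAx{2}K", "domain2")),
    classes = c("EDD-diagnostic", "EDD-diagnostic"),
    weights = c(1, 1))
  lib
}

#' @rdname default_motif_library
#' @param patterns Named list of `motif_pattern`s.
#' @param classes Character vector of class tags per pattern.
#' @param weights Numeric weights per pattern.
#' @export
motif_library <- function(patterns, classes, weights = NULL) {
  stopifnot(length(patterns) == length(classes))
  nm <- names(patterns)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))) {
    stop("configuration error: motif library patterns must have unique names")
  }
  if (!all(classes %in% c("EDD-diagnostic", "auxiliary-EDD"))) {
    stop("configuration error: unknown pattern class")
  }
  if (is.null(weights)) {
    weights <- ifelse(classes == "auxiliary-EDD", 0.25, 1)
  }
  for (p in patterns) {
    if (p$n_scored == 0) {
      stop("configuration error: pattern '", p$name,
           "' has zero scored positions and cannot be scored")
    }
  }
  structure(list(patterns = patterns, classes = setNames(classes, nm),
                 weights = setNames(weights, nm)),
            class = "motif_library")
}

#' @rdname default_motif_library
#' @param library A `motif_library`.
#' @param pattern A `motif_pattern` or pattern string.
#' @param class Class tag for the added pattern.
#' @param weight Weight (defaults to 1 for diagnostic, 0.25 for auxiliary).
#' @export
add_motif <- function(library, pattern, class = "auxiliary-EDD",
                      weight = NULL) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  motif_library(c(library$patterns, setNames(list(pattern), pattern$name)),
                c(unname(library$classes), class),
                c(unname(library$weights),
                  weight %||% if (class == "auxiliary-EDD") 0.25 else 1))
}

#' Read a motif library from TSV (columns: name, class, weight, pattern)
#' @param path TSV path.
#' @return A `motif_library`.
#' @export
read_motif_library <- function(path) {
  df <- read_tsv_table(path)
  need <- c("name", "class", "weight", "pattern")
  if (!all(need %in% names(df))) {
    stop("motif library TSV needs columns: ", paste(need, collapse = ", "))
  }
  pats <- lapply(seq_len(nrow(df)),
                 function(i) parse_pattern(df$pattern[i], df$name[i]))
  names(pats) <- df$name
  motif_library(pats, df$class, as.numeric(df$weight))
}

# ---- Reference similarity and the call --------------------------------------

#' Ungapped k-mer identity between two proteins
#'
#' An alignment-free identity estimate: the fraction C of the query's
#' distinct k-mers present in the reference is mapped back to the
#' per-site scale as `C^(1/k)` (a k-mer survives intact when all k of its
#' sites match, so containment scales roughly as identity^k). Values are
#' comparable to percent identity: ~1 for near copies, near 0 for
#' unrelated proteins. The default k = 5 keeps the background of unrelated
#' pairs (which share at most a stray k-mer at typical protein lengths)
#' safely below the 0.35 call threshold while 40-50% identical relatives
#' still map to ~0.4-0.5. Used to assign a protein to its nearest
#' reference class when motif evidence is absent.
#'
#' @param query,reference [protein_record()]s or residue strings.
#' @param k k-mer size.
#' @return A number in `[0, 1]`.
#' @export
kmer_identity <- function(query, reference, k = 5L) {
  qs <- if (is.character(query)) query else query$residues
  rs <- if (is.character(reference)) reference else reference$residues
  if (nchar(qs) < k || nchar(rs) < k) return(0)
  kmers <- function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  qk <- kmers(qs)
  hits <- sum(qk %in% kmers(rs))
  # guard against chance matches: a single shared substring between
  # unrelated proteins can contribute 1-2 k-mers and, through the 1/k
  # root, inflate the estimate toward the call threshold
  if (hits < 3) return(0)
  (hits / length(qk))^(1 / k)
}

#' Build a reference set for similarity-based calls
#'
#' @param records List of [protein_record()]s.
#' @param classes Character vector (`"EDD"` or `"DHAD"`) per record.
#' @return A `reference_set`.
#' @export
reference_set <- function(records, classes) {
  stopifnot(length(records) == length(classes),
            all(classes %in% c("EDD", "DHAD")))
  structure(list(records = records, classes = classes),
            class = "reference_set")
}

#' Call a protein EDD, DHAD or unknown
#'
#' The central discrimination: `edd_score` is the weighted mean of the
#' best-match scores of the library's patterns against the protein. The
#' protein is called `EDD` when `edd_score >= thresholds$t_edd` (default
#' 0.8, tolerating roughly two mismatches across the 18 scored positions
#' of the two default domains). Below that, and when references are
#' supplied, the protein takes the class of its nearest reference by
#' ungapped k-mer identity provided the identity reaches
#' `thresholds$t_id` (default 0.35); otherwise it is `unknown`. DHAD is
#' never called from a positive motif -- there is no conserved DHAD
#' consensus in the domain-2 region -- only by reference similarity.
#'
#' @param protein A [protein_record()].
#' @param library A `motif_library` with at least one EDD-diagnostic
#'   pattern.
#' @param references Optional `reference_set`.
#' @param thresholds List with `t_edd` and `t_id`.
#' @param max_mismatch Mismatch budget handed to [scan_sequence()].
#' @return A `dehydratase_call`: `id`, `label`, `edd_score`, `evidence`
#'   (matches sorted by score), `reference_identity`, `nearest_reference`.
#' @export
classify_dehydratase <- function(protein, library = default_motif_library(),
                                 references = NULL,
                                 thresholds = list(t_edd = 0.8, t_id = 0.35),
                                 max_mismatch = 2L) {
  stopifnot(inherits(library, "motif_library"))
  if (length(library$patterns) == 0 ||
      !any(library$classes == "EDD-diagnostic")) {
    stop("configuration error: library has no EDD-diagnostic pattern")
  }
  best <- lapply(names(library$patterns), function(nm) {
    m <- scan_sequence(protein, library$patterns[[nm]], max_mismatch)
    if (nrow(m) == 0) {
      data.frame(pattern_name = nm, start = NA_integer_, end = NA_integer_,
                 matched_literals = 0L,
                 max_literals = library$patterns[[nm]]$n_scored,
                 score = 0, mismatches = NA_integer_, sub_threshold = TRUE)
    } else {
      m[1, , drop = FALSE]
    }
  })
  evidence <- do.call(rbind, best)
  evidence <- evidence[order(-evidence$score, evidence$start), , drop = FALSE]
  rownames(evidence) <- NULL
  scores <- vapply(best, function(m) m$score, 0)
  edd_score <- weighted.mean(scores, unname(library$weights))

  label <- "unknown"
  ref_id <- NA_real_; nearest <- NA_character_; nearest_class <- NA_character_
  if (edd_score >= thresholds$t_edd) {
    label <- "EDD"
  } else if (!is.null(references)) {
    ids <- vapply(references$records, kmer_identity, 0, query = protein)
    j <- which.max(ids)
    ref_id <- ids[j]
    nearest <- references$records[[j]]$id
    nearest_class <- references$classes[j]
    if (ref_id >= thresholds$t_id) label <- nearest_class
  }
  structure(list(id = protein$id, label = label, edd_score = edd_score,
                 evidence = evidence, reference_identity = ref_id,
                 nearest_reference = nearest,
                 nearest_reference_class = nearest_class,
                 thresholds = thresholds),
            class = "dehydratase_call")
}

#' @export
print.dehydratase_call <- function(x, ...) {
  cat(sprintf("<dehydratase_call> %s: %s (edd_score %.3f)\n",
              x$id, x$label, x$edd_score))
  invisible(x)
}

#' Classify a list of proteins and tabulate the calls
#'
#' @param proteins List of [protein_record()]s.
#' @param ... Passed to [classify_dehydratase()].
#' @return A data.frame with one row per protein: `id`, `label`,
#'   `edd_score`, `reference_identity`.
#' @export
classify_dehydratases <- function(proteins, ...) {
  calls <- lapply(proteins, classify_dehydratase, ...)
  data.frame(id = vapply(calls, `[[`, "", "id"),
             label = vapply(calls, `[[`, "", "label"),
             edd_score = vapply(calls, `[[`, 0, "edd_score"),
             reference_identity = vapply(calls, `[[`, 0,
                                         "reference_identity"))
}
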