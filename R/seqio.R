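# FASTA / aligned-FASTA / Newick I/O and the canonical in-memory records.
# Parsing of the byte formats is delegated to Biostrings and ape; this file
# owns header metadata, validation and coordinate bookkeeping.

#' Construct a protein record
#'
#' The canonical per-sequence container used throughout the package: an
#' accession-like identifier, optional taxon and group labels, and the
#' residue string over the 20 amino-acid letters plus `X` (unknown).
#'
#' @param id Accession-like identifier (non-empty string).
#' @param residues Amino-acid string; upper-cased on input. Gap characters
#'   are not allowed (see [read_alignment()] for gapped rows).
#' @param taxon Optional taxon name.
#' @param group_label Optional group label (e.g. `"cyanobacteria"`,
#'   `"proteobacteria"`, `"embryophyte"`).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, residues, taxon = NA_character_,
                           group_label = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("protein record '", id, "': residues are empty")
  check_aa_alphabet(residues, id)
  structure(list(id = id, taxon = as.character(taxon),
                 group_label = as.character(group_label),
                 residues = residues),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$residues),
              if (!is.na(x$taxon)) paste0(" [", x$taxon, "]") else ""))
  invisible(x)
}

check_aa_alphabet <- function(residues, id, allow_gap = FALSE) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  ok <- chars %in% c(AA20, "X", if (allow_gap) "-")
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf(
      "sequence '%s': character '%s' at position %d is not an amino-acid letter",
      id, chars[i], i))
  }
  invisible(TRUE)
}

parse_fasta_header <- function(header) {
  fields <- strsplit(trimws(header), "\\s+")[[1]]
  list(id = fields[1],
       taxon = if (length(fields) >= 2) fields[2] else NA_character_,
       group_label = if (length(fields) >= 3) fields[3] else NA_character_)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are parsed as whitespace-separated `id [taxon] [group_label]`.
#' Residues are upper-cased and validated against the amino-acid alphabet
#' (20 letters plus `X`); gaps are rejected -- use [read_alignment()] for
#' aligned input.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0) stop("FASTA format error: file is empty: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  recs <- lapply(seq_along(set), function(i) {
    h <- parse_fasta_header(headers[i])
    protein_record(h$id, as.character(set[[i]]), h$taxon, h$group_label)
  })
  ids <- vapply(recs, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate identifier in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs
}

#' Write protein records to FASTA
#'
#' @param records A list of [protein_record()] objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    # header fields are positional: a group label can only be written when
    # a taxon occupies the second field
    hdr <- paste0(">", r$id,
                  if (!is.na(r$taxon)) paste0(" ", r$taxon) else "",
                  if (!is.na(r$taxon) && !is.na(r$group_label))
                    paste0(" ", r$group_label) else "")
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", r$residues)
    c(hdr, strsplit(body, "\n")[[1]])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an aligned FASTA file into an alignment block
#'
#' All rows must have equal length; gaps are `-`. Per-row ungapped
#' coordinate maps are retained so motif coordinates can be reported in
#' 1-based residue numbering of each member sequence: `maps[[i]][k]` is the
#' alignment column holding the k-th residue of row i.
#'
#' @param path Path to an aligned FASTA file.
#' @return An object of class `alignment_block` with fields `ids`, `taxa`,
#'   `group_labels`, `seqs` (gapped strings), `length` (columns) and `maps`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  headers <- lapply(names(set), parse_fasta_header)
  alignment_block(ids = vapply(headers, `[[`, "", "id"),
                  seqs = toupper(as.character(set)),
                  taxa = vapply(headers, `[[`, "", "taxon"),
                  group_labels = vapply(headers, `[[`, "", "group_label"))
}

#' Construct an alignment block from gapped rows
#'
#' @param ids Row identifiers.
#' @param seqs Gapped residue strings, all the same length.
#' @param taxa,group_labels Optional per-row metadata.
#' @return An `alignment_block`.
#' @export
alignment_block <- function(ids, seqs, taxa = NULL, group_labels = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (length(seqs) < 2) {
    stop("alignment shape error: an alignment needs at least 2 rows")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    stop("alignment shape error: ragged rows (lengths ",
         paste(unique(widths), collapse = ", "), ")")
  }
  if (anyDuplicated(ids)) stop("duplicate identifier in alignment")
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) check_aa_alphabet(seqs[i], ids[i], allow_gap = TRUE)
  maps <- lapply(seqs, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] != "-")
  })
  if (any(vapply(maps, length, 0L) == 0L)) {
    stop("alignment shape error: a row contains no residues (all gaps)")
  }
  structure(list(ids = unname(ids),
                 taxa = unname(taxa %||% rep(NA_character_, length(ids))),
                 group_labels = unname(group_labels %||%
                                         rep(NA_character_, length(ids))),
                 seqs = unname(seqs), length = unname(widths[1]),
                 maps = maps),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %d rows x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Alignment column / coordinate helpers
#'
#' `aln_column()` extracts the residues of one alignment column (gaps
#' included as `-`). `ungapped_to_column()` maps the k-th residue of a row
#' to its alignment column; `column_to_ungapped()` is the inverse and
#' returns `NA` for a gap.
#'
#' @param block An `alignment_block`.
#' @param column,row,k 1-based indices.
#' @return A character vector (`aln_column`) or an integer scalar.
#' @export
aln_column <- function(block, column) {
  stopifnot(column >= 1, column <= block$length)
  vapply(block$seqs, function(s) substr(s, column, column), "",
         USE.NAMES = FALSE)
}

#' @rdname aln_column
#' @export
ungapped_to_column <- function(block, row, k) {
  map <- block$maps[[row]]
  if (k < 1 || k > length(map)) stop("residue index out of range: ", k)
  map[k]
}

#' @rdname aln_column
#' @export
column_to_ungapped <- function(block, row, column) {
  map <- block$maps[[row]]
  hit <- match(column, map)
  if (is.na(hit)) NA_integer_ else hit
}

#' Extract an ungapped protein record from an alignment row
#' @param block An `alignment_block`.
#' @param row Row index.
#' @return A [protein_record()].
#' @export
aln_record <- function(block, row) {
  protein_record(block$ids[row], gsub("-", "", block$seqs[row], fixed = TRUE),
                 block$taxa[row], block$group_labels[row])
}

# ---- Newick -----------------------------------------------------------------

check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("Newick parse error: unbalanced ')' at character offset ", i)
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth,
         " unclosed '(' at end of string (offset ", nchar(text), ")")
  }
  invisible(TRUE)
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that add a
#' parenthesis-balance pre-check with character offsets and keep internal
#' node support labels. Parse-then-write is the identity up to child
#' ordering and float formatting.
#'
#' @param x A Newick string or a file path (for `newick_read`); an
#'   [ape::phylo] object (for `newick_write`).
#' @param path Optional output file; if `NULL` the Newick string is
#'   returned.
#' @return `newick_read`: an [ape::phylo] tree. `newick_write`: a Newick
#'   string or `path` invisibly.
#' @export
newick_read <- function(x) {
  text <- if (length(x) == 1 && !grepl("\\(", x) && file.exists(x)) {
    paste(readLines(x), collapse = "")
  } else {
    x
  }
  check_newick_balance(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree)) stop("Newick parse error: ", text)
  tree
}

#' @rdname newick_read
#' @param digits Significant digits for branch lengths.
#' @export
newick_write <- function(x, path = NULL, digits = 6L) {
  stopifnot(inherits(x, "phylo"))
  s <- ape::write.tree(x, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

# ---- TSV tables -------------------------------------------------------------

#' Read / write a TSV table with header
#'
#' Inventories, accession tables and kinetic tables all travel as plain
#' tab-separated text with a header row.
#'
#' @param path File path.
#' @param x A data.frame.
#' @return A data.frame (`read_tsv_table`) or `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) == 0) stop("table format error: no header in ", path)
  df
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
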