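# Per-genome ED-pathway completeness from gene co-occurrence: a complete
# (phosphorylated) Entner-Doudoroff pathway requires both a genuine EDD
# and an EDA, and KDPG -- the pathway's unique metabolite -- is predicted
# detectable exactly when the pathway is complete. Semi-/non-phosphorylated
# variants (gluconate/KDG routes of some archaea) are deliberately not
# modeled.

#' Construct a gene record
#'
#' @param id Gene/protein identifier.
#' @param gene_class One of `"EDD"`, `"EDA"`, `"DHAD"`, `"other"` (from a
#'   classifier call or annotation input).
#' @param protein Optional [protein_record()].
#' @param cds Optional coding nucleotide sequence (length divisible by 3).
#' @param exon_count Optional exon count (>= 1).
#' @param transit_peptide Optional logical: predicted plastid transit
#'   peptide present.
#' @return A `gene_record`.
#' @export
gene_record <- function(id, gene_class, protein = NULL, cds = NULL,
                        exon_count = NA_integer_, transit_peptide = NA) {
  gene_class <- match.arg(gene_class, c("EDD", "EDA", "DHAD", "other"))
  if (!is.null(cds)) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3 != 0) {
      stop("gene '", id, "': CDS length ", nchar(cds),
           " is not divisible by 3")
    }
  }
  if (!is.na(exon_count) && exon_count < 1) {
    stop("gene '", id, "': exon_count must be >= 1")
  }
  structure(list(id = id, gene_class = gene_class, protein = protein,
                 cds = cds, exon_count = as.integer(exon_count),
                 transit_peptide = transit_peptide),
            class = "gene_record")
}

ed_status_from_flags <- function(has_edd, has_eda) {
  if (has_edd && has_eda) "complete"
  else if (has_eda) "eda_only"
  else if (has_edd) "edd_only"
  else "absent"
}

#' Call ED-pathway status for one genome
#'
#' Presence booleans are taken from any inventory record of each class;
#' genes flagged `artefact` by [artefact_verdict()] are excluded from
#' presence calls but retained in the report with their verdict.
#' `ed_status` is `complete` iff both EDD and EDA are present, and KDPG is
#' predicted detectable iff the status is `complete`.
#'
#' @param inventory List of [gene_record()]s (may be empty).
#' @param taxon Taxon name.
#' @param verdicts Optional named list/vector of verdict strings (from
#'   [artefact_verdict()]) keyed by gene id.
#' @return A `pathway_status`: `taxon`, `has_edd`, `has_eda`, `has_dhad`,
#'   `ed_status`, `kdpg_predicted`, `excluded` (artefact gene ids).
#' @export
call_pathway_status <- function(inventory, taxon, verdicts = NULL) {
  if (inherits(inventory, "gene_record")) inventory <- list(inventory)
  verdict_of <- function(g) {
    v <- if (is.list(verdicts)) verdicts[[g$id]] else verdicts[g$id]
    if (is.null(v) || is.na(v)) "genuine" else as.character(v)
  }
  excluded <- character(0)
  classes <- character(0)
  for (g in inventory) {
    if (identical(verdict_of(g), "artefact")) {
      excluded <- c(excluded, g$id)
    } else {
      classes <- c(classes, g$gene_class)
    }
  }
  has_edd <- "EDD" %in% classes
  has_eda <- "EDA" %in% classes
  has_dhad <- "DHAD" %in% classes
  status <- ed_status_from_flags(has_edd, has_eda)
  structure(list(taxon = taxon, has_edd = has_edd, has_eda = has_eda,
                 has_dhad = has_dhad, ed_status = status,
                 kdpg_predicted = identical(status, "complete"),
                 excluded = excluded),
            class = "pathway_status")
}

#' @export
print.pathway_status <- function(x, ...) {
  cat(sprintf("<pathway_status> %s: %s (EDD %s, EDA %s, DHAD %s; KDPG %s)\n",
              x$taxon, x$ed_status,
              x$has_edd, x$has_eda, x$has_dhad,
              if (x$kdpg_predicted) "predicted" else "not predicted"))
  invisible(x)
}

#' Survey ED-pathway status across genomes
#'
#' @param inventories Named list: taxon -> list of [gene_record()]s.
#' @param groups Named character vector: taxon -> group label.
#' @param verdicts Optional verdicts as in [call_pathway_status()].
#' @return A list with `table` (one row per taxon: taxon, group, has_edd,
#'   has_eda, has_dhad, ed_status, kdpg_predicted) and `summary` (per
#'   group: number of taxa and EDD/EDA-positive and complete counts).
#' @export
survey_table <- function(inventories, groups, verdicts = NULL) {
  taxa <- names(inventories)
  if (is.null(taxa) || anyDuplicated(taxa)) {
    stop("inventories must be a named list with unique taxon names")
  }
  rows <- lapply(taxa, function(tx) {
    st <- call_pathway_status(inventories[[tx]], tx, verdicts)
    data.frame(taxon = tx,
               group = unname(groups[tx]),
               has_edd = st$has_edd, has_eda = st$has_eda,
               has_dhad = st$has_dhad, ed_status = st$ed_status,
               kdpg_predicted = st$kdpg_predicted)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summ <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    data.frame(group = d$group[1], n_taxa = nrow(d),
               n_edd = sum(d$has_edd), n_eda = sum(d$has_eda),
               n_complete = sum(d$ed_status == "complete"))
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ[order(summ$group), , drop = FALSE])
}

#' Summarize a curated dehydratase accession table
#'
#' Takes a table with one row per curated sequence record (columns
#' `accession`, `taxon`, `group`, `gene_class`) -- the shape of a
#' published genome-survey supplement -- and reports total record counts
#' and per-group counts of EDD and DHAD entries.
#'
#' @param df A data.frame or a TSV path.
#' @return A list with `n_records`, `by_group` (data.frame: group, n,
#'   n_edd, n_dhad) and the input `table`.
#' @export
survey_from_accessions <- function(df) {
  if (is.character(df)) df <- read_tsv_table(df)
  need <- c("accession", "taxon", "group", "gene_class")
  if (!all(need %in% names(df))) {
    stop("accession table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$accession)) stop("duplicate accession in table")
  by_group <- do.call(rbind, lapply(split(df, df$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               n_edd = sum(d$gene_class == "EDD"),
               n_dhad = sum(d$gene_class == "DHAD"))
  }))
  rownames(by_group) <- NULL
  list(n_records = nrow(df),
       by_group = by_group[order(by_group$group), , drop = FALSE],
       table = df)
}
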