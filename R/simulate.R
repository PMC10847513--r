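# Seed-deterministic generators for every input the pipeline needs, with
# planted ground truth: dehydratase families diverged from a seed sequence
# with motifs intact or ablated, coding sequences drawn from specified
# codon-usage tables, Michaelis-Menten rate data with multiplicative
# lognormal noise, and linear calibration series with Gaussian noise.
# Sequence evolution uses a uniform substitution kernel over the 20 amino
# acids -- adequate for planting classification signal, not an empirical
# substitution model.

#' Generate a random protein sequence
#' @param length Sequence length.
#' @param seed RNG seed (omit to use the current RNG state).
#' @return A residue string.
#' @export
random_protein <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

#' Seed sequence with the two diagnostic EDD motifs planted
#'
#' A random protein carrying a motif-consistent domain-1 instance
#' (`LAHGFAANPDQEKLGV`, matching `LAHGFAAx{4}[DE]Kx{3}`) at residues
#' 42-57 and a domain-2 instance (`KAKVRQLYAGSK`, matching
#' `KxK[VI]RQLYAx{2}K`) at residues 185-196 -- the coordinates of the
#' E. coli EDD anchors.
#'
#' @param length Total length (>= 250).
#' @param seed RNG seed.
#' @return A list: `residues`, `motif_columns` (integer vector of the
#'   planted positions), `domain1_span`, `domain2_span`.
#' @export
make_edd_seed <- function(length = 300L, seed = 1L) {
  stopifnot(length >= 250)
  base <- random_protein(length, seed)
  d1 <- "LAHGFAANPDQEKLGV"   # instance of LAHGFAAx{4}[DE]Kx{3}
  d2 <- "KAKVRQLYAGSK"       # instance of KxK[VI]RQLYAx{2}K
  substr(base, 42, 57) <- d1
  substr(base, 185, 196) <- d2
  list(residues = base,
       motif_columns = c(42:57, 185:196),
       domain1_span = c(42L, 57L), domain2_span = c(185L, 196L))
}

#' Family specification for the sequence-family generator
#'
#' @param seed_sequence Ancestor residue string.
#' @param n_members Number of family members (>= 2).
#' @param p_sub Expected per-site substitution probability from the
#'   ancestor to a tip, outside protected columns; in `[0, 1)`.
#' @param protected_columns Columns never mutated (`motif_mode =
#'   "intact"`) or fully randomized per member (`"ablated"`).
#' @param motif_mode `"intact"` or `"ablated"`.
#' @param group_label Group label carried by every member.
#' @param seed RNG seed.
#' @return A `family_spec`.
#' @export
family_spec <- function(seed_sequence, n_members, p_sub = 0.2,
                        protected_columns = integer(0),
                        motif_mode = c("intact", "ablated"),
                        group_label = "family", seed = 1L) {
  motif_mode <- match.arg(motif_mode)
  stopifnot(p_sub >= 0, p_sub < 1, n_members >= 2)
  L <- nchar(seed_sequence)
  if (length(protected_columns) &&
      (min(protected_columns) < 1 || max(protected_columns) > L)) {
    stop("protected columns outside the seed sequence")
  }
  structure(list(seed_sequence = toupper(seed_sequence),
                 n_members = as.integer(n_members), p_sub = p_sub,
                 protected_columns = as.integer(protected_columns),
                 motif_mode = motif_mode, group_label = group_label,
                 seed = seed),
            class = "family_spec")
}

mutate_sites <- function(chars, idx) {
  # uniform kernel over the 19 other residues
  for (i in idx) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  chars
}

#' Evolve a synthetic protein family along a random tree
#'
#' Members evolve from the seed sequence down a random bifurcating tree
#' ([ape::rtree()]); branch lengths are rescaled so the mean root-to-tip
#' path carries the spec's per-site substitution probability, and each
#' site mutates independently per branch (uniform kernel). Protected
#' (motif) columns are never mutated when `motif_mode = "intact"`, and are
#' fully randomized per member when `"ablated"`. The true alignment
#' (trivial -- no indels are simulated) and true tree are returned for
#' oracle comparisons, and the spec travels with the output as ground
#' truth.
#'
#' @param spec A [family_spec()].
#' @return A list: `records` (list of [protein_record()]), `alignment`
#'   (an `alignment_block`), `tree` (rooted [ape::phylo]), `spec`.
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  n <- spec$n_members
  L <- nchar(spec$seed_sequence)
  tree <- ape::rtree(n, tip.label = sprintf("%s_%02d", spec$group_label,
                                            seq_len(n)))
  depths <- ape::node.depth.edgelength(tree)
  mean_depth <- mean(depths[seq_len(n)])
  scale <- if (mean_depth > 0) 1 / mean_depth else 0
  free <- setdiff(seq_len(L), spec$protected_columns)

  seq_at_node <- vector("list", n + tree$Nnode)
  root <- n + 1L
  seq_at_node[[root]] <- strsplit(spec$seed_sequence, "", fixed = TRUE)[[1]]
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    q <- min(0.95, spec$p_sub * ord$edge.length[e] * scale)
    chars <- seq_at_node[[parent]]
    if (q > 0 && length(free)) {
      hit <- free[runif(length(free)) < q]
      if (length(hit)) chars <- mutate_sites(chars, hit)
    }
    seq_at_node[[child]] <- chars
  }
  records <- lapply(seq_len(n), function(i) {
    chars <- seq_at_node[[i]]
    if (spec$motif_mode == "ablated" && length(spec$protected_columns)) {
      chars[spec$protected_columns] <-
        sample(AA20, length(spec$protected_columns), replace = TRUE)
    } else if (length(spec$protected_columns)) {
      chars[spec$protected_columns] <-
        strsplit(spec$seed_sequence, "", fixed = TRUE)[[1]][spec$protected_columns]
    }
    protein_record(tree$tip.label[i], paste(chars, collapse = ""),
                   group_label = spec$group_label)
  })
  aln <- alignment_block(ids = vapply(records, `[[`, "", "id"),
                         seqs = vapply(records, `[[`, "", "residues"),
                         group_labels = rep(spec$group_label, n))
  list(records = records, alignment = aln, tree = tree, spec = spec)
}

#' Synthetic codon-usage table with a chosen GC3 bias
#'
#' Synonymous frequencies are proportional to `gc3` for codons whose third
#' base is G or C and `1 - gc3` otherwise, normalized per amino acid. The
#' shipped host/bacterial default fixtures use 0.4 and 0.7 so planted
#' contaminants have unambiguous codon-usage truth.
#'
#' @param gc3 Target third-position G+C weight in (0, 1).
#' @param scale Pseudo-counts assigned per amino acid.
#' @return A `codon_usage`.
#' @export
make_codon_usage <- function(gc3 = 0.5, scale = 1000) {
  stopifnot(gc3 > 0, gc3 < 1)
  third <- substr(SENSE_CODONS, 3, 3)
  w <- ifelse(third %in% c("G", "C"), gc3, 1 - gc3)
  aa <- CODON_AA[SENSE_CODONS]
  aa_tot <- tapply(w, aa, sum)[aa]
  counts <- round(scale * w / aa_tot)
  codon_usage_table(setNames(counts, SENSE_CODONS))
}

#' Reverse-translate a protein into a CDS under a codon-usage table
#'
#' Each residue's codon is sampled from the table's synonymous
#' frequencies; a terminal TAA stop is appended. The origin label travels
#' with the record as hidden truth for contaminant-detection tests.
#'
#' @param protein A [protein_record()] (no `X` residues).
#' @param usage A `codon_usage` table.
#' @param exon_count,transit_peptide Gene-structure truth for the record.
#' @param origin Hidden origin label (e.g. `"bacterial"`, `"host"`).
#' @param seed RNG seed (omit to use the current RNG state).
#' @return A [gene_record()] with attribute `origin`.
#' @export
make_cds <- function(protein, usage, exon_count = 1L, transit_peptide = FALSE,
                     origin = "unknown", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(usage, "codon_usage"))
  chars <- strsplit(protein$residues, "", fixed = TRUE)[[1]]
  if (any(chars == "X")) stop("cannot reverse-translate unknown residue X")
  codons <- character(length(chars))
  for (a in unique(chars)) {
    idx <- which(chars == a)
    syn <- SENSE_CODONS[CODON_AA[SENSE_CODONS] == a]
    p <- usage$freq[syn]
    p <- if (all(is.na(p)) || sum(p, na.rm = TRUE) == 0) {
      rep(1, length(syn))
    } else {
      ifelse(is.na(p), 0, p)
    }
    codons[idx] <- sample(syn, length(idx), replace = TRUE, prob = p)
  }
  g <- gene_record(protein$id, gene_class = "EDD", protein = protein,
                   cds = paste(c(codons, "TAA"), collapse = ""),
                   exon_count = exon_count,
                   transit_peptide = transit_peptide)
  attr(g, "origin") <- origin
  g
}

#' Simulate Michaelis-Menten rate data
#'
#' Rates follow `v = Vmax*S/(Km+S)` multiplied by mean-one lognormal noise
#' with coefficient of variation `noise_cv`; `noise_cv = 0` gives exact
#' curve values. The default design mirrors a four-point 0.25-1 mM
#' substrate series with three replicates.
#'
#' @param km,vmax True parameters (Km in mM).
#' @param design Substrate concentrations (mM).
#' @param noise_cv Multiplicative noise CV.
#' @param replicates Replicates per concentration.
#' @param seed RNG seed.
#' @return A [kinetic_dataset()] with attribute `truth`.
#' @export
make_kinetic_data <- function(km, vmax = 1, design = c(0.25, 0.5, 0.75, 1.0),
                              noise_cv = 0, replicates = 3L, seed = 1L) {
  stopifnot(km > 0, vmax > 0, noise_cv >= 0)
  set.seed(seed)
  S <- rep(design, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(design))
  v <- vmax * S / (km + S)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    v <- v * exp(rnorm(length(v), mean = -sdlog^2 / 2, sd = sdlog))
  }
  out <- kinetic_dataset(S, v, rep_id)
  attr(out, "truth") <- c(km = km, vmax = vmax)
  out
}

#' Simulate a standard-addition calibration series
#'
#' Responses are `slope * (endogenous + added)` plus Gaussian noise
#' (relative, so the series stays scale-invariant), one response per
#' spike level.
#'
#' @param endogenous True endogenous amount per assay.
#' @param slope True response slope.
#' @param added Spike amounts (must include 0).
#' @param rel_noise Relative (multiplicative) Gaussian noise SD.
#' @param blank_sd Blank response SD carried into the series.
#' @param seed RNG seed.
#' @return A [calibration_series()] with attribute `truth`.
#' @export
make_calibration_series <- function(endogenous, slope = 1,
                                    added = c(0, 1, 2, 4, 8),
                                    rel_noise = 0, blank_sd = 0, seed = 1L) {
  stopifnot(endogenous >= 0, slope > 0, rel_noise >= 0)
  set.seed(seed)
  y <- slope * (endogenous + added)
  if (rel_noise > 0) y <- y * (1 + rnorm(length(y), sd = rel_noise))
  out <- calibration_series(added, y, blank_sd = blank_sd,
                            design = "standard_addition")
  attr(out, "truth") <- c(endogenous = endogenous, slope = slope)
  out
}

#' Fixed interspersion fixture for the LGT statistics
#'
#' A 12-leaf tree in which the four in-group leaves (`cyano_edd_1..4`,
#' emulating the rare cyanobacterial EDD sequences) sit inside three
#' separate donor clades of proteobacterial/archaeal leaves. The in-group
#' is therefore non-monophyletic and its Fitch interspersion index is 3.
#'
#' @return A list: `tree` ([ape::phylo]), `ingroup` (tip labels),
#'   `labels` (named in/out vector over all tips).
#' @export
make_interspersion_fixture <- function() {
  nwk <- paste0(
    "((cyano_edd_1:1,(proteo_1:1,proteo_2:1):1):1,",
    "((cyano_edd_2:1,cyano_edd_3:1):1,(archaea_1:1,archaea_2:1):1):1,",
    "((proteo_3:1,cyano_edd_4:1):1,(archaea_3:1,proteo_4:1):1):1);")
  tree <- newick_read(nwk)
  ingroup <- sprintf("cyano_edd_%d", 1:4)
  labels <- setNames(ifelse(tree$tip.label %in% ingroup, "in", "out"),
                     tree$tip.label)
  list(tree = tree, ingroup = ingroup, labels = labels)
}

#' Two-clade alignment for bootstrap sanity checks
#'
#' Generates two well-separated synthetic clades (within-clade divergence
#' small, between-clade divergence large) whose separating edge should
#' earn 100% bootstrap support.
#'
#' @param n_per_clade Leaves per clade.
#' @param length Alignment columns.
#' @param seed RNG seed.
#' @return A list: `alignment`, `clade1`, `clade2` (tip label vectors).
#' @export
make_two_clade_alignment <- function(n_per_clade = 4L, length = 200L,
                                     seed = 1L) {
  set.seed(seed)
  anc1 <- random_protein(length)
  anc2chars <- strsplit(anc1, "", fixed = TRUE)[[1]]
  flip <- sample(length, round(0.6 * length))
  anc2chars <- mutate_sites(anc2chars, flip)
  anc2 <- paste(anc2chars, collapse = "")
  diverge <- function(anc, id) {
    chars <- strsplit(anc, "", fixed = TRUE)[[1]]
    hit <- which(runif(length) < 0.03)
    if (length(hit)) chars <- mutate_sites(chars, hit)
    paste(chars, collapse = "")
  }
  ids1 <- sprintf("cladeA_%d", seq_len(n_per_clade))
  ids2 <- sprintf("cladeB_%d", seq_len(n_per_clade))
  seqs <- c(vapply(ids1, function(i) diverge(anc1, i), ""),
            vapply(ids2, function(i) diverge(anc2, i), ""))
  list(alignment = alignment_block(c(ids1, ids2), unname(seqs)),
       clade1 = ids1, clade2 = ids2)
}
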