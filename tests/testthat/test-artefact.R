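host <- make_codon_usage(0.4)
bact <- make_codon_usage(0.7)

test_that("rscu matches hand values on degenerate compositions", {
  leu6 <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  cds_equal <- paste(c(leu6, "TAA"), collapse = "")
  r <- rscu(cds_equal)
  expect_equal(unname(r$rscu[leu6]), rep(1, 6))

  cds_ctg <- paste(c(rep("CTG", 6), "TAA"), collapse = "")
  r2 <- rscu(cds_ctg)
  expect_equal(unname(r2$rscu["CTG"]), 6)
  expect_equal(unname(r2$rscu["TTA"]), 0)
  # unobserved amino acids are undefined, not zero
  expect_true(is.na(r2$rscu["AAA"]))
})

test_that("rscu rejects frame and alphabet violations", {
  expect_error(rscu("ATGTAAAAA"), "internal stop")
  expect_error(rscu("ATGNNNTAA"), "'N' at nucleotide position 4")
  expect_error(rscu("ATGAA"), "not divisible by 3")
})

test_that("rscu of a concatenation equals count-weighted pooling", {
  set.seed(6)
  for (rep in 1:10) {
    p1 <- protein_record("a", random_protein(80))
    p2 <- protein_record("b", random_protein(120))
    g1 <- make_cds(p1, host); g2 <- make_cds(p2, bact)
    cds1 <- sub("TAA$", "", g1$cds); cds2 <- sub("TAA$", "", g2$cds)
    pooled <- rscu(paste0(cds1, cds2))
    manual <- codon_usage_table(rscu(cds1)$counts + rscu(cds2)$counts)
    expect_equal(pooled$rscu, manual$rscu)
  }
})

test_that("codon_llr: zero on identical tables, antisymmetric, length-linear", {
  set.seed(14)
  cds <- make_cds(protein_record("p", random_protein(100)), host)$cds
  expect_identical(codon_llr(cds, host, host), 0)
  expect_equal(codon_llr(cds, host, bact), -codon_llr(cds, bact, host))
  # doubling the sequence doubles the score (length-extensivity)
  body <- sub("TAA$", "", cds)
  expect_equal(codon_llr(paste0(body, body), host, bact),
               2 * codon_llr(body, host, bact))
})

test_that("codon_llr separates host- from bacterial-origin CDS", {
  # 1000 draws each at 300 codons; the GC3 0.4 vs 0.7 tables should be
  # essentially perfectly separable
  set.seed(99)
  prot <- protein_record("p", random_protein(300))
  llr_host <- replicate(1000, codon_llr(make_cds(prot, host)$cds, host, bact))
  llr_bact <- replicate(1000, codon_llr(make_cds(prot, bact)$cds, host, bact))
  expect_gte(mean(llr_host < 0), 0.99)
  expect_gte(mean(llr_bact > 0), 0.99)
})

test_that("a long host-table CDS scores llr < 0 (10 kb example)", {
  set.seed(23)
  prot <- protein_record("big", random_protein(3333))
  lls <- replicate(50, codon_llr(make_cds(prot, host)$cds, host, bact))
  expect_true(all(lls < 0))
})

test_that("artefact_verdict applies the quorum rule", {
  prot <- protein_record("g", random_protein(200))
  contaminant <- make_cds(prot, bact, exon_count = 1, transit_peptide = FALSE,
                          origin = "bacterial", seed = 31)
  v <- artefact_verdict(contaminant, host, bact,
                        nested_in_bacterial_clade = TRUE)
  expect_identical(v$verdict, "artefact")
  expect_identical(v$criteria_met, 4L)

  genuine <- make_cds(prot, host, exon_count = 5, transit_peptide = TRUE,
                      origin = "host", seed = 32)
  v2 <- artefact_verdict(genuine, host, bact,
                         nested_in_bacterial_clade = FALSE)
  expect_identical(v2$verdict, "genuine")
  expect_identical(v2$criteria_met, 0L)

  # a single observable criterion can never decide
  codon_only <- gene_record("c", "EDD", cds = contaminant$cds)
  v3 <- artefact_verdict(codon_only, host, bact)
  expect_identical(v3$criteria_observed, 1L)
  expect_identical(v3$verdict, "indeterminate")
  expect_identical(sort(v3$missing_criteria),
                   c("bacterial_placement", "no_introns",
                     "no_transit_peptide"))

  # 3 observable -> quorum 2
  three <- gene_record("t", "EDD", cds = contaminant$cds, exon_count = 1)
  v4 <- artefact_verdict(three, host, bact, nested_in_bacterial_clade = TRUE)
  expect_identical(v4$criteria_observed, 3L)
  expect_identical(v4$quorum, 2L)
  expect_identical(v4$verdict, "artefact")

  expect_error(artefact_verdict(gene_record("n", "EDD")),
               "no artefact criterion computable")
})

test_that("planted contaminant mixtures are separated perfectly", {
  set.seed(55)
  n <- 20
  genes <- c(
    lapply(seq_len(n), function(i) {
      make_cds(protein_record(sprintf("cont%02d", i), random_protein(250)),
               bact, exon_count = 1, transit_peptide = FALSE,
               origin = "bacterial")
    }),
    lapply(seq_len(n), function(i) {
      make_cds(protein_record(sprintf("gen%02d", i), random_protein(250)),
               host, exon_count = sample(3:8, 1), transit_peptide = TRUE,
               origin = "host")
    }))
  placements <- setNames(c(rep(TRUE, n), rep(FALSE, n)),
                         vapply(genes, `[[`, "", "id"))
  truth <- vapply(genes, function(g) attr(g, "origin"), "")
  tab <- artefact_screen(genes, host, bact, placements)
  sens <- mean(tab$verdict[truth == "bacterial"] == "artefact")
  spec <- mean(tab$verdict[truth == "host"] == "genuine")
  expect_identical(sens, 1)
  expect_identical(spec, 1)
})

test_that("codon table TSV fixtures load and are per-aa normalized", {
  for (f in c("host_codon_usage.tsv", "bacterial_codon_usage.tsv")) {
    tab <- read_codon_table(extdata(f))
    aa <- vapply(names(tab$freq), function(cd)
      as.character(Biostrings::GENETIC_CODE[[cd]]), "")
    sums <- tapply(tab$freq, aa, sum)
    expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  }
})

test_that("transit-peptide heuristic responds to N-terminal composition", {
  tp <- paste(c(rep("S", 10), rep("A", 45), rep("T", 5),
                rep("L", 100)), collapse = "")
  expect_true(transit_peptide_heuristic(tp))
  acidic <- paste(c(rep("D", 10), rep("A", 50), rep("L", 100)), collapse = "")
  expect_false(transit_peptide_heuristic(acidic))
})
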