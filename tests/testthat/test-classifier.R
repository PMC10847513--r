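test_that("parse_pattern implements the motif grammar", {
  d1 <- parse_pattern("LAHGFAAx{4}[DE]Kx{3}")
  expect_identical(d1$min_length, 16L)
  expect_identical(d1$max_length, 16L)
  expect_identical(d1$n_scored, 9L)   # 7 literals + [DE] + K

  d2 <- parse_pattern("KxK[VI]RQLYAx{2}K")
  expect_identical(d2$min_length, 12L)
  expect_identical(d2$n_scored, 9L)

  w <- parse_pattern("x{3}")
  expect_identical(w$n_scored, 0L)
  expect_error(motif_library(list(w3 = w), "EDD-diagnostic"),
               "zero scored positions")

  v <- parse_pattern("Ax{2,4}K")
  expect_identical(v$min_length, 4L)
  expect_identical(v$max_length, 6L)

  expect_error(parse_pattern("LA?H"), "offset 3")
  expect_error(parse_pattern("L[]A"), "empty alternative")
  expect_error(parse_pattern("L[AC"), "unclosed")
})

test_that("pattern serialization round-trips (canonical form)", {
  # alternative sets are canonicalized to sorted order on parse
  expect_identical(pattern_to_string(parse_pattern("KxK[VI]RQLYAx{2}K")),
                   "KxK[IV]RQLYAx{2}K")
  for (s in c("LAHGFAAx{4}[DE]Kx{3}", "KxK[VI]RQLYAx{2}K", "MKV",
              "Ax{2,4}[KR]xP")) {
    canon <- pattern_to_string(parse_pattern(s))
    expect_identical(pattern_to_string(parse_pattern(canon)), canon)
  }
})

test_that("scan_sequence finds a planted exact motif at residues 42-57", {
  set.seed(4)
  base <- random_protein(200)
  instance <- "LAHGFAAQRSTDKAAA"   # matches domain 1 exactly
  substr(base, 42, 57) <- instance
  d1 <- default_motif_library()$patterns$domain1
  m <- scan_sequence(base, d1)
  expect_identical(m$start[1], 42L)
  expect_identical(m$end[1], 57L)
  expect_equal(m$score[1], 1)
  # brute-force oracle agrees on the best window
  o <- oracle_scan_best(base, pattern_sets(d1))
  expect_identical(o$start, 42L)
  expect_equal(o$score, 1)
})

test_that("scan_sequence agrees with the per-window oracle on random input", {
  set.seed(12)
  d2 <- default_motif_library()$patterns$domain2
  for (rep in 1:20) {
    s <- random_protein(sample(50:500, 1))
    m <- scan_sequence(s, d2, max_mismatch = 0)
    o <- oracle_scan_best(s, pattern_sets(d2))
    best <- m[1, ]
    expect_equal(best$score, o$score)
    if (o$score < 1) expect_true(best$sub_threshold || best$mismatches == 0)
    # random sequences essentially never match all 9 scored positions
    expect_lt(best$score, 1)
  }
})

test_that("scan_sequence edge behavior: overlaps, ties, short sequences", {
  m <- scan_sequence("AAA", parse_pattern("AA"), max_mismatch = 0)
  expect_identical(m$start, c(1L, 2L))
  expect_equal(m$score, c(1, 1))

  short <- scan_sequence("MK", parse_pattern("LAHGFAAx{4}[DE]Kx{3}"))
  expect_identical(nrow(short), 0L)
  expect_true(isTRUE(attr(short, "no_window")))

  # X in the sequence satisfies any element
  mx <- scan_sequence("AXA", parse_pattern("AKA"), max_mismatch = 0)
  expect_equal(mx$score[1], 1)
})

test_that("classify_dehydratase calls planted EDD / DHAD correctly", {
  seed <- make_edd_seed(300, 7)
  call <- classify_dehydratase(protein_record("edd1", seed$residues))
  expect_identical(call$label, "EDD")
  expect_equal(call$edd_score, 1)

  # ablate both motif regions -> near-background score; a close DHAD
  # reference then decides the call
  set.seed(8)
  chars <- strsplit(seed$residues, "", fixed = TRUE)[[1]]
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  chars[seed$motif_columns] <- sample(aa, length(seed$motif_columns),
                                      replace = TRUE)
  ablated <- paste(chars, collapse = "")
  # DHAD reference at ~90% identity to the ablated protein
  ref_chars <- chars
  flip <- sample(300, 30)
  for (i in flip) ref_chars[i] <- sample(setdiff(aa, ref_chars[i]), 1)
  refs <- reference_set(list(protein_record("dhad_ref",
                                            paste(ref_chars, collapse = ""))),
                        "DHAD")
  call2 <- classify_dehydratase(protein_record("q", ablated), references = refs)
  expect_lt(call2$edd_score, 0.8)
  expect_identical(call2$label, "DHAD")
  expect_gte(call2$reference_identity, 0.35)

  # no motifs, no close reference -> unknown
  far <- reference_set(list(protein_record("dhad_far", random_protein(400))),
                       "DHAD")
  call3 <- classify_dehydratase(protein_record("q", ablated), references = far)
  expect_identical(call3$label, "unknown")

  expect_error(
    classify_dehydratase(protein_record("q", ablated),
                         motif_library(list(), character(0))),
    "unique names|no EDD-diagnostic")
})

test_that("classification is deterministic and library-order invariant", {
  seed <- make_edd_seed(300, 19)
  prot <- protein_record("p", seed$residues)
  lib <- default_motif_library()
  flipped <- motif_library(rev(lib$patterns), rev(unname(lib$classes)),
                           rev(unname(lib$weights)))
  c1 <- classify_dehydratase(prot, lib)
  c2 <- classify_dehydratase(prot, flipped)
  expect_identical(c1$label, c2$label)
  expect_equal(c1$edd_score, c2$edd_score)
})

test_that("separation: planted families classify perfectly; degradation is monotone", {
  seed <- make_edd_seed(300, 3)
  edd_fam <- make_family(family_spec(seed$residues, 10, p_sub = 0.3,
                                     protected_columns = seed$motif_columns,
                                     motif_mode = "intact",
                                     group_label = "edd", seed = 41))
  dhad_fam <- make_family(family_spec(seed$residues, 10, p_sub = 0.3,
                                      protected_columns = seed$motif_columns,
                                      motif_mode = "ablated",
                                      group_label = "dhad", seed = 42))
  refs <- reference_set(dhad_fam$records[1:2], c("DHAD", "DHAD"))
  calls_edd <- classify_dehydratases(edd_fam$records)
  expect_true(all(calls_edd$label == "EDD"))
  calls_dhad <- classify_dehydratases(dhad_fam$records[-(1:2)],
                                      references = refs)
  expect_true(all(calls_dhad$label == "DHAD"))
  expect_true(all(calls_dhad$edd_score < 0.5))
  expect_identical(nrow(calls_edd) + nrow(calls_dhad), 18L)

  # progressively randomizing motif columns never raises the score
  set.seed(13)
  chars0 <- strsplit(seed$residues, "", fixed = TRUE)[[1]]
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  scores <- vapply(c(0, 4, 9, 14, 20, 28), function(k) {
    chars <- chars0
    if (k > 0) {
      cols <- seed$motif_columns[seq_len(k)]
      chars[cols] <- vapply(chars[cols],
                            function(c) sample(setdiff(aa, c), 1), "")
    }
    classify_dehydratase(protein_record("p", paste(chars, collapse = "")))$edd_score
  }, 0)
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("motif library TSV round-trips and auxiliary weights default", {
  lib <- add_motif(default_motif_library(), parse_pattern("CP", "aux1"))
  expect_equal(unname(lib$weights["aux1"]), 0.25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(data.frame(
    name = names(lib$patterns),
    class = unname(lib$classes),
    weight = unname(lib$weights),
    pattern = vapply(lib$patterns, pattern_to_string, "")), path)
  lib2 <- read_motif_library(path)
  expect_identical(names(lib2$patterns), names(lib$patterns))
  expect_identical(vapply(lib2$patterns, pattern_to_string, ""),
                   vapply(lib$patterns, pattern_to_string, ""))
})
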