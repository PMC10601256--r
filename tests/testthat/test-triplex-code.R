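test_that("canonical code admits exactly U.A and C.G", {
  expect_equal(canonical_triplet_match("U", "A"), "match")
  expect_equal(canonical_triplet_match("C", "G"), "match")
  expect_equal(canonical_triplet_match("C", "T"), "mismatch")
  expect_equal(canonical_triplet_match("G", "G"), "mismatch")
  # exhaustively: 2 matches among the 16 combinations
  combos <- expand.grid(r = c("A", "C", "G", "U"),
                        p = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  hits <- mapply(canonical_triplet_match, combos$r, combos$p)
  expect_equal(sum(hits == "match"), 2L)
  expect_error(canonical_triplet_match("T", "A"), "invalid RNA base")
  expect_error(canonical_triplet_match("U", "U"), "invalid DNA base")
})

test_that("sequence validation rejects wrong alphabets, names position", {
  expect_error(sequence_record("x", "ACGT", "rna"), "'T' at position 4")
  expect_error(sequence_record("x", "AUCG", "dna"), "'U' at position 2")
  expect_error(sequence_record("x", "", "rna"), "empty")
  expect_equal(dna_as_rna(sequence_record("x", "ACGT", "dna"))$sequence,
               "ACGU")
  expect_error(dna_as_rna(sequence_record("x", "ACGU", "rna")), "not DNA")
})

test_that("scan_tts matches exhaustive enumeration (brute-force oracle)", {
  set.seed(101)
  for (rep in 1:5) {
    rna <- sequence_record("r", random_seq(30, c("A", "C", "G", "U")), "rna")
    pur <- sequence_record("p", random_seq(30, c("A", "C", "G", "T")), "dna")
    w <- 8L; mm_max <- 2L
    hits <- scan_tts(rna, pur, window_len = w, max_mismatch = mm_max)
    # independent enumeration
    rb <- strsplit(rna$sequence, "")[[1]]
    pb <- strsplit(pur$sequence, "")[[1]]
    expected <- list()
    for (ro in 1:(30 - w + 1)) {
      for (po in 1:(30 - w + 1)) {
        mm <- count_mm(rb[ro:(ro + w - 1)], pb[po:(po + w - 1)])
        if (mm <= mm_max) {
          expected[[length(expected) + 1L]] <- c(ro, po, mm)
        }
      }
    }
    got <- lapply(hits, function(a) c(a$rna_start, a$purine_start,
                                      a$n_mismatch))
    expect_setequal(
      vapply(got, paste, "", collapse = ","),
      vapply(expected, paste, "", collapse = ",")
    )
    # sorted by (n_mismatch, purine offset, rna offset)
    key <- do.call(rbind, got)
    if (length(got) > 1) {
      expect_false(is.unsorted(order(key[, 3], key[, 2], key[, 1])))
      expect_identical(order(key[, 3], key[, 2], key[, 1]),
                       seq_len(nrow(key)))
    }
  }
})

test_that("all-canonical poly-U window: single perfect alignment", {
  rna <- sequence_record("r", strrep("U", 15), "rna")
  pur <- sequence_record("p", strrep("A", 15), "dna")
  hits <- scan_tts(rna, pur, window_len = 15, max_mismatch = 0)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$n_mismatch, 0L)
  expect_equal(hits[[1]]$orientation, "parallel")
  expect_equal(hits[[1]]$pairing, strrep("|", 15))
})

test_that("short input yields empty result with a warning", {
  rna <- sequence_record("r", "UUUU", "rna")
  pur <- sequence_record("p", strrep("A", 20), "dna")
  expect_warning(hits <- scan_tts(rna, pur, window_len = 15), "shorter")
  expect_length(hits, 0L)
})

test_that("render/parse round-trips alignments (n_mismatch invariant)", {
  expect_equal(tiny_alignment(4)$pairing, "||||")
  expect_equal(tiny_alignment(5, mismatch = 3)$pairing, "||*||")
  set.seed(7)
  for (rep in 1:10) {
    a <- tiny_alignment(10L, mismatch = sample(10, sample(0:3, 1)))
    b <- parse_alignment(render_alignment(a))
    expect_equal(b$n_mismatch, a$n_mismatch)
    expect_equal(b$pairing, a$pairing)
    expect_equal(b$rna_window, a$rna_window)
    expect_equal(b$purine_window, a$purine_window)
    expect_equal(b$rna_start, a$rna_start)
  }
})

test_that("extract_dbd slices 1-based inclusive with provenance", {
  set.seed(5)
  rna <- sequence_record("lncRNA_synthetic",
                         random_seq(1925, c("A", "C", "G", "U")), "rna")
  dbd <- extract_dbd(rna)               # defaults 1896..1925
  expect_equal(length(dbd), 30L)
  expect_equal(dbd$source_id, "lncRNA_synthetic")
  expect_equal(dbd$start, 1896L)
  expect_equal(dbd$sequence, substr(rna$sequence, 1896, 1925))
  one <- extract_dbd(rna, 1, 1)
  expect_equal(length(one), 1L)
  expect_error(extract_dbd(rna, 1926, 1926), "out of range")
  expect_error(extract_dbd(rna, 10, 5), "out of range")
})

test_that("clip_alignment restricts to the core span, never guesses", {
  aln <- example_alignments()
  clipped <- clip_alignment(aln$extended, aln$short)
  expect_equal(length(clipped), 15L)
  expect_equal(clipped$clip_offset, 4L)
  expect_equal(clipped$rna_window, aln$short$rna_window)
  expect_equal(clipped$pairing, aln$short$pairing)
  # idempotence / identity
  self <- clip_alignment(aln$short, aln$short)
  expect_equal(self$rna_window, aln$short$rna_window)
  expect_equal(self$n_mismatch, aln$short$n_mismatch)
  # absent core
  expect_error(clip_alignment(aln$extended, aln$stable_A), "not found")
  # ambiguous core
  rna <- sequence_record("r", "UUUUUUUU", "rna")
  pur <- sequence_record("p", "AAAAAAAA", "dna")
  ext <- triplex_alignment(rna, pur, 1, 1, 8)
  core <- triplex_alignment(rna, pur, 1, 1, 4)
  expect_error(clip_alignment(ext, core), "multiple offsets")
})

test_that("purine strand selection uses purine content with override", {
  s1 <- sequence_record("s1", "AGAGAGAG", "dna")
  s2 <- sequence_record("s2", "CTCTCTCT", "dna")
  expect_equal(choose_purine_strand(s1, s2)$id, "s1")
  expect_equal(choose_purine_strand(s2, s1)$id, "s1")
  expect_equal(choose_purine_strand(s1, s2, force = 2)$id, "s2")
  s3 <- sequence_record("s3", "AACC", "dna")
  s4 <- sequence_record("s4", "GGTT", "dna")
  expect_error(choose_purine_strand(s3, s4), "equal purine content")
})

test_that("TSV and BED outputs have the documented shapes", {
  aln <- example_alignments()
  hits <- list(aln$stable_A, aln$short)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_tts_tsv(hits, tsv)
  df <- read.delim(tsv)
  expect_equal(names(df), c("rna_start", "rna_end", "purine_start",
                            "purine_end", "length", "n_mismatch",
                            "pairing"))
  expect_equal(df$n_mismatch, c(2L, 2L))
  write_tts_bed(hits, bed)
  bd <- read.delim(bed, header = FALSE)
  expect_equal(ncol(bd), 6L)
  expect_equal(bd$V2, c(0L, 0L))          # 0-based start
  expect_equal(bd$V3, c(15L, 15L))        # half-open end
})
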