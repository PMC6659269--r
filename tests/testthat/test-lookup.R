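test_that("postings enumerate every word position once, both orientations", {
  rb <- read_batch(paste(rep("ACGT", 8), collapse = ""))
  lk <- build_lookup(rb, word_size = 16L)
  # 17 word start positions per orientation; brute-force the expected words
  expect_equal(length(lk$key), 34L)
  words <- vapply(0:16, function(p) substr(rb$seq, p + 1L, p + 16L), "")
  expect_setequal(key_to_word(unique(lk$key[lk$strand == 0L]), 16L),
                  unique(words))
  fwd <- lk$strand == 0L
  expect_setequal(lk$offset[fwd], 0:16)
})

test_that("words containing N are never indexed", {
  rb <- read_batch(paste0(strrep("A", 8), "N", strrep("C", 20)))
  lk <- build_lookup(rb)
  # every surviving posting window must avoid the N at offset 8
  words <- key_to_word(lk$key, 16L)
  expect_false(any(grepl("N", words)))
  # brute force: valid fwd windows are those fully inside the C run
  expect_true(all(lk$offset[lk$strand == 0L] > 8L))
})

test_that("poly-A masking uses the at-least-15-of-16 rule", {
  expect_true(is_polyA_masked(strrep("A", 16)))
  expect_true(is_polyA_masked(strrep("T", 16)))
  expect_true(is_polyA_masked(paste0(strrep("A", 15), "G")))
  expect_false(is_polyA_masked(paste0(strrep("A", 14), "CC")))
  # a 16-A read yields zero postings and a recorded masked word
  lk <- build_lookup(read_batch(strrep("A", 16)))
  expect_equal(length(lk$key), 0L)
  expect_true(strrep("A", 16) %in% masked_words(lk, "polyA") ||
                strrep("T", 16) %in% masked_words(lk, "polyA"))
})

test_that("98 words of the full alphabet are poly-A masked", {
  # combinatorial enumeration: words within Hamming distance 1 of the A-
  # and T-homopolymers; the two sets are disjoint
  n_near <- function() 1 + 16 * 3
  expect_equal(2 * n_near(), 98)
  # spot-check the rule against random members/non-members
  set.seed(42)
  for (i in 1:50) {
    w <- strsplit(strrep("A", 16), "")[[1]]
    k <- sample(0:2, 1)
    if (k > 0) w[sample(16, k)] <- sample(c("C", "G"), k, replace = TRUE)
    expect_equal(is_polyA_masked(paste0(w, collapse = "")), k <= 1)
  }
})

test_that("empty batches and short reads are handled explicitly", {
  expect_error(read_batch(character(0)), "empty")
  expect_warning(build_lookup(read_batch(c("ACGTACGTACGTACGTACGT", "ACGT"))),
                 "shorter than word_size")
})

test_that("reference repeat masking obeys the more-than-cutoff rule", {
  w <- "ACGTTGCAACGTGGCA"   # the word under test
  spacers <- function(n) vapply(seq_len(n), function(i) rand_dna(5), "")
  mk_ref <- function(copies) {
    reference_set(c(chr1 = paste0(paste0(spacers(copies), w, collapse = ""),
                                  rand_dna(30))))
  }
  set.seed(7)
  rb <- read_batch(paste0(rand_dna(10), w, rand_dna(10)))
  lk <- build_lookup(rb)
  key_w <- lk$ukey[key_to_word(lk$ukey, 16L) == w]
  expect_length(key_w, 1L)
  set.seed(8)
  at_cut <- count_and_mask_repeats(lk, mk_ref(60L), cutoff = 60L)
  expect_true(key_w %in% at_cut$ukey)          # exactly 60: retained
  set.seed(8)
  over <- count_and_mask_repeats(lk, mk_ref(61L), cutoff = 60L)
  expect_false(key_w %in% over$ukey)           # 61 > 60: masked
  expect_true(w %in% masked_words(over, "repeat"))
  # a heavily repeated reference word absent from the reads: never counted
  set.seed(9)
  other <- strrep("AC", 8)
  ref2 <- reference_set(c(chr1 = paste0(
    paste0(vapply(1:100, function(i) rand_dna(4), ""), other,
           collapse = ""))))
  lk2 <- count_and_mask_repeats(lk, ref2, cutoff = 60L)
  expect_identical(lk2$ukey, lk$ukey)
})

test_that("no seed ever starts at a masked word's positions", {
  set.seed(11)
  w <- "ACGTTGCAACGTGGCA"
  # a read that is exactly the repeated word: its only lookup entries are
  # the word and its reverse complement
  rb <- read_batch(w)
  body <- paste0(vapply(1:70, function(i) rand_dna(6), ""), w,
                 collapse = "")
  ref <- reference_set(c(chr1 = body))
  lk <- count_and_mask_repeats(build_lookup(rb), ref, cutoff = 60L)
  seeds <- scan_reference(ref, lk, seed_len = 16L)
  expect_equal(nrow(seeds), 0L)
  # poly-A/poly-T reads produce zero seeds outright
  rbA <- read_batch(c(strrep("A", 40), strrep("T", 40)))
  seedsA <- scan_reference(ref, build_lookup(rbA), seed_len = 16L)
  expect_equal(nrow(seedsA), 0L)
})

test_that("seeds are sound and complete on clean unique loci", {
  set.seed(13)
  for (i in 1:25) {
    ref_seq <- rand_dna(1500)
    ref <- reference_set(c(chr1 = ref_seq))
    at <- sample(400, 1)
    len <- sample(30:60, 1)
    rd <- substr(ref_seq, at + 1L, at + len)
    seeds <- scan_reference(ref, build_lookup(read_batch(rd)))
    expect_gt(nrow(seeds), 0L)
    # soundness: reported substrings byte-identical
    for (k in seq_len(nrow(seeds))) {
      s <- seeds[k, ]
      rseq <- if (s$strand == "+") rd else revcomp(rd)
      expect_identical(substr(rseq, s$read_start + 1L, s$read_end),
                       substr(ref_seq, s$ref_start + 1L, s$ref_end))
    }
    # completeness: one seed covers the full locus
    expect_true(any(seeds$strand == "+" & seeds$read_start == 0L &
                      seeds$read_end == len & seeds$ref_start == at))
  }
})

test_that("seed length threshold separates 17 from 18 exact bases", {
  set.seed(17)
  repeat {
    ref_seq <- rand_dna(800)
    run17 <- substr(ref_seq, 301, 317)
    # embed the 17-base run in an otherwise foreign read; break extension
    # on both sides with a base different from the reference continuation
    lflank <- rand_dna(10)
    rflank <- rand_dna(10)
    l_ok <- substr(lflank, 10, 10) != substr(ref_seq, 300, 300)
    r_ok <- substr(rflank, 1, 1) != substr(ref_seq, 318, 318)
    if (l_ok && r_ok) break
  }
  rd <- paste0(lflank, run17, rflank)
  ref <- reference_set(c(chr1 = ref_seq))
  s17 <- scan_reference(ref, build_lookup(read_batch(rd)), seed_len = 18L)
  expect_false(any(s17$ref_start == 300L & s17$ref_end == 317L))
  # same construction one base longer yields the seed
  run18 <- substr(ref_seq, 301, 318)
  repeat {
    rflank2 <- rand_dna(10)
    if (substr(rflank2, 1, 1) != substr(ref_seq, 319, 319)) break
  }
  rd2 <- paste0(lflank, run18, rflank2)
  s18 <- scan_reference(ref, build_lookup(read_batch(rd2)), seed_len = 18L)
  expect_true(any(s18$ref_start == 300L & s18$ref_end == 318L &
                    s18$strand == "+"))
})

test_that("a read spanning an intron yields one seed per exon", {
  set.seed(19)
  fx <- two_exon_fixture(exon1_len = 25L, intron_len = 80L, exon2_len = 25L,
                         lead = 20L)
  ref <- reference_set(c(chr1 = fx$genome))
  seeds <- scan_reference(ref, build_lookup(read_batch(fx$read)))
  plus <- seeds[seeds$strand == "+", ]
  expect_equal(nrow(plus), 2L)
  expect_setequal(plus$read_start, c(0L, fx$junction))
})
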