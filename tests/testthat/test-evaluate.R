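mk_calls <- function(donors, support = 1L) {
  data.frame(ref = rep("chr1", length(donors)), donor = donors,
             acceptor = donors + 100L,
             strand = rep("+", length(donors)),
             class = rep("canonical", length(donors)),
             support = rep_len(support, length(donors)),
             stringsAsFactors = FALSE)
}
mk_truth <- function(donors) {
  data.frame(ref = rep("chr1", length(donors)), donor = donors,
             acceptor = donors + 100L, stringsAsFactors = FALSE)
}

test_that("precision, recall and F reproduce hand-computed values", {
  # TP 3, FP 1, FN 1 -> p = r = F = 0.75
  ev <- evaluate_introns(mk_calls(c(1000L, 2000L, 3000L, 9000L)),
                         mk_truth(c(1000L, 2000L, 3000L, 5000L)))
  expect_equal(ev$overall$TP, 3L)
  expect_equal(ev$overall$FP, 1L)
  expect_equal(ev$overall$FN, 1L)
  expect_equal(ev$overall$precision, 0.75)
  expect_equal(ev$overall$recall, 0.75)
  expect_equal(ev$overall$F, 0.75)
  # perfect agreement: all ones at every coverage with support
  ev2 <- evaluate_introns(mk_calls(c(100L, 200L), support = 5L),
                          mk_truth(c(100L, 200L)))
  expect_true(all(ev2$roc$precision[1:5] == 1))
  expect_true(all(ev2$roc$recall[1:5] == 1))
  expect_equal(ev2$best$F, 1)
})

test_that("edge conventions: empty truth and zero TP", {
  ev <- evaluate_introns(mk_calls(1000L), mk_truth(integer(0)))
  expect_true(is.na(ev$overall$recall))
  ev2 <- evaluate_introns(mk_calls(1000L), mk_truth(2000L))
  expect_equal(ev2$overall$F, 0)
  # calls equal truth via brute-force set operations on random sets
  set.seed(119)
  for (i in 1:20) {
    cd <- sample(seq(100L, 5000L, by = 100L), sample(3:10, 1))
    td <- sample(seq(100L, 5000L, by = 100L), sample(3:10, 1))
    ev3 <- evaluate_introns(mk_calls(cd), mk_truth(td))
    expect_equal(ev3$overall$TP, length(intersect(cd, td)))
    expect_equal(ev3$overall$FP, length(setdiff(cd, td)))
    expect_equal(ev3$overall$FN, length(setdiff(td, cd)))
  }
})

test_that("ROC true and false positives are non-increasing in coverage", {
  set.seed(121)
  calls <- mk_calls(seq(100L, 4000L, by = 100L),
                    support = sample(1:20, 40, replace = TRUE))
  ev <- evaluate_introns(calls, mk_truth(seq(100L, 2000L, by = 100L)))
  expect_true(all(diff(ev$roc$TP) <= 0))
  expect_true(all(diff(ev$roc$FP) <= 0))
  # support above the top bin folds into it
  calls2 <- mk_calls(100L, support = 1000L)
  ev2 <- evaluate_introns(calls2, mk_truth(100L))
  expect_equal(ev2$roc$TP[100], 1L)
})

test_that("alignment categories follow the truth-containment rules", {
  g <- simulate_genome(50000, seed = 123)
  sim <- simulate_transcripts_and_reads(g, n_transcripts = 3, n_exons = 2,
                                        exon_length = c(150, 250),
                                        intron_length = c(60, 200),
                                        n_fragments = 25, read_length = 100,
                                        paired = FALSE, seed = 124)
  res <- align_reads(sim$reads, sim$reference)
  ev <- evaluate_alignments(res$records, sim$truth)
  expect_equal(sum(ev$counts), sim$reads$n)
  # perfect placement is exact
  expect_gt(ev$counts[["exact"]], 0)
  # a placement trimmed inside the truth is partial
  rec <- res$records[bitwAnd(res$records$flag, 256L) == 0L, ]
  k <- which(rec$cigar == "100M")[1]
  trimmed <- rec[k, ]
  trimmed$pos <- trimmed$pos + 5L
  trimmed$cigar <- "5S90M5S"
  ev2 <- evaluate_alignments(trimmed, sim$truth)
  expect_equal(unname(ev2$counts[["partial"]]), 1L)
  # a placement on the wrong chromosome is misaligned
  wrong <- rec[k, ]
  wrong$rname <- "chrX"
  ev3 <- evaluate_alignments(wrong, sim$truth)
  expect_equal(unname(ev3$counts[["misaligned"]]), 1L)
  # an unmapped record counts as unmapped
  un <- rec[k, ]; un$flag <- bitwOr(un$flag, 4L); un$rname <- "*"
  expect_equal(unname(evaluate_alignments(un, sim$truth)$counts[["unmapped"]]),
               1L)
})

test_that("mismatch QC recounts mismatches base by base", {
  # record with NM 3 over 100 aligned bases -> 30 per kb
  ref <- reference_set(c(chr1 = paste0(strrep("ACGT", 50))))
  seq100 <- substr(ref$seq[[1]], 1, 100)
  ch <- strsplit(seq100, "")[[1]]
  stopifnot(all(ch[c(10, 50, 90)] == "C"))
  ch[c(10, 50, 90)] <- "G"
  rec <- data.frame(qname = "r", flag = 0L, rname = "chr1", pos = 1L,
                    mapq = 60L, cigar = "100M", rnext = "*", pnext = 0L,
                    tlen = 0L, seq = paste0(ch, collapse = ""), qual = "*",
                    NM = 3L, AS = 85L, stringsAsFactors = FALSE)
  qc <- mismatch_qc(rec, ref)
  expect_equal(qc$totals$mismatches, 3L)
  expect_equal(qc$totals$mm_per_kb, 30)
  expect_equal(sum(qc$per_cycle$mismatches), 3L)
  expect_equal(which(qc$per_cycle$mismatches == 1L), c(10L, 50L, 90L))
  # all-perfect records: zero
  rec0 <- rec; rec0$seq <- seq100; rec0$NM <- 0L
  expect_equal(mismatch_qc(rec0, ref)$totals$mm_per_kb, 0)
  # secondary records are excluded
  sec <- rec; sec$flag <- 256L
  expect_equal(nrow(mismatch_qc(rbind(rec0, sec), ref)$per_record), 1L)
  # totals equal a brute-force recount on a mixed simulated fixture
  g <- simulate_genome(60000, seed = 127)
  sim <- simulate_transcripts_and_reads(g, n_transcripts = 4, n_exons = 2,
                                        exon_length = c(150, 250),
                                        intron_length = c(60, 200),
                                        n_fragments = 40, read_length = 100,
                                        paired = FALSE, sub_rate = 0.02,
                                        seed = 128)
  res <- align_reads(sim$reads, sim$reference)
  qc2 <- mismatch_qc(res$records, sim$reference)
  prim <- res$records[bitwAnd(res$records$flag, 256L) == 0L &
                        res$records$rname != "*", ]
  expect_equal(qc2$totals$mismatches,
               sum(recompute_nm(prim, sim$reference)) -
                 sum(vapply(prim$cigar, function(cg) {
                   ops <- spliceseed:::parse_cigar(cg)
                   sum(ops$len[ops$op %in% c("I", "D")])
                 }, integer(1))))
})
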