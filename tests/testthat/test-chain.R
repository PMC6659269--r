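# minimal all-match segment for chain tests
m_seg <- function(rs, re, fs, score = re - rs) {
  local_alignment(1L, "+", rs, re, "chr1", fs, fs + (re - rs),
                  "M", re - rs, score)
}

test_that("single alignments and disjoint exon pairs chain as expected", {
  a <- m_seg(0L, 50L, 1000L)
  expect_equal(chain_alignments(list(a))$score, 50L)
  b <- m_seg(50L, 100L, 11000L)
  ch <- chain_alignments(list(a, b))
  expect_equal(ch$score, 100L)
  expect_length(ch$segments, 2L)
  expect_null(chain_alignments(list()))
})

test_that("chain score equals exhaustive enumeration on small instances", {
  set.seed(59)
  for (i in 1:120) {
    n <- sample(2:5, 1)
    segs <- lapply(seq_len(n), function(k) {
      rs <- sample(0:120, 1)
      len <- sample(20:60, 1)
      fs <- sample(0:50000, 1)
      m_seg(rs, rs + len, fs, score = len - sample(0:8, 1))
    })
    got <- chain_alignments(segs)$score
    expect_equal(got, oracle_best_chain(segs))
  }
})

test_that("intron length bounds and read-gap bounds gate chaining", {
  a <- m_seg(0L, 50L, 0L)
  # intron of 29 bases (< 30) cannot be chained; 30 can
  b29 <- m_seg(50L, 100L, 50L + 29L)
  b30 <- m_seg(50L, 100L, 50L + 30L)
  expect_length(chain_alignments(list(a, b29))$segments, 1L)
  expect_length(chain_alignments(list(a, b30))$segments, 2L)
  # read gap of 10 chains, 11 does not
  g10 <- m_seg(60L, 100L, 5000L)
  g11 <- m_seg(61L, 100L, 5000L)
  expect_length(chain_alignments(list(a, g10))$segments, 2L)
  expect_length(chain_alignments(list(a, g11))$segments, 1L)
})

test_that("junction resolution matches the windowed brute-force oracle", {
  set.seed(61)
  n_done <- 0L
  for (i in 1:150) {
    glen <- 500L
    g <- rand_dna(glen)
    a <- sample(30:70, 1)          # junction position on the read
    n <- a + sample(30:70, 1)      # read length
    fsL <- 40L
    e_true <- fsL + a              # implied donor if split at the junction
    q1_true <- sample(250:350, 1)  # exon2 reference start
    # optionally plant signals at a few offsets around the junction
    for (p in sample(-5:5, sample(0:3, 1))) {
      sig <- sample(c("GTAG", "CTAC", "GCAG", "ATAC", "TTTT"), 1)
      g <- paste0(substr(g, 1, e_true + p),
                  substr(sig, 1, 2),
                  substr(g, e_true + p + 3, glen))
      g <- paste0(substr(g, 1, q1_true + p - 2),
                  substr(sig, 3, 4),
                  substr(g, q1_true + p + 1, glen))
    }
    read <- paste0(substr(g, fsL + 1, fsL + a),
                   substr(g, q1_true + 1, q1_true + (n - a)))
    o1 <- sample(0:6, 1); o2 <- sample(0:6, 1)
    left <- labeled_local(read, g, 0L, min(n, a + o1), fsL)
    right <- labeled_local(read, g, max(0L, a - o2), n,
                           q1_true - min(a, o2))
    want <- oracle_junction(left, right, g)
    got <- resolve_junction(left, right, g)
    if (is.null(want)) { expect_null(got); next }
    n_done <- n_done + 1L
    expect_equal(got$donor, want$donor)
    expect_equal(got$acceptor, want$acceptor)
    expect_equal(got$class, want$class)
    # hierarchy property: a canonical candidate is never outranked
    if (want$priority == 1L) expect_equal(got$class, "canonical")
    # the two cut segments remain read-continuous
    expect_equal(got$left$read_end, got$right$read_start)
  }
  expect_gte(n_done, 40L)
})

test_that("minor splice signals require score 50 on both sides", {
  set.seed(67)
  # genome: exon1 | GC-intron-AG | exon2, read continuous across it
  mk <- function(exon1_len) {
    fx <- two_exon_fixture(exon1_len = exon1_len, intron_len = 60L,
                           exon2_len = 60L, signal = c("GC", "AG"))
    left <- labeled_local(fx$read, fx$genome, 0L, fx$junction, 0L)
    right <- labeled_local(fx$read, fx$genome, fx$junction,
                           nchar(fx$read), fx$exon2_start)
    resolve_junction(left, right, fx$genome)
  }
  j50 <- mk(50L)   # both sides score >= 50: minor site eligible
  expect_false(is.null(j50))
  expect_equal(j50$class, "minor_GC_AG")
  j49 <- mk(49L)   # left side scores 49: minor sites are not searched
  expect_null(j49)
})

test_that("short reads only call GT-AG introns", {
  set.seed(71)
  fx <- two_exon_fixture(exon1_len = 55L, intron_len = 60L,
                         exon2_len = 60L, signal = c("GC", "AG"))
  left <- labeled_local(fx$read, fx$genome, 0L, fx$junction, 0L)
  right <- labeled_local(fx$read, fx$genome, fx$junction, nchar(fx$read),
                         fx$exon2_start)
  j <- resolve_junction(left, right, fx$genome)
  sp <- spliced_alignment(list(j$left, j$right),
                          data.frame(donor = j$donor, acceptor = j$acceptor,
                                     class = j$class,
                                     signal_strand = j$signal_strand,
                                     stringsAsFactors = FALSE))
  # 99-base read: the GC-AG intron is dropped, best piece remains
  short <- apply_short_read_policy(sp, 99L, threshold = 100L)
  expect_equal(nrow(short$introns), 0L)
  expect_length(short$segments, 1L)
  # 100-base read: eligible, intron kept
  keep <- apply_short_read_policy(sp, 100L, threshold = 100L)
  expect_equal(nrow(keep$introns), 1L)
  # canonical introns are untouched at any read length
  fx2 <- two_exon_fixture(exon1_len = 55L, intron_len = 60L,
                          exon2_len = 60L, signal = c("GT", "AG"))
  l2 <- labeled_local(fx2$read, fx2$genome, 0L, fx2$junction, 0L)
  r2 <- labeled_local(fx2$read, fx2$genome, fx2$junction, nchar(fx2$read),
                      fx2$exon2_start)
  j2 <- resolve_junction(l2, r2, fx2$genome)
  sp2 <- spliced_alignment(list(j2$left, j2$right),
                           data.frame(donor = j2$donor,
                                      acceptor = j2$acceptor,
                                      class = j2$class,
                                      signal_strand = j2$signal_strand,
                                      stringsAsFactors = FALSE))
  expect_equal(nrow(apply_short_read_policy(sp2, 50L)$introns), 1L)
})

test_that("gap repair recovers GT-AG within its search constraints", {
  fx <- repair_fixture()
  loc <- function(rs, re, fs) labeled_local(fx$read, fx$genome, rs, re, fs)
  right <- loc(50L, 100L, 80L)     # starts 5 bases into exon2
  # donor within 4 bases of the left end: repaired
  j <- repair_gap_junction(loc(0L, 41L, 0L), right, fx$read, fx$genome)
  expect_false(is.null(j))
  expect_equal(j$donor, fx$donor); expect_equal(j$acceptor, fx$acceptor)
  expect_equal(j$class, "canonical")
  expect_equal(j$left$read_end, j$right$read_start)
  # donor 5 bases past the left end and acceptor out of range: no repair
  expect_null(repair_gap_junction(loc(0L, 40L, 0L), right,
                                  fx$read, fx$genome))
  # 11 unaligned bases: repair not attempted at all
  expect_null(repair_gap_junction(loc(0L, 39L, 0L), right,
                                  fx$read, fx$genome))
  # donor-first fails but the acceptor-first pass succeeds
  right_near <- loc(46L, 100L, 76L)  # starts 1 base into exon2
  j2 <- repair_gap_junction(loc(0L, 40L, 0L), right_near,
                            fx$read, fx$genome)
  expect_false(is.null(j2))
  expect_equal(j2$donor, fx$donor); expect_equal(j2$acceptor, fx$acceptor)
})

test_that("gap repair tolerates one extra indel at the junction", {
  fx <- repair_fixture()
  # read with one base deleted right before the junction: continuity needs
  # an extra 1-base deletion
  read_del <- paste0(substr(fx$read, 1, 44), substr(fx$read, 46, 100))
  left <- labeled_local(read_del, fx$genome, 0L, 43L, 0L)
  right <- labeled_local(read_del, fx$genome, 49L, 99L, 80L)
  j <- repair_gap_junction(left, right, read_del, fx$genome)
  expect_false(is.null(j))
  expect_equal(j$acceptor, fx$acceptor)
  cols <- c(rep(j$left$op, j$left$len), rep(j$right$op, j$right$len))
  expect_equal(sum(cols == "D"), 1L)
})

test_that("splice-neutral scoring never prefers spliced over continuous", {
  set.seed(79)
  fx <- two_exon_fixture(exon1_len = 60L, intron_len = 100L,
                         exon2_len = 60L)
  # spliced placement on the genome
  left <- labeled_local(fx$read, fx$genome, 0L, fx$junction, 0L)
  right <- labeled_local(fx$read, fx$genome, fx$junction, nchar(fx$read),
                         fx$exon2_start)
  j <- resolve_junction(left, right, fx$genome)
  sp <- spliced_alignment(list(j$left, j$right),
                          data.frame(donor = j$donor, acceptor = j$acceptor,
                                     class = j$class,
                                     signal_strand = j$signal_strand,
                                     stringsAsFactors = FALSE))
  # continuous placement of the same bases on the spliced-out sequence
  # (a processed retro-copy): identical total score
  retro <- paste0(substr(fx$genome, 1, fx$junction),
                  substr(fx$genome, fx$exon2_start + 1, nchar(fx$genome)))
  cont <- labeled_local(fx$read, retro, 0L, nchar(fx$read), 0L)
  expect_equal(sp$score, cont$score)
  expect_equal(sp$score, nchar(fx$read))
})

test_that("intron calls aggregate by coordinates with read support", {
  seg1 <- m_seg(0L, 50L, 999L)
  seg2 <- m_seg(50L, 100L, 999L + 50L + 100L)
  intr <- data.frame(donor = 1049L, acceptor = 1148L, class = "canonical",
                     signal_strand = "+", stringsAsFactors = FALSE)
  sp <- spliced_alignment(list(seg1, seg2), intr)
  calls <- collect_introns(list(sp, sp))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, 2L)
  expect_equal(calls$donor, 1049L)
  expect_equal(calls$acceptor, 1148L)
  # distinct junctions stay distinct
  intr2 <- intr; intr2$donor <- 1050L
  seg2b <- m_seg(50L, 100L, 999L + 51L + 100L)
  sp2 <- spliced_alignment(list(seg1, seg2b), intr2)
  expect_equal(nrow(collect_introns(list(sp, sp2))), 2L)
})
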