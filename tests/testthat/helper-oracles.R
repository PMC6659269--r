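# Independent oracles and fixture builders used across the suite.
# Everything here recomputes from first principles (sequences, enumeration,
# Smith-Waterman) and never calls the code path it checks.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste0(sample(BASES, n, replace = TRUE), collapse = "")

other_base <- function(b) sample(setdiff(BASES, b), 1L)

# Smith-Waterman local alignment score under the aligner's scoring scheme
# (match 1, mismatch -4, gap open 0, gap extend -4), via Biostrings.
dp_local_score <- function(read, ref) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                baseOnly = TRUE)
  as.integer(Biostrings::score(Biostrings::pairwiseAlignment(
    read, ref, type = "local", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 4)))
}

# Random extension instance with canonically isolated events: <=3-base
# indels and substitutions separated by >= 13 matching bases under EVERY
# equal-score gap placement.  A coincidental match at either indel
# boundary would let the gap slide and shrink the effective spacing below
# the premise, so inserted blocks differ from the template at both ends
# and deletions cannot start a frame-shifted match run in either
# direction.
gen_isolated_instance <- function(ref_len = 260L, tpl_at = 51L,
                                  tpl_len = 120L) {
  ref <- rand_dna(ref_len)
  rd <- strsplit(substr(ref, tpl_at, tpl_at + tpl_len - 1L), "")[[1]]
  shift <- 0L
  pos <- sort(sample(seq(20L, tpl_len - 20L, by = 17L), sample(0:3, 1L)))
  for (p0 in pos) {
    p <- p0 + shift
    ev <- sample(c("sub", "ins", "del"), 1L)
    if (ev == "sub") {
      rd[p] <- other_base(rd[p])
    } else if (ev == "ins") {
      L <- sample(1:3, 1L)
      ins <- sample(BASES, L, replace = TRUE)
      if (L == 1L) {
        ins[1L] <- sample(setdiff(BASES, c(rd[p], rd[p + 1L])), 1L)
      } else {
        ins[1L] <- other_base(rd[p + 1L])   # no rightward slide
        ins[L] <- other_base(rd[p])         # no leftward slide
      }
      rd <- append(rd, ins, after = p)
      shift <- shift + L
    } else {
      L <- sample(1:3, 1L)
      if (p + L > length(rd) || rd[p + L] == rd[p]) next
      if (p > 1L && rd[p - 1L] == rd[p + L - 1L]) next
      rd <- rd[-(p:(p + L - 1L))]
      shift <- shift - L
    }
  }
  list(read = paste0(rd, collapse = ""), ref = ref)
}

# Best seed (longest exact run) for a read on a single-sequence reference.
best_seed <- function(read_seq, refset) {
  lk <- build_lookup(read_batch(read_seq))
  seeds <- scan_reference(refset, lk)
  if (nrow(seeds) == 0L) return(NULL)
  seeds[which.max(seeds$read_end - seeds$read_start), ]
}

# Ungapped local alignment with M/X labels computed directly from the
# sequences (0-based half-open coordinates).
labeled_local <- function(read_seq, ref_seq, rs, re, fs, ref = "chr1",
                          strand = "+", read = 1L) {
  a <- strsplit(substr(read_seq, rs + 1L, re), "")[[1]]
  b <- strsplit(substr(ref_seq, fs + 1L, fs + (re - rs)), "")[[1]]
  lab <- ifelse(a == b & a != "N" & b != "N", "M", "X")
  r <- rle(lab)
  score <- sum(lab == "M") - 4L * sum(lab == "X")
  local_alignment(read, strand, rs, re, ref, fs, fs + (re - rs),
                  r$values, r$lengths, score)
}

# Exhaustive-enumeration chain oracle over all permutations of all subsets
# (n <= 5): the combined score is the sum of segment scores minus
# match * read-overlap per adjacent pair, under the stated compatibility
# rules.
oracle_best_chain <- function(segs, match = 1L, min_intron = 30L,
                              max_intron = 500000L, max_gap = 10L) {
  n <- length(segs)
  rs <- vapply(segs, `[[`, integer(1), "read_start")
  re <- vapply(segs, `[[`, integer(1), "read_end")
  fs <- vapply(segs, `[[`, integer(1), "ref_start")
  fe <- vapply(segs, `[[`, integer(1), "ref_end")
  sc <- vapply(segs, `[[`, integer(1), "score")
  compatible <- function(i, j) {
    if (rs[j] <= rs[i] || re[j] <= re[i]) return(FALSE)
    gap <- rs[j] - re[i]
    if (gap > max_gap) return(FALSE)
    ov <- max(0L, -gap)
    if (ov >= re[i] - rs[i] || ov >= re[j] - rs[j]) return(FALSE)
    ilen <- fs[j] - fe[i] + ov
    ilen >= min_intron && ilen <= max_intron
  }
  best <- -Inf
  recurse <- function(path, remaining, score) {
    best <<- max(best, score)
    for (k in remaining) {
      if (length(path) == 0L || compatible(path[length(path)], k)) {
        ov <- if (length(path)) max(0L, re[path[length(path)]] - rs[k]) else 0L
        recurse(c(path, k), setdiff(remaining, k), score + sc[k] - match * ov)
      }
    }
  }
  recurse(integer(0), seq_len(n), 0L)
  best
}

# Brute-force junction oracle for two ungapped read-continuous locals:
# scans every split offset, classifies the intron dinucleotides, applies
# the hierarchy (canonical > GC-AG > AT-AC > other), the score-50 gate on
# minor/non-canonical, and the (priority, score, upstream donor)
# tie-break.
oracle_junction <- function(left, right, ref_seq, min_side = 50L,
                            min_intron = 30L) {
  pri_of <- function(d, a) {
    sig <- paste0(d, a)
    if (sig %in% c("GTAG", "CTAC")) 1L
    else if (sig %in% c("GCAG", "CTGC")) 2L
    else if (sig %in% c("ATAC", "GTAT")) 3L
    else 4L
  }
  class_of <- c("canonical", "minor_GC_AG", "minor_AT_AC", "non_canonical")
  gate <- left$score >= min_side && right$score >= min_side
  lo <- max(right$read_start, left$read_start + 1L)
  hi <- min(left$read_end, right$read_end - 1L)
  if (lo > hi) return(NULL)
  cut_score <- function(aln, s, side) {
    # ungapped: per-column labels recomputed from run-lengths
    lab <- rep(aln$op, aln$len)
    k <- s - aln$read_start
    lab <- if (side == "L") lab[seq_len(k)] else
      if (k > 0L) lab[-seq_len(k)] else lab
    sum(lab == "M") - 4L * sum(lab == "X")
  }
  best <- NULL
  for (s in lo:hi) {
    e <- left$ref_start + (s - left$read_start)       # donor position
    b <- right$ref_start + (s - right$read_start)     # first exon2 ref base
    if (b - e < min_intron) next
    d <- substr(ref_seq, e + 1L, e + 2L)
    a <- substr(ref_seq, b - 1L, b)
    pri <- pri_of(d, a)
    if (pri > 1L && !gate) next
    sc <- cut_score(left, s, "L") + cut_score(right, s, "R")
    cand <- list(donor = e, acceptor = b - 1L, priority = pri,
                 class = class_of[pri], score = sc)
    if (is.null(best) || cand$priority < best$priority ||
        (cand$priority == best$priority && cand$score > best$score) ||
        (cand$priority == best$priority && cand$score == best$score &&
         cand$donor < best$donor)) {
      best <- cand
    }
  }
  best
}

# Hand-built genome for the gap-repair battery: exon1 ends in C/A bases
# (no stray donor dinucleotide near its end), exon2 starts with 12 T (no
# stray acceptor), GT-AG intron of exactly 30 bases.
repair_fixture <- function() {
  set.seed(73)
  exon1 <- paste0(rand_dna(35), "CCACCACCAC")          # 45 bases
  exon2 <- paste0(strrep("T", 12), rand_dna(43))       # 55 bases
  intron <- paste0("GT", rand_dna(26), "AG")           # 30 bases
  genome <- paste0(exon1, intron, exon2)
  read <- paste0(exon1, exon2)
  list(genome = genome, read = read, donor = 45L, acceptor = 74L)
}

# Genome fixture with one transcript of two exons around a splice signal;
# returns the pieces needed to build junction/repair cases by hand.
two_exon_fixture <- function(exon1_len = 60L, intron_len = 60L,
                             exon2_len = 60L, signal = c("GT", "AG"),
                             lead = 0L) {
  e1 <- rand_dna(exon1_len)
  e2 <- rand_dna(exon2_len)
  interior <- rand_dna(intron_len - 4L)
  intron <- paste0(signal[1L], interior, signal[2L])
  genome <- paste0(strrep("C", lead), e1, intron, e2)
  donor <- lead + exon1_len               # first intron base, 0-based
  acceptor <- donor + intron_len - 1L     # last intron base
  list(genome = genome, read = paste0(e1, e2), junction = exon1_len,
       donor = donor, acceptor = acceptor,
       exon2_start = acceptor + 1L)
}
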