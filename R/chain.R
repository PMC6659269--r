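# --- column-level helpers for cutting/extending local alignments ---------
# A "column" is one edit-script position: M, X, I or D.  Segments handled
# here are short (read-sized), so per-column vectors are cheap.

aln_cols <- function(aln) rep(aln$op, aln$len)

# Build a local_alignment from per-column ops anchored at (read_start,
# ref_start); the score is recomputed from the op labels.
aln_build <- function(aln, read_start, ref_start, cols, scheme) {
  if (length(cols) == 0L) return(NULL)
  enc <- rle_ops(cols)
  local_alignment(aln$read, aln$strand, read_start,
                  read_start + sum(cols != "D"),
                  aln$ref, ref_start, ref_start + sum(cols != "I"),
                  enc$op, enc$len, score_from_ops(enc$op, enc$len, scheme))
}

# Truncate so the read interval becomes [read_start, s); trailing deletions
# are trimmed (they would dangle against the intron).
aln_cut_left_read <- function(aln, s, scheme) {
  if (s >= aln$read_end) return(aln)
  if (s <= aln$read_start) return(NULL)
  cols <- aln_cols(aln)
  idx <- which(cols != "D")[s - aln$read_start]
  cols <- cols[seq_len(idx)]
  while (length(cols) && cols[length(cols)] == "D") cols <- cols[-length(cols)]
  aln_build(aln, aln$read_start, aln$ref_start, cols, scheme)
}

# Truncate so the read interval becomes [s, read_end); leading deletions
# are trimmed.
aln_cut_right_read <- function(aln, s, scheme) {
  if (s <= aln$read_start) return(aln)
  if (s >= aln$read_end) return(NULL)
  cols <- aln_cols(aln)
  idx <- which(cols != "D")[s - aln$read_start + 1L]
  drop <- seq_len(idx - 1L)
  ref_start <- aln$ref_start + sum(cols[drop] != "I")
  cols <- cols[-drop]
  aln_build(aln, s, ref_start, cols, scheme)
}

# Truncate so the reference interval ends exactly at p (needed when a donor
# position is fixed); trailing insertions are returned to the unaligned pool.
aln_cut_left_ref <- function(aln, p, scheme) {
  if (p >= aln$ref_end) return(aln)
  if (p <= aln$ref_start) return(NULL)
  cols <- aln_cols(aln)
  idx <- which(cols != "I")[p - aln$ref_start]
  cols <- cols[seq_len(idx)]
  while (length(cols) && cols[length(cols)] == "I") cols <- cols[-length(cols)]
  aln_build(aln, aln$read_start, aln$ref_start, cols, scheme)
}

# Truncate so the reference interval starts exactly at p.
aln_cut_right_ref <- function(aln, p, scheme) {
  if (p <= aln$ref_start) return(aln)
  if (p >= aln$ref_end) return(NULL)
  cols <- aln_cols(aln)
  idx <- which(cols != "I")[p - aln$ref_start]   # last dropped ref column
  drop <- seq_len(idx)
  read_start <- aln$read_start + sum(cols[drop] != "D")
  cols <- cols[-drop]
  while (length(cols) && cols[1L] == "I") {
    read_start <- read_start + 1L
    cols <- cols[-1L]
  }
  aln_build(aln, read_start, p, cols, scheme)
}

# M/X labels for n ungapped columns pairing read[rs, rs+n) with ref[fs, fs+n).
aligned_cols <- function(read_seq, ref_seq, rs, fs, n) {
  if (n == 0L) return(character(0))
  a <- strsplit(substr(read_seq, rs + 1L, rs + n), "")[[1]]
  b <- strsplit(substr(ref_seq, fs + 1L, fs + n), "")[[1]]
  if (length(a) < n || length(b) < n) return(NULL)
  ifelse(a == b & a != "N" & b != "N", "M", "X")
}

# Extend the right edge of `aln` to read position new_re and reference
# position new_fe; the geometry must be ungapped or carry exactly one extra
# 1-base indel (placed at the outer edge, next to the future intron).
aln_extend_right <- function(aln, new_re, new_fe, read_seq, ref_seq, scheme) {
  dr <- new_re - aln$read_end
  df <- new_fe - aln$ref_end
  if (dr < 0L || df < 0L) return(NULL)
  if (aln$read_end + dr > nchar(read_seq) || aln$ref_end + df > nchar(ref_seq)) {
    return(NULL)
  }
  extra <- df - dr
  if (abs(extra) > 1L) return(NULL)
  n <- min(dr, df)
  mid <- aligned_cols(read_seq, ref_seq, aln$read_end, aln$ref_end, n)
  if (is.null(mid)) return(NULL)
  tailc <- if (extra == 1L) "D" else if (extra == -1L) "I" else character(0)
  aln_build(aln, aln$read_start, aln$ref_start,
            c(aln_cols(aln), mid, tailc), scheme)
}

# Mirror of aln_extend_right for the left edge.
aln_extend_left <- function(aln, new_rs, new_fs, read_seq, ref_seq, scheme) {
  dr <- aln$read_start - new_rs
  df <- aln$ref_start - new_fs
  if (dr < 0L || df < 0L || new_rs < 0L || new_fs < 0L) return(NULL)
  extra <- df - dr
  if (abs(extra) > 1L) return(NULL)
  n <- min(dr, df)
  headc <- if (extra == 1L) "D" else if (extra == -1L) "I" else character(0)
  mid <- aligned_cols(read_seq, ref_seq, new_rs + (extra == -1L),
                      new_fs + (extra == 1L), n)
  if (is.null(mid)) return(NULL)
  aln_build(aln, new_rs, new_fs, c(headc, mid, aln_cols(aln)), scheme)
}

# --- splice-signal machinery ---------------------------------------------

# Classify an intron by its boundary dinucleotides on the reference plus
# strand.  GT-AG (and its minus-strand form CT-AC) is canonical; GC-AG /
# CT-GC and AT-AC / GT-AT are the minor classes.
classify_splice <- function(donor_di, acceptor_di) {
  sig <- paste0(donor_di, "-", acceptor_di)
  switch(sig,
         "GT-AG" = list(class = "canonical", strand = "+", priority = 1L),
         "CT-AC" = list(class = "canonical", strand = "-", priority = 1L),
         "GC-AG" = list(class = "minor_GC_AG", strand = "+", priority = 2L),
         "CT-GC" = list(class = "minor_GC_AG", strand = "-", priority = 2L),
         "AT-AC" = list(class = "minor_AT_AC", strand = "+", priority = 3L),
         "GT-AT" = list(class = "minor_AT_AC", strand = "-", priority = 3L),
         list(class = "non_canonical", strand = "*", priority = 4L))
}

#' Resolve the junction between two read-continuous local alignments
#'
#' Scans every junction offset in the window where the alignments meet
#' (their read overlap), classifies each candidate intron by the
#' splice-signal hierarchy GT-AG > GC-AG > AT-AC > non-canonical
#' (strand complements included), and returns the placement of the
#' highest-priority class, breaking ties by the re-scored overlap (largest
#' combined score) and then by the upstream-most donor.  Minor and
#' non-canonical signals are considered only when both flanking alignments
#' score at least `min_side_score`.
#'
#' @param left,right the two [local_alignment()]s (same read, reference,
#'   strand; `right$read_start <= left$read_end`).
#' @param ref_seq reference sequence.
#' @param scheme a [scoring_scheme()].
#' @param min_side_score minor-signal score gate (default 50).
#' @param min_intron minimum intron length.
#' @return `NULL` when no acceptable junction exists, else a list with the
#'   trimmed `left` and `right` segments, `donor` and `acceptor` positions
#'   (first and last intron base, 0-based), `class`, `signal_strand` and the
#'   combined `score`.
#' @export
resolve_junction <- function(left, right, ref_seq, scheme = scoring_scheme(),
                             min_side_score = 50L, min_intron = 30L) {
  if (right$read_start > left$read_end) return(NULL)
  lo <- max(right$read_start, left$read_start + 1L)
  hi <- min(left$read_end, right$read_end - 1L)
  if (lo > hi) return(NULL)
  gate_ok <- left$score >= min_side_score && right$score >= min_side_score
  best <- NULL
  for (s in lo:hi) {
    L <- aln_cut_left_read(left, s, scheme)
    R <- aln_cut_right_read(right, s, scheme)
    if (is.null(L) || is.null(R)) next
    ilen <- R$ref_start - L$ref_end
    if (ilen < min_intron) next
    donor_di <- substr(ref_seq, L$ref_end + 1L, L$ref_end + 2L)
    acc_di <- substr(ref_seq, R$ref_start - 1L, R$ref_start)
    cls <- classify_splice(donor_di, acc_di)
    if (cls$priority > 1L && !gate_ok) next
    sc <- L$score + R$score
    cand <- list(left = L, right = R, donor = L$ref_end,
                 acceptor = R$ref_start - 1L, class = cls$class,
                 signal_strand = cls$strand, priority = cls$priority,
                 score = sc)
    if (is.null(best) ||
        cand$priority < best$priority ||
        (cand$priority == best$priority && cand$score > best$score) ||
        (cand$priority == best$priority && cand$score == best$score &&
         cand$donor < best$donor)) {
      best <- cand
    }
  }
  best
}

#' Repair a junction with unaligned read bases between two local alignments
#'
#' When 1-10 read bases between two local alignments are unaligned, a
#' splice signal is searched within four bases of the end of the left
#' alignment; if a donor is found, the matching acceptor is searched at
#' offsets that restore read continuity, allowing at most one extra 1-base
#' insertion or deletion.  If the donor-first pass fails the procedure is
#' repeated with the intron end fixed first.  Only the canonical GT-AG
#' signal (or its minus-strand form CT-AC) is accepted here.
#'
#' @inheritParams resolve_junction
#' @param read_seq oriented read sequence.
#' @param window donor/acceptor search half-width (default 4 bases).
#' @return as [resolve_junction()], or `NULL` when no repair is possible.
#' @export
repair_gap_junction <- function(left, right, read_seq, ref_seq,
                                scheme = scoring_scheme(), window = 4L,
                                min_intron = 30L) {
  gap <- right$read_start - left$read_end
  if (gap < 1L || gap > 10L) return(NULL)
  deltas <- order_by_distance(-window:window)
  pair_of <- c(GT = "AG", CT = "AC")

  # donor fixed first
  for (delta in deltas) {
    p <- left$ref_end + delta
    donor_di <- substr(ref_seq, p + 1L, p + 2L)
    if (!donor_di %in% names(pair_of)) next
    L2 <- if (delta > 0L) {
      aln_extend_right(left, left$read_end + delta, p, read_seq, ref_seq, scheme)
    } else if (delta < 0L) {
      aln_cut_left_ref(left, p, scheme)
    } else left
    if (is.null(L2) || L2$ref_end != p) next
    rL <- L2$read_end
    R0 <- if (rL > right$read_start) aln_cut_right_read(right, rL, scheme) else right
    if (is.null(R0)) next
    dlt <- R0$read_start - rL
    if (dlt < 0L) next
    for (d in c(0L, 1L, -1L)) {
      if (d == -1L && dlt == 0L) next
      q1 <- R0$ref_start - dlt - d
      if (q1 - p < min_intron || q1 < 2L) next
      if (substr(ref_seq, q1 - 1L, q1) != pair_of[[donor_di]]) next
      R2 <- aln_extend_left(R0, rL, q1, read_seq, ref_seq, scheme)
      if (is.null(R2)) next
      cls <- classify_splice(donor_di, pair_of[[donor_di]])
      return(list(left = L2, right = R2, donor = p, acceptor = q1 - 1L,
                  class = cls$class, signal_strand = cls$strand,
                  priority = cls$priority, score = L2$score + R2$score))
    }
  }

  # acceptor fixed first
  for (delta in deltas) {
    q1 <- right$ref_start + delta     # new right ref start; acceptor at q1-1
    acc_di <- substr(ref_seq, q1 - 1L, q1)
    if (!acc_di %in% c("AG", "AC")) next
    donor_need <- names(pair_of)[match(acc_di, pair_of)]
    R2 <- if (delta > 0L) {
      aln_cut_right_ref(right, q1, scheme)
    } else if (delta < 0L) {
      aln_extend_left(right, right$read_start + delta, q1,
                      read_seq, ref_seq, scheme)
    } else right
    if (is.null(R2) || R2$ref_start != q1) next
    rR <- R2$read_start
    L0 <- if (rR < left$read_end) aln_cut_left_read(left, rR, scheme) else left
    if (is.null(L0)) next
    gam <- rR - L0$read_end
    if (gam < 0L) next
    for (d in c(0L, 1L, -1L)) {
      if (d == -1L && gam == 0L) next
      p <- L0$ref_end + gam + d
      if (q1 - p < min_intron || p < 0L) next
      if (substr(ref_seq, p + 1L, p + 2L) != donor_need) next
      L2 <- aln_extend_right(L0, rR, p, read_seq, ref_seq, scheme)
      if (is.null(L2)) next
      cls <- classify_splice(donor_need, acc_di)
      return(list(left = L2, right = R2, donor = p, acceptor = q1 - 1L,
                  class = cls$class, signal_strand = cls$strand,
                  priority = cls$priority, score = L2$score + R2$score))
    }
  }
  NULL
}

# search offsets closest-first: 0, 1, -1, 2, -2, ...
order_by_distance <- function(x) x[order(abs(x), -sign(x) < 0)]

#' Spliced alignment container
#'
#' A chain of local alignments on one read with typed introns between
#' consecutive segments.  Scoring is splice-neutral: the total score is the
#' plain sum of the per-base segment contributions, with no reward or
#' penalty per splice, so a spliced and an equal-base continuous placement
#' score identically.
#'
#' @param segments list of [local_alignment()]s with continuous read
#'   coverage and strictly increasing reference coordinates.
#' @param introns data frame with one row per junction: `donor`, `acceptor`
#'   (first/last intron base, 0-based), `class`, `signal_strand`.
#' @return object of class `spliced_alignment`.
#' @export
spliced_alignment <- function(segments, introns = NULL) {
  stopifnot(length(segments) >= 1L)
  if (is.null(introns)) {
    introns <- data.frame(donor = integer(0), acceptor = integer(0),
                          class = character(0), signal_strand = character(0),
                          stringsAsFactors = FALSE)
  }
  if (nrow(introns) != length(segments) - 1L) {
    stop("need exactly one intron per junction")
  }
  if (length(segments) > 1L) {
    re <- vapply(segments, `[[`, integer(1), "read_end")
    rs <- vapply(segments, `[[`, integer(1), "read_start")
    if (!all(re[-length(re)] == rs[-1L])) {
      stop("read coverage must be continuous across segments")
    }
  }
  first <- segments[[1L]]
  structure(list(segments = segments, introns = introns,
                 read = first$read, strand = first$strand, ref = first$ref,
                 read_start = first$read_start,
                 read_end = segments[[length(segments)]]$read_end,
                 score = sum(vapply(segments, `[[`, integer(1), "score"))),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment> read[%d,%d) %s %s score %d, %d segment(s)\n",
              x$read_start, x$read_end, x$strand, x$ref, x$score,
              length(x$segments)))
  if (nrow(x$introns)) {
    for (i in seq_len(nrow(x$introns))) {
      cat(sprintf("  intron %d: [%d,%d] %s (%s)\n", i, x$introns$donor[i],
                  x$introns$acceptor[i], x$introns$class[i],
                  x$introns$signal_strand[i]))
    }
  }
  invisible(x)
}

#' Chain collinear local alignments
#'
#' Finds the chain of local alignments (same read, reference and strand)
#' that maximises the combined score, defined as the sum of segment scores
#' minus `match * overlap` for the read overlap of each adjacent pair
#' (overlap bases counted once).  Adjacent segments may overlap on the read
#' or be separated by at most `max_read_gap` unaligned read bases, and
#' their implied intron length must lie within `[min_intron, max_intron]`.
#'
#' @param locals list of [local_alignment()]s.
#' @param scheme a [scoring_scheme()].
#' @param min_intron,max_intron intron length bounds.
#' @param max_read_gap largest unaligned read gap bridgeable by the repair
#'   procedure (default 10).
#' @return list with `segments` (the chained alignments in order) and
#'   `score` (the combined chain score); empty input gives `NULL`.
#' @export
chain_alignments <- function(locals, scheme = scoring_scheme(),
                             min_intron = 30L, max_intron = 500000L,
                             max_read_gap = 10L) {
  if (length(locals) == 0L) return(NULL)
  ord <- order(vapply(locals, `[[`, integer(1), "read_start"),
               vapply(locals, `[[`, integer(1), "ref_start"))
  locals <- locals[ord]
  n <- length(locals)
  rs <- vapply(locals, `[[`, integer(1), "read_start")
  re <- vapply(locals, `[[`, integer(1), "read_end")
  fs <- vapply(locals, `[[`, integer(1), "ref_start")
  fe <- vapply(locals, `[[`, integer(1), "ref_end")
  sc <- vapply(locals, `[[`, integer(1), "score")
  best <- sc            # best chain score ending at i
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) next
      ok <- chain_compatible(rs[i], re[i], fs[i], fe[i],
                             rs[j], re[j], fs[j], fe[j],
                             min_intron, max_intron, max_read_gap)
      if (!ok) next
      ov <- max(0L, re[i] - rs[j])
      cand <- best[i] + sc[j] - scheme$match * ov
      if (cand > best[j]) { best[j] <- cand; prev[j] <- i }
    }
  }
  end <- which.max(best)
  path <- end
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  list(segments = locals[path], score = best[end])
}

# adjacency test for chaining i -> j
chain_compatible <- function(rs_i, re_i, fs_i, fe_i, rs_j, re_j, fs_j, fe_j,
                             min_intron, max_intron, max_read_gap) {
  if (rs_j <= rs_i || re_j <= re_i) return(FALSE)   # strict read progress
  gap <- rs_j - re_i
  if (gap > max_read_gap) return(FALSE)
  ov <- max(0L, -gap)
  if (ov >= re_i - rs_i || ov >= re_j - rs_j) return(FALSE)
  ilen <- fs_j - fe_i + ov
  ilen >= min_intron && ilen <= max_intron
}

# Split same-(ref,strand) locals into loci separated by more than
# max_intron on the reference; chaining never crosses a split.
cluster_loci <- function(locals, max_intron) {
  ord <- order(vapply(locals, `[[`, integer(1), "ref_start"))
  locals <- locals[ord]
  fs <- vapply(locals, `[[`, integer(1), "ref_start")
  fe <- vapply(locals, `[[`, integer(1), "ref_end")
  grp <- cumsum(c(0L, fs[-1L] > cummax(fe)[-length(fe)] + max_intron))
  split(locals, grp)
}

# Join a chain into spliced alignments: resolve every junction (overlap ->
# hierarchy scan; 1-10 base gap -> GT-AG repair); a junction that cannot be
# resolved splits the chain and the highest-scoring piece is reported.
finalize_chain <- function(segments, read_seq, ref_seq,
                           scheme = scoring_scheme(),
                           min_side_score = 50L, min_intron = 30L,
                           window = 4L) {
  pieces <- list()
  cur_segs <- list(segments[[1L]])
  cur_introns <- NULL
  flush <- function(pieces, segs, introns) {
    c(pieces, list(spliced_alignment(segs, introns)))
  }
  empty_introns <- data.frame(donor = integer(0), acceptor = integer(0),
                              class = character(0),
                              signal_strand = character(0),
                              stringsAsFactors = FALSE)
  cur_introns <- empty_introns
  for (k in seq_along(segments)[-1L]) {
    left <- cur_segs[[length(cur_segs)]]
    right <- segments[[k]]
    gap <- right$read_start - left$read_end
    j <- if (gap <= 0L) {
      resolve_junction(left, right, ref_seq, scheme, min_side_score,
                       min_intron)
    } else {
      repair_gap_junction(left, right, read_seq, ref_seq, scheme, window,
                          min_intron)
    }
    if (is.null(j)) {
      pieces <- flush(pieces, cur_segs, cur_introns)
      cur_segs <- list(right)
      cur_introns <- empty_introns
    } else {
      cur_segs[[length(cur_segs)]] <- j$left
      cur_segs <- c(cur_segs, list(j$right))
      cur_introns <- rbind(cur_introns,
                           data.frame(donor = j$donor, acceptor = j$acceptor,
                                      class = j$class,
                                      signal_strand = j$signal_strand,
                                      stringsAsFactors = FALSE))
    }
  }
  pieces <- flush(pieces, cur_segs, cur_introns)
  scores <- vapply(pieces, `[[`, integer(1), "score")
  pieces[[which.max(scores)]]
}

#' Restrict short reads to canonical GT-AG introns
#'
#' For reads shorter than `threshold` bases only canonical GT-AG (or CT-AC)
#' introns are called: junctions of any other class are dissolved, the
#' chain is split there, and the highest-scoring remaining piece represents
#' the read.
#'
#' @param spliced a [spliced_alignment()].
#' @param read_length length of the read in bases.
#' @param threshold read length below which the policy applies (default 100).
#' @return a [spliced_alignment()] (possibly the input, unchanged).
#' @export
apply_short_read_policy <- function(spliced, read_length, threshold = 100L) {
  if (read_length >= threshold) return(spliced)
  bad <- which(spliced$introns$class != "canonical")
  if (length(bad) == 0L) return(spliced)
  n <- length(spliced$segments)
  # piece boundaries at the offending junctions
  grp <- cumsum(c(0L, seq_len(n - 1L) %in% bad))
  pieces <- lapply(split(seq_len(n), grp), function(idx) {
    spliced_alignment(spliced$segments[idx],
                      spliced$introns[idx[-length(idx)], , drop = FALSE])
  })
  scores <- vapply(pieces, `[[`, integer(1), "score")
  pieces[[which.max(scores)]]
}

#' Collect intron calls from spliced alignments
#'
#' Aggregates one call per distinct (reference, donor, acceptor), with the
#' number of supporting reads; equivalent to extracting `N` operations from
#' the CIGAR strings of the SAM output.
#'
#' @param alignments list of [spliced_alignment()]s.
#' @return data frame with columns `ref`, `donor`, `acceptor`, `strand`,
#'   `class`, `support`, sorted by position.
#' @export
collect_introns <- function(alignments) {
  rows <- lapply(alignments, function(a) {
    if (is.null(a) || nrow(a$introns) == 0L) return(NULL)
    data.frame(ref = a$ref, donor = a$introns$donor,
               acceptor = a$introns$acceptor,
               strand = a$introns$signal_strand,
               class = a$introns$class, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(ref = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      class = character(0), support = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(rows$ref, rows$donor, rows$acceptor, sep = ":")
  agg <- rows[!duplicated(key), , drop = FALSE]
  agg$support <- as.integer(table(key)[paste(agg$ref, agg$donor,
                                             agg$acceptor, sep = ":")])
  agg <- agg[order(agg$ref, agg$donor, agg$acceptor), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
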