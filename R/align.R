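#' Aligner parameters
#'
#' Collects every tunable of the pipeline with its default.  The defaults
#' are the algorithm's standard operating point: 16-base lookup words with
#' the 15-of-16 poly-A mask, 18-base seeds, a reference-repeat cutoff of
#' 60, +1/-4/0/-4 scoring with the X-drop bound derived from the scheme,
#' the score-50 gate on minor splice signals, GT-AG-only introns for reads
#' under 100 bases, and 1-10-base junction gap repair with a 4-base signal
#' search window.
#'
#' @param word_size lookup word size in bases.
#' @param seed_len minimum exact seed length.
#' @param max_db_word_count reference occurrence cutoff above which a read
#'   word is masked.
#' @param polyA_threshold A/T count masking a word (default
#'   `word_size - 1`).
#' @param scheme a [scoring_scheme()].
#' @param table operation table (see [default_operation_table()]).
#' @param xdrop X-drop bound; `NULL` derives it from `scheme` and `table`.
#' @param splice_score_threshold minimum flanking-alignment score for
#'   minor/non-canonical splice signals.
#' @param short_read_threshold read length below which only GT-AG introns
#'   are called.
#' @param min_intron,max_intron intron length bounds.
#' @param repair_window splice-signal search half-width at gap junctions.
#' @param no_splice disable spliced alignment (DNA-style mapping).
#' @param max_pair_distance concordant-pair mate distance limit.
#' @param max_secondary maximum reported secondary alignments per read.
#' @param batch_size reads per processing batch.
#' @return list of parameters, class `align_params`.
#' @export
align_params <- function(word_size = 16L, seed_len = 18L,
                         max_db_word_count = 60L,
                         polyA_threshold = word_size - 1L,
                         scheme = scoring_scheme(),
                         table = default_operation_table(),
                         xdrop = NULL,
                         splice_score_threshold = 50L,
                         short_read_threshold = 100L,
                         min_intron = 30L, max_intron = 500000L,
                         repair_window = 4L,
                         no_splice = FALSE,
                         max_pair_distance = 1000000L,
                         max_secondary = 10L,
                         batch_size = 100000L) {
  if (is.null(xdrop)) {
    xdrop <- xdrop_bound(scheme, max(table$length[table$op != "substitution"]))
  }
  structure(list(word_size = as.integer(word_size),
                 seed_len = as.integer(seed_len),
                 max_db_word_count = as.integer(max_db_word_count),
                 polyA_threshold = as.integer(polyA_threshold),
                 scheme = scheme, table = table, xdrop = as.integer(xdrop),
                 splice_score_threshold = as.integer(splice_score_threshold),
                 short_read_threshold = as.integer(short_read_threshold),
                 min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron),
                 repair_window = as.integer(repair_window),
                 no_splice = isTRUE(no_splice),
                 max_pair_distance = as.integer(max_pair_distance),
                 max_secondary = as.integer(max_secondary),
                 batch_size = as.integer(batch_size)),
            class = "align_params")
}

# Reference window handed to the extension: generous enough that the
# extension can never run out of it before running out of read.
ref_window <- function(ref_seq, seed, read_len) {
  margin <- 2L * read_len + 64L
  lo <- max(0L, seed$ref_start - margin)
  hi <- min(nchar(ref_seq), seed$ref_end + margin)
  list(seq = substr(ref_seq, lo + 1L, hi), offset = lo)
}

# Extend all seeds of one oriented read on one reference; returns deduped
# local alignments (gap-normalised).
extend_read_seeds <- function(seeds, read_seq, ref_name, ref_seq, strand,
                              read_idx, params) {
  out <- list()
  seen <- character(0)
  ord <- order(-(seeds$read_end - seeds$read_start), seeds$ref_start)
  for (k in ord) {
    s <- seeds[k, ]
    win <- ref_window(ref_seq, s, nchar(read_seq))
    res <- cpp_greedy_extend(read_seq, win$seq,
                             s$read_start, s$read_end,
                             s$ref_start - win$offset,
                             op_table_matrix(params$table),
                             params$scheme$match, params$scheme$mismatch,
                             params$scheme$gap_open, params$scheme$gap_extend,
                             params$xdrop)
    aln <- local_alignment(read = read_idx, strand = strand,
                           read_start = res$read_start,
                           read_end = res$read_end,
                           ref = ref_name,
                           ref_start = res$ref_start + win$offset,
                           ref_end = res$ref_end + win$offset,
                           op = as.character(res$op), len = res$len,
                           score = res$score)
    key <- paste(aln$read_start, aln$read_end, aln$ref_start, aln$ref_end)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (any(aln$op %in% c("I", "D"))) {
      aln <- shift_gaps_upstream(aln, read_seq, ref_seq)
    }
    out[[length(out) + 1L]] <- aln
  }
  out
}

# Candidate spliced alignments for one read: per (ref, strand) group,
# cluster into loci, chain, resolve junctions, apply the short-read policy.
read_candidates <- function(seeds, read_seq_fwd, read_seq_rev, reference,
                            read_idx, params) {
  cands <- list()
  if (nrow(seeds) == 0L) return(cands)
  for (grp in split(seq_len(nrow(seeds)),
                    paste(seeds$ref, seeds$strand))) {
    g <- seeds[grp, , drop = FALSE]
    strand <- g$strand[1L]
    ref_name <- g$ref[1L]
    ref_seq <- reference$seq[[ref_name]]
    read_seq <- if (strand == "+") read_seq_fwd else read_seq_rev
    locals <- extend_read_seeds(g, read_seq, ref_name, ref_seq, strand,
                                read_idx, params)
    if (length(locals) == 0L) next
    for (locus in cluster_loci(locals, params$max_intron)) {
      if (params$no_splice) {
        best <- locus[[which.max(vapply(locus, `[[`, integer(1), "score"))]]
        cands[[length(cands) + 1L]] <- spliced_alignment(list(best))
        next
      }
      ch <- chain_alignments(locus, params$scheme, params$min_intron,
                             params$max_intron)
      sp <- finalize_chain(ch$segments, read_seq, ref_seq, params$scheme,
                           params$splice_score_threshold, params$min_intron,
                           params$repair_window)
      sp <- apply_short_read_policy(sp, nchar(read_seq),
                                    params$short_read_threshold)
      cands[[length(cands) + 1L]] <- sp
    }
  }
  # drop duplicated placements (same locus reached via different groups)
  if (length(cands) > 1L) {
    key <- vapply(cands, function(a) {
      paste(a$ref, a$strand, a$segments[[1L]]$ref_start, a$read_start,
            a$read_end, a$score)
    }, character(1))
    cands <- cands[!duplicated(key)]
  }
  cands
}

#' Align a read batch against a reference
#'
#' Runs the full pipeline: word lookup over the reads (both orientations),
#' poly-A and reference-repeat masking, plus-strand reference scan for
#' exact seeds, greedy gapped extension, splice-aware chaining with
#' junction resolution and gap repair, and single or pair placement
#' selection.
#'
#' @param reads a [read_batch()].
#' @param reference a [reference_set()].
#' @param params an [align_params()] list.
#' @param verbose print progress.
#' @return object of class `spliceseed_alignments`: a list with `records`
#'   (SAM-record data frame: all primaries, secondaries up to the
#'   configured cap, and unmapped records), `alignments` (per read, the
#'   primary [spliced_alignment()] or `NULL`), `reads`, `params`.
#' @export
align_reads <- function(reads, reference, params = align_params(),
                        verbose = FALSE) {
  stopifnot(inherits(reads, "read_batch"), inherits(reference, "reference_set"))
  batches <- split_batches(reads, params$batch_size)
  res <- lapply(batches, function(b) {
    align_batch(b, reference, params, verbose)
  })
  records <- do.call(rbind, lapply(res, `[[`, "records"))
  alignments <- do.call(c, lapply(res, `[[`, "alignments"))
  ids <- do.call(c, lapply(res, `[[`, "ids"))
  alignments <- alignments[match(reads$id, ids)]
  structure(list(records = records, alignments = alignments,
                 reads = reads, params = params),
            class = "spliceseed_alignments")
}

align_batch <- function(reads, reference, params, verbose = FALSE) {
  lookup <- build_lookup(reads, params$word_size, params$polyA_threshold)
  lookup <- count_and_mask_repeats(lookup, reference, params$max_db_word_count)
  seeds <- scan_reference(reference, lookup, params$seed_len)
  if (verbose) {
    message(sprintf("batch: %d reads, %d seeds", reads$n,
                    if (is.null(seeds)) 0L else nrow(seeds)))
  }
  rev_seqs <- lookup$reads_rev
  seed_split <- if (is.null(seeds) || nrow(seeds) == 0L) {
    list()
  } else {
    split(seq_len(nrow(seeds)), seeds$read)
  }
  empty_seeds <- data.frame(read = integer(0), strand = character(0),
                            read_start = integer(0), read_end = integer(0),
                            ref = character(0), ref_start = integer(0),
                            ref_end = integer(0), stringsAsFactors = FALSE)
  cands <- vector("list", reads$n)
  for (i in seq_len(reads$n)) {
    s <- seed_split[[as.character(i)]]
    g <- if (is.null(s)) empty_seeds else seeds[s, , drop = FALSE]
    cands[[i]] <- read_candidates(g, reads$seq[i], rev_seqs[i], reference,
                                  i, params)
  }
  if (reads$paired) {
    select_paired(reads, cands, reference, params)
  } else {
    select_single(reads, cands, params)
  }
}

orient_seq <- function(seq_fwd, qual, strand) {
  if (strand == "+") {
    list(seq = seq_fwd, qual = qual)
  } else {
    list(seq = revcomp(seq_fwd),
         qual = if (is.null(qual)) NULL else
           paste(rev(strsplit(qual, "")[[1]]), collapse = ""))
  }
}

select_single <- function(reads, cands, params) {
  recs <- vector("list", reads$n)
  primaries <- vector("list", reads$n)
  for (i in seq_len(reads$n)) {
    ci <- cands[[i]]
    pr <- designate_primary(ci)
    qual_i <- if (is.null(reads$qual)) NULL else reads$qual[i]
    if (is.na(pr$primary)) {
      recs[[i]] <- sam_unmapped_record(reads$id[i], reads$seq[i], qual_i)
      next
    }
    rows <- list()
    n_out <- min(length(pr$order), 1L + params$max_secondary)
    for (k in seq_len(n_out)) {
      a <- ci[[pr$order[k]]]
      o <- orient_seq(reads$seq[i], qual_i, a$strand)
      flag <- 0L
      if (a$strand == "-") flag <- flag + 16L
      if (k > 1L) flag <- flag + 256L
      mapq <- if (k > 1L) 0L else mapq_for(pr$n_best, length(ci))
      rows[[k]] <- sam_record(a, reads$id[i], o$seq, o$qual, flag, mapq)
    }
    primaries[[i]] <- ci[[pr$primary]]
    recs[[i]] <- do.call(rbind, rows)
  }
  list(records = do.call(rbind, recs), alignments = primaries,
       ids = reads$id)
}

select_paired <- function(reads, cands, reference, params) {
  recs <- vector("list", reads$n)
  primaries <- vector("list", reads$n)
  frag_index <- split(seq_len(reads$n), reads$fragment_id)
  for (frag in frag_index) {
    i1 <- frag[reads$mate[frag] == 1L]
    i2 <- frag[reads$mate[frag] == 2L]
    sel <- resolve_pairs(cands[[i1]], cands[[i2]], params$max_pair_distance)
    a1 <- if (!is.na(sel$idx1)) cands[[i1]][[sel$idx1]] else NULL
    a2 <- if (!is.na(sel$idx2)) cands[[i2]][[sel$idx2]] else NULL
    mapq <- if (sel$unique) 60L else if (sel$n_best > 1L) 0L else 1L
    for (side in 1:2) {
      i <- if (side == 1L) i1 else i2
      a <- if (side == 1L) a1 else a2
      mate_a <- if (side == 1L) a2 else a1
      qual_i <- if (is.null(reads$qual)) NULL else reads$qual[i]
      flag <- 1L + (if (side == 1L) 64L else 128L)
      if (is.null(a)) {
        flag <- flag + 4L
        if (is.null(mate_a)) {
          flag <- flag + 8L
          recs[[i]] <- sam_unmapped_record(reads$id[i], reads$seq[i], qual_i,
                                           flag)
        } else {
          if (mate_a$strand == "-") flag <- flag + 32L
          r <- sam_unmapped_record(reads$id[i], reads$seq[i], qual_i, flag)
          r$rname <- mate_a$ref
          r$pos <- mate_a$segments[[1L]]$ref_start + 1L
          recs[[i]] <- r
        }
        next
      }
      if (sel$proper) flag <- flag + 2L
      if (a$strand == "-") flag <- flag + 16L
      if (is.null(mate_a)) {
        flag <- flag + 8L
        rnext <- "="; pnext <- a$segments[[1L]]$ref_start + 1L; tlen <- 0L
      } else {
        if (mate_a$strand == "-") flag <- flag + 32L
        rnext <- if (mate_a$ref == a$ref) "=" else mate_a$ref
        pnext <- mate_a$segments[[1L]]$ref_start + 1L
        tlen <- if (mate_a$ref == a$ref) {
          lo <- min(a$segments[[1L]]$ref_start,
                    mate_a$segments[[1L]]$ref_start)
          hi <- max(a$segments[[length(a$segments)]]$ref_end,
                    mate_a$segments[[length(mate_a$segments)]]$ref_end)
          span <- hi - lo
          if (a$segments[[1L]]$ref_start <= mate_a$segments[[1L]]$ref_start) {
            span
          } else {
            -span
          }
        } else 0L
      }
      o <- orient_seq(reads$seq[i], qual_i, a$strand)
      primaries[[i]] <- a
      recs[[i]] <- sam_record(a, reads$id[i], o$seq, o$qual, flag, mapq,
                              rnext, pnext, tlen)
    }
  }
  list(records = do.call(rbind, recs), alignments = primaries,
       ids = reads$id)
}

#' @export
print.spliceseed_alignments <- function(x, ...) {
  n <- x$reads$n
  mapped <- sum(!vapply(x$alignments, is.null, logical(1)))
  cat(sprintf("<spliceseed_alignments> %d read(s), %d mapped (%.1f%%)\n",
              n, mapped, 100 * mapped / n))
  invisible(x)
}

#' @export
summary.spliceseed_alignments <- function(object, ...) {
  aln <- object$alignments
  mapped <- !vapply(aln, is.null, logical(1))
  introns <- collect_introns(aln[mapped])
  prim <- object$records[bitwAnd(object$records$flag, 256L) == 0L &
                           object$records$rname != "*", , drop = FALSE]
  aligned_bases <- sum(vapply(aln[mapped], function(a) {
    a$read_end - a$read_start
  }, integer(1)))
  out <- list(n_reads = object$reads$n, n_mapped = sum(mapped),
              pct_mapped = 100 * sum(mapped) / object$reads$n,
              aligned_bases = aligned_bases,
              total_mismatch = sum(prim$NM),
              n_introns = nrow(introns),
              intron_support = if (nrow(introns)) summary(introns$support))
  class(out) <- "summary.spliceseed_alignments"
  out
}

#' @export
print.summary.spliceseed_alignments <- function(x, ...) {
  cat(sprintf(paste0("reads: %d   mapped: %d (%.1f%%)\n",
                     "aligned bases: %d   total NM: %d\n",
                     "distinct introns: %d\n"),
              x$n_reads, x$n_mapped, x$pct_mapped, x$aligned_bases,
              x$total_mismatch, x$n_introns))
  invisible(x)
}
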