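#' Intron-discovery evaluation with coverage-binned ROC points
#'
#' Compares called introns against a truth set, requiring exact donor and
#' acceptor coordinates.  For every minimal read coverage c in
#' `1..max_coverage` the calls with support >= c are scored: TP (in the
#' truth), FP (not), FN (truth introns not called), with precision
#' `p = TP/(TP+FP)`, recall `r = TP/(TP+FN)` and `F = 2pr/(p+r)`.  The
#' F-score is 0 when TP = 0 and FP or FN is positive; with an empty truth
#' set recall (and F) are reported as `NA`.
#'
#' @param calls intron calls from [collect_introns()] (columns `ref`,
#'   `donor`, `acceptor`, `support`).
#' @param truth_introns data frame of true introns (`ref`, `donor`,
#'   `acceptor`).
#' @param max_coverage largest minimal-coverage bin (default 100; calls
#'   above it fold into the top bin).
#' @return object of class `intron_eval`: list with `roc` (one row per
#'   coverage), `overall` (the coverage-1 row) and `best` (row of maximal
#'   F-score, at the lowest coverage achieving it).
#' @export
evaluate_introns <- function(calls, truth_introns, max_coverage = 100L) {
  truth_key <- unique(paste(truth_introns$ref, truth_introns$donor,
                            truth_introns$acceptor))
  call_key <- paste(calls$ref, calls$donor, calls$acceptor)
  support <- pmin(calls$support, max_coverage)
  n_truth <- length(truth_key)
  cov <- seq_len(max_coverage)
  tp <- fp <- integer(max_coverage)
  is_tp <- call_key %in% truth_key
  for (c in cov) {
    keep <- support >= c
    tp[c] <- sum(is_tp & keep)
    fp[c] <- sum(!is_tp & keep)
  }
  fn <- n_truth - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- if (n_truth > 0) tp / (tp + fn) else rep(NA_real_, max_coverage)
  f <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
              2 * precision * recall / (precision + recall),
              ifelse(tp == 0 & (fp > 0 | fn > 0), 0, NA_real_))
  roc <- data.frame(coverage = cov, TP = tp, FP = fp, FN = fn,
                    precision = precision, recall = recall, F = f)
  best_i <- if (all(is.na(f))) NA_integer_ else which.max(f)
  structure(list(roc = roc, overall = roc[1L, ],
                 best = if (is.na(best_i)) NULL else roc[best_i, ],
                 n_truth = n_truth),
            class = "intron_eval")
}

#' @export
print.intron_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0("<intron_eval> %d truth intron(s)\n",
                     "  coverage>=1: TP %d  FP %d  FN %d  ",
                     "p %.3f  r %.3f  F %.3f\n"),
              x$n_truth, o$TP, o$FP, o$FN, o$precision, o$recall, o$F))
  if (!is.null(x$best)) {
    cat(sprintf("  best F %.3f at coverage >= %d\n", x$best$F,
                x$best$coverage))
  }
  invisible(x)
}

#' @export
plot.intron_eval <- function(x, ...) {
  graphics::plot(x$roc$FP, x$roc$TP, type = "b", pch = 20,
                 xlab = "false positive introns",
                 ylab = "true positive introns",
                 main = "intron discovery by minimal coverage", ...)
  invisible(x)
}

# does record blocks lie entirely within truth blocks?
blocks_within <- function(rec_blocks, truth_blocks) {
  if (nrow(rec_blocks) == 0L) return(FALSE)
  for (k in seq_len(nrow(rec_blocks))) {
    inside <- any(truth_blocks$start <= rec_blocks$start[k] &
                    rec_blocks$end[k] <= truth_blocks$end)
    if (!inside) return(FALSE)
  }
  TRUE
}

blocks_equal <- function(a, b) {
  nrow(a) == nrow(b) && all(a$start == b$start) && all(a$end == b$end)
}

#' Classify alignments against the simulated truth
#'
#' Each read's primary record is placed in one of four categories:
#' `exact` -- completely aligned, without mismatch or indel, on the true
#' reference and strand with genome blocks identical to the truth;
#' `partial` -- aligned without leaving the truth (every aligned block
#' contained in a true block, same reference and strand), but not exact;
#' `misaligned` -- any aligned part outside the truth (or wrong
#' reference/strand); `unmapped` otherwise.
#'
#' @param records SAM-record data frame (primary records are selected
#'   internally: secondary flag 0x100 excluded).
#' @param truth truth list from [simulate_transcripts_and_reads()].
#' @return object of class `alignment_eval`: list with `counts` (named
#'   vector over the four categories) and `per_read` (data frame `qname`,
#'   `category`).
#' @export
evaluate_alignments <- function(records, truth) {
  prim <- records[bitwAnd(records$flag, 256L) == 0L, , drop = FALSE]
  tb_split <- split(truth$read_blocks[c("start", "end")],
                    truth$read_blocks$id)
  tstrand <- stats::setNames(truth$reads$strand, truth$reads$id)
  tref <- stats::setNames(truth$reads$ref, truth$reads$id)
  cat_of <- function(k) {
    if (bitwAnd(prim$flag[k], 4L) != 0L || prim$rname[k] == "*") {
      return("unmapped")
    }
    id <- prim$qname[k]
    tb <- tb_split[[id]]
    if (is.null(tb)) return("misaligned")
    tb <- tb[order(tb$start), , drop = FALSE]
    strand <- if (bitwAnd(prim$flag[k], 16L) != 0L) "-" else "+"
    rb <- cigar_blocks(prim$pos[k] - 1L, prim$cigar[k])
    if (prim$rname[k] != tref[[id]] || strand != tstrand[[id]]) {
      return("misaligned")
    }
    ops <- parse_cigar(prim$cigar[k])
    full <- !any(ops$op %in% c("S", "I", "D")) && prim$NM[k] == 0L
    if (full && blocks_equal(rb, tb)) return("exact")
    if (blocks_within(rb, tb)) return("partial")
    "misaligned"
  }
  category <- vapply(seq_len(nrow(prim)), cat_of, character(1))
  counts <- c(exact = sum(category == "exact"),
              partial = sum(category == "partial"),
              misaligned = sum(category == "misaligned"),
              unmapped = sum(category == "unmapped"))
  structure(list(counts = counts,
                 per_read = data.frame(qname = prim$qname,
                                       category = category,
                                       stringsAsFactors = FALSE)),
            class = "alignment_eval")
}

#' @export
print.alignment_eval <- function(x, ...) {
  n <- sum(x$counts)
  cat("<alignment_eval>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-10s %6d (%.2f%%)\n", nm, x$counts[[nm]],
                100 * x$counts[[nm]] / n))
  }
  invisible(x)
}

#' Mismatch quality control over primary alignments
#'
#' Recomputes, base by base against the reference, the mismatches of every
#' primary record: total mismatches per kilobase aligned
#' (`1000 * mismatches / aligned bases`), the per-cycle (read position)
#' mismatch profile, substitution types, and the aligned-length histogram.
#'
#' @param records SAM-record data frame.
#' @param reference the [reference_set()] the records were aligned to.
#' @param length_binwidth histogram bin width in bases (default 10).
#' @return object of class `mismatch_qc`: list with `totals` (aligned
#'   bases, mismatches, `mm_per_kb`), `per_cycle`, `types` (substitution
#'   table, `ref>read`), `length_hist` and `per_record`.
#' @export
mismatch_qc <- function(records, reference, length_binwidth = 10L) {
  prim <- records[bitwAnd(records$flag, 256L) == 0L &
                    records$rname != "*", , drop = FALSE]
  if (nrow(prim) > 0L &&
      !all(prim$rname %in% reference$names)) {
    stop("records reference sequences missing from `reference`")
  }
  max_len <- if (nrow(prim)) max(nchar(prim$seq)) else 0L
  cyc_aln <- integer(max_len); cyc_mm <- integer(max_len)
  types <- new.env(parent = emptyenv())
  aligned <- integer(nrow(prim)); mism <- integer(nrow(prim))
  for (k in seq_len(nrow(prim))) {
    ops <- parse_cigar(prim$cigar[k])
    refseq <- reference$seq[[prim$rname[k]]]
    seqchars <- strsplit(prim$seq[k], "")[[1]]
    p <- prim$pos[k] - 1L; r <- 0L
    for (t in seq_len(nrow(ops))) {
      op <- ops$op[t]; l <- ops$len[t]
      if (op %in% c("M", "=", "X")) {
        a <- seqchars[r + seq_len(l)]
        b <- strsplit(substr(refseq, p + 1L, p + l), "")[[1]]
        mm <- a != b | a == "N" | b == "N"
        aligned[k] <- aligned[k] + l
        mism[k] <- mism[k] + sum(mm)
        idx <- r + seq_len(l)
        cyc_aln[idx] <- cyc_aln[idx] + 1L
        cyc_mm[idx] <- cyc_mm[idx] + mm
        if (any(mm)) {
          for (z in which(mm)) {
            key <- paste0(b[z], ">", a[z])
            types[[key]] <- (if (is.null(types[[key]])) 0L else types[[key]]) + 1L
          }
        }
        p <- p + l; r <- r + l
      } else if (op == "I") { r <- r + l
      } else if (op %in% c("D", "N")) { p <- p + l
      } else if (op == "S") { r <- r + l }
    }
  }
  total_aligned <- sum(aligned)
  total_mm <- sum(mism)
  type_names <- ls(types)
  type_tab <- stats::setNames(
    vapply(type_names, function(nm) types[[nm]], integer(1)), type_names)
  breaks <- seq(0L, max(length_binwidth, max_len + length_binwidth),
                by = length_binwidth)
  hist_counts <- if (nrow(prim)) {
    table(cut(aligned, breaks = breaks, right = FALSE))
  } else table(factor(levels = character(0)))
  structure(list(totals = list(aligned_bases = total_aligned,
                               mismatches = total_mm,
                               mm_per_kb = if (total_aligned > 0)
                                 1000 * total_mm / total_aligned else NA_real_),
                 per_cycle = data.frame(cycle = seq_len(max_len),
                                        aligned = cyc_aln,
                                        mismatches = cyc_mm),
                 types = type_tab,
                 length_hist = hist_counts,
                 per_record = data.frame(qname = prim$qname,
                                         aligned = aligned,
                                         mismatches = mism,
                                         NM = prim$NM,
                                         stringsAsFactors = FALSE)),
            class = "mismatch_qc")
}

#' @export
print.mismatch_qc <- function(x, ...) {
  cat(sprintf(paste0("<mismatch_qc> %d record(s), %d aligned bases\n",
                     "  mismatches: %d (%.2f per kb)\n"),
              nrow(x$per_record), x$totals$aligned_bases,
              x$totals$mismatches, x$totals$mm_per_kb))
  invisible(x)
}
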