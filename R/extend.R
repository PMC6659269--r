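#' Alignment scoring scheme
#'
#' The default system scores +1 per matching pair, -4 per substituted base,
#' 0 for opening a gap (in either sequence) and -4 per base of gap
#' extension.  Base qualities never enter the score.
#'
#' @param match reward per matching base (> 0).
#' @param mismatch penalty per substituted base (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend penalty per base of gap extension (<= 0).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -4L, gap_open = 0L,
                           gap_extend = -4L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match reward must be positive")
  if (mismatch > 0L || gap_open > 0L || gap_extend > 0L) {
    stop("penalties must be <= 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' X-drop bound for a scoring scheme
#'
#' The extension stops once the running score falls below the best score by
#' more than the most penalised gapped operation in the table: a
#' `max_gap`-base gap, i.e. `|gap_open| + max_gap * |gap_extend|` (12 under
#' the defaults).
#'
#' @param scheme a [scoring_scheme()].
#' @param max_gap longest indel in the operation table (default 3).
#' @return integer X-drop value.
#' @export
xdrop_bound <- function(scheme, max_gap = 3L) {
  abs(scheme$gap_open) + as.integer(max_gap) * abs(scheme$gap_extend)
}

#' Default alignment operation table
#'
#' The 14 candidate operations tried, in order, when the extension hits a
#' mismatch.  Each operation is accepted when, among the
#' `required_matches + allowed_mismatches` bases following it, at least
#' `required_matches` match; the first satisfied operation is applied, and a
#' single substitution is the fallback when none is.
#'
#' @return data frame with columns `op` (`substitution`/`insertion`/
#'   `deletion`), `length`, `required_matches`, `allowed_mismatches`.
#' @export
default_operation_table <- function() {
  data.frame(
    op = c("substitution", "insertion", "deletion", "insertion", "deletion",
           "insertion", "deletion", "substitution",
           "insertion", "deletion", "insertion", "deletion",
           "insertion", "deletion"),
    length = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 2L, 1L, 1L, 2L, 2L, 3L, 3L),
    required_matches = c(9L, 10L, 10L, 10L, 10L, 13L, 13L, 12L,
                         10L, 10L, 10L, 10L, 13L, 13L),
    allowed_mismatches = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                           2L, 2L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Read an operation table from a plain-text config file
#'
#' One rule per line: `kind length required_matches allowed_mismatches`,
#' whitespace-separated; `#` comments allowed.
#'
#' @param file path to the config file.
#' @return operation-table data frame as in [default_operation_table()].
#' @export
read_operation_table <- function(file) {
  tab <- utils::read.table(file, comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("op", "length", "required_matches",
                                         "allowed_mismatches"))
  ok <- tab$op %in% c("substitution", "insertion", "deletion")
  if (!all(ok)) stop("unknown operation kind in table: ", tab$op[!ok][1])
  tab
}

# kind codes for the C++ core: 0 substitution, 1 insertion, 2 deletion
op_table_matrix <- function(table) {
  kind <- match(table$op, c("substitution", "insertion", "deletion")) - 1L
  m <- cbind(kind, as.integer(table$length),
             as.integer(table$required_matches),
             as.integer(table$allowed_mismatches))
  storage.mode(m) <- "integer"
  m
}

#' Choose the alignment operation at a mismatch
#'
#' Applies the operation table to the two sequence tails whose first bases
#' mismatch and returns the first operation whose requirement is met, or the
#' fallback single substitution (`rule = NA`).
#'
#' @param read_tail read suffix starting at the mismatching base.
#' @param ref_tail reference suffix starting at the mismatching base.
#' @param table operation table (default [default_operation_table()]).
#' @return list with `op`, `length` and the 1-based `rule` index (NA for the
#'   fallback substitution).
#' @export
step_state_machine <- function(read_tail, ref_tail,
                               table = default_operation_table()) {
  res <- cpp_step_state_machine(toupper(read_tail), toupper(ref_tail),
                                op_table_matrix(table))
  list(op = c("substitution", "insertion", "deletion")[res$kind + 1L],
       length = res$length, rule = res$rule)
}

#' Local alignment container
#'
#' One gapped exon-level alignment.  The edit script is run-length encoded
#' over `M` (match), `X` (substitution), `I` (read insertion) and `D`
#' (deletion); intervals are 0-based half-open on the oriented read and the
#' reference plus strand.
#'
#' @param read read index within its batch (may be `NA` for free-standing
#'   alignments).
#' @param strand `"+"` or `"-"` (orientation of the read).
#' @param read_start,read_end read interval.
#' @param ref reference sequence name.
#' @param ref_start,ref_end reference interval.
#' @param op,len run-length encoded edit script.
#' @param score alignment score.
#' @return object of class `local_alignment`.
#' @export
local_alignment <- function(read, strand, read_start, read_end,
                            ref, ref_start, ref_end, op, len, score) {
  stopifnot(length(op) == length(len))
  rd <- sum(len[op != "D"]); rf <- sum(len[op != "I"])
  if (rd != read_end - read_start || rf != ref_end - ref_start) {
    stop("edit script is inconsistent with the alignment intervals")
  }
  if (any(op[-1] == "M" & op[-length(op)] == "M")) {
    stop("adjacent match runs must be merged")
  }
  structure(list(read = read, strand = strand,
                 read_start = as.integer(read_start),
                 read_end = as.integer(read_end),
                 ref = ref, ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end),
                 op = op, len = as.integer(len), score = as.integer(score)),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> read[%d,%d) %s %s:[%d,%d) score %d  %s\n",
              x$read_start, x$read_end, x$strand, x$ref, x$ref_start,
              x$ref_end, x$score, paste0(x$len, x$op, collapse = "")))
  invisible(x)
}

# Score from the op labels alone (labels are trusted; see alignment_score
# for the from-sequence recomputation used by the invariants).
score_from_ops <- function(op, len, scheme) {
  gaps <- op %in% c("I", "D")
  sum(len[op == "M"]) * scheme$match +
    sum(len[op == "X"]) * scheme$mismatch +
    sum(gaps) * scheme$gap_open +
    sum(len[gaps]) * scheme$gap_extend
}

#' Recompute an alignment score from the sequences
#'
#' Walks the edit script over the actual read and reference sequences,
#' verifying that `M` runs match and `X` runs mismatch, and returns the
#' score under `scheme`.  Used by the self-consistency invariant.
#'
#' @param aln a [local_alignment()].
#' @param read_seq oriented read sequence.
#' @param ref_seq reference sequence (full, plus strand).
#' @param scheme a [scoring_scheme()].
#' @return integer score.
#' @export
alignment_score <- function(aln, read_seq, ref_seq, scheme = scoring_scheme()) {
  i <- aln$read_start; j <- aln$ref_start; s <- 0L
  rch <- strsplit(substr(read_seq, aln$read_start + 1L, aln$read_end), "")[[1]]
  fch <- strsplit(substr(ref_seq, aln$ref_start + 1L, aln$ref_end), "")[[1]]
  ri <- 0L; fi <- 0L
  for (k in seq_along(aln$op)) {
    l <- aln$len[k]
    switch(aln$op[k],
      M = {
        a <- rch[ri + seq_len(l)]; b <- fch[fi + seq_len(l)]
        if (!all(a == b & a != "N")) stop("M run does not match the sequences")
        s <- s + l * scheme$match; ri <- ri + l; fi <- fi + l
      },
      X = {
        a <- rch[ri + seq_len(l)]; b <- fch[fi + seq_len(l)]
        if (any(a == b & a != "N")) stop("X run contains matching bases")
        s <- s + l * scheme$mismatch; ri <- ri + l; fi <- fi + l
      },
      I = { s <- s + scheme$gap_open + l * scheme$gap_extend; ri <- ri + l },
      D = { s <- s + scheme$gap_open + l * scheme$gap_extend; fi <- fi + l },
      stop("unknown op ", aln$op[k]))
  }
  s
}

#' Greedily extend a seed into a local gapped alignment
#'
#' Extends rightward from the seed end and leftward from the seed start
#' (with the operation table mirrored on the reversed sequences), applying
#' the operation state machine at each mismatch, stopping by the X-drop
#' rule and backtracking each side to its running-score maximum.
#'
#' @param read_seq oriented read sequence.
#' @param ref_seq reference sequence the seed lies on.
#' @param seed list/row with `read_start`, `read_end`, `ref_start` (and the
#'   implied exact match of that length on the reference).
#' @param scheme a [scoring_scheme()].
#' @param table operation table.
#' @param xdrop X-drop value; default computed from `scheme` and the longest
#'   gap in `table` via [xdrop_bound()].
#' @param read,strand,ref carried into the returned alignment.
#' @return a [local_alignment()].
#' @export
greedy_extend <- function(read_seq, ref_seq, seed,
                          scheme = scoring_scheme(),
                          table = default_operation_table(),
                          xdrop = NULL,
                          read = NA_integer_, strand = "+", ref = "ref") {
  if (is.null(xdrop)) xdrop <- xdrop_bound(scheme, max(table$length[table$op != "substitution"]))
  res <- cpp_greedy_extend(read_seq, ref_seq,
                           as.integer(seed$read_start),
                           as.integer(seed$read_end),
                           as.integer(seed$ref_start),
                           op_table_matrix(table),
                           scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend,
                           as.integer(xdrop))
  local_alignment(read = read, strand = strand,
                  read_start = res$read_start, read_end = res$read_end,
                  ref = ref, ref_start = res$ref_start, ref_end = res$ref_end,
                  op = as.character(res$op), len = res$len, score = res$score)
}

# Expand a run-length edit script to per-column vectors.
expand_ops <- function(op, len) rep(op, len)

# Re-encode per-column ops, merging adjacent runs.
rle_ops <- function(cols) {
  r <- rle(cols)
  list(op = r$values, len = r$lengths)
}

#' Shift sliding gaps upstream
#'
#' When a base adjacent to an indel can sit on either side of the gap at
#' equal score, the gap is moved to the upstream-most equal-score position
#' in the orientation of the target (smaller reference coordinate), the
#' convention that stabilises downstream SNP calling.
#'
#' @param aln a [local_alignment()].
#' @param read_seq oriented read sequence.
#' @param ref_seq reference sequence.
#' @return the normalised [local_alignment()]; score unchanged.
#' @export
shift_gaps_upstream <- function(aln, read_seq, ref_seq) {
  if (!any(aln$op %in% c("I", "D"))) return(aln)
  cols <- expand_ops(aln$op, aln$len)
  # read/ref positions consumed by each column (0-based, absolute)
  rpos <- aln$read_start + cumsum(cols != "D") - (cols != "D")
  fpos <- aln$ref_start + cumsum(cols != "I") - (cols != "I")
  rch <- function(p) substr(read_seq, p + 1L, p + 1L)
  fch <- function(p) substr(ref_seq, p + 1L, p + 1L)
  mstat <- function(a, b) (a == b) && a != "N" && b != "N"
  repeat {
    moved <- FALSE
    k <- 2L
    while (k <= length(cols)) {
      if (cols[k] %in% c("I", "D") && cols[k - 1L] %in% c("M", "X")) {
        # gap run [k, e]
        e <- k
        while (e < length(cols) && cols[e + 1L] == cols[k]) e <- e + 1L
        if (cols[k] == "D") {
          # aligned column k-1 pairs read rpos[k-1] with ref fpos[k-1];
          # shifting left re-pairs that read base with ref fpos[e]
          a <- rch(rpos[k - 1L])
          same <- mstat(a, fch(fpos[k - 1L])) == mstat(a, fch(fpos[e]))
        } else {
          b <- fch(fpos[k - 1L])
          same <- mstat(rch(rpos[k - 1L]), b) == mstat(rch(rpos[e]), b)
        }
        if (same) {
          # rotate: aligned column moves to position e, gap run to k-1..e-1
          gap <- cols[k]
          cols[(k - 1L):(e - 1L)] <- gap
          cols[e] <- if (cols[k - 1L] %in% c("M", "X")) cols[k - 1L] else "M"
          # recompute column op label at e from the sequences
          rp <- if (gap == "D") rpos[k - 1L] else rpos[e]
          fp <- if (gap == "D") fpos[e] else fpos[k - 1L]
          cols[e] <- if (mstat(rch(rp), fch(fp))) "M" else "X"
          rpos <- aln$read_start + cumsum(cols != "D") - (cols != "D")
          fpos <- aln$ref_start + cumsum(cols != "I") - (cols != "I")
          moved <- TRUE
          k <- max(2L, k - 1L)
          next
        }
        k <- e + 1L
      } else {
        k <- k + 1L
      }
    }
    if (!moved) break
  }
  enc <- rle_ops(cols)
  local_alignment(aln$read, aln$strand, aln$read_start, aln$read_end,
                  aln$ref, aln$ref_start, aln$ref_end,
                  enc$op, enc$len, aln$score)
}
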