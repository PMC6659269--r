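# --- CIGAR construction ---------------------------------------------------

# CIGAR for a spliced alignment: soft-clips for unaligned read termini,
# M (X folded in), I, D inside segments, N for introns between them.
cigar_of <- function(spliced, read_length) {
  parts <- character(0)
  lens <- integer(0)
  push <- function(op, l) {
    if (l == 0L) return()
    n <- length(parts)
    if (n > 0L && parts[n] == op) {
      lens[n] <<- lens[n] + l
    } else {
      parts[n + 1L] <<- op
      lens[n + 1L] <<- l
    }
  }
  push("S", spliced$read_start)
  segs <- spliced$segments
  for (k in seq_along(segs)) {
    if (k > 1L) {
      push("N", segs[[k]]$ref_start - segs[[k - 1L]]$ref_end)
    }
    a <- segs[[k]]
    for (t in seq_along(a$op)) {
      push(switch(a$op[t], M = "M", X = "M", I = "I", D = "D"), a$len[t])
    }
  }
  push("S", read_length - spliced$read_end)
  paste0(lens, parts, collapse = "")
}

# NM tag: substitutions + inserted + deleted bases over all segments.
nm_of <- function(spliced) {
  sum(vapply(spliced$segments, function(a) {
    sum(a$len[a$op %in% c("X", "I", "D")])
  }, integer(1)))
}

parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(op = character(0), len = integer(0)))
  data.frame(op = strsplit(gsub("[0-9]+", "", cigar), "")[[1]],
             len = as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar),
                                       " +")[[1]]),
             stringsAsFactors = FALSE)
}

# genome blocks ([start,end) 0-based) covered by a SAM record
cigar_blocks <- function(pos0, cigar) {
  ops <- parse_cigar(cigar)
  starts <- integer(0); ends <- integer(0)
  p <- pos0; open <- NA_integer_
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; l <- ops$len[k]
    if (op %in% c("M", "D", "=", "X")) {
      if (is.na(open)) open <- p
      p <- p + l
    } else if (op == "N") {
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, p) }
      open <- NA_integer_
      p <- p + l
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, p) }
  data.frame(start = starts, end = ends)
}

# --- building SAM records -------------------------------------------------

# One SAM record (as a one-row data frame) from a spliced alignment.
sam_record <- function(spliced, qname, seq_oriented, qual_oriented,
                       flag, mapq, rnext = "*", pnext = 0L, tlen = 0L) {
  data.frame(qname = qname, flag = as.integer(flag), rname = spliced$ref,
             pos = spliced$segments[[1L]]$ref_start + 1L,
             mapq = as.integer(mapq),
             cigar = cigar_of(spliced, nchar(seq_oriented)),
             rnext = rnext, pnext = as.integer(pnext),
             tlen = as.integer(tlen), seq = seq_oriented,
             qual = if (is.null(qual_oriented)) "*" else qual_oriented,
             NM = nm_of(spliced), AS = spliced$score,
             stringsAsFactors = FALSE)
}

sam_unmapped_record <- function(qname, seq, qual, flag = 4L) {
  data.frame(qname = qname, flag = as.integer(flag), rname = "*", pos = 0L,
             mapq = 0L, cigar = "*", rnext = "*", pnext = 0L, tlen = 0L,
             seq = seq, qual = if (is.null(qual)) "*" else qual,
             NM = NA_integer_, AS = NA_integer_, stringsAsFactors = FALSE)
}

#' Write alignments as SAM text
#'
#' Emits a v1.6 text SAM with `@SQ` lines for every reference sequence, one
#' primary record per mapped read, `0x4` records for unmapped reads, `N`
#' CIGAR operations for introns, soft clips for partial alignments, and
#' `NM`/`AS` tags.
#'
#' @param records data frame of SAM records as produced by [align_reads()]
#'   (element `records`).
#' @param reference the [reference_set()] aligned against.
#' @param file path or connection; `""` prints to stdout.
#' @param sorted sort records by (reference, position, qname) instead of
#'   input order.
#' @return invisibly, the SAM lines.
#' @export
write_sam <- function(records, reference, file = "", sorted = FALSE) {
  bad <- records$rname != "*" & !(records$rname %in% reference$names)
  if (any(bad)) {
    stop("record reference name not in the reference set: ",
         records$rname[bad][1L])
  }
  hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s",
                   if (sorted) "coordinate" else "unsorted"),
           sprintf("@SQ\tSN:%s\tLN:%d", reference$names,
                   nchar(reference$seq)),
           "@PG\tID:spliceseed\tPN:spliceseed")
  if (sorted) {
    mapped <- records$rname != "*"
    records <- rbind(
      records[mapped, , drop = FALSE][order(records$rname[mapped],
                                            records$pos[mapped],
                                            records$qname[mapped]), ,
                                      drop = FALSE],
      records[!mapped, , drop = FALSE])
  }
  tags <- ifelse(is.na(records$NM), "",
                 sprintf("\tNM:i:%d\tAS:i:%d", records$NM, records$AS))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, records$qual, tags)
  out <- c(hdr, body)
  writeLines(out, file)
  invisible(out)
}

#' Parse a SAM text file
#'
#' Minimal reader for the 11 mandatory columns plus `NM:i` and `AS:i` tags,
#' sufficient to round-trip this package's output and to evaluate SAM files
#' produced elsewhere.  (Binary BAM is out of scope; convert externally.)
#'
#' @param file path to a SAM text file.
#' @return list with `header` (character vector) and `records` (data frame
#'   in the layout written by [write_sam()]).
#' @export
parse_sam <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(list(header = hdr, records = NULL))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  tagval <- function(f, tag) {
    hit <- grep(paste0("^", tag, ":i:"), f[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(".*:i:", "", hit[1L])) else NA_integer_
  }
  records <- data.frame(
    qname = vapply(fields, `[`, "", 1L),
    flag = as.integer(vapply(fields, `[`, "", 2L)),
    rname = vapply(fields, `[`, "", 3L),
    pos = as.integer(vapply(fields, `[`, "", 4L)),
    mapq = as.integer(vapply(fields, `[`, "", 5L)),
    cigar = vapply(fields, `[`, "", 6L),
    rnext = vapply(fields, `[`, "", 7L),
    pnext = as.integer(vapply(fields, `[`, "", 8L)),
    tlen = as.integer(vapply(fields, `[`, "", 9L)),
    seq = vapply(fields, `[`, "", 10L),
    qual = vapply(fields, `[`, "", 11L),
    NM = vapply(fields, tagval, 0L, "NM"),
    AS = vapply(fields, tagval, 0L, "AS"),
    stringsAsFactors = FALSE)
  list(header = hdr, records = records)
}

#' Recompute the NM edit distance of SAM records against the reference
#'
#' Walks each record's CIGAR over the reference and counts mismatching
#' aligned bases plus inserted and deleted bases; the result must equal the
#' stored `NM` tag for every record this package emits.
#'
#' @param records SAM record data frame.
#' @param reference the [reference_set()].
#' @return integer vector of recomputed edit distances (`NA` for unmapped).
#' @export
recompute_nm <- function(records, reference) {
  vapply(seq_len(nrow(records)), function(k) {
    if (records$rname[k] == "*") return(NA_integer_)
    ops <- parse_cigar(records$cigar[k])
    refseq <- reference$seq[[records$rname[k]]]
    p <- records$pos[k] - 1L; r <- 0L; nm <- 0L
    seqchars <- strsplit(records$seq[k], "")[[1]]
    for (t in seq_len(nrow(ops))) {
      op <- ops$op[t]; l <- ops$len[t]
      if (op %in% c("M", "=", "X")) {
        a <- seqchars[r + seq_len(l)]
        b <- strsplit(substr(refseq, p + 1L, p + l), "")[[1]]
        nm <- nm + sum(a != b | a == "N" | b == "N")
        p <- p + l; r <- r + l
      } else if (op == "I") { nm <- nm + l; r <- r + l
      } else if (op == "D") { nm <- nm + l; p <- p + l
      } else if (op == "N") { p <- p + l
      } else if (op == "S") { r <- r + l }
    }
    nm
  }, integer(1))
}

#' Write alignments in a BLAST-like tabular format
#'
#' One row per alignment with a `#`-prefixed header line documenting the
#' columns: query id, reference id, percent identity, query start/stop,
#' reference start/stop (1-based inclusive), strand, alignment score, edit
#' distance, intron count and the btop-style edit string.
#'
#' @param alignments list of [spliced_alignment()]s (NULLs are skipped).
#' @param qnames character vector of query names, parallel to `alignments`.
#' @param file path or connection; `""` prints to stdout.
#' @return invisibly, the written lines.
#' @export
write_tabular <- function(alignments, qnames, file = "") {
  header <- paste0("# query\treference\tpident\tqstart\tqend\trstart\trend",
                   "\tstrand\tscore\tedit_distance\tintrons\tbtop")
  keep <- !vapply(alignments, is.null, logical(1))
  alignments <- alignments[keep]
  qnames <- qnames[keep]
  rows <- vapply(seq_along(alignments), function(k) {
    a <- alignments[[k]]
    ncols <- sum(vapply(a$segments, function(s) sum(s$len), integer(1)))
    nmatch <- sum(vapply(a$segments, function(s) sum(s$len[s$op == "M"]),
                         integer(1)))
    btop <- paste(vapply(a$segments, function(s)
      paste0(s$len, s$op, collapse = ""), character(1)),
      collapse = "^")
    sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%s\t%d\t%d\t%d\t%s",
            qnames[k], a$ref, 100 * nmatch / ncols,
            a$read_start + 1L, a$read_end,
            a$segments[[1L]]$ref_start + 1L,
            a$segments[[length(a$segments)]]$ref_end,
            a$strand, a$score, nm_of(a), nrow(a$introns), btop)
  }, character(1))
  out <- c(header, rows)
  writeLines(out, file)
  invisible(out)
}
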