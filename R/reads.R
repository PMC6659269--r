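#' Reference sequence set
#'
#' A named collection of genome (or transcript) sequences over `{A,C,G,T,N}`.
#' Sequences are normalised to uppercase; names must be unique and sequences
#' non-empty.  Coordinates used throughout the package are 0-based half-open
#' internally; SAM output converts to 1-based.
#'
#' @param sequences named character vector of DNA sequences.
#' @return an object of class `reference_set` with elements `names`, `seq`
#'   (named character vector) and `total_length`.
#' @export
reference_set <- function(sequences) {
  if (length(sequences) == 0L) stop("reference must contain at least one sequence")
  nms <- names(sequences)
  if (is.null(nms) || any(nms == "") || anyNA(nms)) {
    stop("every reference sequence must be named")
  }
  # FASTA headers: keep the first word as the identifier
  nms <- sub("\\s.*$", "", nms)
  if (anyDuplicated(nms)) stop("reference sequence names must be unique")
  seqs <- normalize_dna(unname(sequences), "reference sequence")
  if (any(nchar(seqs) == 0L)) stop("reference sequences must be non-empty")
  names(seqs) <- nms
  structure(list(names = nms, seq = seqs,
                 total_length = sum(nchar(seqs))),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d sequence(s), %s bases total\n",
              length(x$names), format(x$total_length, big.mark = ",")))
  for (i in seq_len(min(6L, length(x$names)))) {
    cat(sprintf("  %s  (%s bases)\n", x$names[i],
                format(nchar(x$seq[[i]]), big.mark = ",")))
  }
  if (length(x$names) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' Multi-record, wrapped-line FASTA; gzip input is transparent.
#'
#' @param file path to a FASTA file (optionally `.gz`).
#' @return a [reference_set()].
#' @export
read_reference <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  reference_set(stats::setNames(as.character(ss), names(ss)))
}

#' Read batch
#'
#' An ordered batch of reads, single or paired.  For paired batches every
#' fragment must have exactly mates 1 and 2.  Base qualities, when present,
#' are carried through to SAM output but have no effect on alignment scores.
#'
#' @param sequences character vector of read sequences.
#' @param ids read identifiers; defaults to `read1, read2, ...`.
#' @param qualities optional character vector of quality strings (same
#'   lengths as `sequences`).
#' @param mate integer vector of 1/2 mate indices, or `NULL` for single-end.
#' @param fragment_id fragment (template) identifiers; defaults to `ids`
#'   stripped of a trailing `/1` or `/2`.
#' @param paired logical; whether the batch is paired-end.
#' @return an object of class `read_batch`.
#' @export
read_batch <- function(sequences, ids = NULL, qualities = NULL,
                       mate = NULL, fragment_id = NULL, paired = FALSE) {
  if (length(sequences) == 0L) stop("empty read batch", call. = FALSE)
  seqs <- normalize_dna(sequences, "read sequence")
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  ids <- as.character(ids)
  if (!is.null(qualities)) {
    if (length(qualities) != n || any(nchar(qualities) != nchar(seqs))) {
      stop("qualities must match read sequences in number and length")
    }
  }
  if (paired) {
    if (is.null(mate)) stop("paired batches need a `mate` vector")
    mate <- as.integer(mate)
    if (!all(mate %in% c(1L, 2L))) stop("mate indices must be 1 or 2")
    if (is.null(fragment_id)) fragment_id <- sub("/[12]$", "", ids)
    tab <- table(fragment_id, mate)
    if (!all(dim(tab) == c(length(unique(fragment_id)), 2L)) || !all(tab == 1L)) {
      stop("every fragment_id must have exactly one mate 1 and one mate 2")
    }
  } else {
    mate <- rep(NA_integer_, n)
    if (is.null(fragment_id)) fragment_id <- ids
  }
  structure(list(id = ids, seq = unname(seqs), qual = qualities,
                 mate = mate, fragment_id = as.character(fragment_id),
                 paired = isTRUE(paired), n = n),
            class = "read_batch")
}

#' @export
print.read_batch <- function(x, ...) {
  cat(sprintf("<read_batch> %d read(s)%s, lengths %d-%d\n", x$n,
              if (x$paired) " (paired)" else "",
              min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is taken from the file extension (`.fq`/`.fastq` vs anything
#' else), or forced with `format`.  Two files give a paired batch; a single
#' file with `interleaved = TRUE` is split into alternating mates.
#'
#' @param file path to the (first) read file; gzip transparent.
#' @param file2 optional path to the mate-2 file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @param interleaved logical; treat `file` as interleaved pairs.
#' @return a [read_batch()].
#' @export
read_reads <- function(file, file2 = NULL, format = "auto",
                       interleaved = FALSE) {
  guess <- function(f) {
    if (grepl("\\.(fq|fastq)(\\.gz)?$", f, ignore.case = TRUE)) "fastq" else "fasta"
  }
  read_one <- function(f) {
    fmt <- if (format == "auto") guess(f) else format
    ss <- Biostrings::readDNAStringSet(f, format = fmt,
                                       with.qualities = (fmt == "fastq"))
    qual <- if (fmt == "fastq") as.character(S4Vectors::mcols(ss)$qualities) else NULL
    list(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss), qual = qual)
  }
  a <- read_one(file)
  if (!is.null(file2)) {
    b <- read_one(file2)
    if (length(a$seq) != length(b$seq)) stop("mate files differ in read count")
    idx <- rep(seq_along(a$seq), each = 2L)
    sel <- rep(c(TRUE, FALSE), length(a$seq))
    seqs <- ifelse(sel, a$seq[idx], b$seq[idx])
    ids <- ifelse(sel, a$id[idx], b$id[idx])
    qual <- if (!is.null(a$qual) && !is.null(b$qual)) {
      ifelse(sel, a$qual[idx], b$qual[idx])
    } else NULL
    read_batch(seqs, ids = ids, qualities = qual,
               mate = rep(c(1L, 2L), length(a$seq)),
               fragment_id = sub("/[12]$", "", ids), paired = TRUE)
  } else if (interleaved) {
    n <- length(a$seq)
    if (n %% 2L != 0L) stop("interleaved file has an odd number of reads")
    read_batch(a$seq, ids = a$id, qualities = a$qual,
               mate = rep(c(1L, 2L), n %/% 2L),
               fragment_id = sub("/[12]$", "", a$id), paired = TRUE)
  } else {
    read_batch(a$seq, ids = a$id, qualities = a$qual)
  }
}

#' Split a read batch into bounded-size batches
#'
#' Mates of one fragment always land in the same batch.
#'
#' @param reads a [read_batch()].
#' @param batch_size maximum reads per batch.
#' @return list of `read_batch` objects.
#' @export
split_batches <- function(reads, batch_size = 100000L) {
  frags <- unique(reads$fragment_id)
  per <- max(1L, if (reads$paired) batch_size %/% 2L else batch_size)
  groups <- split(frags, ceiling(seq_along(frags) / per))
  lapply(groups, function(g) {
    k <- which(reads$fragment_id %in% g)
    read_batch(reads$seq[k], ids = reads$id[k],
               qualities = if (!is.null(reads$qual)) reads$qual[k],
               mate = if (reads$paired) reads$mate[k],
               fragment_id = reads$fragment_id[k], paired = reads$paired)
  })
}
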