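#' Poly-A word masking rule
#'
#' A lookup word is masked when it contains at least `threshold` A's or at
#' least `threshold` T's; with the default 16-base words the threshold is
#' 15, which removes seeding on poly-A tails (and their complements).
#'
#' @param word character vector of words, all of the lookup word size.
#' @param threshold minimum A (or T) count that masks; default
#'   `nchar(word) - 1`.
#' @return logical vector.
#' @export
is_polyA_masked <- function(word, threshold = NULL) {
  if (length(word) == 0L) return(logical(0))
  w <- unique(nchar(word))
  if (length(w) != 1L) stop("all words must have the same length")
  if (is.null(threshold)) threshold <- w - 1L
  word <- toupper(word)
  nA <- nchar(gsub("[^A]", "", word))
  nT <- nchar(gsub("[^T]", "", word))
  nA >= threshold | nT >= threshold
}

#' Build the read-side word lookup table
#'
#' Indexes every `word_size`-base word of every read, in both the given and
#' the reverse-complement orientation, so that the reference is later
#' scanned on its plus strand only.  Words containing `N` are not indexed;
#' poly-A words (see [is_polyA_masked()]) are masked at build time.
#'
#' @param reads a [read_batch()].
#' @param word_size word width in bases (default 16; allowed 8-26).
#' @param polyA_threshold A/T count that masks a word; default
#'   `word_size - 1`.
#' @return an object of class `word_lookup`.
#' @export
build_lookup <- function(reads, word_size = 16L,
                         polyA_threshold = word_size - 1L) {
  if (!inherits(reads, "read_batch")) stop("`reads` must be a read_batch")
  if (reads$n == 0L) stop("empty read batch", call. = FALSE)
  word_size <- as.integer(word_size)
  if (word_size < 8L || word_size > 26L) {
    stop("word_size must be between 8 and 26")
  }
  fwd <- reads$seq
  rev <- revcomp(fwd)
  res <- cpp_build_postings(fwd, rev, word_size, as.integer(polyA_threshold))
  if (res$n_short_reads > 0L) {
    warning(sprintf("%d read(s) shorter than word_size contribute no postings",
                    res$n_short_reads))
  }
  ord <- order(res$key, res$read, res$strand, res$offset)
  key <- res$key[ord]
  ukey <- unique(key)
  # 0-based start offsets of each unique key's posting run (length nu + 1)
  pstart <- c(0L, cumsum(tabulate(match(key, ukey), nbins = length(ukey))))
  structure(list(word_size = word_size,
                 polyA_threshold = as.integer(polyA_threshold),
                 n_reads = reads$n,
                 reads_fwd = fwd, reads_rev = rev,
                 key = key,
                 read = res$read[ord], offset = res$offset[ord],
                 strand = res$strand[ord],
                 ukey = ukey, pstart = as.integer(pstart),
                 masked_polyA = sort(res$masked_polyA),
                 masked_repeat = numeric(0)),
            class = "word_lookup")
}

#' @export
print.word_lookup <- function(x, ...) {
  cat(sprintf(paste0("<word_lookup> %d-base words, %d read(s), %s postings\n",
                     "  masked: %d poly-A word(s), %d repeat word(s)\n"),
              x$word_size, x$n_reads, format(length(x$key), big.mark = ","),
              length(x$masked_polyA), length(x$masked_repeat)))
  invisible(x)
}

#' Words currently masked in a lookup table
#'
#' @param lookup a [build_lookup()] object.
#' @param which `"polyA"`, `"repeat"` or `"both"`.
#' @return character vector of masked words.
#' @export
masked_words <- function(lookup, which = c("both", "polyA", "repeat")) {
  which <- match.arg(which)
  keys <- switch(which,
                 polyA = lookup$masked_polyA,
                 `repeat` = lookup$masked_repeat,
                 both = c(lookup$masked_polyA, lookup$masked_repeat))
  key_to_word(keys, lookup$word_size)
}

#' Mask reference-repeat words in a lookup table
#'
#' Counts, on the reference plus strand, the occurrences of exactly those
#' words already present in the lookup (words absent from the reads are
#' never counted) and removes the postings of every word seen more than
#' `cutoff` times.  Reverse-complement repeats are caught through the
#' read-side reverse-strand postings.
#'
#' @param lookup a [build_lookup()] object.
#' @param reference a [reference_set()].
#' @param cutoff maximum tolerated reference occurrence count (default 60);
#'   a word occurring exactly `cutoff` times is retained.
#' @return the updated `word_lookup`.
#' @export
count_and_mask_repeats <- function(lookup, reference, cutoff = 60L) {
  stopifnot(inherits(lookup, "word_lookup"), inherits(reference, "reference_set"))
  cutoff <- as.integer(cutoff)
  if (cutoff < 1L) stop("cutoff must be >= 1")
  counts <- cpp_count_ref_words(unname(reference$seq), lookup$word_size,
                                lookup$ukey)
  bad <- counts$key[counts$count > cutoff]
  if (length(bad) == 0L) return(lookup)
  drop <- lookup$key %in% bad
  lookup$masked_repeat <- sort(unique(c(lookup$masked_repeat, bad)))
  lookup$key <- lookup$key[!drop]
  lookup$read <- lookup$read[!drop]
  lookup$offset <- lookup$offset[!drop]
  lookup$strand <- lookup$strand[!drop]
  lookup$ukey <- unique(lookup$key)
  lookup$pstart <- as.integer(c(0L, cumsum(tabulate(
    match(lookup$key, lookup$ukey), nbins = length(lookup$ukey)))))
  lookup
}

#' Scan a reference for exact-match seeds
#'
#' Slides over every reference sequence (plus strand), looks up each word in
#' the posting table, extends hits to the maximal exact run on their
#' diagonal (N never matches), merges duplicate hits on the same diagonal,
#' and keeps runs of at least `seed_len` bases.
#'
#' @param reference a [reference_set()].
#' @param lookup a [build_lookup()] object (repeat-masked or not).
#' @param seed_len minimum exact-run length for a seed (default 18).
#' @return a data frame of seed matches with columns `read` (index into the
#'   batch), `strand` (`"+"`/`"-"`), `read_start`, `read_end`, `ref`,
#'   `ref_start`, `ref_end` (0-based half-open; read coordinates are on the
#'   oriented read, i.e. on the reverse complement for `"-"` seeds).
#' @export
scan_reference <- function(reference, lookup, seed_len = 18L) {
  stopifnot(inherits(lookup, "word_lookup"), inherits(reference, "reference_set"))
  out <- vector("list", length(reference$names))
  for (i in seq_along(reference$names)) {
    hits <- cpp_scan_reference(reference$seq[[i]], lookup$word_size,
                               as.integer(seed_len),
                               lookup$ukey, lookup$pstart,
                               lookup$read, lookup$offset, lookup$strand,
                               lookup$reads_fwd, lookup$reads_rev)
    n <- length(hits$read)
    out[[i]] <- data.frame(read = hits$read,
                           strand = c("+", "-")[hits$strand + 1L],
                           read_start = hits$read_start,
                           read_end = hits$read_end,
                           ref = rep(reference$names[i], n),
                           ref_start = hits$ref_start,
                           ref_end = hits$ref_end,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
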