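#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over `A,C,G,T,N` (case preserved as
#' uppercase output).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalise a sequence to uppercase and check the alphabet.
normalize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what),
         call. = FALSE)
  }
  x
}

# Encode/decode the 2-bit word keys used by the lookup table.  Keys are
# stored as doubles; word sizes up to 26 keep 2*w <= 52 bits exact.
word_to_key <- function(word) {
  codes <- c(A = 0, C = 1, G = 2, T = 3)
  vapply(strsplit(toupper(word), ""), function(ch) {
    v <- codes[ch]
    if (anyNA(v)) return(NA_real_)
    sum(v * 4^(rev(seq_along(v)) - 1))
  }, numeric(1))
}

#' Decode a lookup-table word key back to its DNA word
#'
#' @param key numeric key(s) as stored in a [build_lookup()] object.
#' @param word_size word width in bases.
#' @return character vector of words.
#' @export
key_to_word <- function(key, word_size) {
  bases <- c("A", "C", "G", "T")
  vapply(key, function(k) {
    out <- character(word_size)
    for (i in seq_len(word_size)) {
      out[word_size - i + 1L] <- bases[(k %% 4) + 1L]
      k <- k %/% 4
    }
    paste0(out, collapse = "")
  }, character(1))
}

# Restore-on-exit RNG handling so `seed` arguments are local to a call.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
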