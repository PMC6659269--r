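# helpers over candidate lists (spliced_alignment objects)
cand_score <- function(x) vapply(x, `[[`, integer(1), "score")
cand_field <- function(x, f) vapply(x, `[[`, vector(mode(x[[1]][[f]]), 1), f)

#' Designate the primary alignment among candidates
#'
#' Exactly one candidate becomes primary; ties are broken by higher score,
#' then fewer introns, then smaller reference coordinate (then reference
#' name and strand, for determinism).
#'
#' @param cands list of [spliced_alignment()] candidates (may be empty).
#' @return list with `primary` (index or `NA` when unmapped), `order`
#'   (candidate indices, primary first) and `n_best` (how many candidates
#'   tie at the top score).
#' @export
designate_primary <- function(cands) {
  if (length(cands) == 0L) {
    return(list(primary = NA_integer_, order = integer(0), n_best = 0L))
  }
  score <- cand_score(cands)
  nintr <- vapply(cands, function(x) nrow(x$introns), integer(1))
  pos <- vapply(cands, function(x) x$segments[[1L]]$ref_start, integer(1))
  ref <- vapply(cands, `[[`, character(1), "ref")
  strand <- vapply(cands, `[[`, character(1), "strand")
  ord <- order(-score, nintr, pos, ref, strand)
  list(primary = ord[1L], order = ord, n_best = sum(score == max(score)))
}

#' Select the reported placements for a read pair
#'
#' Enumerates concordant combinations of the two candidate lists (same
#' reference, opposite strands, start distance within
#' `max_pair_distance`) and reports the combination with the maximal pair
#' score (the plain sum of the mate scores).  A mate that is ambiguous on
#' its own but whose partner maps best at a single site is thereby reported
#' uniquely at the partner-dictated site.  Without any concordant
#' combination the mates are reported independently at their best
#' individual scores.
#'
#' @param cands1,cands2 candidate lists ([spliced_alignment()]s) for mate 1
#'   and mate 2; either may be empty (unmapped mate).
#' @param max_pair_distance maximum mate start distance (default 1e6, large
#'   enough for intron-spanning fragments).
#' @return list with `idx1`, `idx2` (chosen candidate index per mate, `NA`
#'   if unmapped), `proper` (concordant pair found), `pair_score`,
#'   `n_best` (number of combinations tying at the maximal pair score) and
#'   `unique` (`TRUE` when exactly one combination attains it).
#' @export
resolve_pairs <- function(cands1, cands2, max_pair_distance = 1000000L) {
  n1 <- length(cands1); n2 <- length(cands2)
  if (n1 > 0L && n2 > 0L) {
    best <- NULL; n_best <- 0L
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        a <- cands1[[i]]; b <- cands2[[j]]
        if (a$ref != b$ref || a$strand == b$strand) next
        d <- abs(a$segments[[1L]]$ref_start - b$segments[[1L]]$ref_start)
        if (d > max_pair_distance) next
        sc <- a$score + b$score
        if (is.null(best) || sc > best$score) {
          best <- list(i = i, j = j, score = sc); n_best <- 1L
        } else if (sc == best$score) {
          n_best <- n_best + 1L
          # deterministic tie-break: smaller leftmost coordinate
          cur <- min(a$segments[[1L]]$ref_start, b$segments[[1L]]$ref_start)
          old <- min(cands1[[best$i]]$segments[[1L]]$ref_start,
                     cands2[[best$j]]$segments[[1L]]$ref_start)
          if (cur < old) best <- list(i = i, j = j, score = sc)
        }
      }
    }
    if (!is.null(best)) {
      return(list(idx1 = best$i, idx2 = best$j, proper = TRUE,
                  pair_score = best$score, n_best = n_best,
                  unique = n_best == 1L))
    }
  }
  # no concordant combination: independent placement
  p1 <- designate_primary(cands1); p2 <- designate_primary(cands2)
  sc <- 0L
  if (!is.na(p1$primary)) sc <- sc + cands1[[p1$primary]]$score
  if (!is.na(p2$primary)) sc <- sc + cands2[[p2$primary]]$score
  list(idx1 = p1$primary, idx2 = p2$primary, proper = FALSE,
       pair_score = sc,
       n_best = max(1L, p1$n_best) * max(1L, p2$n_best),
       unique = p1$n_best <= 1L && p2$n_best <= 1L)
}

# MAPQ convention: 60 unique, 1 best-of-multiple, 0 tied.
mapq_for <- function(n_best, n_cands) {
  if (n_best > 1L) 0L else if (n_cands > 1L) 1L else 60L
}
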