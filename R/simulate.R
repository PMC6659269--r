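#' Simulate a random genome with tunable AT content
#'
#' Bases are drawn i.i.d. with `P(A) = P(T) = at_fraction/2` and
#' `P(C) = P(G) = (1 - at_fraction)/2`, which reproduces compositional
#' extremes up to the ~80% AT of e.g. the malaria parasite genome.
#'
#' @param length genome length in bases.
#' @param at_fraction combined A+T probability, in (0, 1).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param name sequence name.
#' @return a [reference_set()] with one sequence.
#' @export
simulate_genome <- function(length, at_fraction = 0.5, seed = NULL,
                            name = "chr1") {
  stopifnot(at_fraction > 0, at_fraction < 1, length >= 1)
  with_seed(seed, {
    p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
           G = (1 - at_fraction) / 2, T = at_fraction / 2)
    seq <- paste0(sample(names(p), length, replace = TRUE, prob = p),
                  collapse = "")
    reference_set(stats::setNames(seq, name))
  })
}

# splice signals written at intron boundaries, keyed by class and the
# genome strand of the transcript
splice_signal_bases <- function(class, strand) {
  sig <- switch(class,
                canonical = c("GT", "AG"),
                minor_GC_AG = c("GC", "AG"),
                minor_AT_AC = c("AT", "AC"),
                stop("unknown splice class ", class))
  if (strand == "-") {
    # complement form on the genome plus strand (e.g. GT-AG -> CT-AC)
    sig <- rev(vapply(sig, function(s) revcomp(s), character(1)))
  }
  sig
}

# priority of the dinucleotide pair at a shifted junction
shifted_priority <- function(genome, e, q, k) {
  d <- substr(genome, e + k + 1L, e + k + 2L)
  a <- substr(genome, q + k, q + k + 1L)
  classify_splice(d, a)$priority
}

# A junction is in conflict when a shifted placement within `window` bases
# carries a signal of equal or higher priority, which would make the true
# placement ambiguous (or stolen outright by a higher-priority signal).
junction_conflict <- function(genome, e, q, true_priority, window = 16L) {
  for (k in c(-(window:1), 1:window)) {
    if (shifted_priority(genome, e, q, k) <= true_priority) return(TRUE)
  }
  FALSE
}

# overwrite genome[at, at + nchar(sub)) (0-based) with sub
splice_in <- function(genome, at, sub) {
  paste0(substr(genome, 1L, at),
         sub,
         substr(genome, at + nchar(sub) + 1L, nchar(genome)))
}

#' Simulate transcripts and sequencing reads with a truth track
#'
#' Lays multi-exon transcripts on disjoint genome regions (random strand),
#' writes splice signals at every intron boundary (GT-AG, or a requested
#' fraction of minor signals), and samples single or paired reads with
#' i.i.d. substitution and indel errors.  Every read records its true
#' genome blocks and injected edits.
#'
#' Intron boundary neighbourhoods are resampled so that no equal-or-higher
#' priority splice signal occurs at a shifted offset near the junction:
#' clean-data junction placement is then unambiguous and the truth is
#' well-defined.  Real genomes do contain a small fraction of genuinely
#' ambiguous junctions; see the package vignette.
#'
#' @param genome a [reference_set()] with one sequence, e.g. from
#'   [simulate_genome()]; returned modified (splice signals written in).
#' @param n_transcripts number of transcripts to lay down.
#' @param n_exons exons per transcript (single value or range).
#' @param exon_length,intron_length length ranges (min, max), drawn
#'   uniformly.
#' @param n_fragments number of sequenced fragments (a fragment yields one
#'   read, or two mates when `paired`).
#' @param read_length bases per read.
#' @param paired paired-end sequencing.
#' @param fragment_length mean fragment length (paired mode); fragments are
#'   drawn within +/- 20% of it and truncated to the transcript.
#' @param sub_rate,indel_rate per-base substitution and indel rates, in
#'   [0, 0.2]; indel lengths are geometric with mean 1.2, capped at 3.
#' @param minor_fraction fraction of introns given minor (GC-AG / AT-AC)
#'   signals instead of GT-AG.
#' @param seed optional integer seed.
#' @return list of class `sim_data` with elements `reference` (the genome
#'   with signals written), `reads` (a [read_batch()]), and `truth`: a list
#'   with data frames `reads` (id, ref, strand, spans_junction),
#'   `read_blocks` (id, start, end: true genome intervals, ascending),
#'   `edits` (id, read_pos, type, len), `introns` (ref, donor, acceptor,
#'   strand, class, transcript), `transcripts` and `exons`.
#' @export
simulate_transcripts_and_reads <- function(genome,
                                           n_transcripts = 20L,
                                           n_exons = c(2L, 8L),
                                           exon_length = c(80L, 300L),
                                           intron_length = c(50L, 2000L),
                                           n_fragments = 1000L,
                                           read_length = 100L,
                                           paired = TRUE,
                                           fragment_length = 260L,
                                           sub_rate = 0,
                                           indel_rate = 0,
                                           minor_fraction = 0,
                                           seed = NULL) {
  stopifnot(inherits(genome, "reference_set"), length(genome$names) == 1L,
            sub_rate >= 0, sub_rate <= 0.2, indel_rate >= 0,
            indel_rate <= 0.2)
  with_seed(seed, {
    gseq <- genome$seq[[1L]]
    gname <- genome$names[1L]
    glen <- nchar(gseq)
    rint <- function(rng) if (length(rng) == 1L) rng else
      sample(seq(rng[1L], rng[2L]), 1L)

    tx_rows <- list(); exon_rows <- list(); intron_rows <- list()
    cursor <- 100L
    made <- 0L
    for (t in seq_len(n_transcripts)) {
      ne <- rint(n_exons)
      elens <- vapply(seq_len(ne), function(i) rint(exon_length), integer(1))
      ilens <- if (ne > 1L) {
        vapply(seq_len(ne - 1L), function(i) rint(intron_length), integer(1))
      } else integer(0)
      span <- sum(elens) + sum(ilens)
      if (cursor + span + 100L > glen) {
        warning(sprintf("genome exhausted after %d transcript(s)", made))
        break
      }
      strand <- sample(c("+", "-"), 1L)
      starts <- cursor + c(0L, cumsum(elens[-ne] + ilens))
      ends <- starts + elens
      tid <- sprintf("tx%03d", t)
      # write splice signals and de-conflict each junction
      if (ne > 1L) {
        for (j in seq_len(ne - 1L)) {
          cls <- if (stats::runif(1) < minor_fraction) {
            sample(c("minor_GC_AG", "minor_AT_AC"), 1L)
          } else "canonical"
          sig <- splice_signal_bases(cls, strand)
          e <- ends[j]               # first intron base (0-based)
          q <- starts[j + 1L] - 1L   # last intron base
          gseq <- splice_in(gseq, e, sig[1L])
          gseq <- splice_in(gseq, q - 1L, sig[2L])
          pri <- classify_splice(substr(gseq, e + 1L, e + 2L),
                                 substr(gseq, q, q + 1L))$priority
          tries <- 0L
          while (junction_conflict(gseq, e, q, pri) && tries < 100L) {
            ilen <- q - e + 1L
            lo <- e + 2L; hi <- q - 2L
            idx <- unique(c(seq(lo, min(hi, lo + 15L)),
                            seq(max(lo, hi - 15L), hi)))
            repl <- paste0(sample(c("A", "C", "G", "T"), length(idx),
                                  replace = TRUE), collapse = "")
            for (z in seq_along(idx)) {
              gseq <- splice_in(gseq, idx[z], substr(repl, z, z))
            }
            tries <- tries + 1L
          }
          # record with the genome-sense class label
          intron_rows[[length(intron_rows) + 1L]] <-
            data.frame(ref = gname, donor = e, acceptor = q, strand = strand,
                       class = cls, transcript = tid,
                       stringsAsFactors = FALSE)
        }
      }
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(transcript = tid, start = starts, end = ends,
                   stringsAsFactors = FALSE)
      tx_rows[[length(tx_rows) + 1L]] <-
        data.frame(transcript = tid, ref = gname, strand = strand,
                   tx_start = starts[1L], tx_end = ends[ne],
                   n_exons = ne, length = sum(elens),
                   stringsAsFactors = FALSE)
      made <- made + 1L
      cursor <- ends[ne] + rint(c(200L, 800L))
    }
    if (made == 0L) stop("no transcript fits in the genome")
    transcripts <- do.call(rbind, tx_rows)
    exons <- do.call(rbind, exon_rows)
    introns <- if (length(intron_rows)) do.call(rbind, intron_rows) else
      data.frame(ref = character(0), donor = integer(0),
                 acceptor = integer(0), strand = character(0),
                 class = character(0), transcript = character(0),
                 stringsAsFactors = FALSE)

    # transcript sequences (strand-resolved)
    tx_seq <- vapply(seq_len(nrow(transcripts)), function(i) {
      ex <- exons[exons$transcript == transcripts$transcript[i], ]
      s <- paste0(substring(gseq, ex$start + 1L, ex$end), collapse = "")
      if (transcripts$strand[i] == "-") revcomp(s) else s
    }, character(1))

    usable <- which(transcripts$length >= max(read_length,
                                              if (paired) read_length else 0L))
    skipped <- nrow(transcripts) - length(usable)
    if (skipped > 0L) {
      warning(sprintf("%d transcript(s) shorter than the read length skipped",
                      skipped))
    }
    if (length(usable) == 0L) stop("no transcript is long enough to sequence")

    seqs <- character(0); ids <- character(0); mates <- integer(0)
    frags <- character(0)
    read_rows <- list(); block_rows <- list(); edit_rows <- list()

    emit_read <- function(tx_i, t0, t1, mate, frag_id) {
      # template on the transcript: [t0, t1), mate 2 is reverse-complemented
      tpl <- substr(tx_seq[tx_i], t0 + 1L, t1)
      if (mate == 2L) tpl <- revcomp(tpl)
      r <- inject_errors(tpl, read_length, sub_rate, indel_rate)
      consumed <- r$consumed
      # transcript interval actually covered by the read
      tt0 <- if (mate == 2L) t1 - consumed else t0
      tt1 <- if (mate == 2L) t1 else t0 + consumed
      ex <- exons[exons$transcript == transcripts$transcript[tx_i], ]
      blocks <- tx_to_genome_blocks(ex, transcripts$strand[tx_i], tt0, tt1)
      tx_strand <- transcripts$strand[tx_i]
      read_strand <- if (mate == 2L) {
        if (tx_strand == "+") "-" else "+"
      } else tx_strand
      id <- paste0(frag_id, "/", mate)
      list(id = id, seq = r$seq,
           row = data.frame(id = id, ref = gname, strand = read_strand,
                            spans_junction = nrow(blocks) > 1L,
                            stringsAsFactors = FALSE),
           blocks = data.frame(id = id, start = blocks$start,
                               end = blocks$end, stringsAsFactors = FALSE),
           edits = if (nrow(r$edits)) cbind(id = id, r$edits) else NULL)
    }

    for (f in seq_len(n_fragments)) {
      tx_i <- usable[sample.int(length(usable), 1L)]
      txlen <- transcripts$length[tx_i]
      frag_id <- sprintf("frag%06d", f)
      if (paired) {
        want <- round(stats::runif(1, 0.8, 1.2) * fragment_length)
        flen <- max(read_length, min(txlen, want))
        f0 <- sample.int(txlen - flen + 1L, 1L) - 1L
        r1 <- emit_read(tx_i, f0, f0 + min(read_length + 20L, flen), 1L,
                        frag_id)
        r2 <- emit_read(tx_i, max(f0, f0 + flen - read_length - 20L),
                        f0 + flen, 2L, frag_id)
        for (r in list(r1, r2)) {
          seqs <- c(seqs, r$seq); ids <- c(ids, r$id)
          mates <- c(mates, as.integer(sub(".*/", "", r$id)))
          frags <- c(frags, frag_id)
          read_rows[[length(read_rows) + 1L]] <- r$row
          block_rows[[length(block_rows) + 1L]] <- r$blocks
          if (!is.null(r$edits)) edit_rows[[length(edit_rows) + 1L]] <- r$edits
        }
      } else {
        t0 <- sample.int(txlen - read_length + 1L, 1L) - 1L
        r1 <- emit_read(tx_i, t0, min(txlen, t0 + read_length + 20L), 1L,
                        frag_id)
        seqs <- c(seqs, r1$seq); ids <- c(ids, sub("/1$", "", r1$id))
        mates <- c(mates, NA_integer_); frags <- c(frags, frag_id)
        r1$row$id <- sub("/1$", "", r1$row$id)
        r1$blocks$id <- sub("/1$", "", r1$blocks$id)
        read_rows[[length(read_rows) + 1L]] <- r1$row
        block_rows[[length(block_rows) + 1L]] <- r1$blocks
        if (!is.null(r1$edits)) {
          r1$edits$id <- sub("/1$", "", r1$edits$id)
          edit_rows[[length(edit_rows) + 1L]] <- r1$edits
        }
      }
    }

    reference <- reference_set(stats::setNames(gseq, gname))
    reads <- read_batch(seqs, ids = ids,
                        mate = if (paired) mates,
                        fragment_id = frags, paired = paired)
    truth <- list(reads = do.call(rbind, read_rows),
                  read_blocks = do.call(rbind, block_rows),
                  edits = if (length(edit_rows)) do.call(rbind, edit_rows)
                    else data.frame(id = character(0), read_pos = integer(0),
                                    type = character(0), len = integer(0),
                                    stringsAsFactors = FALSE),
                  introns = introns, transcripts = transcripts,
                  exons = exons)
    structure(list(reference = reference, reads = reads, truth = truth),
              class = "sim_data")
  })
}

# Apply i.i.d. substitution/indel errors while consuming a template; stops
# once `read_length` bases are emitted (or the template is exhausted).
inject_errors <- function(template, read_length, sub_rate, indel_rate) {
  tpl <- strsplit(template, "")[[1]]
  if (sub_rate == 0 && indel_rate == 0) {
    n <- min(read_length, length(tpl))
    return(list(seq = paste0(tpl[seq_len(n)], collapse = ""), consumed = n,
                edits = data.frame(read_pos = integer(0),
                                   type = character(0), len = integer(0),
                                   stringsAsFactors = FALSE)))
  }
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  edits <- list()
  i <- 1L
  while (length(out) < read_length && i <= length(tpl)) {
    u <- stats::runif(1)
    if (u < indel_rate) {
      len <- min(3L, 1L + stats::rgeom(1L, 5 / 6))
      if (stats::runif(1) < 0.5) {            # insertion into the read
        ins <- sample(bases, len, replace = TRUE)
        edits[[length(edits) + 1L]] <-
          data.frame(read_pos = length(out), type = "ins", len = len,
                     stringsAsFactors = FALSE)
        out <- c(out, ins)
      } else {                                 # deletion from the template
        edits[[length(edits) + 1L]] <-
          data.frame(read_pos = length(out), type = "del", len = len,
                     stringsAsFactors = FALSE)
        i <- i + len
      }
    } else if (u < indel_rate + sub_rate) {
      edits[[length(edits) + 1L]] <-
        data.frame(read_pos = length(out), type = "sub", len = 1L,
                   stringsAsFactors = FALSE)
      out <- c(out, sample(setdiff(bases, tpl[i]), 1L))
      i <- i + 1L
    } else {
      out <- c(out, tpl[i])
      i <- i + 1L
    }
  }
  list(seq = paste0(utils::head(out, read_length), collapse = ""),
       consumed = i - 1L,
       edits = if (length(edits)) do.call(rbind, edits) else
         data.frame(read_pos = integer(0), type = character(0),
                    len = integer(0), stringsAsFactors = FALSE))
}

# Map a transcript interval [t0, t1) to ascending genome blocks.
tx_to_genome_blocks <- function(exons, strand, t0, t1) {
  lens <- exons$end - exons$start
  total <- sum(lens)
  if (strand == "-") {
    tmp <- total - t1; t1 <- total - t0; t0 <- tmp
  }
  offs <- cumsum(c(0L, lens))
  starts <- integer(0); ends <- integer(0)
  for (k in seq_len(nrow(exons))) {
    a <- max(t0, offs[k]); b <- min(t1, offs[k + 1L])
    if (a < b) {
      starts <- c(starts, exons$start[k] + (a - offs[k]))
      ends <- c(ends, exons$start[k] + (b - offs[k]))
    }
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Truth introns covered by an anchored junction-spanning read
#'
#' The subset of truth introns for which at least one simulated read spans
#' the junction with at least `min_anchor` aligned bases on each side --
#' the introns a seed-and-extend aligner can recover when the anchor covers
#' a full seed.
#'
#' @param truth truth list from [simulate_transcripts_and_reads()].
#' @param min_anchor minimum exon overhang on both sides (default 18, the
#'   seed length).
#' @return subset of `truth$introns`.
#' @export
truth_spanning_introns <- function(truth, min_anchor = 18L) {
  tb <- truth$read_blocks
  if (nrow(truth$introns) == 0L) return(truth$introns)
  covered <- character(0)
  for (id in unique(tb$id)) {
    b <- tb[tb$id == id, , drop = FALSE]
    if (nrow(b) < 2L) next
    b <- b[order(b$start), , drop = FALSE]
    for (k in seq_len(nrow(b) - 1L)) {
      anchor <- min(b$end[k] - b$start[k], b$end[k + 1L] - b$start[k + 1L])
      if (anchor >= min_anchor) {
        covered <- c(covered, paste(b$end[k], b$start[k + 1L] - 1L))
      }
    }
  }
  keep <- paste(truth$introns$donor, truth$introns$acceptor) %in% covered
  truth$introns[keep, , drop = FALSE]
}

#' Serialise a truth track to tab-delimited text
#'
#' @param truth truth list from [simulate_transcripts_and_reads()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_truth_track <- function(truth, file) {
  con <- file(file, "w")
  on.exit(close(con))
  blocks <- vapply(split(truth$read_blocks,
                         factor(truth$read_blocks$id,
                                levels = unique(truth$read_blocks$id))),
                   function(b) paste(sprintf("%d-%d", b$start, b$end),
                                     collapse = ","),
                   character(1))
  rd <- truth$reads
  rd$blocks <- blocks[rd$id]
  ed <- truth$edits
  edstr <- if (nrow(ed)) {
    vapply(split(ed, factor(ed$id, levels = unique(rd$id))),
           function(e) if (nrow(e) == 0L) "." else
             paste(sprintf("%d:%s:%d", e$read_pos, e$type, e$len),
                   collapse = ","),
           character(1))[rd$id]
  } else rep(".", nrow(rd))
  edstr[is.na(edstr) | edstr == ""] <- "."
  writeLines("#type\tid\tref\tstrand\tinfo1\tinfo2", con)
  writeLines(sprintf("read\t%s\t%s\t%s\t%s\t%s", rd$id, rd$ref, rd$strand,
                     rd$blocks, edstr), con)
  it <- truth$introns
  if (nrow(it)) {
    writeLines(sprintf("intron\t%s\t%s\t%s\t%d-%d\t%s", it$transcript,
                       it$ref, it$strand, it$donor, it$acceptor, it$class),
               con)
  }
  invisible(file)
}

#' Read a truth track written by [write_truth_track()]
#'
#' @param file path.
#' @return truth list with `reads`, `read_blocks`, `edits`, `introns`.
#' @export
read_truth_track <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(f, `[`, "", 1L)
  rd <- f[type == "read"]
  parse_blocks <- function(s, id) {
    parts <- strsplit(strsplit(s, ",")[[1]], "-")
    data.frame(id = id,
               start = as.integer(vapply(parts, `[`, "", 1L)),
               end = as.integer(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, lapply(rd, function(x) parse_blocks(x[5], x[2])))
  edits <- do.call(rbind, lapply(rd, function(x) {
    if (x[6] == ".") return(NULL)
    parts <- strsplit(strsplit(x[6], ",")[[1]], ":")
    data.frame(id = x[2],
               read_pos = as.integer(vapply(parts, `[`, "", 1L)),
               type = vapply(parts, `[`, "", 2L),
               len = as.integer(vapply(parts, `[`, "", 3L)),
               stringsAsFactors = FALSE)
  }))
  reads <- do.call(rbind, lapply(rd, function(x) {
    data.frame(id = x[2], ref = x[3], strand = x[4],
               spans_junction = grepl(",", x[5]), stringsAsFactors = FALSE)
  }))
  it <- f[type == "intron"]
  introns <- if (length(it)) do.call(rbind, lapply(it, function(x) {
    da <- as.integer(strsplit(x[5], "-")[[1]])
    data.frame(ref = x[3], donor = da[1], acceptor = da[2], strand = x[4],
               class = x[6], transcript = x[2], stringsAsFactors = FALSE)
  })) else data.frame(ref = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      class = character(0), transcript = character(0),
                      stringsAsFactors = FALSE)
  list(reads = reads, read_blocks = blocks,
       edits = if (is.null(edits)) data.frame(id = character(0),
                                              read_pos = integer(0),
                                              type = character(0),
                                              len = integer(0),
                                              stringsAsFactors = FALSE)
              else edits,
       introns = introns)
}
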