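#' Canonical-code match of a third-strand base against a duplex purine
#'
#' In the parallel (pyrimidine) motif the third strand reads the purine
#' strand of the Watson-Crick duplex through Hoogsteen pairing: U recognizes
#' the A of an A-T pair (U.A-T triplet) and protonated C recognizes the G of
#' a G-C pair (C+.G-C triplet). Every other combination is a mismatch; G.T
#' and other non-canonical triplets are deliberately excluded.
#'
#' @param rna_base one of `A,C,G,U`.
#' @param purine_base one of `A,C,G,T` (the purine-strand base actually
#'   present, which at mismatch positions may be a pyrimidine).
#' @return `"match"` or `"mismatch"`.
#' @examples
#' canonical_triplet_match("U", "A")  # match
#' canonical_triplet_match("C", "T")  # mismatch
#' @export
canonical_triplet_match <- function(rna_base, purine_base) {
  if (!is.character(rna_base) || length(rna_base) != 1L ||
      !rna_base %in% c("A", "C", "G", "U")) {
    stop("canonical_triplet_match: invalid RNA base '", rna_base,
         "' (expected one of A,C,G,U)")
  }
  if (!is.character(purine_base) || length(purine_base) != 1L ||
      !purine_base %in% c("A", "C", "G", "T")) {
    stop("canonical_triplet_match: invalid DNA base '", purine_base,
         "' (expected one of A,C,G,T)")
  }
  if ((rna_base == "U" && purine_base == "A") ||
      (rna_base == "C" && purine_base == "G")) "match" else "mismatch"
}

# vectorized internal form: TRUE where canonical
.canonical_ok <- function(rna_bases, purine_bases) {
  (rna_bases == "U" & purine_bases == "A") |
    (rna_bases == "C" & purine_bases == "G")
}

#' Construct a triplex alignment
#'
#' Pairs an RNA window in parallel orientation with a window of the duplex
#' purine strand and annotates each position as canonical (`"|"`) or
#' mismatch (`"*"`). Coordinates are 1-based inclusive on the source
#' sequences.
#'
#' @param rna `sequence_record` (RNA source).
#' @param purine `sequence_record` (DNA purine strand source).
#' @param rna_start,purine_start 1-based window starts.
#' @param window_len window length (equal on both strands).
#' @return object of class `triplex_alignment` with fields `rna_id`,
#'   `purine_id`, `rna_window`, `purine_window`, `rna_start`, `rna_end`,
#'   `purine_start`, `purine_end`, `orientation` (always `"parallel"`),
#'   `pairing`, `mismatch_positions` (window-local, 1-based), `n_mismatch`.
#' @export
triplex_alignment <- function(rna, purine, rna_start, purine_start,
                              window_len) {
  stopifnot(inherits(rna, "sequence_record"), rna$kind == "rna")
  stopifnot(inherits(purine, "sequence_record"), purine$kind == "dna")
  window_len <- as.integer(window_len)
  rna_start <- as.integer(rna_start); purine_start <- as.integer(purine_start)
  if (rna_start < 1L || rna_start + window_len - 1L > length(rna)) {
    stop("triplex_alignment: RNA window out of range")
  }
  if (purine_start < 1L || purine_start + window_len - 1L > length(purine)) {
    stop("triplex_alignment: purine window out of range")
  }
  rw <- substr(rna$sequence, rna_start, rna_start + window_len - 1L)
  pw <- substr(purine$sequence, purine_start, purine_start + window_len - 1L)
  ok <- .canonical_ok(strsplit(rw, "")[[1]], strsplit(pw, "")[[1]])
  structure(
    list(
      rna_id = rna$id, purine_id = purine$id,
      rna_window = rw, purine_window = pw,
      rna_start = rna_start, rna_end = rna_start + window_len - 1L,
      purine_start = purine_start,
      purine_end = purine_start + window_len - 1L,
      orientation = "parallel",
      pairing = paste(ifelse(ok, "|", "*"), collapse = ""),
      mismatch_positions = which(!ok),
      n_mismatch = sum(!ok)
    ),
    class = "triplex_alignment"
  )
}

#' @export
length.triplex_alignment <- function(x) nchar(x$rna_window)

#' @export
print.triplex_alignment <- function(x, ...) {
  cat(render_alignment(x))
  invisible(x)
}

#' Scan for triplex target sites under the canonical code
#'
#' Slides a window of `window_len` over every (RNA offset, purine offset)
#' pair in parallel orientation and keeps windows with at most
#' `max_mismatch` non-canonical positions. Output is sorted by
#' (n_mismatch, purine offset, RNA offset), all ascending, and is fully
#' deterministic. Sequences shorter than the window give an empty result
#' with a warning rather than an error.
#'
#' @param rna RNA `sequence_record`.
#' @param purine_strand DNA `sequence_record` (purine strand of the
#'   duplex).
#' @param window_len window length (default 15, the canonical TTS length).
#' @param max_mismatch mismatch budget.
#' @return list of [triplex_alignment()] objects.
#' @export
scan_tts <- function(rna, purine_strand, window_len = 15L, max_mismatch = 2L) {
  stopifnot(inherits(rna, "sequence_record"), rna$kind == "rna")
  stopifnot(inherits(purine_strand, "sequence_record"),
            purine_strand$kind == "dna")
  window_len <- as.integer(window_len)
  max_mismatch <- as.integer(max_mismatch)
  if (window_len < 4L) stop("scan_tts: window_len must be >= 4")
  if (max_mismatch < 0L) stop("scan_tts: max_mismatch must be >= 0")
  nr <- length(rna); np <- length(purine_strand)
  if (nr < window_len || np < window_len) {
    warning(sprintf(
      "scan_tts: sequence shorter than window (%d); empty result", window_len
    ))
    return(list())
  }
  rb <- seq_bases(rna); pb <- seq_bases(purine_strand)
  hits <- list()
  for (po in seq_len(np - window_len + 1L)) {
    pw <- pb[po:(po + window_len - 1L)]
    for (ro in seq_len(nr - window_len + 1L)) {
      mm <- sum(!.canonical_ok(rb[ro:(ro + window_len - 1L)], pw))
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <- c(mm, po, ro)
      }
    }
  }
  if (length(hits) == 0L) return(list())
  key <- do.call(rbind, hits)
  ord <- order(key[, 1], key[, 2], key[, 3])
  lapply(ord, function(k) {
    triplex_alignment(rna, purine_strand,
                      rna_start = key[k, 3], purine_start = key[k, 2],
                      window_len = window_len)
  })
}

#' Render a triplex alignment as a three-line text block
#'
#' Line 1: the DNA purine strand 5'->3'; line 2: the pairing annotation
#' (`|` canonical, `*` mismatch); line 3: the RNA third strand 5'->3'
#' (parallel orientation). [parse_alignment()] round-trips the block.
#'
#' @param a `triplex_alignment`.
#' @return a single character string (three newline-terminated lines).
#' @export
render_alignment <- function(a) {
  stopifnot(inherits(a, "triplex_alignment"))
  paste0(
    sprintf("5'-%s-3' DNA %s:%d-%d\n", a$purine_window, a$purine_id,
            a$purine_start, a$purine_end),
    sprintf("   %s\n", a$pairing),
    sprintf("5'-%s-3' RNA %s:%d-%d\n", a$rna_window, a$rna_id,
            a$rna_start, a$rna_end)
  )
}

#' Parse a rendered alignment block back into a triplex_alignment
#' @param text a block produced by [render_alignment()].
#' @return `triplex_alignment`.
#' @export
parse_alignment <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  if (length(lines) < 3L) stop("parse_alignment: expected three lines")
  m1 <- regmatches(lines[1],
    regexec("^5'-([ACGT]+)-3' DNA (.+):(\\d+)-(\\d+)$", lines[1]))[[1]]
  m3 <- regmatches(lines[3],
    regexec("^5'-([ACGU]+)-3' RNA (.+):(\\d+)-(\\d+)$", lines[3]))[[1]]
  if (length(m1) == 0L || length(m3) == 0L) {
    stop("parse_alignment: malformed sequence lines")
  }
  purine <- sequence_record(m1[3], m1[2], "dna")
  rna <- sequence_record(m3[3], m3[2], "rna")
  a <- triplex_alignment(rna, purine, rna_start = 1L, purine_start = 1L,
                         window_len = nchar(m1[2]))
  # restore original coordinates
  a$rna_start <- as.integer(m3[4]); a$rna_end <- as.integer(m3[5])
  a$purine_start <- as.integer(m1[4]); a$purine_end <- as.integer(m1[5])
  ann <- trimws(lines[2])
  if (nchar(ann) != length(a) || ann != a$pairing) {
    stop("parse_alignment: annotation line inconsistent with sequences")
  }
  a
}

#' Clip an extended alignment to the span of a core alignment
#'
#' Extended models (additional flanking base pairs added to tame terminal
#' fraying) are compared with the short model on the shared span only. The
#' core RNA window must occur exactly once as a contiguous subsequence of
#' the extended RNA window, with the purine windows agreeing at the same
#' offset; otherwise this is an ambiguity error, never a guess.
#'
#' @param extended,core `triplex_alignment` objects.
#' @return `triplex_alignment` restricted to the core span.
#' @export
clip_alignment <- function(extended, core) {
  stopifnot(inherits(extended, "triplex_alignment"),
            inherits(core, "triplex_alignment"))
  hits <- gregexpr(core$rna_window, extended$rna_window, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  # keep offsets where the purine window also matches
  hits <- hits[vapply(hits, function(off) {
    substr(extended$purine_window, off, off + length(core) - 1L) ==
      core$purine_window
  }, logical(1))]
  if (length(hits) == 0L) {
    stop("clip_alignment: core windows not found in extended alignment")
  }
  if (length(hits) > 1L) {
    stop("clip_alignment: core found at multiple offsets (",
         paste(hits, collapse = ", "), "); refusing to guess")
  }
  off <- hits[1]
  rna_src <- sequence_record(extended$rna_id, extended$rna_window, "rna")
  pur_src <- sequence_record(extended$purine_id, extended$purine_window, "dna")
  a <- triplex_alignment(rna_src, pur_src, rna_start = off,
                         purine_start = off, window_len = length(core))
  a$rna_start <- extended$rna_start + off - 1L
  a$rna_end <- a$rna_start + length(core) - 1L
  a$purine_start <- extended$purine_start + off - 1L
  a$purine_end <- a$purine_start + length(core) - 1L
  a$clip_offset <- off
  a
}

#' Tabulate triplex alignments
#' @param alignments list of `triplex_alignment`.
#' @return data.frame with columns rna_start, rna_end, purine_start,
#'   purine_end, length, n_mismatch, pairing.
#' @export
tts_table <- function(alignments) {
  if (inherits(alignments, "triplex_alignment")) alignments <- list(alignments)
  do.call(rbind, lapply(alignments, function(a) {
    data.frame(
      rna_start = a$rna_start, rna_end = a$rna_end,
      purine_start = a$purine_start, purine_end = a$purine_end,
      length = length(a), n_mismatch = a$n_mismatch,
      pairing = a$pairing, stringsAsFactors = FALSE
    )
  }))
}

#' Write a TTS scan as TSV
#' @param alignments list of `triplex_alignment`.
#' @param path output TSV path.
#' @export
write_tts_tsv <- function(alignments, path) {
  utils::write.table(tts_table(alignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write target sites as BED6 on the duplex
#'
#' Intervals are the purine-strand windows converted to 0-based half-open
#' coordinates; the score column carries the mismatch count and the strand
#' column the purine strand's strand.
#'
#' @param alignments list of `triplex_alignment`.
#' @param path output BED path.
#' @param chrom chromosome/sequence name for the duplex (defaults to the
#'   purine record id).
#' @param strand strand of the purine strand on the reference, "+" or "-".
#' @export
write_tts_bed <- function(alignments, path, chrom = NULL, strand = "+") {
  if (inherits(alignments, "triplex_alignment")) alignments <- list(alignments)
  rows <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    data.frame(
      chrom = if (is.null(chrom)) a$purine_id else chrom,
      start = a$purine_start - 1L,   # 0-based half-open
      end = a$purine_end,
      name = sprintf("TTS_%d_mm%d", i, a$n_mismatch),
      score = a$n_mismatch,
      strand = strand,
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
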