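#' Sequence records for triplex scanning
#'
#' A `sequence_record` is a light container for a single nucleic-acid
#' sequence with an explicit molecule kind. RNA records may not contain T
#' and DNA records may not contain U; validation is strict so that a DNA
#' sequence is never silently read as RNA (use `dna_as_rna()` for an
#' explicit transliteration).
#'
#' @param id character label.
#' @param sequence character scalar, bases 5'->3' over `{A,C,G,U,T}`.
#' @param kind `"rna"` or `"dna"`.
#' @return An object of class `sequence_record` with fields `id`,
#'   `sequence`, `kind` and optional provenance (`source_id`, `start`,
#'   `end`) filled in by [extract_dbd()].
#' @examples
#' sequence_record("dbd", "UCCUUC", "rna")
#' @export
sequence_record <- function(id, sequence, kind = c("rna", "dna")) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) == 0L) {
    stop("sequence_record: empty sequence for id '", id, "'")
  }
  bases <- strsplit(sequence, "")[[1]]
  allowed <- if (kind == "rna") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  bad <- which(!bases %in% allowed)
  if (length(bad) > 0L) {
    stop(sprintf(
      "sequence_record: invalid %s symbol '%s' at position %d in '%s'",
      toupper(kind), bases[bad[1]], bad[1], id
    ))
  }
  structure(
    list(id = id, sequence = sequence, kind = kind),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s [%s], %d nt\n", x$id, x$kind,
              nchar(x$sequence)))
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  5'-", s, "-3'\n", sep = "")
  invisible(x)
}

#' @export
length.sequence_record <- function(x) nchar(x$sequence)

seq_bases <- function(rec) strsplit(rec$sequence, "")[[1]]

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a list of
#' [sequence_record()] objects with the stated molecule kind enforced.
#'
#' @param path FASTA file.
#' @param kind `"rna"` or `"dna"`; every record is validated against it.
#' @return list of `sequence_record`.
#' @export
read_fasta <- function(path, kind = c("rna", "dna")) {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("read_fasta: no records in ", path)
  recs <- lapply(seq_along(set), function(i) {
    sequence_record(names(set)[i], as.character(set[[i]]), kind)
  })
  names(recs) <- names(set)
  recs
}

#' Write sequence records to FASTA
#' @param recs a `sequence_record` or list of them.
#' @param path output file.
#' @export
write_fasta <- function(recs, path) {
  if (inherits(recs, "sequence_record")) recs <- list(recs)
  lines <- unlist(lapply(recs, function(r) c(paste0(">", r$id), r$sequence)))
  writeLines(lines, path)
  invisible(path)
}

#' Explicitly transliterate a DNA record to RNA (T -> U)
#' @param rec a DNA `sequence_record`.
#' @return an RNA `sequence_record` with the same id.
#' @export
dna_as_rna <- function(rec) {
  stopifnot(inherits(rec, "sequence_record"))
  if (rec$kind != "dna") stop("dna_as_rna: input is not DNA")
  sequence_record(rec$id, chartr("T", "U", rec$sequence), "rna")
}

#' Pick the purine strand of a duplex
#'
#' A triplex target duplex may be supplied as both strands; the scanner
#' works on the purine-rich strand (the strand the third strand is parallel
#' to). By default the strand with more purines (A/G) wins; ties are an
#' error unless `force` selects a strand explicitly.
#'
#' @param strand1,strand2 DNA `sequence_record`s (reverse-complementary
#'   strands of one duplex; complementarity is not enforced).
#' @param force `NULL`, `1` or `2` to override the purine-content rule.
#' @return the chosen `sequence_record`.
#' @export
choose_purine_strand <- function(strand1, strand2, force = NULL) {
  stopifnot(inherits(strand1, "sequence_record"),
            inherits(strand2, "sequence_record"))
  if (!is.null(force)) {
    if (!force %in% c(1, 2)) stop("choose_purine_strand: force must be 1 or 2")
    return(if (force == 1) strand1 else strand2)
  }
  pur <- function(r) sum(seq_bases(r) %in% c("A", "G")) / length(r)
  p1 <- pur(strand1); p2 <- pur(strand2)
  if (p1 == p2) {
    stop("choose_purine_strand: equal purine content; pass force = 1 or 2")
  }
  if (p1 > p2) strand1 else strand2
}

#' Extract the DNA-binding domain window of a lncRNA
#'
#' Coordinates are 1-based and inclusive on both ends, the convention used
#' for lncRNA DBD annotations (e.g. the Snhg15 DBD at nt 1896-1925, a 30-nt
#' window). Provenance (source id, start, end) is retained on the slice.
#'
#' @param rna_full `sequence_record` (RNA).
#' @param start,end 1-based inclusive coordinates; defaults are the Snhg15
#'   DBD window.
#' @return `sequence_record` of length `end - start + 1`.
#' @export
extract_dbd <- function(rna_full, start = 1896L, end = 1925L) {
  stopifnot(inherits(rna_full, "sequence_record"))
  n <- length(rna_full)
  if (!(start >= 1L && start <= end && end <= n)) {
    stop(sprintf(
      "extract_dbd: coordinates [%d, %d] out of range for '%s' (length %d)",
      start, end, rna_full$id, n
    ))
  }
  rec <- sequence_record(
    sprintf("%s:%d-%d", rna_full$id, start, end),
    substr(rna_full$sequence, start, end),
    rna_full$kind
  )
  rec$source_id <- rna_full$id
  rec$start <- as.integer(start)
  rec$end <- as.integer(end)
  rec
}
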