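# Sequence I/O: FASTQ/FASTA reading and writing, quality filtering, and IUPAC
# utilities shared by every assay module. Records travel as tibbles with one
# row per sequence: `id`, `sequence`, and (FASTQ only) a `quality` list-column
# of integer Phred scores.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set -> IUPAC code
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Quality characters at or above 'K' (Phred+33 score 42) are taken as evidence
# of a Phred+64 file; modern Phred+33 data top out at Q41.
.MAX_Q_CHAR <- 74L

normalize_nt <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Read a 4-line FASTQ file
#'
#' Reads Phred+33 FASTQ into a tibble with one row per record. Sequences are
#' uppercased and RNA `U` is mapped to `T`. Malformed records (bad header,
#' missing `+` line, quality length different from sequence length) raise an
#' error naming the offending line. Files that look Phred+64 (quality
#' characters above score 41) are rejected.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `id` (text before the first space of the
#'   header), `sequence`, and `quality` (list-column of integer Phred scores).
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  lines <- readLines(path)
  empty <- tibble(id = character(), sequence = character(), quality = list())
  if (length(lines) == 0) return(empty)
  if (length(lines) %% 4 != 0) {
    abort(paste0("truncated FASTQ record starting at line ",
                 4 * (length(lines) %/% 4) + 1))
  }
  idx <- seq(1, length(lines), by = 4)
  hdr <- lines[idx]
  seqs <- lines[idx + 1]
  plus <- lines[idx + 2]
  qual <- lines[idx + 3]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(paste0("malformed FASTQ header at line ", idx[bad[1]],
                 ": expected '@', got '", substr(hdr[bad[1]], 1, 1), "'"))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(paste0("malformed FASTQ separator at line ", idx[bad[1]] + 2))
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad)) {
    abort(paste0("quality length differs from sequence length at line ",
                 idx[bad[1]] + 3))
  }
  qint <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  lo <- vapply(qint, function(q) if (length(q)) min(q) else 0L, 0L)
  hi <- vapply(qint, function(q) if (length(q)) max(q) else 0L, 0L)
  if (any(lo < 0L)) {
    abort(paste0("quality character below '!' at line ",
                 idx[which(lo < 0L)[1]] + 3, "; not Phred+33"))
  }
  if (any(hi > .MAX_Q_CHAR - 33L)) {
    abort(paste0("quality scores exceed the Phred+33 range at line ",
                 idx[which(hi > .MAX_Q_CHAR - 33L)[1]] + 3,
                 "; Phred+64 input is not supported"))
  }
  tibble(
    id = sub("\\s.*$", "", substring(hdr, 2)),
    sequence = normalize_nt(seqs),
    quality = qint
  )
}

#' Write records to FASTQ
#'
#' @param records Tibble with `id`, `sequence`, `quality` columns (as produced
#'   by [read_fastq()] or the simulators).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(records)))
  qchr <- vapply(records$quality, function(q) intToUtf8(q + 33L), "")
  out <- rbind(paste0("@", records$id), records$sequence, "+", qchr)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a tibble.
#' Nucleotide input is uppercased with `U` mapped to `T`.
#'
#' @param path FASTA path.
#' @param alphabet `"nt"` (default) or `"aa"`.
#' @return Tibble with `id` and `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  if (alphabet == "nt") seqs <- normalize_nt(seqs) else seqs <- toupper(seqs)
  tibble(id = sub("\\s.*$", "", names(ss)), sequence = unname(seqs))
}

#' Write FASTA (wrapped at 60 columns)
#'
#' @param records Tibble with `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Filter reads by mean Phred quality
#'
#' Retains records whose mean Phred score is strictly greater than
#' `min_mean_q` (default 20), preserving input order. Every record must carry
#' quality scores.
#'
#' @param records FASTQ record tibble.
#' @param min_mean_q Threshold; reads with mean quality exactly equal to it
#'   are discarded.
#' @return The filtered tibble.
#' @export
quality_filter <- function(records, min_mean_q = 20) {
  if (!"quality" %in% names(records)) abort("records carry no quality scores")
  if (nrow(records) == 0) return(records)
  ok <- vapply(records$quality, function(q) {
    if (is.null(q)) abort("record without quality scores")
    mean(q) > min_mean_q
  }, logical(1))
  records[ok, , drop = FALSE]
}

#' Reverse complement (IUPAC-aware)
#'
#' Vectorized reverse complement honouring the full IUPAC degeneracy alphabet
#' (R<->Y, etc.). Errors on non-IUPAC characters.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("ACGT", "NGG"))
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_nt(seq)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seq)
  if (any(bad)) {
    abort(paste0("non-IUPAC character in sequence: ", seq[which(bad)[1]]))
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

iupac_regex <- function(pattern) {
  pattern <- normalize_nt(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad)) abort(paste0("non-IUPAC character in pattern: ", chars[bad][1]))
  paste0(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Match a sequence against an IUPAC pattern
#'
#' Position-wise containment test: `TRUE` iff every base of `seq` lies in the
#' degeneracy set of the pattern base at that position. Vectorized over `seq`.
#'
#' @param pattern IUPAC pattern (e.g. `"NGG"`).
#' @param seq Character vector of concrete sequences, each the same length as
#'   `pattern`.
#' @return Logical vector.
#' @examples
#' iupac_match("NGG", c("AGG", "ACG"))
#' @export
iupac_match <- function(pattern, seq) {
  seq <- normalize_nt(seq)
  if (any(nchar(seq) != nchar(pattern))) {
    abort("pattern and sequence lengths differ")
  }
  grepl(paste0("^", iupac_regex(pattern), "$"), seq)
}

# IUPAC code for a set of concrete bases ("N" for empty/complete handled by caller)
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_FROM_SET[[key]]
  if (is.null(code)) abort(paste0("no IUPAC code for base set {", key, "}"))
  code
}
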