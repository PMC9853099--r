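#' Read FASTA or FASTQ sequences
#'
#' Streams a FASTA or FASTQ file (plain or gzip, auto-detected from the
#' magic bytes and the leading record character) into a data.frame.
#' Multi-line FASTA is joined; sequence case is preserved (matching is
#' case-insensitive downstream). Only the first whitespace-delimited token
#' of a header is the sequence name. Malformed records -- an empty header,
#' or a FASTQ quality string whose length differs from its sequence --
#' signal a parse error naming the offending line.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzip-compressed.
#' @return A data.frame with columns `name`, `seq`, `qual` (`NA` for FASTA).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a desc", "ACGT", "TTAA"), f)
#' read_sequences(f)
#' @export
read_sequences <- function(path) {
  con <- gzfile(path, "rt") # transparently reads plain files too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonempty <- which(nzchar(lines))
  if (length(nonempty) == 0L)
    return(data.frame(name = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  first <- substr(lines[nonempty[1L]], 1L, 1L)
  if (first == ">") parse_fasta(lines)
  else if (first == "@") parse_fastq(lines)
  else stop("unrecognized sequence format (expected '>' or '@') at line ",
            nonempty[1L])
}

header_name <- function(line, lineno) {
  name <- sub("\\s.*$", "", substring(line, 2L))
  if (!nzchar(name)) stop("empty header at line ", lineno)
  name
}

parse_fasta <- function(lines) {
  keep <- nzchar(lines)
  heads <- which(keep & startsWith(lines, ">"))
  if (length(heads) == 0L || any(which(keep)[1L] < heads[1L]))
    stop("sequence data before first header at line ", which(keep)[1L])
  names <- vapply(heads, function(i) header_name(lines[i], i), character(1))
  bounds <- c(heads, length(lines) + 1L)
  seqs <- vapply(seq_along(heads), function(j) {
    lo <- bounds[j] + 1L
    hi <- bounds[j + 1L] - 1L
    if (lo > hi) return("")
    body <- lines[lo:hi]
    paste(body[nzchar(body)], collapse = "")
  }, character(1))
  data.frame(name = names, seq = seqs, qual = NA_character_,
             stringsAsFactors = FALSE)
}

parse_fastq <- function(lines) {
  # FASTQ here is the common 4-line form; trailing blank lines tolerated
  lines <- lines[seq_len(max(which(nzchar(lines))))]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at line ", length(lines))
  n <- length(lines) %/% 4L
  i0 <- (seq_len(n) - 1L) * 4L
  names <- character(n); seqs <- character(n); quals <- character(n)
  for (j in seq_len(n)) {
    h <- lines[i0[j] + 1L]
    if (!startsWith(h, "@")) stop("expected '@' header at line ", i0[j] + 1L)
    names[j] <- header_name(h, i0[j] + 1L)
    seqs[j] <- lines[i0[j] + 2L]
    if (!startsWith(lines[i0[j] + 3L], "+"))
      stop("expected '+' separator at line ", i0[j] + 3L)
    quals[j] <- lines[i0[j] + 4L]
    if (nchar(quals[j]) != nchar(seqs[j]))
      stop("quality length differs from sequence length at line ", i0[j] + 4L)
  }
  data.frame(name = names, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

empty_paf <- function() {
  data.frame(qname = character(0), qlen = integer(0), qstart = integer(0),
             qend = integer(0), strand = character(0), tname = character(0),
             tlen = integer(0), tstart = integer(0), tend = integer(0),
             nmatch = integer(0), alen = integer(0), mapq = integer(0),
             tags = character(0), stringsAsFactors = FALSE)
}

validate_paf <- function(records) {
  req <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
           "tstart", "tend", "nmatch", "alen", "mapq")
  missing <- setdiff(req, names(records))
  if (length(missing)) stop("missing PAF columns: ", paste(missing, collapse = ", "))
  with(records, {
    if (any(qstart < 0 | qstart >= qend | qend > qlen))
      stop("invalid query interval: need 0 <= start < end <= len")
    if (any(tstart < 0 | tstart >= tend | tend > tlen))
      stop("invalid target interval: need 0 <= start < end <= len")
    if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(mapq < 0 | mapq > 255)) stop("mapq must be in 0..255")
  })
  invisible(records)
}

#' Write and parse PAF (Pairwise mApping Format)
#'
#' Twelve mandatory tab-separated columns -- query name/length/start/end,
#' strand, target name/length/start/end, residue matches, block length,
#' mapping quality -- with 0-based half-open coordinates; reverse-strand
#' records carry forward-strand target coordinates. A `tags` column, when
#' present and non-`NA`, is appended verbatim (pre-formatted `TAG:TYPE:VAL`
#' text). `write_paf()` validates records (empty intervals are rejected;
#' `mapq = 255` is the missing-quality sentinel and accepted) and returns
#' the number of lines written; `parse_paf()` inverts it field-for-field
#' and signals a parse error with the line number on rows having fewer
#' than 12 columns.
#'
#' @param records PAF data.frame (see [chains_to_records()]).
#' @param path File path or connection; `""` writes to stdout.
#' @return `write_paf()`: line count, invisibly. `parse_paf()`: a PAF
#'   data.frame.
#' @examples
#' rec <- data.frame(qname = "q", qlen = 100L, qstart = 0L, qend = 50L,
#'                   strand = "+", tname = "t", tlen = 500L, tstart = 10L,
#'                   tend = 60L, nmatch = 40L, alen = 50L, mapq = 60L)
#' f <- tempfile(fileext = ".paf")
#' write_paf(rec, f)
#' parse_paf(f)
#' @export
write_paf <- function(records, path = "") {
  validate_paf(records)
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "alen", "mapq")
  fields <- do.call(paste, c(lapply(cols, function(cn) records[[cn]]),
                             sep = "\t"))
  if (!is.null(records$tags)) {
    has <- !is.na(records$tags) & nzchar(records$tags)
    fields[has] <- paste(fields[has], records$tags[has], sep = "\t")
  }
  writeLines(fields, path)
  invisible(length(fields))
}

#' @rdname write_paf
#' @export
parse_paf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_paf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short)) stop("fewer than 12 PAF columns at line ", short[1L])
  get <- function(i) vapply(parts, `[[`, character(1), i)
  out <- data.frame(
    qname = get(1), qlen = as.integer(get(2)), qstart = as.integer(get(3)),
    qend = as.integer(get(4)), strand = get(5), tname = get(6),
    tlen = as.integer(get(7)), tstart = as.integer(get(8)),
    tend = as.integer(get(9)), nmatch = as.integer(get(10)),
    alen = as.integer(get(11)), mapq = as.integer(get(12)),
    tags = vapply(parts, function(p) {
      if (length(p) > 12L) paste(p[-(1:12)], collapse = "\t") else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE)
  out
}
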