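# Independent oracles and small generators used across the suite.
# These stay deliberately naive: per-bit counting in plain R, recursive
# chain enumeration, a textbook edit-distance DP.

NIBBLE_BITS <- vapply(0:15, function(v) as.integer(intToBits(v))[1:4],
                      integer(4)) # 4 x 16, LSB-first per nibble

# hex string vector -> bit matrix (rows = items, cols = bit 0 .. b-1)
hex_bit_matrix <- function(items, b) {
  w <- (b + 3L) %/% 4L
  nib <- matrix(strtoi(unlist(strsplit(tolower(items), "")), 16L),
                ncol = w, byrow = TRUE)
  bits <- matrix(0L, nrow = length(items), ncol = 4L * w)
  for (j in seq_len(w)) {
    # nibble column j is the (w - j)-th 4-bit block from the bottom
    cols <- 4L * (w - j) + 1:4
    bits[, cols] <- t(NIBBLE_BITS[, nib[, j] + 1L, drop = FALSE])
  }
  bits[, seq_len(b), drop = FALSE]
}

bits_to_hex <- function(bits, b) {
  w <- (b + 3L) %/% 4L
  full <- c(bits, rep(0L, 4L * w - b))
  nibs <- vapply(seq_len(w), function(j) {
    chunk <- full[4L * (j - 1L) + 1:4]
    sum(chunk * c(1L, 2L, 4L, 8L))
  }, integer(1))
  paste(format.hexmode(rev(nibs)), collapse = "")
}

# naive per-bit majority oracle, independent of the compiled path
naive_simhash <- function(items, b) {
  bits <- hex_bit_matrix(items, b)
  cnt <- colSums(bits) - colSums(1L - bits)
  bits_to_hex(as.integer(cnt > 0), b)
}

complement_hex <- function(h, b) {
  bits <- hex_bit_matrix(h, b)
  bits_to_hex(1L - as.integer(bits[1L, ]), b)
}

rand_hex_items <- function(m, b) {
  w <- (b + 3L) %/% 4L
  top <- b - 4L * (w - 1L)
  lead <- sample(0:(2^top - 1L), m, replace = TRUE)
  rest <- if (w > 1L)
    vapply(seq_len(m), function(i)
      paste(format.hexmode(sample(0:15, w - 1L, replace = TRUE)),
            collapse = ""), character(1))
  else rep("", m)
  paste0(format.hexmode(lead), rest)
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# textbook Levenshtein DP, independent of utils::adist
dp_edit <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n; D[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L,
                             D[i, j] + (x[i] != y[j]))
  D[n + 1L, m + 1L]
}

# exhaustive best co-linear chain score: recursive extension over anchors
# sorted by (t, q); same transition rules as the DP under test
oracle_chain_best <- function(q, t, span, max_gap) {
  ord <- order(t, q)
  q <- q[ord]; t <- t[ord]; span <- span[ord]
  m <- length(q)
  best <- -Inf
  extend <- function(i, score) {
    if (score > best) best <<- score
    if (i < m) for (j in (i + 1L):m) {
      dq <- q[j] - q[i]; dt <- t[j] - t[i]
      if (dq <= 0 || dt <= 0 || dq > max_gap || dt > max_gap) next
      extend(j, score + span[j] - abs(dq - dt))
    }
  }
  for (i in seq_len(m)) extend(i, span[i])
  best
}

write_fasta <- function(records, path) {
  writeLines(as.vector(rbind(paste0(">", records$name), records$seq)), path)
  path
}

write_fastq <- function(records, path) {
  qual <- records$qual
  qual[is.na(qual)] <- vapply(nchar(records$seq[is.na(qual)]),
                              function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", records$name), records$seq,
                             "+", qual)), path)
  path
}

rand_paf_records <- function(n) {
  qlen <- sample(50:5000, n, replace = TRUE)
  qstart <- vapply(qlen, function(l) sample(0:(l - 2L), 1L), integer(1))
  qend <- vapply(seq_len(n), function(i)
    sample((qstart[i] + 1L):qlen[i], 1L), integer(1))
  tlen <- sample(50:5000, n, replace = TRUE)
  tstart <- vapply(tlen, function(l) sample(0:(l - 2L), 1L), integer(1))
  tend <- vapply(seq_len(n), function(i)
    sample((tstart[i] + 1L):tlen[i], 1L), integer(1))
  data.frame(
    qname = paste0("q", seq_len(n)), qlen = qlen, qstart = qstart, qend = qend,
    strand = sample(c("+", "-"), n, replace = TRUE),
    tname = paste0("t", sample(20, n, replace = TRUE)), tlen = tlen,
    tstart = tstart, tend = tend,
    nmatch = sample(1:1000, n, replace = TRUE),
    alen = sample(1:5000, n, replace = TRUE),
    mapq = sample(c(0:60, 255L), n, replace = TRUE),
    tags = ifelse(runif(n) < 0.5, sprintf("tp:A:P\tcm:i:%d", sample(100, n)),
                  NA_character_),
    stringsAsFactors = FALSE)
}
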