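#' SimHash configuration
#'
#' Bit width and hash seed shared by the base hash and the SimHash voting
#' stage. Hash values throughout the package are fixed-width lowercase hex
#' strings of `ceiling(b / 4)` characters; bit position `t = 0` is the
#' least-significant bit.
#'
#' @param b Integer bit width of item hashes and of the output hash value,
#'   between 1 and 64. Defaults to 64, matching the low-collision hash width
#'   conventional in minimizer-based mappers; exhaustive tests use smaller
#'   widths.
#' @param hash_seed Non-negative integer seed of the base hash function.
#'   Identical inputs hash identically across runs for a fixed seed.
#' @return An object of class `simhash_config`.
#' @examples
#' cfg <- simhash_config(b = 16, hash_seed = 7)
#' @export
simhash_config <- function(b = 64L, hash_seed = 0L) {
  b <- as.integer(b)
  if (is.na(b) || b < 1L || b > 64L) stop("b must be in 1..64")
  hash_seed <- as.numeric(hash_seed)
  if (is.na(hash_seed) || hash_seed < 0 || hash_seed >= 2^53)
    stop("hash_seed must be a non-negative integer below 2^53")
  structure(list(b = b, hash_seed = hash_seed), class = "simhash_config")
}

#' @export
print.simhash_config <- function(x, ...) {
  cat(sprintf("simhash_config: b = %d bits, hash_seed = %.0f\n", x$b, x$hash_seed))
  invisible(x)
}

hex_width <- function(b) (b + 3L) %/% 4L

#' Convert between integers and hex hash strings
#'
#' `int_to_hash()` formats a non-negative integer (exact up to 2^53) as the
#' fixed-width hex string used for b-bit hash values; `hash_to_int()` is the
#' inverse and refuses values that cannot be represented exactly as an R
#' double.
#'
#' @param x Numeric vector of non-negative integers.
#' @param b Bit width.
#' @param h Character vector of hex hash strings.
#' @return Character vector of hex strings, or numeric vector of values.
#' @examples
#' int_to_hash(6, 8)       # "06"
#' hash_to_int("1f")       # 31
#' @export
int_to_hash <- function(x, b) {
  x <- as.numeric(x)
  if (any(is.na(x) | x < 0)) stop("hash values must be non-negative")
  if (b < 64 && any(x >= 2^b)) stop("item overflow")
  if (any(x >= 2^53)) stop("values above 2^53 are not exactly representable; use hex strings")
  w <- hex_width(b)
  vapply(x, function(v) {
    digits <- character(w)
    for (i in w:1) {
      digits[i] <- format.hexmode(as.integer(v %% 16))
      v <- v %/% 16
    }
    paste(digits, collapse = "")
  }, character(1))
}

#' @rdname int_to_hash
#' @export
hash_to_int <- function(h) {
  if (any(nchar(h) > 13L))
    stop("hash wider than 52 bits cannot be converted exactly; keep it as hex")
  vapply(h, function(s) {
    d <- strtoi(strsplit(tolower(s), "")[[1]], base = 16L)
    if (any(is.na(d))) stop("invalid hex digit in hash value")
    sum(d * 16^(rev(seq_along(d)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

# Coerce user-supplied items (numeric or hex character) to hex at width b.
as_hash_items <- function(items, b) {
  if (is.numeric(items)) return(int_to_hash(items, b))
  if (!is.character(items)) stop("items must be numeric or hex character")
  w <- hex_width(b)
  items <- tolower(items)
  trimmed <- sub("^0+", "", items)
  trimmed[trimmed == ""] <- "0"
  if (any(nchar(trimmed) > w)) stop("item overflow")
  padded <- paste0(strrep("0", pmax(0L, w - nchar(trimmed))), trimmed)
  top_bits <- b - 4L * (w - 1L) # bits available in the leading nibble
  lead <- strtoi(substr(padded, 1L, 1L), base = 16L)
  if (any(is.na(lead))) stop("invalid hex digit in hash value")
  if (any(lead >= 2^top_bits)) stop("item overflow")
  padded
}

#' Pack a nucleotide word into a 2-bit k-mer code
#'
#' Encodes A=0, C=1, G=2, T=3 with the first base in the most-significant
#' bit pair. Case-insensitive. Words containing any other character
#' (N or other IUPAC codes) are unpackable and signal an error; seed
#' extraction skips the windows that contain them.
#'
#' @param window A single nucleotide string of length at most 26 (so the
#'   packed value stays exactly representable as an R double).
#' @return An object of class `kmer_code` with fields `value`, `k`, `strand`.
#' @examples
#' pack_kmer("ACG")$value  # 6
#' @export
pack_kmer <- function(window) {
  stopifnot(is.character(window), length(window) == 1L)
  k <- nchar(window)
  if (k < 1L || k > 26L) stop("window length must be in 1..26")
  codes <- match(strsplit(toupper(window), "")[[1]], c("A", "C", "G", "T")) - 1L
  if (any(is.na(codes))) stop("unpackable window: ambiguous base in '", window, "'")
  value <- sum(codes * 4^(rev(seq_len(k)) - 1))
  structure(list(value = value, k = k, strand = "forward"), class = "kmer_code")
}

#' @export
print.kmer_code <- function(x, ...) {
  cat(sprintf("kmer_code: value %.0f, k = %d, strand %s%s\n", x$value, x$k, x$strand,
              if (isTRUE(x$palindromic)) " (palindromic)" else ""))
  invisible(x)
}

#' Reverse complement of a k-mer code
#'
#' @param code A `kmer_code`.
#' @return The reverse-complement `kmer_code` on the opposite strand.
#' @export
revcomp <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  k <- code$k
  v <- code$value
  digits <- integer(k)
  for (i in k:1) {
    digits[i] <- v %% 4
    v <- v %/% 4
  }
  rc <- rev(3 - digits)
  structure(list(value = sum(rc * 4^(rev(seq_len(k)) - 1)), k = k,
                 strand = if (code$strand == "forward") "reverse" else "forward"),
            class = "kmer_code")
}

#' Canonical k-mer code
#'
#' Returns whichever of the code and its reverse complement has the smaller
#' packed value; `strand` records which orientation was chosen. Palindromic
#' words (equal to their reverse complement, only possible at even k) are
#' flagged with `palindromic = TRUE` and are skipped during seeding because
#' their strand is ambiguous.
#'
#' @param code A `kmer_code` (forward-strand as produced by [pack_kmer()]).
#' @return A `kmer_code` with `strand` set and a `palindromic` field.
#' @export
canonical <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  rc <- revcomp(code)
  if (code$value < rc$value) {
    out <- code
    out$palindromic <- FALSE
  } else if (rc$value < code$value) {
    out <- rc
    out$palindromic <- FALSE
  } else {
    out <- code
    out$palindromic <- TRUE
  }
  out
}

#' Seedable low-collision base hash
#'
#' A 64-bit invertible mixing finalizer (splitmix64 family) applied to the
#' packed k-mer value XORed with a seed-derived constant, truncated to the
#' low `b` bits. This is the conventional low-collision hash of
#' minimizer-based mappers, and also generates the per-item hashes that the
#' SimHash stage votes over.
#'
#' @param code A `kmer_code`, or a numeric vector of packed values.
#' @param cfg A [simhash_config()].
#' @return Hex hash string(s) of width `ceiling(b / 4)`.
#' @examples
#' base_hash(pack_kmer("ACGTA"), simhash_config(b = 16))
#' @export
base_hash <- function(code, cfg = simhash_config()) {
  stopifnot(inherits(cfg, "simhash_config"))
  v <- if (inherits(code, "kmer_code")) code$value else as.numeric(code)
  as.character(cpp_base_hash(v, cfg$b, cfg$hash_seed))
}

#' SimHash of a multiset of item hashes
#'
#' Per bit position `t`, the counter is (#items with bit t set) minus
#' (#items with bit t clear), counting multiplicity; the output bit is 1
#' exactly when the counter is positive (ties and negative counts give 0).
#' Item order is irrelevant. Highly similar multisets therefore tend to
#' receive identical hash values: a few changed items rarely overturn the
#' per-bit majorities.
#'
#' @param items Item hashes: a numeric vector (values below `2^b`) or a
#'   character vector of hex strings. Repeated items vote with multiplicity.
#' @param cfg A [simhash_config()].
#' @return A single hex hash string.
#' @examples
#' simhash(c(0x0c, 0x0a, 0x09), simhash_config(b = 4))  # "8"
#' @export
simhash <- function(items, cfg = simhash_config()) {
  stopifnot(inherits(cfg, "simhash_config"))
  if (length(items) == 0L) stop("empty set")
  as.character(cpp_simhash(as_hash_items(items, cfg$b), cfg$b))
}

#' Counter vector of a multiset of item hashes
#'
#' The intermediate signed per-bit vote totals behind [simhash()]; element
#' `t + 1` corresponds to bit position `t` (least-significant first). Each
#' entry has absolute value at most the multiset size and shares its parity.
#'
#' @inheritParams simhash
#' @return Integer vector of length `cfg$b`.
#' @export
counter_vector <- function(items, cfg = simhash_config()) {
  stopifnot(inherits(cfg, "simhash_config"))
  if (length(items) == 0L) stop("empty set")
  cpp_counter_vector(as_hash_items(items, cfg$b), cfg$b)
}
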