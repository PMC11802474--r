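# Internal sequence utilities shared across modules.

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA sequences
#'
#' Vectorised reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")  # "NACGT"
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement, which makes k-mer indexing strand-insensitive.
#'
#' @param kmers character vector of k-mers over {A,C,G,T}.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# Map A,C,G,T,N characters (as integer codes from utf8ToInt) to 1..5.
# Everything else maps to NA.
.base_code_map <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A")] <- 1L
  m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L
  m[utf8ToInt("T")] <- 4L
  m[utf8ToInt("N")] <- 5L
  m
})

# utf8 codes -> 1..5 base index (A,C,G,T,N)
base_codes <- function(int_codes) .base_code_map[int_codes]

# Normalise raw sequence text: uppercase, then collapse any IUPAC ambiguity
# code other than A/C/G/T to N. Downstream modules assume a 5-letter alphabet.
normalize_bases <- function(x) {
  x <- toupper(x)
  chartr("RYSWKMBDHVU", "NNNNNNNNNNN", x)
}

# 32-bit mixing finalizer (lowbias32-style: xor-shift / odd-constant multiply
# rounds), computed exactly in doubles. Input and output are doubles holding
# unsigned 32-bit values. Fully deterministic, no per-run salt.
mix32 <- function(x) {
  two16 <- 65536
  two32 <- 4294967296
  mulmod32 <- function(a, c) {
    # (a * c) mod 2^32 with 16-bit limb split so products stay < 2^53
    lo <- a %% two16
    hi <- (a - lo) / two16
    (lo * c + ((hi * c) %% two16) * two16) %% two32
  }
  x <- x %% two32
  x <- xor32(x, floor(x / two16))
  x <- mulmod32(x, 2146121005)  # 0x7feb352d
  x <- xor32(x, floor(x / 32768))
  x <- mulmod32(x, 2221713035)  # 0x846ca68b
  xor32(x, floor(x / two16))
}

# bitwise xor of two doubles holding unsigned 32-bit values
xor32 <- function(a, b) {
  two16 <- 65536
  alo <- a %% two16; ahi <- (a - alo) / two16
  blo <- b %% two16; bhi <- (b - blo) / two16
  bitwXor(as.integer(ahi), as.integer(bhi)) * two16 +
    bitwXor(as.integer(alo), as.integer(blo))
}

# Pack 16-base ACGT strings into unsigned 32-bit values (2 bits/base),
# returned as doubles. Input must be exactly 16 characters of A/C/G/T.
pack16 <- function(x) {
  digits <- chartr("ACGT", "0123", x)
  hi <- strtoi(substr(digits, 1L, 8L), base = 4L)
  lo <- strtoi(substr(digits, 9L, 16L), base = 4L)
  hi * 65536 + lo
}

# Generate n random DNA sequences with the given lengths (vectorised).
random_dna <- function(n, lengths) {
  lengths <- rep_len(lengths, n)
  if (n == 0L) return(character(0))
  total <- sum(lengths)
  big <- paste(sample(BASES, total, replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  substring(big, starts, ends)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
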