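# Duplication-profile estimation. Each read is reduced to a 16 bp
# fingerprint sampled from fixed offsets; fingerprints are streamed into an
# adaptive hash-threshold sketch: at depth d, a fingerprint is tracked iff
# hash(fingerprint) mod 2^d == 0. When the tracked set outgrows its
# capacity, d increments and entries failing the tighter criterion are
# evicted (counts discarded). Scaling surviving counts by 2^d yields an
# accurate distinct-count estimate in bounded memory. Because the criteria
# are nested (passing depth d implies passing every d' < d), batch-wise
# insertion is exactly equivalent to one-at-a-time insertion.

#' Compute the duplication fingerprint of reads
#'
#' Sixteen bases per read: 8 from a front window and 8 from a back window,
#' both offset `min(64, L - 16)` bases inward when the read is long enough
#' (skipping likely adapter/barcode sequence at read starts); shorter reads
#' use the whole read left-padded with `A`. `N` inside a window maps to `A`
#' deterministically, so identical reads always produce identical
#' fingerprints. Empty reads yield the distinguished empty fingerprint
#' `""`, counted separately by the sketch.
#'
#' @param sequence character vector of read sequences (or a [seq_record]).
#' @param cfg a [qc_config()].
#' @return character vector of 16-base fingerprints (`""` for empty reads).
#' @export
fingerprint <- function(sequence, cfg = qc_config()) {
  if (inherits(sequence, "seq_record")) sequence <- sequence$sequence
  flen <- cfg$fingerprint_len
  half <- flen %/% 2L
  L <- nchar(sequence)
  out <- character(length(sequence))
  long <- L >= flen
  if (any(long)) {
    Ll <- L[long]
    off <- pmin(64L, Ll - flen)
    front <- substr(sequence[long], off + 1L, off + half)
    back <- substr(sequence[long], Ll - off - half + 1L, Ll - off)
    out[long] <- paste0(front, back)
  }
  short <- !long & L > 0L
  if (any(short))
    out[short] <- paste0(strrep("A", flen - L[short]), sequence[short])
  chartr("N", "A", out)
}

#' Create an empty duplication sketch
#'
#' @param capacity maximum number of tracked fingerprints before the
#'   sampling depth increases.
#' @return a `dup_sketch` accumulator (environment).
#' @export
dup_sketch <- function(capacity = 100000L) {
  s <- new.env(parent = emptyenv())
  s$tracked <- numeric(0)   # named by fingerprint string
  s$d <- 0L
  s$capacity <- as.integer(capacity)
  s$total_reads <- 0
  s$empty_reads <- 0
  class(s) <- "dup_sketch"
  s
}

fingerprint_hash <- function(fps) mix32(pack16(fps))

# does a fingerprint pass the depth-d criterion?
passes_depth <- function(fps, d) {
  if (d == 0L) rep(TRUE, length(fps)) else fingerprint_hash(fps) %% 2^d == 0
}

#' Insert fingerprints into a duplication sketch
#'
#' Accepts a vector of fingerprints (batch insertion is exactly equivalent
#' to sequential insertion because the depth criteria are nested). Empty
#' fingerprints are counted separately and never tracked.
#'
#' @param sketch a [dup_sketch()].
#' @param fps character vector of fingerprints from [fingerprint()].
#' @return the updated sketch, invisibly.
#' @export
sketch_insert <- function(sketch, fps) {
  if (length(fps) == 0L) return(invisible(sketch))
  empty <- !nzchar(fps)
  sketch$empty_reads <- sketch$empty_reads + sum(empty)
  fps <- fps[!empty]
  sketch$total_reads <- sketch$total_reads + length(fps)
  if (length(fps) == 0L) return(invisible(sketch))
  fps <- fps[passes_depth(fps, sketch$d)]
  if (length(fps)) {
    tab <- table(fps)
    m <- match(names(tab), names(sketch$tracked))
    hit <- !is.na(m)
    if (any(hit))
      sketch$tracked[m[hit]] <- sketch$tracked[m[hit]] + as.numeric(tab[hit])
    if (any(!hit)) {
      add <- as.numeric(tab[!hit])
      names(add) <- names(tab)[!hit]
      sketch$tracked <- c(sketch$tracked, add)
    }
  }
  while (length(sketch$tracked) > sketch$capacity) {
    sketch$d <- sketch$d + 1L
    keep <- passes_depth(names(sketch$tracked), sketch$d)
    sketch$tracked <- sketch$tracked[keep]
  }
  invisible(sketch)
}

#' Estimate the duplication profile from a sketch
#'
#' The estimated number of distinct sequences is the number of tracked
#' fingerprints scaled by `2^d`; the estimated fraction of reads remaining
#' after deduplication divides that by the total reads inserted. The
#' multiplicity histogram scales the count of tracked fingerprints seen
#' `m` times (m = 1..15, then `>= 16`) by the same factor; after eviction
#' it is approximate, which the report labels.
#'
#' @param sketch a [dup_sketch()] with at least one inserted read.
#' @return list with `dedup_fraction`, `estimated_distinct`, `total_reads`,
#'   `empty_reads`, `depth`, `exact` (TRUE when no eviction ever
#'   happened), and `multiplicity` (data frame `m`/`estimated_distinct`).
#' @export
estimate_duplication <- function(sketch) {
  if (sketch$total_reads == 0) stop("no reads inserted into the sketch")
  scale <- 2^sketch$d
  est_distinct <- length(sketch$tracked) * scale
  mult <- pmin(sketch$tracked, 16)
  counts <- tabulate(mult, nbins = 16L) * scale
  list(dedup_fraction = est_distinct / sketch$total_reads,
       estimated_distinct = est_distinct,
       total_reads = sketch$total_reads,
       empty_reads = sketch$empty_reads,
       depth = sketch$d,
       exact = sketch$d == 0L,
       multiplicity = data.frame(m = c(as.character(1:15), ">=16"),
                                 estimated_distinct = counts))
}
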