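# Paired-end overlap detection: reverse-complement r2, enumerate every
# ungapped alignment offset against r1, and accept the offset with the
# most matching bases among those with enough overlap and a tolerable
# mismatch fraction. The implied fragment length is the insert size; when
# the insert is shorter than a read, the bases past it are adapter.

#' Detect overlap between the mates of a read pair
#'
#' Reverse-complements `r2` and scans all ungapped offsets against `r1`.
#' An offset qualifies when the overlap spans at least `cfg$min_overlap`
#' bases with a mismatch fraction at most `cfg$max_overlap_error`; among
#' qualifying offsets the one with the most matching bases wins, ties going
#' to the smallest insert size. `N` never matches. When no offset
#' qualifies, all fields except `overlap_len = 0` are `NA` — absence is a
#' valid result, not an error.
#'
#' @param pair a `read_pair` from [pair_reads()], or a list with elements
#'   `r1`, `r2` (each a [seq_record]).
#' @param cfg a [qc_config()].
#' @return an `overlap_result`: list with `insert_size`,
#'   `adapter_start_r1`, `adapter_start_r2` (0-based positions, `NA` when
#'   no read-through adapter), `overlap_len`, `mismatches`.
#' @export
find_overlap <- function(pair, cfg = qc_config()) {
  s1 <- pair$r1$sequence
  s2 <- pair$r2$sequence
  if (nchar(s1) == 0L || nchar(s2) == 0L)
    stop("both mates must be non-empty")
  res <- .overlap_scan_cpp(s1, revcomp(s2), cfg$min_overlap,
                           cfg$max_overlap_error)
  overlap_result_from_scan(res, nchar(s1), nchar(s2))
}

overlap_result_from_scan <- function(res, len1, len2) {
  if (res[1L] == 0L)
    return(structure(list(insert_size = NA_integer_,
                          adapter_start_r1 = NA_integer_,
                          adapter_start_r2 = NA_integer_,
                          overlap_len = 0L, mismatches = 0L),
                     class = "overlap_result"))
  insert <- res[2L]
  structure(list(
    insert_size = insert,
    adapter_start_r1 = if (insert < len1) insert else NA_integer_,
    adapter_start_r2 = if (insert < len2) insert else NA_integer_,
    overlap_len = res[3L], mismatches = res[4L]),
    class = "overlap_result")
}

# chunk-wise overlap over two parallel chunks; returns list of overlap_result
find_overlaps_chunk <- function(chunk1, chunk2, cfg) {
  n <- chunk_size_of(chunk1)
  rc2 <- revcomp(chunk2$sequence)
  lapply(seq_len(n), function(i) {
    if (nchar(chunk1$sequence[i]) == 0L || nchar(chunk2$sequence[i]) == 0L)
      return(overlap_result_from_scan(c(0L, NA, 0L, 0L, 0L), 0L, 0L))
    res <- .overlap_scan_cpp(chunk1$sequence[i], rc2[i],
                             cfg$min_overlap, cfg$max_overlap_error)
    overlap_result_from_scan(res, nchar(chunk1$sequence[i]),
                             nchar(chunk2$sequence[i]))
  })
}

#' Histogram of insert sizes from overlap results
#'
#' Pairs with no detected overlap are counted in an `undetermined` bin;
#' the histogram total plus the undetermined count equals the number of
#' pairs (conservation).
#'
#' @param results list of `overlap_result` objects.
#' @return list with `histogram` (data frame insert_size/count),
#'   `undetermined`, `n_pairs`, and `fraction_with_adapter` (pairs whose
#'   detected insert is shorter than a read).
#' @export
insert_size_histogram <- function(results) {
  inserts <- vapply(results, `[[`, integer(1), "insert_size")
  with_adapter <- vapply(results, function(r)
    !is.na(r$adapter_start_r1) || !is.na(r$adapter_start_r2), logical(1))
  det <- inserts[!is.na(inserts)]
  hist <- if (length(det)) {
    tab <- table(det)
    data.frame(insert_size = as.integer(names(tab)),
               count = as.integer(tab), row.names = NULL)
  } else data.frame(insert_size = integer(0), count = integer(0))
  list(histogram = hist,
       undetermined = sum(is.na(inserts)),
       n_pairs = length(results),
       fraction_with_adapter = if (length(results))
         mean(with_adapter) else 0)
}

# ---- accumulator used by run_qc --------------------------------------------

new_overlap_stats <- function() {
  o <- new.env(parent = emptyenv())
  o$insert_hist <- integer(0)  # named by insert size
  o$undetermined <- 0L
  o$n_pairs <- 0L
  o$with_adapter <- 0L
  class(o) <- "overlap_stats"
  o
}

overlap_stats_update <- function(o, results) {
  o$n_pairs <- o$n_pairs + length(results)
  inserts <- vapply(results, `[[`, integer(1), "insert_size")
  o$undetermined <- o$undetermined + sum(is.na(inserts))
  o$with_adapter <- o$with_adapter + sum(vapply(results, function(r)
    !is.na(r$adapter_start_r1) || !is.na(r$adapter_start_r2), logical(1)))
  det <- inserts[!is.na(inserts)]
  if (length(det)) {
    tab <- table(det)
    for (nm in names(tab)) {
      cur <- o$insert_hist[nm]
      o$insert_hist[nm] <- (if (is.na(cur)) 0L else cur) + as.integer(tab[[nm]])
    }
  }
  invisible(o)
}

overlap_stats_table <- function(o) {
  list(histogram = if (length(o$insert_hist))
         data.frame(insert_size = as.integer(names(o$insert_hist)),
                    count = as.integer(o$insert_hist), row.names = NULL)
       else data.frame(insert_size = integer(0), count = integer(0)),
       undetermined = o$undetermined,
       n_pairs = o$n_pairs,
       fraction_with_adapter = if (o$n_pairs) o$with_adapter / o$n_pairs else 0)
}
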