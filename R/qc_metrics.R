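# Generic per-position and per-read statistics: base content, quality, GC,
# length; per-read mean quality both via the expected error rate (the
# statistically correct average) and via naive arithmetic Phred averaging
# (the comparison mode, which overestimates quality).

#' Convert a Phred score to an error probability
#'
#' @param q numeric vector of Phred scores, each `>= 0`.
#' @return `10^(-q/10)`.
#' @export
#' @examples
#' phred_to_error(c(0, 10, 20))  # 1, 0.1, 0.01
phred_to_error <- function(q) {
  if (any(q < 0)) stop("negative Phred score")
  10^(-q / 10)
}

#' Per-read mean quality via the expected error rate
#'
#' Converts each base quality to its error probability, averages the
#' probabilities, and converts back to the Phred scale:
#' `-10 * log10(mean(10^(-q/10)))`. This is the statistically meaningful
#' per-read quality; arithmetic averaging of Phred scores is always at
#' least as large (Jensen's inequality) and overestimates quality whenever
#' base qualities vary within the read.
#'
#' @param qualities integer/numeric vector of per-base Phred scores.
#' @return mean quality on the Phred scale (real-valued).
#' @export
#' @examples
#' read_mean_quality_expected_error(c(10, 20))  # ~12.6, not 15
read_mean_quality_expected_error <- function(qualities) {
  if (length(qualities) == 0L) stop("empty quality vector")
  -10 * log10(mean(phred_to_error(qualities)))
}

#' Per-read mean quality by arithmetic Phred averaging
#'
#' The naive mode used by several older QC tools, provided for comparison:
#' it systematically overestimates read quality relative to
#' [read_mean_quality_expected_error()].
#'
#' @inheritParams read_mean_quality_expected_error
#' @return arithmetic mean of the Phred scores.
#' @export
read_mean_quality_arithmetic <- function(qualities) {
  if (length(qualities) == 0L) stop("empty quality vector")
  mean(qualities)
}

#' Per-read GC percentage
#'
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from both
#' numerator and denominator. All-N or empty reads are undefined (`NA`),
#' reported downstream in a distinguished bin.
#'
#' @param sequence character vector of base strings.
#' @return numeric vector of GC percentages (`NA` where undefined).
#' @export
gc_percent <- function(sequence) {
  gc <- nchar(gsub("[^GC]", "", sequence))
  acgt <- nchar(gsub("N", "", sequence, fixed = TRUE))
  ifelse(acgt > 0L, 100 * gc / acgt, NA_real_)
}

# ---- position binning -------------------------------------------------------
# Exact per-base statistics up to position 500; beyond that, geometrically
# growing bins (width x1.1 per bin, rounded, minimum 1) bound memory on
# ultra-long reads.

EXACT_POSITIONS <- 500L

# start position (1-based) of each bin; enough bins to cover max_pos
position_bin_starts <- function(max_pos) {
  starts <- seq_len(EXACT_POSITIONS)
  if (max_pos > EXACT_POSITIONS) {
    pos <- EXACT_POSITIONS + 1L
    w <- 1
    while (pos <= max_pos) {
      starts <- c(starts, pos)
      w <- w * 1.1
      pos <- pos + max(1L, as.integer(round(w)))
    }
  }
  starts
}

# map 1-based positions to bin indices given bin starts
position_to_bin <- function(pos, starts) findInterval(pos, starts)

#' Create an empty per-position profile
#'
#' Accumulates per-position base counts (A, C, G, T, N), Phred sums and
#' error-probability sums. Positions above 500 are aggregated into
#' geometrically growing bins.
#'
#' @return a `position_profile` accumulator (environment).
#' @export
new_position_profile <- function() {
  p <- new.env(parent = emptyenv())
  p$starts <- position_bin_starts(EXACT_POSITIONS)
  nb <- length(p$starts)
  p$counts <- matrix(0, nrow = nb, ncol = 5L,
                     dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  p$qual_sum <- numeric(nb)
  p$err_sum <- numeric(nb)
  p$max_len <- 0L
  class(p) <- "position_profile"
  p
}

profile_grow <- function(p, max_len) {
  if (max_len <= max(p$starts)) return(invisible(p))
  starts <- position_bin_starts(max_len)
  add <- length(starts) - length(p$starts)
  if (add > 0L) {
    p$starts <- starts
    p$counts <- rbind(p$counts, matrix(0, nrow = add, ncol = 5L))
    p$qual_sum <- c(p$qual_sum, numeric(add))
    p$err_sum <- c(p$err_sum, numeric(add))
  }
  invisible(p)
}

# vectorised chunk update: flattens all reads of the chunk into one
# position/base/quality stream and tabulates once
profile_update <- function(p, chunk) {
  n <- chunk_size_of(chunk)
  if (n == 0L) return(invisible(p))
  lens <- nchar(chunk$sequence)
  p$max_len <- max(p$max_len, lens, 0L)
  profile_grow(p, p$max_len)
  keep <- lens > 0L
  if (!any(keep)) return(invisible(p))
  codes <- base_codes(utf8ToInt(paste(chunk$sequence[keep], collapse = "")))
  q <- utf8ToInt(paste(chunk$quality[keep], collapse = "")) - 33L
  pos <- sequence(lens[keep])
  bin <- position_to_bin(pos, p$starts)
  nb <- length(p$starts)
  idx <- (codes - 1L) * nb + bin
  p$counts[] <- p$counts + tabulate(idx, nbins = 5L * nb)
  qs <- rowsum(as.numeric(q), bin)
  es <- rowsum(phred_to_error(q), bin)
  at <- as.integer(rownames(qs))
  p$qual_sum[at] <- p$qual_sum[at] + qs[, 1L]
  p$err_sum[at] <- p$err_sum[at] + es[, 1L]
  invisible(p)
}

#' Summarise a position profile as a data frame
#'
#' @param p a `position_profile`.
#' @return data frame with one row per position bin: bin start/end, base
#'   fractions, bases observed, mean Phred, and the Phred of the mean error
#'   probability (the expected-error version shown by default in reports).
#' @export
profile_table <- function(p) {
  used <- which(p$starts <= p$max_len)
  if (length(used) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      A = numeric(0), C = numeric(0), G = numeric(0),
                      T = numeric(0), N = numeric(0), observed = numeric(0),
                      mean_phred = numeric(0), phred_of_mean_error = numeric(0)))
  starts <- p$starts[used]
  ends <- c(p$starts[-1L], Inf)[used] - 1L
  ends <- pmin(ends, p$max_len)
  counts <- p$counts[used, , drop = FALSE]
  obs <- rowSums(counts)
  frac <- counts / ifelse(obs > 0, obs, 1)
  data.frame(start = starts, end = as.integer(ends),
             A = frac[, "A"], C = frac[, "C"], G = frac[, "G"],
             T = frac[, "T"], N = frac[, "N"], observed = obs,
             mean_phred = ifelse(obs > 0, p$qual_sum[used] / obs, NA_real_),
             phred_of_mean_error =
               ifelse(obs > 0, -10 * log10(p$err_sum[used] / obs), NA_real_),
             row.names = NULL)
}

# ---- per-read summaries -----------------------------------------------------

#' Create empty per-read summary accumulators
#'
#' Holds the read-length histogram, the per-read GC histogram (integer
#' percent bins 0-100 plus an "undefined" bin for all-N/empty reads), and
#' the per-read mean-quality histograms in both averaging modes (1 Phred
#' unit bins, 0-93, binned at the floor of the real-valued mean).
#'
#' @return a `read_summaries` accumulator (environment).
#' @export
new_read_summaries <- function() {
  s <- new.env(parent = emptyenv())
  s$n_reads <- 0L
  s$total_bases <- 0
  s$length_hist <- integer(0)      # named by length
  s$gc_hist <- integer(102L)       # bins 0..100 plus undefined
  s$q_hist_ee <- integer(94L)      # floor(meanQ) 0..93
  s$q_hist_arith <- integer(94L)
  class(s) <- "read_summaries"
  s
}

# per-read mean qualities for a chunk, both modes (vectorised)
chunk_mean_qualities <- function(chunk) {
  lens <- nchar(chunk$quality)
  q <- utf8ToInt(paste(chunk$quality, collapse = "")) - 33L
  grp <- rep.int(seq_along(lens), lens)
  qsum <- esum <- numeric(length(lens))
  if (length(q)) {
    sums <- rowsum(cbind(as.numeric(q), phred_to_error(q)), grp)
    at <- as.integer(rownames(sums))
    qsum[at] <- sums[, 1L]
    esum[at] <- sums[, 2L]
  }
  arith <- ifelse(lens > 0L, qsum / lens, NA_real_)
  ee <- ifelse(lens > 0L, -10 * log10(esum / lens), NA_real_)
  list(arithmetic = arith, expected_error = ee)
}

summaries_update <- function(s, chunk) {
  n <- chunk_size_of(chunk)
  if (n == 0L) return(invisible(s))
  lens <- nchar(chunk$sequence)
  s$n_reads <- s$n_reads + n
  s$total_bases <- s$total_bases + sum(lens)
  lh <- table(lens)
  for (nm in names(lh)) {
    cur <- s$length_hist[nm]
    s$length_hist[nm] <- (if (is.na(cur)) 0L else cur) + as.integer(lh[[nm]])
  }
  gc <- gc_percent(chunk$sequence)
  gcbin <- ifelse(is.na(gc), 102L, pmin(100L, floor(gc)) + 1L)
  s$gc_hist <- s$gc_hist + tabulate(gcbin, nbins = 102L)
  mq <- chunk_mean_qualities(chunk)
  qb <- function(x) pmin(93L, pmax(0L, floor(x)))
  nz <- lens > 0L
  s$q_hist_ee <- s$q_hist_ee +
    tabulate(qb(mq$expected_error[nz]) + 1L, nbins = 94L)
  s$q_hist_arith <- s$q_hist_arith +
    tabulate(qb(mq$arithmetic[nz]) + 1L, nbins = 94L)
  # zero-length reads have no defined mean quality; keep conservation by
  # counting them in the Q0 bin of both histograms
  nzero <- sum(!nz)
  if (nzero) {
    s$q_hist_ee[1L] <- s$q_hist_ee[1L] + nzero
    s$q_hist_arith[1L] <- s$q_hist_arith[1L] + nzero
  }
  invisible(s)
}

#' Accumulate one read into the generic statistics
#'
#' Single-record convenience wrapper over the chunk-wise accumulators used
#' by [run_qc()]: updates the per-position profile and the per-read
#' summaries exactly once for `record`.
#'
#' @param record a [seq_record].
#' @param profile a `position_profile` from [new_position_profile()].
#' @param summaries a `read_summaries` from [new_read_summaries()].
#' @return invisibly, a list with the updated accumulators.
#' @export
accumulate <- function(record, profile, summaries) {
  chunk <- records_to_chunk(list(record))
  profile_update(profile, chunk)
  summaries_update(summaries, chunk)
  invisible(list(profile = profile, summaries = summaries))
}

summaries_table <- function(s) {
  list(
    n_reads = s$n_reads,
    total_bases = s$total_bases,
    length_histogram = if (length(s$length_hist))
      data.frame(length = as.integer(names(s$length_hist)),
                 count = as.integer(s$length_hist), row.names = NULL)
    else data.frame(length = integer(0), count = integer(0)),
    gc_histogram = data.frame(gc_percent = c(0:100, NA),
                              count = as.integer(s$gc_hist)),
    mean_quality_expected_error = data.frame(q = 0:93,
                                             count = as.integer(s$q_hist_ee)),
    mean_quality_arithmetic = data.frame(q = 0:93,
                                         count = as.integer(s$q_hist_arith)))
}
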