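# Single-end adapter detection: every read is scanned for a set of short
# fixed-length probes in one pass. The matcher packs each probe into a
# 2-bit code and slides a rolling code over the read (a fixed-length
# dictionary automaton); output is identical to naive substring scanning.
# Probes contain no N, and any window containing N has no code, so N
# matches nothing by construction.

#' Load the bundled adapter probe set
#'
#' Probes are 12 bp prefixes of common Illumina (TruSeq, Nextera) and ONT
#' (ligation kit, rapid kit) adapter sequences, each also present as a
#' separately labelled reverse-complement entry so strandedness is
#' explicit. `"auto"` returns the union of both platforms.
#'
#' @param platform_hint one of `"illumina"`, `"ont"`, `"auto"`.
#' @param file optional path to a custom tab-separated probe file with
#'   columns `label`, `sequence` (and optionally `platform`).
#' @return data frame with columns `label`, `sequence`.
#' @export
default_probe_set <- function(platform_hint = c("auto", "illumina", "ont"),
                              file = NULL) {
  if (!is.character(platform_hint) ||
      !platform_hint[1L] %in% c("auto", "illumina", "ont"))
    stop("unknown platform hint: ", platform_hint[1L])
  platform_hint <- platform_hint[1L]
  file <- file %||% system.file("extdata", "adapter_probes.tsv",
                                package = "seqscope", mustWork = TRUE)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("label", "sequence") %in% names(tab)))
    stop("probe file must have columns 'label' and 'sequence'")
  if (platform_hint != "auto" && "platform" %in% names(tab))
    tab <- tab[tab$platform == platform_hint, , drop = FALSE]
  data.frame(label = tab$label, sequence = toupper(tab$sequence),
             row.names = NULL)
}

#' Build a multi-pattern probe matcher
#'
#' @param probes data frame with columns `label` and `sequence`; 1-64
#'   probes, each exactly `probe_len` bases of A/C/G/T (no N).
#' @param probe_len required probe length in bases.
#' @return a `probe_matcher` object usable with [scan_read()].
#' @export
build_matcher <- function(probes, probe_len = 12L) {
  if (nrow(probes) < 1L || nrow(probes) > 64L)
    stop("need between 1 and 64 probes")
  seqs <- toupper(probes$sequence)
  if (any(nchar(seqs) != probe_len))
    stop("all probes must be exactly ", probe_len, " bases")
  if (any(grepl("[^ACGT]", seqs)))
    stop("probes must contain only A/C/G/T (no N)")
  codes <- strtoi(chartr("ACGT", "0123", seqs), base = 4L)
  if (anyDuplicated(codes)) stop("duplicate probe sequences")
  structure(list(labels = probes$label, sequences = seqs,
                 codes = codes, probe_len = as.integer(probe_len),
                 weights = 4^(0:(probe_len - 1L))),
            class = "probe_matcher")
}

# Scan a chunk of reads for all probes at once. Reads are concatenated with
# an N spacer; a rolling 2-bit code is computed with a one-sided linear
# filter and matched against the probe dictionary. Windows containing N (or
# the spacer) have no code. Returns the leftmost hit per (read, probe):
# data.frame(read, probe, pos) with 0-based probe start positions.
scan_chunk_hits <- function(matcher, sequences) {
  plen <- matcher$probe_len
  lens <- nchar(sequences)
  n <- length(sequences)
  if (n == 0L || !any(lens >= plen))
    return(data.frame(read = integer(0), probe = integer(0), pos = integer(0)))
  big <- paste(sequences, collapse = "N")
  d <- c(0L, 1L, 2L, 3L, NA_integer_)[base_codes(utf8ToInt(big))]
  y <- stats::filter(d, matcher$weights, sides = 1)
  m <- match(as.numeric(y), matcher$codes)
  hit <- which(!is.na(m))
  if (length(hit) == 0L)
    return(data.frame(read = integer(0), probe = integer(0), pos = integer(0)))
  offs <- cumsum(c(1L, lens + 1L))[seq_len(n)]  # global start of each read
  wstart <- hit - plen + 1L
  read <- findInterval(wstart, offs)
  pos0 <- wstart - offs[read]
  probe <- m[hit]
  o <- order(read, probe, pos0)
  keep <- !duplicated(cbind(read[o], probe[o]))
  data.frame(read = read[o][keep], probe = probe[o][keep],
             pos = pos0[o][keep])
}

#' Scan one read for all probes
#'
#' Exact-match semantics; for each probe only the leftmost occurrence is
#' reported. Positions are 0-based offsets of the probe start within the
#' read.
#'
#' @param matcher a `probe_matcher` from [build_matcher()].
#' @param record a [seq_record] (or a plain sequence string).
#' @return data frame with columns `label`, `position`.
#' @export
scan_read <- function(matcher, record) {
  seqs <- if (inherits(record, "seq_record")) record$sequence else record
  hits <- scan_chunk_hits(matcher, seqs)
  data.frame(label = matcher$labels[hits$probe], position = hits$pos,
             row.names = NULL)
}

# ---- accumulator ------------------------------------------------------------

new_probe_hits <- function(matcher) {
  h <- new.env(parent = emptyenv())
  h$labels <- matcher$labels
  h$reads_with_hit <- integer(length(matcher$labels))
  h$starts <- position_bin_starts(EXACT_POSITIONS)
  h$pos_hist <- matrix(0L, nrow = length(h$starts),
                       ncol = length(matcher$labels))
  h$total_reads <- 0L
  class(h) <- "probe_hits"
  h
}

probe_hits_update <- function(h, matcher, chunk) {
  n <- chunk_size_of(chunk)
  if (n == 0L) return(invisible(h))
  h$total_reads <- h$total_reads + n
  hits <- scan_chunk_hits(matcher, chunk$sequence)
  if (nrow(hits) == 0L) return(invisible(h))
  maxpos <- max(hits$pos) + 1L
  if (maxpos > max(h$starts)) {
    starts <- position_bin_starts(maxpos)
    add <- length(starts) - length(h$starts)
    h$starts <- starts
    h$pos_hist <- rbind(h$pos_hist,
                        matrix(0L, nrow = add, ncol = ncol(h$pos_hist)))
  }
  h$reads_with_hit <- h$reads_with_hit +
    tabulate(hits$probe, nbins = length(h$labels))
  bin <- position_to_bin(hits$pos + 1L, h$starts)
  nb <- length(h$starts)
  h$pos_hist[] <- h$pos_hist +
    tabulate((hits$probe - 1L) * nb + bin, nbins = nb * ncol(h$pos_hist))
  invisible(h)
}

probe_hits_table <- function(h) {
  data.frame(label = h$labels,
             reads_with_hit = h$reads_with_hit,
             fraction = if (h$total_reads > 0)
               h$reads_with_hit / h$total_reads else 0,
             row.names = NULL)
}
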