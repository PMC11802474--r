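#' QC configuration
#'
#' All tunable constants of the engine in one place. The defaults are the
#' engine's operating points: 12 bp adapter probes, 16 bp duplication
#' fingerprints, 1-in-8 read sampling into fragments, a 5-million-fragment
#' store, and a 0.1% overrepresentation threshold; the remaining values
#' (fragment length, k-mer size, sketch capacity, overlap and identity
#' thresholds) are documented engine defaults.
#'
#' @param probe_len adapter probe length in bases.
#' @param fingerprint_len duplication fingerprint length in bases.
#' @param sample_rate_denom fragment sampling rate denominator: read `i`
#'   (0-based) is sampled into fragments iff `i %% sample_rate_denom == 0`.
#' @param fragment_store_cap maximum number of distinct fragments stored.
#' @param overrep_threshold occurrence fraction (of sampled reads) above
#'   which a fragment is flagged; strict inequality.
#' @param fragment_len fragment window length in bases (odd, so no fragment
#'   is its own reverse complement).
#' @param kmer_size canonical k-mer size for the contaminant index.
#' @param sketch_capacity maximum tracked fingerprints in the duplication
#'   sketch before the sampling depth increases.
#' @param min_overlap minimum paired-end overlap length in bases.
#' @param max_overlap_error maximum mismatch fraction tolerated in an
#'   overlap.
#' @param min_identity minimum alignment identity for a contaminant hit.
#' @param sw_match,sw_mismatch,sw_gap_open,sw_gap_extend Smith-Waterman
#'   scoring; a gap of length k costs `gap_open + k * gap_extend`.
#' @param seed integer seed echoed into the report; the engine itself is
#'   deterministic.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(probe_len = 12L,
                      fingerprint_len = 16L,
                      sample_rate_denom = 8L,
                      fragment_store_cap = 5000000L,
                      overrep_threshold = 0.001,
                      fragment_len = 21L,
                      kmer_size = 16L,
                      sketch_capacity = 100000L,
                      min_overlap = 10L,
                      max_overlap_error = 0.10,
                      min_identity = 0.80,
                      sw_match = 2L, sw_mismatch = -3L,
                      sw_gap_open = 5L, sw_gap_extend = 2L,
                      seed = 1L) {
  cfg <- list(probe_len = as.integer(probe_len),
              fingerprint_len = as.integer(fingerprint_len),
              sample_rate_denom = as.integer(sample_rate_denom),
              fragment_store_cap = as.integer(fragment_store_cap),
              overrep_threshold = overrep_threshold,
              fragment_len = as.integer(fragment_len),
              kmer_size = as.integer(kmer_size),
              sketch_capacity = as.integer(sketch_capacity),
              min_overlap = as.integer(min_overlap),
              max_overlap_error = max_overlap_error,
              min_identity = min_identity,
              sw_match = as.integer(sw_match),
              sw_mismatch = as.integer(sw_mismatch),
              sw_gap_open = as.integer(sw_gap_open),
              sw_gap_extend = as.integer(sw_gap_extend),
              seed = as.integer(seed))
  lens <- c(cfg$probe_len, cfg$fingerprint_len, cfg$fragment_len,
            cfg$kmer_size, cfg$sketch_capacity, cfg$fragment_store_cap,
            cfg$min_overlap)
  if (any(lens <= 0L)) stop("all lengths and capacities must be > 0")
  if (cfg$sample_rate_denom < 1L) stop("sample_rate_denom must be >= 1")
  if (cfg$overrep_threshold <= 0 || cfg$overrep_threshold >= 1)
    stop("overrep_threshold must be in (0, 1)")
  structure(cfg, class = "qc_config")
}
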