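# Independent oracles and small fixture helpers used across the suite.

# Write a FASTQ file from parallel vectors; returns the path.
write_tmp_fastq <- function(names, seqs, quals, comments = NULL, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  header <- paste0("@", names,
                   if (!is.null(comments)) ifelse(nzchar(comments),
                                                  paste0(" ", comments), "")
                   else "")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(rbind(header, seqs, "+", quals), con)
  close(con)
  path
}

random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""),
    character(1))
}

# Naive leftmost substring search oracle for the probe matcher:
# independent route through regexpr(fixed = TRUE).
naive_first_hits <- function(probe_seqs, reads) {
  out <- lapply(probe_seqs, function(p) {
    m <- regexpr(p, reads, fixed = TRUE)
    ifelse(m > 0L, as.integer(m) - 1L, NA_integer_)  # 0-based, NA = no hit
  })
  do.call(cbind, out)
}

# matcher first hits in the same matrix layout (reads x probes, 0-based, NA)
matcher_first_hits <- function(matcher, reads) {
  hits <- seqscope:::scan_chunk_hits(matcher, reads)
  m <- matrix(NA_integer_, nrow = length(reads),
              ncol = length(matcher$labels))
  if (nrow(hits)) m[cbind(hits$read, hits$probe)] <- hits$pos
  m
}

# Exhaustive local-alignment score oracle: top-down enumeration over
# alignment extensions with explicit gap-state costs (memoised), written
# independently of the package's bottom-up Gotoh implementation.
# Gap of length k costs open + k * ext.
bf_local_score <- function(a, b, match = 2, mismatch = -3,
                           open = 5, ext = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    key <- paste0(i, ",", j, ",", last)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- 0  # stopping here is always allowed
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "d"))
    }
    if (j <= m) {
      cost <- if (last == "gb") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1L, "gb"))
    }
    if (i <= n) {
      cost <- if (last == "ga") ext else open + ext
      best <- max(best, -cost + rec(i + 1L, j, "ga"))
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, rec(i, j, "start"))
  best
}

# Biostrings local alignment score with the same scoring convention,
# as a second independent cross-check.
biostrings_local_score <- function(a, b, match = 2, mismatch = -3,
                                   open = 5, ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = open, gapExtension = ext)))
}

# strip volatile fields so two reports can be compared for determinism
report_fingerprint <- function(report) {
  report$metadata$timestamp <- NULL
  report$metadata$inputs <- NULL
  unclass(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
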