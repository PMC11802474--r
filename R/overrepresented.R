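# Overrepresented-fragment analysis. One in sample_rate_denom reads is cut
# into fixed-length fragments; the first fragment_store_cap distinct
# fragments are stored and counted across the rest of the stream. Fragments
# occurring in more than overrep_threshold of the sampled reads are flagged
# and identified against a contaminant database (UniVec-style FASTA) by
# canonical k-mer candidate gathering plus Smith-Waterman alignment.

#' Cut a sampled read into fragments
#'
#' Read `read_index` (0-based) is sampled iff
#' `read_index %% cfg$sample_rate_denom == 0`. Fragments are
#' non-overlapping `cfg$fragment_len`-base windows across the read; long
#' reads contribute at most 8 evenly spaced windows so ultra-long reads
#' cannot dominate the table. Fragments containing `N` are skipped.
#'
#' @param sequence read sequence (or a [seq_record]).
#' @param read_index 0-based index of the read in the stream.
#' @param cfg a [qc_config()].
#' @return character vector of fragments (possibly empty).
#' @export
sample_fragments <- function(sequence, read_index, cfg = qc_config()) {
  if (inherits(sequence, "seq_record")) sequence <- sequence$sequence
  if (read_index %% cfg$sample_rate_denom != 0L) return(character(0))
  read_to_fragments(sequence, cfg$fragment_len)
}

read_to_fragments <- function(sequence, flen, max_fragments = 8L) {
  L <- nchar(sequence)
  nwin <- L %/% flen
  if (nwin == 0L) return(character(0))
  wins <- seq_len(nwin)
  if (nwin > max_fragments)
    wins <- unique(round(seq(1L, nwin, length.out = max_fragments)))
  starts <- (wins - 1L) * flen + 1L
  frags <- substring(sequence, starts, starts + flen - 1L)
  frags[!grepl("N", frags, fixed = TRUE)]
}

#' Create an empty fragment table
#'
#' @param distinct_cap maximum number of distinct fragments stored.
#' @return a `fragment_table` accumulator (environment).
#' @export
fragment_table <- function(distinct_cap = 5000000L) {
  t <- new.env(parent = emptyenv())
  t$counts <- new.env(parent = emptyenv(), size = 4096L)
  t$n_distinct <- 0L
  t$distinct_cap <- as.integer(distinct_cap)
  t$sampled_reads <- 0
  t$saturated <- FALSE
  class(t) <- "fragment_table"
  t
}

#' Count fragments into the table
#'
#' New distinct fragments are accepted only while the table is below its
#' cap; existing fragments keep counting after saturation.
#'
#' @param table a [fragment_table()].
#' @param fragments character vector of fragments from one sampled read.
#' @param n_sampled_reads how many sampled reads these fragments came from
#'   (1 for a single read).
#' @return the updated table, invisibly.
#' @export
table_update <- function(table, fragments, n_sampled_reads = 1L) {
  table$sampled_reads <- table$sampled_reads + n_sampled_reads
  for (f in fragments) {
    cur <- table$counts[[f]]
    if (!is.null(cur)) {
      table$counts[[f]] <- cur + 1L
    } else if (table$n_distinct < table$distinct_cap) {
      table$counts[[f]] <- 1L
      table$n_distinct <- table$n_distinct + 1L
    } else {
      table$saturated <- TRUE
    }
  }
  invisible(table)
}

#' Flag overrepresented fragments
#'
#' A fragment is flagged when its count exceeds
#' `cfg$overrep_threshold` of the sampled reads (strict inequality).
#'
#' @param table a [fragment_table()] with `sampled_reads > 0`.
#' @param cfg a [qc_config()].
#' @return data frame with columns `fragment`, `count`, `fraction`, sorted
#'   by count descending, ties lexicographic.
#' @export
flag_overrepresented <- function(table, cfg = qc_config()) {
  if (table$sampled_reads == 0) stop("no sampled reads in the table")
  frags <- ls(table$counts, sorted = FALSE)
  if (length(frags) == 0L)
    return(data.frame(fragment = character(0), count = integer(0),
                      fraction = numeric(0)))
  counts <- vapply(frags, function(f) table$counts[[f]], numeric(1),
                   USE.NAMES = FALSE)
  frac <- counts / table$sampled_reads
  keep <- frac > cfg$overrep_threshold
  o <- order(-counts[keep], frags[keep], method = "radix")
  data.frame(fragment = frags[keep][o], count = as.integer(counts[keep][o]),
             fraction = frac[keep][o], row.names = NULL)
}

# ---- contaminant database ---------------------------------------------------

#' Build a canonical k-mer index over a contaminant FASTA
#'
#' Every A/C/G/T-only window of length `cfg$kmer_size` in every entry is
#' indexed under its canonical form (lexicographic minimum of the k-mer and
#' its reverse complement), so lookups are strand-insensitive. Non-ACGT
#' IUPAC characters are treated as N and the windows containing them are
#' skipped.
#'
#' @param fasta path to a FASTA file (UniVec-compatible headers).
#' @param cfg a [qc_config()].
#' @return a `contaminant_db`: list with `id`, `description`, `sequence`
#'   vectors and the k-mer index.
#' @export
build_contaminant_index <- function(fasta, cfg = qc_config()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("empty contaminant FASTA: ", fasta)
  headers <- names(seqs)
  sp <- regexpr("[ \t]", headers)
  id <- ifelse(sp > 0L, substr(headers, 1L, sp - 1L), headers)
  description <- ifelse(sp > 0L, substring(headers, sp + 1L), "")
  sequence <- unname(normalize_bases(as.character(seqs)))
  k <- cfg$kmer_size
  index <- new.env(parent = emptyenv(), size = 4096L)
  for (e in seq_along(sequence)) {
    s <- sequence[e]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    if (!any(ok)) next
    canon <- canonical_kmer(kmers[ok])
    pos <- starts[ok] - 1L
    for (i in seq_along(canon)) {
      key <- canon[i]
      index[[key]] <- rbind(index[[key]], c(e, pos[i]))
    }
  }
  structure(list(id = id, description = description, sequence = sequence,
                 kmer_size = k, index = index),
            class = "contaminant_db")
}

#' Identify a fragment against the contaminant database
#'
#' Candidate entries are those sharing at least one canonical k-mer with
#' the fragment (both orientations covered by canonicalisation); each
#' candidate is aligned with Smith-Waterman against the fragment in forward
#' and reverse-complement orientation, and the best hit is returned when
#' its identity reaches `cfg$min_identity`, else `NULL`.
#'
#' @param fragment base string of length `>= cfg$kmer_size`.
#' @param db a `contaminant_db` from [build_contaminant_index()].
#' @param cfg a [qc_config()].
#' @return an `alignment_result` (see [smith_waterman()]) with an added
#'   `target_id` field, or `NULL` when nothing qualifies.
#' @export
identify_fragment <- function(fragment, db, cfg = qc_config()) {
  k <- db$kmer_size
  if (nchar(fragment) < k)
    stop("fragment shorter than the k-mer size (", k, ")")
  starts <- seq_len(nchar(fragment) - k + 1L)
  kmers <- substring(fragment, starts, starts + k - 1L)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0L) return(NULL)
  canon <- unique(canonical_kmer(kmers))
  cand <- unique(unlist(lapply(canon, function(km) {
    hits <- db$index[[km]]
    if (is.null(hits)) integer(0) else hits[, 1L]
  })))
  if (length(cand) == 0L) return(NULL)
  cand <- sort(cand)
  frag_rc <- revcomp(fragment)
  best <- NULL
  for (e in cand) {
    for (q in c(fragment, frag_rc)) {
      al <- smith_waterman(q, db$sequence[e], cfg = cfg)
      if (is.null(best) || al$score > best$score) {
        best <- al
        best$target_id <- db$id[e]
      }
    }
  }
  if (!is.null(best) && !is.na(best$identity) &&
      best$identity >= cfg$min_identity) best else NULL
}

#' Smith-Waterman local alignment
#'
#' Standard local alignment with affine gap penalties: a gap of length `k`
#' costs `gap_open + k * gap_extend`. The score is the DP maximum; identity
#' is matches over alignment columns along the traceback of the best cell.
#' Tie-breaking is deterministic: first maximal cell in row-major order,
#' traceback preferring diagonal over up over left. `N` matches nothing.
#'
#' @param query,target non-empty base strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters (defaults
#'   from `cfg`).
#' @param cfg a [qc_config()] supplying the default scoring.
#' @return an `alignment_result`: list with `score`, `identity`,
#'   `matches`, `columns`, `query_span` and `target_span` (0-based
#'   half-open), all spans `NA` when the best score is 0 (no alignment).
#' @export
smith_waterman <- function(query, target,
                           match = cfg$sw_match, mismatch = cfg$sw_mismatch,
                           gap_open = cfg$sw_gap_open,
                           gap_extend = cfg$sw_gap_extend,
                           cfg = qc_config()) {
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("query and target must be non-empty")
  r <- .sw_align_cpp(query, target, match, mismatch, gap_open, gap_extend)
  structure(list(
    score = r$score,
    identity = if (r$columns > 0) r$matches / r$columns else NA_real_,
    matches = r$matches, columns = r$columns,
    query_span = c(r$query_start, r$query_end),
    target_span = c(r$target_start, r$target_end)),
    class = "alignment_result")
}

# fast chunk path used by run_qc: fragments for every sampled read of a chunk
chunk_fragments <- function(chunk, first_index, cfg) {
  n <- chunk_size_of(chunk)
  idx <- first_index + seq_len(n) - 1L
  sampled <- which(idx %% cfg$sample_rate_denom == 0L)
  frags <- lapply(sampled, function(i)
    read_to_fragments(chunk$sequence[i], cfg$fragment_len))
  list(n_sampled = length(sampled), fragments = unlist(frags, use.names = FALSE))
}

# identify every flagged fragment; returns the report table
overrep_report_table <- function(flagged, db, cfg) {
  if (nrow(flagged) == 0L || is.null(db)) {
    flagged$best_match_id <- character(nrow(flagged))
    flagged$identity <- numeric(nrow(flagged))
    return(flagged)
  }
  ids <- character(nrow(flagged))
  idents <- rep(NA_real_, nrow(flagged))
  for (i in seq_len(nrow(flagged))) {
    hit <- identify_fragment(flagged$fragment[i], db, cfg)
    if (!is.null(hit)) {
      ids[i] <- hit$target_id
      idents[i] <- hit$identity
    }
  }
  flagged$best_match_id <- ids
  flagged$identity <- idents
  flagged
}
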