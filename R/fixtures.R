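# Deterministic synthetic-read generator. Produces FASTQ (plain/gzip) or
# uBAM libraries with known ground truth — duplicate structure, adapter
# spike positions, insert sizes, contaminant content, ONT metadata — plus a
# per-read manifest, so every QC module is testable without downloads.
#
# The quality model is a two-state Markov chain over {high ~ Q36, low ~
# Q12} per base with persistent states, mimicking within-read quality
# structure; this makes expected-error and arithmetic Phred averaging
# diverge measurably, as they do on real data.

#' Specify a synthetic library
#'
#' @param n_reads number of reads (pairs, in paired mode).
#' @param read_len read length in bases (fixed).
#' @param length_dist `"fixed"`, or `"lognormal"` for ONT-style lengths
#'   (parameters `len_meanlog`, `len_sdlog`, truncated to `[30, 200000]`).
#' @param len_meanlog,len_sdlog log-normal length parameters.
#' @param paired generate read pairs from inserts.
#' @param insert_mean,insert_sd insert-size distribution (normal, rounded,
#'   truncated `>= 1`), paired mode only.
#' @param duplicate_fraction fraction of reads that are exact copies of
#'   other reads (before error injection); the manifest's exact
#'   deduplicated fraction is `1 - duplicate_fraction`.
#' @param adapter_seq adapter sequence for single-end spiking and paired
#'   read-through.
#' @param adapter_spike_fraction fraction of single-end reads carrying the
#'   adapter (placed fully inside the 3' half, position recorded).
#' @param contaminant_seq,contaminant_fraction contaminant fragment pasted
#'   over the read prefix in this fraction of reads.
#' @param error_rate per-base substitution rate applied last.
#' @param q_high,q_low,q_stay two-state Markov quality model: state
#'   qualities and per-base persistence probability.
#' @param name_style `"simple"` (`read_<i>`) or `"illumina"`
#'   (Casava-style `SIM:1:FC1:1:<tile>:<x>:<y>` names).
#' @param tiles tile ids used with `name_style = "illumina"`.
#' @param ont_meta emit `ch=`/`start_time=`/`duration=` comment tokens
#'   (channels uniform on 1..`n_channels`, translocation speed normal
#'   around `speed_mean` b/s with sd `speed_sd`).
#' @param n_channels,speed_mean,speed_sd ONT metadata distributions.
#' @param format `"fastq"`, `"fastq.gz"` or `"ubam"`.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return a `library_spec` object.
#' @export
library_spec <- function(n_reads = 1000L, read_len = 150L,
                         length_dist = c("fixed", "lognormal"),
                         len_meanlog = log(5000), len_sdlog = 0.7,
                         paired = FALSE,
                         insert_mean = 200, insert_sd = 30,
                         duplicate_fraction = 0,
                         adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                         adapter_spike_fraction = 0,
                         contaminant_seq = NULL, contaminant_fraction = 0,
                         error_rate = 0,
                         q_high = 36L, q_low = 12L, q_stay = 0.95,
                         name_style = c("simple", "illumina"),
                         tiles = c(1101L, 1102L, 2101L, 2102L),
                         ont_meta = FALSE, n_channels = 512L,
                         speed_mean = 400, speed_sd = 40,
                         format = c("fastq", "fastq.gz", "ubam"),
                         seed = 1L) {
  spec <- list(n_reads = as.integer(n_reads), read_len = as.integer(read_len),
               length_dist = match.arg(length_dist),
               len_meanlog = len_meanlog, len_sdlog = len_sdlog,
               paired = isTRUE(paired),
               insert_mean = insert_mean, insert_sd = insert_sd,
               duplicate_fraction = duplicate_fraction,
               adapter_seq = toupper(adapter_seq),
               adapter_spike_fraction = adapter_spike_fraction,
               contaminant_seq = if (is.null(contaminant_seq)) NULL
                                 else toupper(contaminant_seq),
               contaminant_fraction = contaminant_fraction,
               error_rate = error_rate,
               q_high = as.integer(q_high), q_low = as.integer(q_low),
               q_stay = q_stay,
               name_style = match.arg(name_style), tiles = as.integer(tiles),
               ont_meta = isTRUE(ont_meta), n_channels = as.integer(n_channels),
               speed_mean = speed_mean, speed_sd = speed_sd,
               format = match.arg(format), seed = as.integer(seed))
  fracs <- c(spec$duplicate_fraction, spec$adapter_spike_fraction,
             spec$contaminant_fraction, spec$error_rate)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must be in [0, 1]")
  if (spec$n_reads <= 0L) stop("n_reads must be > 0")
  if (spec$adapter_spike_fraction > 0 &&
      nchar(spec$adapter_seq) > spec$read_len)
    stop("adapter longer than the read")
  structure(spec, class = "library_spec")
}

# Markov two-state per-base qualities for reads with the given lengths;
# returns an integer vector over the flattened bases
markov_qualities <- function(lens, q_high, q_low, q_stay) {
  total <- sum(lens)
  if (total == 0L) return(integer(0))
  n <- length(lens)
  sw <- as.integer(runif(total) < (1 - q_stay))
  starts <- cumsum(c(1L, lens))[seq_len(n)]
  starts <- starts[lens > 0L]
  init <- as.integer(runif(length(starts)) < 0.5)
  sw[starts] <- 0L
  cs <- cumsum(sw)
  base_cs <- rep.int(cs[starts], lens[lens > 0L])
  base_init <- rep.int(init, lens[lens > 0L])
  state <- (base_init + (cs - base_cs)) %% 2L
  q <- ifelse(state == 1L, q_low, q_high) +
    sample(-2:2, total, replace = TRUE)
  pmax(2L, pmin(93L, as.integer(q)))
}

# substitute bases at rate e over a character vector of sequences
inject_errors <- function(seqs, e) {
  if (e <= 0) return(seqs)
  lens <- nchar(seqs)
  big <- utf8ToInt(paste(seqs, collapse = ""))
  idx <- which(runif(length(big)) < e)
  if (length(idx)) {
    codes <- base_codes(big[idx])          # 1..4 (N untouched)
    ok <- !is.na(codes) & codes <= 4L
    idx <- idx[ok]; codes <- codes[ok]
    shift <- sample(1:3, length(idx), replace = TRUE)
    big[idx] <- utf8ToInt(paste(BASES, collapse = ""))[
      ((codes - 1L + shift) %% 4L) + 1L]
  }
  ends <- cumsum(lens)
  substring(intToUtf8(big), ends - lens + 1L, ends)
}

quals_to_strings <- function(q, lens) {
  ends <- cumsum(lens)
  substring(intToUtf8(q + 33L), ends - lens + 1L, ends)
}

#' Generate a synthetic library with known ground truth
#'
#' Deterministic given the spec (same seed twice gives byte-identical
#' files). Duplicates are exact copies of other reads made before error
#' injection, so at zero error rate their fingerprints collide by
#' construction. In paired mode, whenever the insert is shorter than the
#' read length both mates read through into the adapter at position equal
#' to the insert size.
#'
#' @param spec a [library_spec()].
#' @param dir output directory (created if needed).
#' @param basename file name stem.
#' @return list with `files` (paths), `manifest` (per-read ground truth
#'   data frame) and `truth` (library-level totals).
#' @export
generate_library <- function(spec, dir = tempfile("seqscope_lib_"),
                             basename = "library") {
  stopifnot(inherits(spec, "library_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  n <- spec$n_reads
  n_dup <- round(n * spec$duplicate_fraction)
  n_orig <- n - n_dup

  if (spec$paired) {
    inserts <- pmax(1L, as.integer(round(rnorm(n_orig, spec$insert_mean,
                                               spec$insert_sd))))
    R <- spec$read_len
    frags <- random_dna(n_orig, inserts)
    fill_len1 <- pmax(0L, R - inserts - nchar(spec$adapter_seq))
    build_mate <- function(core) {
      tail_fill <- random_dna(n_orig, fill_len1)
      full <- paste0(substr(core, 1L, R),
                     ifelse(inserts < R, spec$adapter_seq, ""),
                     ifelse(inserts < R, tail_fill, ""))
      substr(full, 1L, R)
    }
    s1 <- build_mate(frags)
    s2 <- build_mate(revcomp(frags))
    orig <- list(s1 = s1, s2 = s2, inserts = inserts)
  } else {
    lens <- if (spec$length_dist == "fixed") rep(spec$read_len, n_orig)
            else pmin(200000L, pmax(30L, as.integer(round(
              rlnorm(n_orig, spec$len_meanlog, spec$len_sdlog)))))
    seqs <- random_dna(n_orig, lens)
    contam <- rep(FALSE, n_orig)
    if (!is.null(spec$contaminant_seq) && spec$contaminant_fraction > 0) {
      contam <- runif(n_orig) < spec$contaminant_fraction
      if (any(contam)) {
        cl <- pmin(nchar(spec$contaminant_seq), lens[contam])
        pre <- substr(spec$contaminant_seq, 1L, max(cl))
        seqs[contam] <- paste0(substr(rep(pre, sum(contam)), 1L, cl),
                               substring(seqs[contam], cl + 1L))
      }
    }
    adapter_start <- rep(NA_integer_, n_orig)
    if (spec$adapter_spike_fraction > 0) {
      alen <- nchar(spec$adapter_seq)
      spiked <- runif(n_orig) < spec$adapter_spike_fraction
      spiked <- spiked & lens >= alen
      if (any(spiked)) {
        lo <- pmax(1L, ceiling(lens[spiked] / 2))
        hi <- lens[spiked] - alen + 1L
        lo <- pmin(lo, hi)
        pos1 <- lo + floor(runif(sum(spiked)) * (hi - lo + 1L))
        seqs[spiked] <- paste0(substr(seqs[spiked], 1L, pos1 - 1L),
                               spec$adapter_seq,
                               substring(seqs[spiked], pos1 + alen))
        adapter_start[spiked] <- pos1 - 1L
      }
    }
    orig <- list(seqs = seqs, lens = lens, contam = contam,
                 adapter_start = adapter_start)
  }

  # duplicate structure: copies reference originals; distinct count is
  # exactly n_orig regardless of how sources are drawn
  src <- if (n_dup > 0L) {
    if (n_dup <= n_orig) sample.int(n_orig, n_dup)
    else sample.int(n_orig, n_dup, replace = TRUE)
  } else integer(0)
  group <- c(seq_len(n_orig), src)
  perm <- sample.int(n)
  group <- group[perm]
  is_dup <- c(rep(FALSE, n_orig), rep(TRUE, n_dup))[perm]

  make_meta <- function(lens) {
    ch <- sample.int(spec$n_channels, n, replace = TRUE)
    speed <- pmax(1, rnorm(n, spec$speed_mean, spec$speed_sd))
    duration <- round(lens / speed, 3)
    t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
    st <- t0 + round(runif(n, 0, 72000))
    list(ch = ch, du = duration,
         st = format(st, "%Y-%m-%dT%H:%M:%SZ"))
  }

  make_names <- function() {
    if (spec$name_style == "illumina") {
      tile <- sample(spec$tiles, n, replace = TRUE)
      x <- sample.int(25000L, n, replace = TRUE)
      y <- sample.int(25000L, n, replace = TRUE)
      list(names = paste0("SIM:1:FC1:1:", tile, ":", x, ":", y), tile = tile)
    } else list(names = paste0("read_", seq_len(n)), tile = rep(NA_integer_, n))
  }

  files <- character(0)
  nm <- make_names()

  if (spec$paired) {
    s1 <- inject_errors(orig$s1[group], spec$error_rate)
    s2 <- inject_errors(orig$s2[group], spec$error_rate)
    l1 <- nchar(s1); l2 <- nchar(s2)
    q1 <- quals_to_strings(markov_qualities(l1, spec$q_high, spec$q_low,
                                            spec$q_stay), l1)
    q2 <- quals_to_strings(markov_qualities(l2, spec$q_high, spec$q_low,
                                            spec$q_stay), l2)
    manifest <- data.frame(
      read = nm$names, insert_size = orig$inserts[group],
      adapter_start = ifelse(orig$inserts[group] < spec$read_len,
                             orig$inserts[group], NA_integer_),
      duplicate_group = group, is_duplicate = is_dup,
      tile = nm$tile, row.names = NULL)
    ext <- if (spec$format == "fastq.gz") ".fastq.gz" else ".fastq"
    f1 <- file.path(dir, paste0(basename, "_R1", ext))
    f2 <- file.path(dir, paste0(basename, "_R2", ext))
    write_fastq_chunk(new_read_chunk(nm$names, rep("", n), s1, q1), f1)
    write_fastq_chunk(new_read_chunk(nm$names, rep("", n), s2, q2), f2)
    files <- c(f1, f2)
    truth <- list(n_pairs = n, n_distinct = n_orig,
                  dedup_fraction = n_orig / n,
                  insert_sizes = orig$inserts)
  } else {
    seqs <- inject_errors(orig$seqs[group], spec$error_rate)
    lens <- nchar(seqs)
    q <- quals_to_strings(markov_qualities(lens, spec$q_high, spec$q_low,
                                           spec$q_stay), lens)
    comments <- rep("", n)
    meta <- NULL
    if (spec$ont_meta) {
      meta <- make_meta(lens)
      comments <- paste0("ch=", meta$ch, " start_time=", meta$st,
                         " duration=", meta$du)
    }
    manifest <- data.frame(
      read = nm$names, length = lens,
      duplicate_group = group, is_duplicate = is_dup,
      adapter_start = orig$adapter_start[group],
      contaminant = orig$contam[group],
      tile = nm$tile,
      channel = if (spec$ont_meta) meta$ch else NA_integer_,
      duration = if (spec$ont_meta) meta$du else NA_real_,
      row.names = NULL)
    chunk <- new_read_chunk(nm$names, comments, seqs, q)
    if (spec$format == "ubam") {
      f <- file.path(dir, paste0(basename, ".bam"))
      write_ubam_chunk(chunk, f, meta)
      files <- f
    } else {
      ext <- if (spec$format == "fastq.gz") ".fastq.gz" else ".fastq"
      f <- file.path(dir, paste0(basename, ext))
      write_fastq_chunk(chunk, f)
      files <- f
    }
    truth <- list(n_reads = n, n_distinct = n_orig,
                  dedup_fraction = n_orig / n,
                  n_adapter = sum(!is.na(manifest$adapter_start)),
                  n_contaminant = sum(manifest$contaminant))
  }
  stopifnot(nrow(manifest) == n)  # manifest/file self-consistency
  list(files = files, manifest = manifest, truth = truth)
}

# write a chunk as an unaligned BAM via a temporary SAM (flag 4, no
# reference); ONT metadata goes into ch/st/du tags
write_ubam_chunk <- function(chunk, path, meta = NULL) {
  n <- chunk_size_of(chunk)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  tags <- if (!is.null(meta))
    paste0("\tch:i:", meta$ch, "\tst:Z:", meta$st, "\tdu:f:", meta$du)
  else rep("", n)
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             if (n) paste0(chunk$name, "\t4\t*\t0\t0\t*\t*\t0\t0\t",
                           chunk$sequence, "\t", chunk$quality, tags))
  writeLines(lines, sam)
  out <- Rsamtools::asBam(sam, sub("\\.bam$", "", path),
                          indexDestination = FALSE, overwrite = TRUE)
  invisible(out)
}
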