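# Streaming readers for Sanger FASTQ (plain or gzip) and unaligned BAM,
# normalising both into the same read representation, plus paired-end
# synchronisation.
#
# Internally the engine works on "read chunks": plain lists of parallel
# character vectors (name, comment, sequence, quality string) so every
# module can update its accumulators with vectorised operations. The
# one-read seq_record object is the user-facing record type.

#' A single sequencing read
#'
#' @param name read identifier without the leading `@`.
#' @param sequence base string over `{A,C,G,T,N}` (lowercase and IUPAC
#'   ambiguity codes are normalised on construction).
#' @param qualities integer vector of Phred scores, one per base, each in
#'   `[0, 93]` (the printable Sanger range).
#' @param comment everything after the first whitespace of the header; may
#'   be the empty string.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(name, sequence, qualities, comment = "") {
  sequence <- normalize_bases(sequence)
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities))
    stop("sequence/quality length mismatch for read '", name, "': ",
         nchar(sequence), " bases vs ", length(qualities), " quality values")
  if (length(qualities) && (min(qualities) < 0L || max(qualities) > 93L))
    stop("quality values for read '", name,
         "' outside the Sanger range [0, 93]")
  if (grepl("[^ACGTN]", sequence))
    stop("read '", name, "' contains characters outside {A,C,G,T,N}")
  structure(list(name = name, comment = comment,
                 sequence = sequence, qualities = qualities),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$name,
      if (nzchar(x$comment)) paste0(" [", x$comment, "]"), "\n",
      "  ", nchar(x$sequence), " bp, mean Q (expected-error) ",
      if (nchar(x$sequence)) round(read_mean_quality_expected_error(x$qualities), 2)
      else NA, "\n", sep = "")
  invisible(x)
}

# ---- chunk representation ---------------------------------------------------

new_read_chunk <- function(name = character(0), comment = character(0),
                           sequence = character(0), quality = character(0)) {
  list(name = name, comment = comment, sequence = sequence, quality = quality)
}

chunk_size_of <- function(chunk) length(chunk$name)

# decode a chunk's quality strings to a list of integer Phred vectors
chunk_qualities <- function(chunk) {
  lapply(chunk$quality, function(q) utf8ToInt(q) - 33L)
}

chunk_to_records <- function(chunk) {
  quals <- chunk_qualities(chunk)
  lapply(seq_along(chunk$name), function(i)
    seq_record(chunk$name[i], chunk$sequence[i], quals[[i]], chunk$comment[i]))
}

records_to_chunk <- function(records) {
  new_read_chunk(
    name = vapply(records, `[[`, character(1), "name"),
    comment = vapply(records, `[[`, character(1), "comment"),
    sequence = vapply(records, `[[`, character(1), "sequence"),
    quality = vapply(records, function(r) intToUtf8(r$qualities + 33L),
                     character(1)))
}

# ---- FASTQ ------------------------------------------------------------------

is_gzip_path <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

#' Open a FASTQ file for chunked streaming
#'
#' Returns a reader object whose `$read_chunk(n)` method yields the next
#' `n` records as a read chunk (possibly fewer at EOF; zero-length chunk at
#' end of stream) and whose `$close()` releases the connection. Gzip
#' compression is detected from the `.gz` extension unless `compressed` is
#' given.
#'
#' @param path path to a Sanger FASTQ file, plain or gzip-compressed.
#' @param compressed logical; override gzip autodetection.
#' @return a `fastq_reader` object.
#' @export
open_fastq <- function(path, compressed = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  compressed <- compressed %||% is_gzip_path(path)
  con <- if (compressed) gzfile(path, "rt") else file(path, "rt")
  n_seen <- 0L
  reader <- new.env(parent = emptyenv())
  reader$path <- path
  reader$read_chunk <- function(n = 10000L) {
    lines <- readLines(con, n = 4L * n)
    if (length(lines) == 0L) return(new_read_chunk())
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at record index ",
           n_seen + length(lines) %/% 4L + 1L, " in ", path)
    idx <- seq(1L, length(lines), by = 4L)
    header <- lines[idx]
    seqs <- lines[idx + 1L]
    plus <- lines[idx + 2L]
    qual <- lines[idx + 3L]
    bad <- which(!startsWith(header, "@"))
    if (length(bad))
      stop("malformed FASTQ header (no '@'; multi-line records are not ",
           "supported) at record index ", n_seen + bad[1L], " in ", path)
    badp <- which(!startsWith(plus, "+"))
    if (length(badp))
      stop("malformed FASTQ separator line (multi-line records are not ",
           "supported) at record index ", n_seen + badp[1L], " in ", path)
    if (any(nchar(seqs) != nchar(qual))) {
      i <- which(nchar(seqs) != nchar(qual))[1L]
      stop("sequence/quality length mismatch at record index ",
           n_seen + i, " in ", path)
    }
    header <- substring(header, 2L)
    sp <- regexpr("[ \t]", header)
    name <- ifelse(sp > 0L, substr(header, 1L, sp - 1L), header)
    comment <- ifelse(sp > 0L, substring(header, sp + 1L), "")
    # range-check quality characters: '!' (33) .. '~' (126)
    qr <- range(utf8ToInt(paste(qual, collapse = "")), na.rm = TRUE)
    if (length(qual) && nzchar(paste(qual, collapse = ""))) {
      if (qr[1L] < 33L)
        stop("quality character below '!' (not offset-33 Sanger?) in ", path)
      if (qr[2L] > 126L)
        stop("quality character above '~' (Phred > 93) in ", path)
    }
    n_seen <<- n_seen + length(idx)
    seqs <- normalize_bases(seqs)
    badb <- grep("[^ACGTN]", seqs)
    if (length(badb))
      stop("invalid sequence characters at record index ",
           n_seen - length(idx) + badb[1L], " in ", path)
    new_read_chunk(name = name, comment = comment,
                   sequence = seqs, quality = qual)
  }
  reader$close <- function() close(con)
  class(reader) <- "fastq_reader"
  reader
}

#' Read a whole FASTQ file into a list of records
#'
#' Convenience wrapper over [open_fastq()] for small files; the streaming
#' reader is what [run_qc()] uses. Decoding is lossless: writing the result
#' back with [write_fastq()] reproduces the input bytes for single-line
#' records.
#'
#' @inheritParams open_fastq
#' @return list of [seq_record] objects, in file order.
#' @export
read_fastq <- function(path, compressed = NULL) {
  r <- open_fastq(path, compressed)
  on.exit(r$close())
  out <- list()
  repeat {
    chunk <- r$read_chunk(50000L)
    if (chunk_size_of(chunk) == 0L) break
    out <- c(out, chunk_to_records(chunk))
  }
  out
}

#' Write records as Sanger FASTQ
#'
#' @param records list of [seq_record] objects.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  chunk <- if (length(records)) records_to_chunk(records) else new_read_chunk()
  write_fastq_chunk(chunk, path)
}

write_fastq_chunk <- function(chunk, path, append = FALSE) {
  con <- if (is_gzip_path(path)) gzfile(path, if (append) "ab" else "wb")
         else file(path, if (append) "ab" else "wb")
  on.exit(close(con))
  if (chunk_size_of(chunk)) {
    header <- paste0("@", chunk$name,
                     ifelse(nzchar(chunk$comment), paste0(" ", chunk$comment), ""))
    writeLines(rbind(header, chunk$sequence, "+", chunk$quality), con, sep = "\n")
  }
  invisible(path)
}

# ---- uBAM -------------------------------------------------------------------

#' Read an unaligned BAM (uBAM) into a list of records
#'
#' Reads every record of a BAM file through Rsamtools and normalises it to
#' the same record type as the FASTQ reader: 4-bit nibble sequences are
#' decoded (ambiguity codes other than N become N), qualities come from the
#' QUAL field, and the ONT-style instrument tags `ch` (channel), `st`
#' (start time) and `du` (duration, seconds) are carried into the comment
#' as `ch=`, `start_time=` and `duration=` tokens so platform metrics work
#' identically on both containers.
#'
#' Records flagged as aligned are processed from SEQ/QUAL as stored, with a
#' warning; records with a missing QUAL field (0xFF) are an error.
#'
#' @param path path to a BAM file.
#' @return list of [seq_record] objects.
#' @export
read_ubam <- function(path) {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual", "flag"),
    tag = c("ch", "st", "du"),
    flag = Rsamtools::scanBamFlag())
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  n <- length(res$qname)
  if (n == 0L) return(list())
  if (any(bitwAnd(res$flag, 4L) == 0L))
    warning("BAM contains records not flagged unmapped; ",
            "processing SEQ/QUAL as stored")
  seqs <- normalize_bases(as.character(res$seq))
  qual_str <- as.character(res$qual)
  tags <- res$tag
  comments <- character(n)
  tok <- function(label, v) {
    if (is.null(v)) return(rep("", n))
    ifelse(is.na(v), "", paste0(label, "=", v))
  }
  parts <- cbind(tok("ch", tags$ch), tok("start_time", tags$st),
                 tok("duration", tags$du))
  comments <- apply(parts, 1L, function(p) paste(p[nzchar(p)], collapse = " "))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- utf8ToInt(qual_str[i]) - 33L
    if (length(q) && any(q > 93L))
      stop("missing or invalid QUAL field (0xFF?) for BAM record '",
           res$qname[i], "'")
    if (nchar(qual_str[i]) == 0L && nchar(seqs[i]) > 0L)
      stop("missing QUAL field for BAM record '", res$qname[i], "'")
    out[[i]] <- seq_record(res$qname[i], seqs[i], q, comments[i])
  }
  out
}

# ---- pairing ----------------------------------------------------------------

# canonical pair name: strip exactly one trailing /1 or /2
canonical_read_name <- function(name) sub("/[12]$", "", name)

#' Synchronise two mate streams into read pairs
#'
#' Validates that mates correspond: canonical names (after stripping one
#' trailing `/1` or `/2`) must match at every position. Casava-style
#' pairing, where mate identity lives in the comment's leading `1:`/`2:`
#' token, is accepted because the name itself is then identical.
#'
#' @param reads1,reads2 lists of [seq_record] objects of equal length.
#' @return list of `read_pair` objects (`list(r1 =, r2 =)`).
#' @export
pair_reads <- function(reads1, reads2) {
  if (length(reads1) != length(reads2))
    stop("unequal stream lengths: ", length(reads1), " vs ", length(reads2))
  if (length(reads1) == 0L) return(list())
  n1 <- canonical_read_name(vapply(reads1, `[[`, character(1), "name"))
  n2 <- canonical_read_name(vapply(reads2, `[[`, character(1), "name"))
  bad <- which(n1 != n2)
  if (length(bad))
    stop("read name mismatch at pair ", bad[1L], ": '",
         n1[bad[1L]], "' vs '", n2[bad[1L]], "'")
  lapply(seq_along(reads1), function(i)
    structure(list(r1 = reads1[[i]], r2 = reads2[[i]]), class = "read_pair"))
}

check_pair_chunk <- function(chunk1, chunk2, offset = 0L) {
  if (chunk_size_of(chunk1) != chunk_size_of(chunk2))
    stop("unequal stream lengths between mate files near record ",
         offset + min(chunk_size_of(chunk1), chunk_size_of(chunk2)) + 1L)
  n1 <- canonical_read_name(chunk1$name)
  n2 <- canonical_read_name(chunk2$name)
  bad <- which(n1 != n2)
  if (length(bad))
    stop("read name mismatch at pair ", offset + bad[1L], ": '",
         n1[bad[1L]], "' vs '", n2[bad[1L]], "'")
  invisible(TRUE)
}
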