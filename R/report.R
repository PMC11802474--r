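# Aggregation of all module outputs into a single serializable QC report,
# produced by one streaming pass over the input reads.

SCHEMA_VERSION <- "1.0"

detect_input_format <- function(path) {
  if (grepl("\\.(bam)$", path, ignore.case = TRUE)) return("ubam")
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    return("fastq")
  if (file.size(path) == 0L) return("fastq")  # empty stream, zero records
  # sniff: BAM is BGZF (gzip magic) with "BAM\1" inside; FASTQ starts '@'
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) >= 2L && magic[1L] == as.raw(0x1f) &&
      magic[2L] == as.raw(0x8b)) {
    gz <- gzfile(path, "rb")
    on.exit(close(gz), add = TRUE)
    inner <- readBin(gz, "raw", 4L)
    if (length(inner) == 4L &&
        rawToChar(inner[1:3]) == "BAM") return("ubam")
    return("fastq")
  }
  if (length(magic) >= 1L && magic[1L] == as.raw(64L)) return("fastq")
  stop("cannot detect input format of ", path,
       " (expected FASTQ, gzipped FASTQ, or BAM)")
}

# chunked reader over a uBAM, same interface as open_fastq
open_ubam <- function(path, yield = 10000L) {
  bf <- Rsamtools::BamFile(path, yieldSize = yield)
  open(bf)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual", "flag"), tag = c("ch", "st", "du"))
  reader <- new.env(parent = emptyenv())
  reader$warned_aligned <- FALSE
  reader$read_chunk <- function(n = yield) {
    res <- Rsamtools::scanBam(bf, param = param)[[1L]]
    k <- length(res$qname)
    if (k == 0L) return(new_read_chunk())
    if (!reader$warned_aligned && any(bitwAnd(res$flag, 4L) == 0L)) {
      reader$warned_aligned <- TRUE
      warning("BAM contains records not flagged unmapped; ",
              "processing SEQ/QUAL as stored")
    }
    qual <- as.character(res$qual)
    if (any(!nzchar(qual) & nzchar(as.character(res$seq))))
      stop("missing QUAL field in BAM record")
    tok <- function(label, v) {
      if (is.null(v)) return(rep("", k))
      ifelse(is.na(v), "", paste0(label, "=", v))
    }
    parts <- cbind(tok("ch", res$tag$ch), tok("start_time", res$tag$st),
                   tok("duration", res$tag$du))
    comments <- apply(parts, 1L, function(p)
      paste(p[nzchar(p)], collapse = " "))
    new_read_chunk(name = res$qname, comment = comments,
                   sequence = normalize_bases(as.character(res$seq)),
                   quality = qual)
  }
  reader$close <- function() close(bf)
  reader
}

#' Run the full QC engine over one library
#'
#' Makes a single streaming pass over the input reads (one FASTQ, a
#' FASTQ pair, or a uBAM) and feeds every applicable module: generic
#' statistics, adapter probes, paired-end overlap, duplication sketch,
#' overrepresented fragments, and platform metrics. Deterministic given
#' `(inputs, cfg)`.
#'
#' @param inputs character vector of 1 (single-end FASTQ or uBAM) or 2
#'   (paired FASTQ) file paths.
#' @param cfg a [qc_config()].
#' @param contaminants path to a contaminant FASTA; `NULL` uses the
#'   bundled database, `NA` disables identification.
#' @param probes probe set data frame (see [default_probe_set()]) or a
#'   platform hint string.
#' @param chunk_size reads per streaming chunk.
#' @return a `qc_report` object.
#' @export
run_qc <- function(inputs, cfg = qc_config(), contaminants = NULL,
                   probes = "auto", chunk_size = 10000L) {
  if (length(inputs) < 1L || length(inputs) > 2L)
    stop("expected 1 or 2 input files")
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) stop("input file not found: ", missing_in[1L])
  formats <- vapply(inputs, detect_input_format, character(1))
  paired <- length(inputs) == 2L
  if (paired && any(formats != "fastq"))
    stop("paired-end input must be two FASTQ files")

  if (is.character(probes)) probes <- default_probe_set(probes)
  matcher <- build_matcher(probes, cfg$probe_len)
  db <- if (is.null(contaminants)) {
    build_contaminant_index(system.file("extdata",
                                        "contaminants_synthetic.fasta",
                                        package = "seqscope", mustWork = TRUE),
                            cfg)
  } else if (length(contaminants) == 1L && is.na(contaminants)) NULL
  else build_contaminant_index(contaminants, cfg)

  profile <- new_position_profile()
  summaries <- new_read_summaries()
  hits <- new_probe_hits(matcher)
  sketch <- dup_sketch(cfg$sketch_capacity)
  ftable <- fragment_table(cfg$fragment_store_cap)
  tiles <- new_tile_stats()
  ont <- new_ont_stats()
  ostats <- if (paired) new_overlap_stats() else NULL
  warnings_seen <- character(0)

  readers <- lapply(inputs, function(p)
    if (detect_input_format(p) == "ubam") open_ubam(p, chunk_size)
    else open_fastq(p))
  on.exit(for (r in readers) r$close())

  read_index <- 0L   # 0-based global index over the full read stream
  pair_offset <- 0L
  repeat {
    chunks <- lapply(readers, function(r)
      withCallingHandlers(r$read_chunk(chunk_size),
                          warning = function(w) {
                            warnings_seen <<- c(warnings_seen,
                                                conditionMessage(w))
                            invokeRestart("muffleWarning")
                          }))
    sizes <- vapply(chunks, chunk_size_of, integer(1))
    if (paired) {
      check_pair_chunk(chunks[[1L]], chunks[[2L]], pair_offset)
      pair_offset <- pair_offset + sizes[1L]
    }
    if (all(sizes == 0L)) break
    for (chunk in chunks) {
      profile_update(profile, chunk)
      summaries_update(summaries, chunk)
      probe_hits_update(hits, matcher, chunk)
      tile_stats_update(tiles, chunk)
      ont_stats_update(ont, chunk)
      sketch_insert(sketch, fingerprint(chunk$sequence, cfg))
      fr <- chunk_fragments(chunk, read_index, cfg)
      table_update(ftable, fr$fragments, fr$n_sampled)
      read_index <- read_index + chunk_size_of(chunk)
    }
    if (paired && sizes[1L] > 0L)
      overlap_stats_update(ostats,
                           find_overlaps_chunk(chunks[[1L]], chunks[[2L]], cfg))
  }

  dup <- if (sketch$total_reads > 0 || sketch$empty_reads > 0)
    estimate_duplication_safe(sketch) else empty_duplication()
  overrep <- if (ftable$sampled_reads > 0) {
    flagged <- flag_overrepresented(ftable, cfg)
    overrep_report_table(flagged, db, cfg)
  } else data.frame(fragment = character(0), count = integer(0),
                    fraction = numeric(0), best_match_id = character(0),
                    identity = numeric(0))

  tile_tab <- tile_stats_table(tiles)
  ont_tab <- ont_stats_table(ont)

  report <- structure(list(
    metadata = list(tool = "seqscope",
                    version = as.character(utils::packageVersion("seqscope")),
                    schema_version = SCHEMA_VERSION,
                    inputs = unname(inputs), formats = unname(formats),
                    paired = paired, config = unclass(cfg),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    summary = summaries_table(summaries),
    positions = profile_table(profile),
    adapters = list(total_reads = hits$total_reads,
                    probes = probe_hits_table(hits)),
    insert_sizes = if (paired) overlap_stats_table(ostats)
                   else list(available = FALSE),
    duplication = dup,
    overrepresented = list(sampled_reads = ftable$sampled_reads,
                           distinct_fragments = ftable$n_distinct,
                           table_saturated = ftable$saturated,
                           approximate_after_eviction = !dup$exact,
                           table = overrep),
    per_tile = tile_tab,
    ont = ont_tab,
    warnings = warnings_seen), class = "qc_report")
  report
}

empty_duplication <- function() {
  list(dedup_fraction = NA_real_, estimated_distinct = 0, total_reads = 0,
       empty_reads = 0, depth = 0L, exact = TRUE,
       multiplicity = data.frame(m = c(as.character(1:15), ">=16"),
                                 estimated_distinct = numeric(16L)))
}

estimate_duplication_safe <- function(sketch) {
  if (sketch$total_reads == 0) {
    out <- empty_duplication()
    out$empty_reads <- sketch$empty_reads
    return(out)
  }
  estimate_duplication(sketch)
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat("<qc_report> seqscope ", x$metadata$version, "\n", sep = "")
  cat("  inputs: ", paste(basename(x$metadata$inputs), collapse = ", "),
      if (x$metadata$paired) "  (paired-end)", "\n", sep = "")
  cat("  reads: ", s$n_reads, "   bases: ", format(s$total_bases,
      big.mark = ","), "\n", sep = "")
  if (s$n_reads > 0) {
    qe <- reads_at_least_q(x, 20, "expected_error")
    qa <- reads_at_least_q(x, 20, "arithmetic")
    cat("  reads >= Q20: ", qe, " (expected-error mode), ",
        qa, " (arithmetic mode)\n", sep = "")
    cat("  estimated deduplicated fraction: ",
        round(x$duplication$dedup_fraction, 4), "\n", sep = "")
    cat("  overrepresented fragments flagged: ",
        nrow(x$overrepresented$table), "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method summary qc_report
summary.qc_report <- function(object, ...) {
  print(object)
  if (object$metadata$paired && isTRUE(object$insert_sizes$n_pairs > 0)) {
    h <- object$insert_sizes$histogram
    if (nrow(h)) {
      mode_insert <- h$insert_size[which.max(h$count)]
      cat("  insert size mode: ", mode_insert, "  (undetermined pairs: ",
          object$insert_sizes$undetermined, ")\n", sep = "")
    }
  }
  if (isTRUE(object$ont$available))
    cat("  mean translocation speed: ",
        round(object$ont$mean_speed, 1), " b/s\n", sep = "")
  invisible(object)
}

#' Count reads at or above a mean-quality threshold
#'
#' Reads whose per-read mean quality (binned at the floor of the real
#' value) reaches `q`, in either averaging mode.
#'
#' @param report a `qc_report`.
#' @param q integer Phred threshold.
#' @param mode `"expected_error"` or `"arithmetic"`.
#' @return integer count.
#' @export
reads_at_least_q <- function(report, q,
                             mode = c("expected_error", "arithmetic")) {
  mode <- match.arg(mode)
  h <- if (mode == "expected_error") report$summary$mean_quality_expected_error
       else report$summary$mean_quality_arithmetic
  sum(h$count[h$q >= q])
}

#' Serialize a QC report to JSON
#'
#' Stable key ordering, full numeric precision, schema version field;
#' parseable by any generic JSON consumer (the schema is bundled at
#' `inst/extdata/qc_report_schema.json`).
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a self-contained HTML report
#'
#' One static file: every numeric table of the JSON report rendered as an
#' HTML table, inline CSS, no external references, renders without network
#' access.
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_html <- function(report, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  tab <- function(df, max_rows = 2000L) {
    if (is.null(df) || nrow(df) == 0L) return("<p>(no data)</p>")
    df <- utils::head(df, max_rows)
    cells <- vapply(seq_len(nrow(df)), function(i)
      paste0("<tr>", paste0("<td>", esc(vapply(df[i, , drop = FALSE],
        function(v) format(v, digits = 6), character(1))), "</td>",
        collapse = ""), "</tr>"), character(1))
    paste0("<table><thead><tr>",
           paste0("<th>", esc(names(df)), "</th>", collapse = ""),
           "</tr></thead><tbody>", paste(cells, collapse = "\n"),
           "</tbody></table>")
  }
  kv <- function(...) {
    x <- c(...)
    paste0("<ul>", paste0("<li><b>", esc(names(x)), ":</b> ",
                          esc(unname(x)), "</li>", collapse = ""), "</ul>")
  }
  s <- report$summary
  sections <- c(
    "<h2>Summary</h2>",
    kv(reads = s$n_reads, bases = s$total_bases,
       inputs = paste(basename(report$metadata$inputs), collapse = ", "),
       paired = report$metadata$paired),
    "<h3>Read length histogram</h3>", tab(s$length_histogram),
    "<h3>Per-read GC content</h3>", tab(s$gc_histogram),
    "<h3>Per-read mean quality (expected-error mode)</h3>",
    tab(s$mean_quality_expected_error),
    "<h3>Per-read mean quality (arithmetic mode)</h3>",
    tab(s$mean_quality_arithmetic),
    "<h2>Per-position profile</h2>", tab(report$positions),
    "<h2>Adapter content</h2>", tab(report$adapters$probes),
    "<h2>Insert sizes</h2>",
    if (isTRUE(report$metadata$paired))
      paste0(kv(undetermined = report$insert_sizes$undetermined,
                fraction_with_adapter =
                  report$insert_sizes$fraction_with_adapter),
             tab(report$insert_sizes$histogram))
    else "<p>section unavailable (single-end input)</p>",
    "<h2>Duplication</h2>",
    kv(estimated_deduplicated_fraction = report$duplication$dedup_fraction,
       total_reads = report$duplication$total_reads,
       sampling_depth = report$duplication$depth,
       exact = report$duplication$exact),
    tab(report$duplication$multiplicity),
    "<h2>Overrepresented fragments</h2>",
    kv(sampled_reads = report$overrepresented$sampled_reads,
       table_saturated = report$overrepresented$table_saturated),
    tab(report$overrepresented$table),
    "<h2>Per-tile quality (Illumina)</h2>",
    if (isTRUE(report$per_tile$available)) tab(report$per_tile$table)
    else "<p>section unavailable (no parseable tile ids)</p>",
    "<h2>ONT metrics</h2>",
    if (isTRUE(report$ont$available))
      paste0(kv(mean_translocation_speed = report$ont$mean_speed),
             "<h3>Channel activity</h3>", tab(report$ont$channels),
             "<h3>Translocation speed histogram</h3>",
             tab(report$ont$speed_histogram),
             "<h3>Speed over time</h3>", tab(report$ont$speed_time_series))
    else "<p>section unavailable (no channel/duration metadata)</p>",
    "<h2>Warnings</h2>",
    if (length(report$warnings))
      paste0("<pre>", esc(paste(report$warnings, collapse = "\n")), "</pre>")
    else "<p>(none)</p>")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>seqscope report</title><style>",
    "body{font-family:sans-serif;margin:2em;}",
    "table{border-collapse:collapse;margin:0.5em 0;}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:0.85em;}",
    "th{background:#eee;}</style></head><body>",
    "<h1>seqscope QC report</h1>",
    "<p>version ", report$metadata$version,
    ", schema ", report$metadata$schema_version, "</p>",
    paste(sections, collapse = "\n"),
    "</body></html>\n")
  writeLines(html, path)
  invisible(path)
}
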