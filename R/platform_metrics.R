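# Platform-specific statistics: Illumina per-tile quality from Casava-style
# read names; ONT per-channel activity, start-time series and translocation
# speed from ch=/start_time=/duration= metadata tokens (carried identically
# from FASTQ comments and uBAM tags).

#' Parse the tile id out of an Illumina read name
#'
#' Casava 1.8+ names are colon-delimited
#' `instrument:run:flowcell:lane:tile:x:y`; the fifth field is the tile.
#' Returns `NA` (never throws) when the name has fewer than 7 colon fields
#' or the fifth field is not numeric.
#'
#' @param name character vector of read names.
#' @return integer vector of tile ids (`NA` where unparseable).
#' @export
parse_illumina_tile <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 7L) return(NA_integer_)
    if (!grepl("^[0-9]+$", p[5L])) return(NA_integer_)
    as.integer(p[5L])
  }, integer(1))
}

#' Parse ONT metadata from a read's comment
#'
#' Scans the comment for `ch=`, `start_time=` and `duration=` tokens (the
#' same tokens the uBAM reader synthesises from the `ch`/`st`/`du` tags).
#' Missing tokens give `NA` fields; a malformed numeric value gives `NA`
#' plus a counted warning in the returned structure.
#'
#' @param record a [seq_record], or a plain comment string.
#' @return an `ont_read_meta`: list with `channel` (integer), `start_time`
#'   (POSIXct), `duration` (seconds), `n_warnings`.
#' @export
parse_ont_meta <- function(record) {
  comment <- if (inherits(record, "seq_record")) record$comment else record
  meta <- parse_ont_meta_vec(comment)
  structure(list(channel = meta$channel[1L],
                 start_time = meta$start_time[1L],
                 duration = meta$duration[1L],
                 n_warnings = meta$n_warnings),
            class = "ont_read_meta")
}

# vectorised version over comment strings
parse_ont_meta_vec <- function(comments) {
  grab <- function(key) {
    m <- regmatches(comments,
                    regexpr(paste0("(^|[ \t])", key, "=[^ \t]+"), comments))
    out <- rep(NA_character_, length(comments))
    hit <- grepl(paste0("(^|[ \t])", key, "="), comments)
    out[hit] <- sub(paste0("^.*", key, "="), "", m)
    out
  }
  n_warn <- 0L
  ch_raw <- grab("ch")
  ch <- suppressWarnings(as.integer(ch_raw))
  n_warn <- n_warn + sum(!is.na(ch_raw) & is.na(ch))
  ch[!is.na(ch) & ch < 1L] <- NA_integer_
  du_raw <- grab("duration")
  du <- suppressWarnings(as.numeric(du_raw))
  n_warn <- n_warn + sum(!is.na(du_raw) & is.na(du))
  du[!is.na(du) & du <= 0] <- NA_real_
  st_raw <- grab("start_time")
  st <- .POSIXct(rep(NA_real_, length(comments)), tz = "UTC")
  has <- !is.na(st_raw)
  if (any(has)) {
    parsed <- as.POSIXct(st_raw[has], format = "%Y-%m-%dT%H:%M:%SZ",
                         tz = "UTC")
    n_warn <- n_warn + sum(is.na(parsed))
    st[has] <- parsed
  }
  list(channel = ch, start_time = st, duration = du, n_warnings = n_warn)
}

#' Translocation speed of a read
#'
#' `length(sequence) / duration` in bases per second when a duration is
#' known, else `NA`. Aggregation into a histogram and a start-time series
#' happens in the ONT statistics accumulator of [run_qc()].
#'
#' @param record a [seq_record].
#' @param meta an `ont_read_meta` from [parse_ont_meta()] (parsed from the
#'   record when omitted).
#' @return bases per second, or `NA`.
#' @export
translocation_speed <- function(record, meta = parse_ont_meta(record)) {
  if (is.na(meta$duration)) return(NA_real_)
  nchar(record$sequence) / meta$duration
}

#' Per-channel activity
#'
#' @param metas list of `ont_read_meta` objects.
#' @param read_lengths integer vector of matching read lengths (for yield);
#'   zero lengths assumed when omitted.
#' @return data frame `channel`, `reads`, `bases` (channels absent from
#'   the data are simply missing).
#' @export
channel_activity <- function(metas, read_lengths = NULL) {
  ch <- vapply(metas, `[[`, integer(1), "channel")
  if (is.null(read_lengths)) read_lengths <- integer(length(metas))
  keep <- !is.na(ch)
  if (!any(keep))
    return(data.frame(channel = integer(0), reads = integer(0),
                      bases = numeric(0)))
  tab <- rowsum(cbind(1, as.numeric(read_lengths[keep])), ch[keep])
  data.frame(channel = as.integer(rownames(tab)),
             reads = as.integer(tab[, 1L]), bases = tab[, 2L],
             row.names = NULL)
}

# ---- accumulators used by run_qc -------------------------------------------

new_tile_stats <- function() {
  t <- new.env(parent = emptyenv())
  t$count <- numeric(0)    # named by tile id
  t$q_sum <- numeric(0)    # sum of per-read expected-error mean quality
  t$n_with_tile <- 0L
  t$n_reads <- 0L
  class(t) <- "tile_stats"
  t
}

tile_stats_update <- function(t, chunk) {
  n <- chunk_size_of(chunk)
  if (n == 0L) return(invisible(t))
  t$n_reads <- t$n_reads + n
  tiles <- parse_illumina_tile(chunk$name)
  keep <- !is.na(tiles) & nchar(chunk$sequence) > 0L
  if (!any(keep)) return(invisible(t))
  mq <- chunk_mean_qualities(chunk)$expected_error
  sums <- rowsum(cbind(1, mq[keep]), tiles[keep])
  ids <- rownames(sums)
  for (i in seq_along(ids)) {
    nm <- ids[i]
    cur_c <- t$count[nm]; cur_q <- t$q_sum[nm]
    t$count[nm] <- (if (is.na(cur_c)) 0 else cur_c) + sums[i, 1L]
    t$q_sum[nm] <- (if (is.na(cur_q)) 0 else cur_q) + sums[i, 2L]
  }
  t$n_with_tile <- t$n_with_tile + sum(keep)
  invisible(t)
}

tile_stats_table <- function(t) {
  if (length(t$count) == 0L)
    return(list(available = FALSE, n_with_tile = 0L,
                table = data.frame(tile = integer(0), reads = integer(0),
                                   mean_quality = numeric(0),
                                   deviation = numeric(0))))
  mean_q <- t$q_sum / t$count
  global <- sum(t$q_sum) / sum(t$count)
  list(available = TRUE, n_with_tile = t$n_with_tile,
       table = data.frame(tile = as.integer(names(t$count)),
                          reads = as.integer(t$count),
                          mean_quality = mean_q,
                          deviation = mean_q - global, row.names = NULL))
}

new_ont_stats <- function() {
  o <- new.env(parent = emptyenv())
  o$ch_reads <- numeric(0)   # named by channel
  o$ch_bases <- numeric(0)
  o$n_with_channel <- 0L
  o$n_with_duration <- 0L
  o$speed_sum <- 0
  o$speed_hist <- integer(0)  # named by floor(speed / 25) * 25 bin
  o$times <- numeric(0)       # start times (s since epoch) of reads w/ time
  o$speeds_by_time <- numeric(0)
  o$n_warnings <- 0L
  class(o) <- "ont_stats"
  o
}

ont_stats_update <- function(o, chunk) {
  n <- chunk_size_of(chunk)
  if (n == 0L) return(invisible(o))
  meta <- parse_ont_meta_vec(chunk$comment)
  o$n_warnings <- o$n_warnings + meta$n_warnings
  lens <- nchar(chunk$sequence)
  keep <- !is.na(meta$channel)
  if (any(keep)) {
    o$n_with_channel <- o$n_with_channel + sum(keep)
    tab <- rowsum(cbind(1, as.numeric(lens[keep])), meta$channel[keep])
    ids <- rownames(tab)
    for (i in seq_along(ids)) {
      nm <- ids[i]
      cr <- o$ch_reads[nm]; cb <- o$ch_bases[nm]
      o$ch_reads[nm] <- (if (is.na(cr)) 0 else cr) + tab[i, 1L]
      o$ch_bases[nm] <- (if (is.na(cb)) 0 else cb) + tab[i, 2L]
    }
  }
  hasdu <- !is.na(meta$duration)
  if (any(hasdu)) {
    o$n_with_duration <- o$n_with_duration + sum(hasdu)
    speed <- lens[hasdu] / meta$duration[hasdu]
    o$speed_sum <- o$speed_sum + sum(speed)
    bins <- as.character(floor(speed / 25) * 25)
    tb <- table(bins)
    for (nm in names(tb)) {
      cur <- o$speed_hist[nm]
      o$speed_hist[nm] <- (if (is.na(cur)) 0L else cur) + as.integer(tb[[nm]])
    }
    hast <- hasdu & !is.na(meta$start_time)
    if (any(hast)) {
      o$times <- c(o$times, as.numeric(meta$start_time[hast]))
      o$speeds_by_time <- c(o$speeds_by_time,
                            lens[hast] / meta$duration[hast])
    }
  }
  invisible(o)
}

# time series binned over the run span: span/100 bins, minimum width 60 s
ont_stats_table <- function(o) {
  avail <- o$n_with_channel > 0L || o$n_with_duration > 0L
  channels <- if (length(o$ch_reads))
    data.frame(channel = as.integer(names(o$ch_reads)),
               reads = as.integer(o$ch_reads), bases = o$ch_bases,
               row.names = NULL)
  else data.frame(channel = integer(0), reads = integer(0), bases = numeric(0))
  o2 <- order(channels$channel)
  channels <- channels[o2, , drop = FALSE]
  rownames(channels) <- NULL
  speed_hist <- if (length(o$speed_hist)) {
    ord <- order(as.numeric(names(o$speed_hist)))
    data.frame(speed_bin = as.numeric(names(o$speed_hist))[ord],
               count = as.integer(o$speed_hist)[ord], row.names = NULL)
  } else data.frame(speed_bin = numeric(0), count = integer(0))
  series <- data.frame(time = numeric(0), mean_speed = numeric(0),
                       reads = integer(0))
  if (length(o$times) > 1L) {
    span <- diff(range(o$times))
    width <- max(60, span / 100)
    bin <- floor((o$times - min(o$times)) / width)
    agg <- rowsum(cbind(o$speeds_by_time, 1), bin)
    series <- data.frame(time = min(o$times) + as.numeric(rownames(agg)) * width,
                         mean_speed = agg[, 1L] / agg[, 2L],
                         reads = as.integer(agg[, 2L]), row.names = NULL)
  }
  list(available = avail,
       n_with_channel = o$n_with_channel,
       n_with_duration = o$n_with_duration,
       mean_speed = if (o$n_with_duration > 0)
         o$speed_sum / o$n_with_duration else NA_real_,
       channels = channels,
       speed_histogram = speed_hist,
       speed_time_series = series,
       n_warnings = o$n_warnings)
}
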