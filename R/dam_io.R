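# TriKinetics DAM2 monitor text I/O and assembly of experiment-level
# activity tables aligned to the lights-off origin.

MONTHS3 <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
             "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Read a DAM2 monitor text file
#'
#' Parses the 42-column tab-separated text layout written by DAMSystem3:
#' column 1 is the reading index, column 2 the date (`"D Mon YY"`), column 3
#' the time (`"HH:MM:SS"`), column 4 the monitor status, columns 5-10 unused
#' metadata, and columns 11-42 the beam-break counts for channels 1-32.
#'
#' @param path Path to a DAM2 text file.
#' @param monitor_id Monitor identifier; defaults to the file name without
#'   extension.
#' @return A `monitor_file` object: a list with `monitor_id`, a `readings`
#'   data frame (`reading_index`, `datetime` in UTC, `status`) and an
#'   integer `counts` matrix with one column per channel.
#' @export
read_dam2 <- function(path, monitor_id = NULL) {
  if (is.null(monitor_id)) {
    monitor_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(monitor_file(monitor_id,
                        reading_index = integer(0),
                        datetime = as.POSIXct(character(0), tz = "UTC"),
                        status = integer(0),
                        counts = matrix(integer(0), nrow = 0, ncol = 32)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 42L)
  if (length(bad)) {
    stop(sprintf("DAM2 format error: line %d has %d columns, expected >= 42",
                 bad[1], nf[bad[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:42], character(42)))
  reading_index <- suppressWarnings(as.integer(m[, 1]))
  status <- suppressWarnings(as.integer(m[, 4]))
  counts <- suppressWarnings(matrix(as.integer(m[, 11:42]), ncol = 32))
  if (anyNA(counts)) {
    bad_row <- which(apply(is.na(counts), 1, any))[1]
    stop(sprintf("DAM2 parse error: non-integer count on line %d", bad_row))
  }
  if (anyNA(reading_index)) {
    stop(sprintf("DAM2 parse error: non-integer reading index on line %d",
                 which(is.na(reading_index))[1]))
  }
  datetime <- parse_dam2_datetime(m[, 2], m[, 3])
  if (anyNA(datetime)) {
    stop(sprintf("DAM2 parse error: bad date/time on line %d",
                 which(is.na(datetime))[1]))
  }
  monitor_file(monitor_id, reading_index, datetime, status, counts)
}

#' Construct a monitor_file object
#'
#' @param monitor_id Identifier.
#' @param reading_index Integer vector, strictly increasing.
#' @param datetime POSIXct vector (UTC).
#' @param status Integer status codes.
#' @param counts Integer matrix with 32 columns (channels 1-32).
#' @return A `monitor_file` list.
#' @export
monitor_file <- function(monitor_id, reading_index, datetime, status, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (ncol(counts) != 32L) stop("counts must have exactly 32 channel columns")
  n <- length(reading_index)
  if (length(datetime) != n || length(status) != n || nrow(counts) != n) {
    stop("monitor_file fields must have matching lengths")
  }
  if (n > 1L && any(diff(as.integer(reading_index)) <= 0L)) {
    stop("reading_index must be strictly increasing")
  }
  if (any(counts < 0L)) stop("channel counts must be non-negative")
  structure(list(monitor_id = monitor_id,
                 readings = data.frame(reading_index = as.integer(reading_index),
                                       datetime = datetime,
                                       status = as.integer(status)),
                 counts = counts),
            class = "monitor_file")
}

#' @export
print.monitor_file <- function(x, ...) {
  cat(sprintf("DAM2 monitor '%s': %d readings", x$monitor_id,
              nrow(x$readings)))
  if (nrow(x$readings)) {
    cat(sprintf(", %s .. %s",
                format(x$readings$datetime[1], "%Y-%m-%d %H:%M"),
                format(x$readings$datetime[nrow(x$readings)],
                       "%Y-%m-%d %H:%M")))
  }
  cat("\n")
  invisible(x)
}

parse_dam2_datetime <- function(date_str, time_str) {
  parts <- strsplit(date_str, " ", fixed = TRUE)
  ok <- lengths(parts) == 3L
  day <- rep(NA_integer_, length(parts))
  mon <- rep(NA_integer_, length(parts))
  yy <- rep(NA_integer_, length(parts))
  day[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[`, "", 1L)))
  mon[ok] <- match(vapply(parts[ok], `[`, "", 2L), MONTHS3)
  yy[ok] <- suppressWarnings(as.integer(vapply(parts[ok], `[`, "", 3L)))
  year <- ifelse(yy >= 70, 1900L + yy, 2000L + yy)
  iso <- sprintf("%04d-%02d-%02d %s", year, mon, day, time_str)
  iso[is.na(year) | is.na(mon) | is.na(day)] <- NA
  as.POSIXct(iso, tz = "UTC")
}

format_dam2_date <- function(dt) {
  lt <- as.POSIXlt(dt, tz = "UTC")
  sprintf("%d %s %02d", lt$mday, MONTHS3[lt$mon + 1L], lt$year %% 100L)
}

#' Write a DAM2 monitor text file
#'
#' Inverse of [read_dam2()]: emits the 42-column tab-separated dialect so
#' that `read_dam2(write_dam2(m))` reproduces `m` exactly.
#'
#' @param monitor A `monitor_file` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dam2 <- function(monitor, path) {
  stopifnot(inherits(monitor, "monitor_file"))
  r <- monitor$readings
  if (nrow(r) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  meta <- matrix(0L, nrow = nrow(r), ncol = 6)
  body <- cbind(r$reading_index,
                format_dam2_date(r$datetime),
                format(r$datetime, "%H:%M:%S", tz = "UTC"),
                r$status, meta, monitor$counts)
  writeLines(apply(body, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a channel layout table
#'
#' The layout maps monitor channels to flies. Expected tab-separated columns:
#' `monitor_id`, `channel`, `fly_id`, `strain_id`, `condition`.
#'
#' @param path Path to the layout TSV.
#' @return A data frame with the five layout columns.
#' @export
read_layout <- function(path) {
  lay <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("monitor_id", "channel", "fly_id", "strain_id", "condition")
  miss <- setdiff(need, names(lay))
  if (length(miss)) stop("layout missing columns: ", paste(miss, collapse = ", "))
  lay$channel <- as.integer(lay$channel)
  lay
}

#' Assemble an activity table from monitor files
#'
#' Sums raw readings into 30-minute bins anchored at the lights-off origin
#' (bin 0 starts at `origin`), discards readings before the origin, and
#' retains at most 120 bins (the 60-h assay). The raw cadence is inferred
#' from the timestamps and must divide 30 minutes. Bins with an incomplete
#' set of raw readings are dropped and recorded in the `missing_bins`
#' attribute rather than zero-filled.
#'
#' @param monitors A `monitor_file` or list of them.
#' @param layout Layout data frame (see [read_layout()]); only mapped
#'   channels are emitted.
#' @param origin Lights-off datetime (POSIXct UTC, or a string parseable as
#'   `"YYYY-MM-DD HH:MM:SS"`).
#' @param n_bins Maximum number of bins to retain (default 120).
#' @return Long-format activity data frame with columns `fly_id`,
#'   `strain_id`, `condition`, `monitor_id`, `channel`, `bin_index`,
#'   `count`; attribute `missing_bins` lists dropped (monitor, bin) pairs.
#' @export
to_activity_table <- function(monitors, layout, origin, n_bins = 120L) {
  if (inherits(monitors, "monitor_file")) monitors <- list(monitors)
  if (is.character(origin)) origin <- as.POSIXct(origin, tz = "UTC")
  key <- paste(layout$monitor_id, layout$channel)
  if (anyDuplicated(key)) {
    stop("layout error: channel mapped twice: ", key[duplicated(key)][1])
  }
  out <- list()
  missing_bins <- list()
  for (mon in monitors) {
    lay <- layout[layout$monitor_id == mon$monitor_id, , drop = FALSE]
    if (nrow(lay) == 0L) next
    if (any(lay$channel < 1L | lay$channel > 32L)) {
      stop("layout error: channel outside 1..32 for monitor ", mon$monitor_id)
    }
    offset_min <- as.numeric(difftime(mon$readings$datetime, origin,
                                      units = "mins"))
    keep <- offset_min >= 0
    off <- offset_min[keep]
    cnt <- mon$counts[keep, , drop = FALSE]
    if (length(off) == 0L) next
    if (length(off) > 1L) {
      cad <- round(diff(off), 6)
      cadence <- as.numeric(names(sort(table(cad), decreasing = TRUE))[1])
    } else {
      cadence <- 30
    }
    if (cadence <= 0 || abs(30 / cadence - round(30 / cadence)) > 1e-9) {
      stop(sprintf("raw cadence %.3g min does not divide 30 min (monitor %s)",
                   cadence, mon$monitor_id))
    }
    per_bin <- round(30 / cadence)
    bin <- floor(off / 30)
    keep2 <- bin < n_bins
    bin <- bin[keep2]
    cnt <- cnt[keep2, , drop = FALSE]
    if (length(bin) == 0L) next
    nread <- tabulate(bin + 1L, nbins = n_bins)
    present <- seq_len(n_bins) - 1L
    span <- present >= min(bin) & present <= max(bin)
    complete <- nread == per_bin
    good_bins <- present[complete]
    dropped <- present[span & !complete]
    if (length(dropped)) {
      missing_bins[[length(missing_bins) + 1L]] <-
        data.frame(monitor_id = mon$monitor_id, bin_index = dropped)
    }
    sel <- bin %in% good_bins
    sums <- rowsum(cnt[sel, , drop = FALSE], group = bin[sel])
    bins_here <- as.integer(rownames(sums))
    for (i in seq_len(nrow(lay))) {
      ch <- lay$channel[i]
      out[[length(out) + 1L]] <- data.frame(
        fly_id = lay$fly_id[i], strain_id = lay$strain_id[i],
        condition = lay$condition[i], monitor_id = mon$monitor_id,
        channel = ch, bin_index = bins_here,
        count = as.integer(sums[, ch]),
        stringsAsFactors = FALSE)
    }
  }
  at <- if (length(out)) do.call(rbind, out) else
    data.frame(fly_id = character(0), strain_id = character(0),
               condition = character(0), monitor_id = character(0),
               channel = integer(0), bin_index = integer(0),
               count = integer(0))
  rownames(at) <- NULL
  attr(at, "missing_bins") <- if (length(missing_bins))
    do.call(rbind, missing_bins) else NULL
  at
}

#' Write an activity table as long-format TSV
#'
#' @param activity Activity data frame from [to_activity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_tsv <- function(activity, path) {
  utils::write.table(activity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format activity TSV
#' @param path Path written by [write_activity_tsv()].
#' @return Activity data frame.
#' @export
read_activity_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
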