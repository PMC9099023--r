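#' Read a Trikinetics-style activity monitor file
#'
#' Monitor text files are tab-separated with one row per time bin:
#' record index, date (`%d %b %y`), time (`%H:%M:%S`), a status flag
#' (`1` = OK, anything else = reader error), then one integer count column
#' per channel.  Rows whose status flag marks a reader error keep their
#' place in the time grid but have their counts stored as missing.
#'
#' @param path Path to the monitor text file.
#' @param bin_minutes Expected bin length in minutes (default 5, the usual
#'   monitor configuration).
#' @return A `monitor_table`: a tibble with columns `index`, `datetime`,
#'   `status`, and one `ch<N>` column per channel, plus attributes
#'   `bin_minutes` and `source_id`.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' mt <- tibble::tibble(datetime = as.POSIXct("2021-06-01 08:00:00", tz = "UTC") +
#'                        60 * 5 * (0:5), ch1 = rpois(6, 2), ch2 = rpois(6, 2))
#' write_monitor(mt, tf)
#' read_monitor(tf)
#' @export
read_monitor <- function(path, bin_minutes = 5) {
  if (!file.exists(path)) abort(sprintf("Monitor file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 5)
    abort("Monitor file needs >= 5 tab-separated columns (index, date, time, status, counts).")
  datetime <- as.POSIXct(paste(raw[[2]], raw[[3]]), format = "%d %b %y %H:%M:%S", tz = "UTC")
  bad <- which(is.na(datetime))
  if (length(bad))
    abort(sprintf("Malformed timestamp on line(s): %s", paste(head(bad, 5), collapse = ", ")))
  counts <- raw[, 5:ncol(raw), drop = FALSE]
  counts <- purrr::map_dfc(counts, as.numeric)
  names(counts) <- paste0("ch", seq_len(ncol(counts)))
  if (any(counts < 0, na.rm = TRUE)) {
    ln <- which(rowSums(as.matrix(counts) < 0, na.rm = TRUE) > 0)
    abort(sprintf("Negative counts on line(s): %s", paste(head(ln, 5), collapse = ", ")))
  }
  status <- raw[[4]]
  # reader-error rows: counts become missing, the bin stays on the grid
  err <- status != "1"
  if (any(err)) counts[err, ] <- NA_real_

  dt_min <- as.numeric(diff(datetime), units = "mins")
  if (any(dt_min <= 0))
    abort(sprintf("Non-monotone timestamps at row(s): %s",
                  paste(head(which(dt_min <= 0) + 1L, 5), collapse = ", ")))
  gaps <- which(abs(dt_min - bin_minutes) > 1e-6)
  if (length(gaps))
    abort(sprintf("Irregular bin spacing (gap) after row(s): %s (expected %d min)",
                  paste(head(gaps, 5), collapse = ", "), bin_minutes))

  out <- tibble::tibble(index = as.integer(raw[[1]]), datetime = datetime,
                        status = status) |>
    dplyr::bind_cols(counts)
  attr(out, "bin_minutes") <- bin_minutes
  attr(out, "source_id") <- basename(path)
  class(out) <- c("monitor_table", class(out))
  out
}

#' Write a monitor table (or plain tibble of counts) to monitor text format
#'
#' The inverse of [read_monitor()]: the written file round-trips counts
#' bit-exactly.  Missing counts are written as status-error rows with 0s.
#'
#' @param x A tibble with a `datetime` column and one or more count columns
#'   (any columns named `index`/`status` are honoured, else synthesized).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monitor <- function(x, path) {
  x <- tibble::as_tibble(x)
  stopifnot("datetime" %in% names(x))
  cnt_cols <- setdiff(names(x), c("index", "datetime", "status"))
  cnt <- as.matrix(x[, cnt_cols, drop = FALSE])
  status <- if ("status" %in% names(x)) x$status else rep("1", nrow(x))
  status[rowSums(is.na(cnt)) > 0] <- "51"   # reader-error flag
  cnt[is.na(cnt)] <- 0
  df <- data.frame(
    index = if ("index" %in% names(x)) x$index else seq_len(nrow(x)),
    date = format(x$datetime, "%d %b %y"),
    time = format(x$datetime, "%H:%M:%S"),
    status = status
  )
  df <- cbind(df, as.data.frame(cnt))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Turn one monitor channel into a per-animal activity series
#'
#' An `activity_series` is a tibble with one row per time bin and columns
#' `time_h` (hours since schedule start), `zt`, `light` (`"ON"`/`"OFF"`),
#' and `counts`; the animal's identity and the schedule ride along as
#' attributes.  This is the unit every LD and free-run analysis consumes.
#'
#' @param counts Integer vector of per-bin counts (NA = unreadable bin).
#' @param schedule A [light_schedule()] covering the recording.
#' @param bin_minutes Bin length in minutes.
#' @param animal_id,genotype Identifiers carried into reports.
#' @return An `activity_series` tibble.
#' @export
activity_series <- function(counts, schedule, bin_minutes = 5,
                            animal_id = "animal", genotype = "WT") {
  stopifnot(inherits(schedule, "light_schedule"))
  n <- length(counts)
  if (n < 24 * 60 / bin_minutes)
    abort("An activity series must cover at least one full day.")
  if (any(counts < 0, na.rm = TRUE)) abort("Counts must be non-negative.")
  time_h <- (seq_len(n) - 1L) * bin_minutes / 60
  if (max(time_h) >= schedule$span_h + 1e-9)
    abort("Series extends past the schedule span.")
  out <- tibble::tibble(
    time_h = time_h,
    zt = zt_of(time_h, schedule),
    light = light_state_at(time_h, schedule),
    counts = as.numeric(counts)
  )
  attr(out, "animal_id") <- animal_id
  attr(out, "genotype") <- genotype
  attr(out, "bin_minutes") <- bin_minutes
  attr(out, "schedule") <- schedule
  class(out) <- c("activity_series", class(out))
  out
}

series_meta <- function(series) {
  list(animal_id = attr(series, "animal_id"),
       genotype = attr(series, "genotype"),
       bin_minutes = attr(series, "bin_minutes"),
       schedule = attr(series, "schedule"))
}

#' Restrict an activity series to a block of its schedule
#'
#' @param series An `activity_series`.
#' @param block `"constant"` for the trailing DD/LL block, `"entrainment"`
#'   for the leading LD block, or a 2-vector of hours `c(from, to)`.
#' @return An `activity_series` re-based so `time_h` starts at 0, bound to
#'   the corresponding sub-schedule.
#' @export
series_window <- function(series, block = "constant") {
  m <- series_meta(series)
  sch <- m$schedule
  blocks <- attr(sch, "blocks")
  if (is.character(block)) {
    if (is.null(blocks)) {
      if (block == "constant" && is_constant_schedule(sch)) return(series)
      if (block == "entrainment" && !is_constant_schedule(sch)) return(series)
      abort(sprintf("Schedule '%s' has no %s block.", sch$label, block))
    }
    want <- if (block == "constant") blocks$constant else !blocks$constant
    if (!any(want)) abort(sprintf("Schedule '%s' has no %s block.", sch$label, block))
    b <- blocks[want, ][1, ]
    from <- b$start_h; to <- b$end_h
    lab <- b$label
  } else {
    from <- block[1]; to <- block[2]
    lab <- sch$label
  }
  keep <- series$time_h >= from - 1e-9 & series$time_h < to - 1e-9
  sub_sch <- light_schedule(lab, span_days = ceiling((to - from) / 24),
                            t0_zt = zt_of(from, sch))
  sub_sch$span_h <- to - from
  sub_sch$segments <- dplyr::filter(sub_sch$segments, .data$start_h < to - from)
  sub_sch$segments$end_h <- pmin(sub_sch$segments$end_h, to - from)
  activity_series(series$counts[keep], sub_sch, m$bin_minutes,
                  m$animal_id, m$genotype)
}

#' Export a cohort of activity series as one long tibble
#'
#' @param cohort List of `activity_series`.
#' @return Long tibble: `animal_id`, `genotype`, `time_h`, `zt`, `light`,
#'   `counts` — ready for TSV export or ggplot2.
#' @export
cohort_long <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    m <- series_meta(s)
    dplyr::mutate(tibble::as_tibble(s), animal_id = m$animal_id,
                  genotype = m$genotype, .before = 1)
  })
}
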