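#' Construct a light schedule
#'
#' Builds the piecewise light program an activity recording was made under:
#' cyclic light--dark (LD) days, constant darkness (DD) or constant light
#' (LL), optionally with acute light/dark pulses superimposed.  All
#' downstream analyses express time in Zeitgeber time (ZT), where ZT0 is
#' lights-on of the (current or most recent) LD cycle.
#'
#' Times inside a schedule are hours since the schedule start, which for LD
#' schedules coincides with lights-on (so the schedule starts at ZT0 unless
#' `t0_zt` says otherwise).  Every segment is a half-open interval
#' `[start, end)`: a time bin belongs to the light state at its start, so
#' switch instants are never double-counted.
#'
#' @param label Schedule label: `"LD<light>:<dark>"` (e.g. `"LD18:6"`,
#'   `"LD12:12"`), `"DD"`, or `"LL"`.  For LD labels the light and dark
#'   hours must sum to 24.
#' @param span_days Number of 24-h days the schedule covers.
#' @param pulses Optional tibble/data frame of acute pulses with columns
#'   `day` (1-based day index), `start_zt` (hours), `duration_h` and
#'   `state` (`"ON"` or `"OFF"`), overriding the background program.
#' @param t0_zt ZT of the schedule start in `[0, 24)`.  Constant schedules
#'   that continue a prior entrainment keep ZT running from the old cycle;
#'   `append_schedule()` sets this automatically.
#' @return A `light_schedule` object: a list with `label`, `photoperiod_h`
#'   (NA for constant conditions), `span_h`, `t0_zt`, a `segments` tibble
#'   (`start_h`, `end_h`, `state`) and a `pulses` tibble.
#' @examples
#' ld <- light_schedule("LD18:6", span_days = 5)
#' light_state_at(8, ld)   # mid-photophase -> "ON"
#' zt_of(30, ld)           # 30 h after lights-on -> ZT6
#' @export
light_schedule <- function(label, span_days, pulses = NULL, t0_zt = 0) {
  stopifnot(is.character(label), length(label) == 1L)
  if (span_days < 1) abort("`span_days` must be at least 1.")
  if (t0_zt < 0 || t0_zt >= 24) abort("`t0_zt` must lie in [0, 24).")
  span_h <- span_days * 24

  if (grepl("^LD", label)) {
    parts <- strsplit(sub("^LD", "", label), ":", fixed = TRUE)[[1]]
    ph <- suppressWarnings(as.numeric(parts))
    if (length(ph) != 2L || anyNA(ph))
      abort(sprintf("Cannot parse LD label '%s' (expected e.g. 'LD18:6').", label))
    if (abs(sum(ph) - 24) > 1e-9)
      abort(sprintf("LD label '%s': light + dark hours must sum to 24.", label))
    if (ph[1] <= 0 || ph[1] >= 24)
      abort(sprintf("LD label '%s': photoperiod must lie in (0, 24).", label))
    photoperiod_h <- ph[1]
    # one ON + one OFF segment per day, phased so that ZT0 = lights-on
    day0 <- tibble::tibble(
      start_h = c(0, photoperiod_h),
      end_h   = c(photoperiod_h, 24),
      state   = c("ON", "OFF")
    )
    segments <- purrr::map_dfr(seq_len(span_days) - 1L, function(d) {
      dplyr::mutate(day0, start_h = .data$start_h + 24 * d,
                    end_h = .data$end_h + 24 * d)
    })
    if (t0_zt > 0) {
      # shift the program so that schedule time 0 is at ZT t0_zt
      segments <- segments |>
        dplyr::mutate(start_h = .data$start_h - t0_zt,
                      end_h = .data$end_h - t0_zt) |>
        dplyr::filter(.data$end_h > 0, .data$start_h < span_h) |>
        dplyr::mutate(start_h = pmax(.data$start_h, 0),
                      end_h = pmin(.data$end_h, span_h))
    }
  } else if (label %in% c("DD", "LL")) {
    photoperiod_h <- NA_real_
    segments <- tibble::tibble(
      start_h = 0, end_h = span_h,
      state = if (label == "DD") "OFF" else "ON"
    )
  } else {
    abort(sprintf("Unknown schedule label '%s' (use 'LD<l>:<d>', 'DD' or 'LL').", label))
  }

  pulses <- normalize_pulses(pulses, span_h, t0_zt)
  structure(
    list(label = label, photoperiod_h = photoperiod_h, span_h = span_h,
         t0_zt = t0_zt, segments = segments, pulses = pulses),
    class = "light_schedule"
  )
}

normalize_pulses <- function(pulses, span_h, t0_zt) {
  if (is.null(pulses) || nrow(as.data.frame(pulses)) == 0L) {
    return(tibble::tibble(start_h = double(), end_h = double(), state = character()))
  }
  pulses <- tibble::as_tibble(pulses)
  need <- c("day", "start_zt", "duration_h", "state")
  if (!all(need %in% names(pulses)))
    abort(paste0("Pulses need columns: ", paste(need, collapse = ", ")))
  out <- pulses |>
    dplyr::mutate(
      start_h = (.data$day - 1) * 24 + (.data$start_zt - t0_zt) %% 24,
      end_h = .data$start_h + .data$duration_h
    ) |>
    dplyr::select("start_h", "end_h", "state")
  if (any(out$start_h < 0) || any(out$end_h > span_h))
    abort("A pulse lies outside the schedule span.")
  out
}

#' Append a constant-condition (or further LD) segment to a schedule
#'
#' The standard recording protocol entrains animals under an LD cycle and
#' then releases them into constant darkness or light.  ZT continues to run
#' from the prior LD phase in the constant segment, so phases stay
#' comparable across the switch.
#'
#' @param first A `light_schedule` (typically LD entrainment).
#' @param label Label for the appended block (`"DD"`, `"LL"`, or an LD label).
#' @param span_days Days the appended block lasts.
#' @return A `light_schedule` covering both blocks, with
#'   `attr(, "blocks")` recording the boundary.
#' @export
append_schedule <- function(first, label, span_days) {
  stopifnot(inherits(first, "light_schedule"))
  zt_at_end <- zt_of(first$span_h, first, .boundary_ok = TRUE)
  second <- light_schedule(label, span_days, t0_zt = zt_at_end)
  segs2 <- second$segments |>
    dplyr::mutate(start_h = .data$start_h + first$span_h,
                  end_h = .data$end_h + first$span_h)
  # merge contiguous same-state segments at the seam
  segments <- dplyr::bind_rows(first$segments, segs2)
  out <- structure(
    list(label = paste(first$label, label, sep = "+"),
         photoperiod_h = first$photoperiod_h,
         span_h = first$span_h + second$span_h,
         t0_zt = first$t0_zt,
         segments = segments,
         pulses = first$pulses),
    class = "light_schedule"
  )
  attr(out, "blocks") <- rbind(attr(first, "blocks"),
    data.frame(label = label, start_h = first$span_h,
               end_h = first$span_h + second$span_h,
               constant = label %in% c("DD", "LL")))
  if (is.null(attr(first, "blocks"))) {
    attr(out, "blocks") <- rbind(
      data.frame(label = first$label, start_h = 0, end_h = first$span_h,
                 constant = first$label %in% c("DD", "LL")),
      attr(out, "blocks"))
  }
  out
}

#' Zeitgeber time of an instant within a schedule
#'
#' ZT0 is lights-on; on cyclic schedules `zt_of()` is periodic with period
#' 24 h, and in constant blocks ZT keeps running from the prior entrainment
#' phase.
#'
#' @param t_h Hours since schedule start (vectorized).
#' @param schedule A `light_schedule`.
#' @param .boundary_ok Allow `t_h` equal to the span end (internal use).
#' @return ZT hours in `[0, 24)`.
#' @export
zt_of <- function(t_h, schedule, .boundary_ok = FALSE) {
  stopifnot(inherits(schedule, "light_schedule"))
  hi <- if (.boundary_ok) schedule$span_h else schedule$span_h - 1e-12
  if (any(t_h < 0) || any(t_h > hi + 1e-9))
    abort("Timestamp outside the schedule span.")
  (t_h + schedule$t0_zt) %% 24
}

#' Light state at an instant
#'
#' @inheritParams zt_of
#' @return Character vector, `"ON"` or `"OFF"`, after applying pulses.
#' @export
light_state_at <- function(t_h, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  segs <- schedule$segments
  idx <- findInterval(t_h, segs$start_h)
  if (any(idx < 1) || any(t_h >= schedule$span_h))
    abort("Timestamp outside the schedule span.")
  state <- segs$state[idx]
  pl <- schedule$pulses
  if (nrow(pl) > 0) {
    for (i in seq_len(nrow(pl))) {
      hit <- t_h >= pl$start_h[i] & t_h < pl$end_h[i]
      state[hit] <- pl$state[i]
    }
  }
  state
}

#' Light on/off transition times of a schedule
#'
#' Returns every instant the light state changes (segment boundaries and
#' pulse edges), with the direction of the switch.  Used by the activity
#' simulator's masking dynamics.
#'
#' @param schedule A `light_schedule`.
#' @return Tibble with `time_h` and `to_state`.
#' @export
schedule_transitions <- function(schedule) {
  # sample the state on a fine grid is wasteful; walk segment/pulse edges
  edges <- sort(unique(c(schedule$segments$start_h, schedule$segments$end_h,
                         schedule$pulses$start_h, schedule$pulses$end_h)))
  edges <- edges[edges > 0 & edges < schedule$span_h]
  if (length(edges) == 0L)
    return(tibble::tibble(time_h = double(), to_state = character()))
  before <- light_state_at(pmax(edges - 1e-9, 0), schedule)
  after <- light_state_at(edges, schedule)
  keep <- before != after
  tibble::tibble(time_h = edges[keep], to_state = after[keep])
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %s, %.0f h span, t0 = ZT%.1f\n",
              x$label, x$span_h, x$t0_zt))
  if (nrow(x$pulses)) cat(sprintf("  %d pulse(s)\n", nrow(x$pulses)))
  invisible(x)
}

#' Is the schedule (or its tail block) free of light transitions?
#' @param schedule A `light_schedule`.
#' @return TRUE when the schedule holds a single constant light state.
#' @export
is_constant_schedule <- function(schedule) {
  length(unique(schedule$segments$state)) == 1L && nrow(schedule$pulses) == 0L
}
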