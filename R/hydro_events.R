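## Segmentation of the monitoring period into large events, small events and
## dry periods. Classification uses rain intensity alone: an event is a
## maximal wet spell whose internal rainless gaps are shorter than the
## configured separation (2 h), and it is "large" iff its maximum 10-min
## intensity exceeds the threshold (1 mm/10 min). Water level enters only the
## dry-day criterion (quiescent level, zero rain).

#' Event classification configuration
#'
#' @param intensity_threshold mm per 10-min step separating large from small
#'   events (default 1).
#' @param event_gap rainless duration (seconds) that splits two events
#'   (default 2 h).
#' @param small_window,large_window analysis-window length (seconds) attached
#'   after the event start for small (3 h) and large (14 h) events.
#' @param dry_level_sd_threshold maximum within-day standard deviation of the
#'   water level (cm) for a rain-free day to count as dry (default 0.5; a
#'   configuration choice, exposed because no universal value exists).
#' @return A validated configuration list.
#' @export
eventConfig <- function(intensity_threshold = 1.0, event_gap = 2 * 3600,
                        small_window = 3 * 3600, large_window = 14 * 3600,
                        dry_level_sd_threshold = 0.5) {
  stopifnot(intensity_threshold > 0, event_gap > 0, small_window > 0,
            large_window > 0, dry_level_sd_threshold >= 0)
  list(intensity_threshold = intensity_threshold, event_gap = event_gap,
       small_window = small_window, large_window = large_window,
       dry_level_sd_threshold = dry_level_sd_threshold)
}

#' Segment rainfall into classified events
#'
#' Every wet step (rain > 0) belongs to exactly one event; events end at the
#' last wet step before a rainless spell of at least \code{event_gap}. Events
#' touching the record boundaries are kept and flagged partial.
#'
#' @param rain rainfall \linkS4class{HydroSeries} on a regular grid.
#' @param cfg an [eventConfig()].
#' @return An \linkS4class{EventCatalog}s (dry periods empty; see
#'   [findDryPeriods()]).
#' @export
segmentEvents <- function(rain, cfg = eventConfig()) {
  r <- hydroValue(rain)
  tt <- hydroTime(rain)
  step <- if (length(r) > 1) gridSpacing(rain) else 600
  gap_steps <- ceiling(cfg$event_gap / step)
  spells <- .wet_spells(r, gap_steps)  # split at rainless gaps >= event_gap
  if (!nrow(spells)) {
    ev <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                     end = as.POSIXct(character(), tz = "UTC"),
                     kind = character(), max_intensity = numeric(),
                     total_rain = numeric(),
                     window_end = as.POSIXct(character(), tz = "UTC"),
                     partial = logical())
    return(new("EventCatalog", events = ev,
               dryPeriods = data.frame(), config = cfg))
  }
  ## rescale intensities to the 10-min reference used by the threshold
  to10 <- 600 / step
  ev <- do.call(rbind, lapply(seq_len(nrow(spells)), function(i) {
    idx <- spells$start[i]:spells$end[i]
    mx <- max(r[idx]) * to10
    kind <- if (mx > cfg$intensity_threshold) "large" else "small"
    win <- if (kind == "large") cfg$large_window else cfg$small_window
    data.frame(start = tt[spells$start[i]],
               end = tt[spells$end[i]] + step,
               kind = kind, max_intensity = mx,
               total_rain = sum(r[idx]),
               window_end = tt[spells$start[i]] + win,
               partial = (spells$start[i] <= gap_steps) ||
                         (spells$end[i] > length(r) - gap_steps))
  }))
  new("EventCatalog", events = ev, dryPeriods = data.frame(), config = cfg)
}

#' Identify dry periods
#'
#' A calendar day is dry iff its total rain is zero and the standard
#' deviation of the water level over the day is at or below the configured
#' threshold (groundwater-dominated recession days are excluded).
#' Consecutive dry days are merged.
#'
#' @param rain rainfall \linkS4class{HydroSeries}.
#' @param level water-level \linkS4class{HydroSeries}.
#' @param cfg an [eventConfig()].
#' @return data.frame with columns \code{start}, \code{end} (day bounds).
#' @export
findDryPeriods <- function(rain, level, cfg = eventConfig()) {
  rd <- as.Date(hydroTime(rain), tz = "UTC")
  ld <- as.Date(hydroTime(level), tz = "UTC")
  days <- sort(unique(rd))
  dry <- vapply(days, function(d) {
    sum(hydroValue(rain)[rd == d]) == 0 &&
      any(ld == d) &&
      sd(hydroValue(level)[ld == d]) <= cfg$dry_level_sd_threshold
  }, logical(1))
  days <- days[dry]
  if (!length(days))
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  brk <- which(diff(as.numeric(days)) > 1)
  first <- days[c(1L, brk + 1L)]
  last <- days[c(brk, length(days))]
  data.frame(start = as.POSIXct(paste(first, "00:00:00"), tz = "UTC"),
             end = as.POSIXct(paste(last, "00:00:00"), tz = "UTC") + 86400)
}

#' Classify a campaign into events and dry periods
#'
#' @inheritParams findDryPeriods
#' @return An \linkS4class{EventCatalog} with both events and dry periods.
#' @export
classifyHydrology <- function(rain, level, cfg = eventConfig()) {
  cat0 <- segmentEvents(rain, cfg)
  new("EventCatalog", events = eventTable(cat0),
      dryPeriods = findDryPeriods(rain, level, cfg), config = cfg)
}

#' Per-event and campaign rainfall summary
#'
#' @param catalog an \linkS4class{EventCatalog}.
#' @param rain the rainfall series the catalog was built from.
#' @return list with \code{events} (per-event table with duration in hours)
#'   and \code{campaign} (event counts, total rain of the whole series, total
#'   rain within events, maximum intensity).
#' @export
eventSummary <- function(catalog, rain) {
  ev <- eventTable(catalog)
  r <- hydroValue(rain)
  ev$duration_h <- as.numeric(ev$end - ev$start, units = "hours")
  list(events = ev,
       campaign = data.frame(
         n_large = sum(ev$kind == "large"),
         n_small = sum(ev$kind == "small"),
         total_rain = sum(r),
         event_rain = sum(ev$total_rain),
         max_intensity = if (nrow(ev)) max(ev$max_intensity) else 0))
}
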