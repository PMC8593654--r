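## Readers/writers for concentration tables, compound metadata and hydro
## series, plus grid alignment between the 10-min rain, 15-min level and
## 20-min chemistry grids.

.parse_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d"))
  if (any(is.na(out))) stop("unparseable timestamp(s): ",
                            paste(head(x[is.na(out)], 3), collapse = ", "))
  out
}

#' Read a compound metadata table
#'
#' CSV columns: compound_id, chem_class, legacy, loq, error_fraction, aqs,
#' rac. Missing aqs/rac cells mean "no standard defined".
#'
#' @param path CSV file path.
#' @return validated metadata \code{data.frame}.
#' @export
readCompoundMeta <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("chem_class", "legacy", "aqs", "rac"))
    if (!col %in% names(tab))
      tab[[col]] <- if (col == "legacy") FALSE else NA
  compoundMeta(tab$compound_id, tab$loq, tab$error_fraction,
               chem_class = tab$chem_class, legacy = as.logical(tab$legacy),
               aqs = tab$aqs, rac = tab$rac)
}

#' Read a wide-format concentration table
#'
#' One timestamp column plus one column per compound; an empty cell marks a
#' maintenance/QC gap. Missing grid instants are completed with explicit gap
#' rows so gap accounting stays checkable downstream. The measured value is
#' kept even below LOQ; no substitution happens at read time.
#'
#' @param path CSV file (column \code{timestamp} + one column per compound).
#' @param meta compound metadata; every non-timestamp column must be listed.
#' @return A \linkS4class{ConcentrationMatrix}.
#' @export
readConcentrationTable <- function(path, meta) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"timestamp" %in% names(tab)) stop("no 'timestamp' column")
  tt <- .parse_time(tab$timestamp)
  if (any(diff(as.numeric(tt)) <= 0))
    stop("non-monotone timestamps at row(s): ",
         paste(head(which(diff(as.numeric(tt)) <= 0) + 1L, 3), collapse = ", "))
  comps <- setdiff(names(tab), "timestamp")
  unknown <- setdiff(comps, meta$compound_id)
  if (length(unknown))
    stop("unknown compound column(s): ", paste(unknown, collapse = ", "))
  meta <- meta[match(comps, meta$compound_id), , drop = FALSE]
  vals <- as.matrix(tab[, comps, drop = FALSE])
  storage.mode(vals) <- "double"
  neg <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative concentration at row ", neg[1, 1], ", compound ",
         comps[neg[1, 2]])
  ## complete to the modal grid spacing: missing instants become gap rows
  if (length(tt) > 1) {
    d <- diff(as.numeric(tt))
    step <- min(d)
    if (any(abs(d / step - round(d / step)) > 1e-6))
      stop("timestamps are not on a common grid")
    full <- seq(tt[1], tt[length(tt)], by = step)
    idx <- match(as.numeric(full), as.numeric(tt))
    vals <- vals[idx, , drop = FALSE]
    tt <- full
  }
  gap <- apply(vals, 1L, function(r) all(is.na(r)))
  ConcentrationMatrix(tt, vals, meta, gap = gap)
}

#' Write a ConcentrationMatrix as a wide CSV
#'
#' Inverse of [readConcentrationTable()]: gap rows become empty cells.
#'
#' @param x a \linkS4class{ConcentrationMatrix}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeConcentrationTable <- function(x, path) {
  vals <- concValues(x)
  vals[gapMask(x), ] <- NA
  ## %.17g so a write -> read cycle reproduces doubles bit-exactly
  txt <- apply(vals, 2L, function(col)
    ifelse(is.na(col), "", sprintf("%.17g", col)))
  tab <- data.frame(timestamp = format(sampleTimes(x), "%Y-%m-%d %H:%M:%S"),
                    txt, check.names = FALSE)
  names(tab) <- c("timestamp", colnames(vals))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single hydro series (rain or water level)
#'
#' @param path CSV with columns \code{timestamp}, \code{value}.
#' @param unit unit label to attach.
#' @return A \linkS4class{HydroSeries}.
#' @export
readHydroSeries <- function(path, unit = "") {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  HydroSeries(.parse_time(tab$timestamp), tab$value, unit = unit)
}

#' Write a HydroSeries CSV
#' @param x a \linkS4class{HydroSeries}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHydroSeries <- function(x, path) {
  write.csv(data.frame(timestamp = format(hydroTime(x), "%Y-%m-%d %H:%M:%S"),
                       value = sprintf("%.17g", hydroValue(x))),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rebin rainfall onto a target grid, conserving total depth
#'
#' Each source interval's depth is spread uniformly over its duration and
#' integrated over the half-open target bins, so totals are conserved to
#' rounding error for any combination of spacings (no multiple/divisor
#' relationship required).
#'
#' @param rain a rainfall \linkS4class{HydroSeries} (depth per step).
#' @param spacing target spacing in seconds.
#' @param origin optional POSIXct start of the target grid (default: the
#'   source start).
#' @return A rebinned \linkS4class{HydroSeries}.
#' @export
rebinRainfall <- function(rain, spacing, origin = NULL) {
  src_t <- as.numeric(hydroTime(rain))
  src_v <- hydroValue(rain)
  if (!length(src_t)) stop("empty series")
  step <- gridSpacing(rain)
  t0 <- if (is.null(origin)) src_t[1] else as.numeric(as.POSIXct(origin, tz = "UTC"))
  t_end <- src_t[length(src_t)] + step
  nbin <- max(1L, ceiling((t_end - t0) / spacing - 1e-9))
  bin_start <- t0 + spacing * (seq_len(nbin) - 1)
  out <- numeric(nbin)
  for (i in seq_along(src_t)) {
    if (src_v[i] == 0) next
    a <- src_t[i]; b <- a + step
    j0 <- max(1L, floor((a - t0) / spacing) + 1L)
    j1 <- min(nbin, floor((b - t0 - 1e-9) / spacing) + 1L)
    for (j in j0:j1) {
      ov <- min(b, bin_start[j] + spacing) - max(a, bin_start[j])
      if (ov > 0) out[j] <- out[j] + src_v[i] * ov / step
    }
  }
  HydroSeries(as.POSIXct(bin_start, tz = "UTC", origin = "1970-01-01"),
              out, unit = rain@unit)
}

#' Interpolate water level at target grid instants
#'
#' Linear interpolation; endpoints are extended flat.
#'
#' @param level a water-level \linkS4class{HydroSeries}.
#' @param spacing target spacing in seconds.
#' @param origin optional POSIXct target-grid start.
#' @return An interpolated \linkS4class{HydroSeries}.
#' @export
interpolateLevel <- function(level, spacing, origin = NULL) {
  src_t <- as.numeric(hydroTime(level))
  if (!length(src_t)) stop("empty series")
  t0 <- if (is.null(origin)) src_t[1] else as.numeric(as.POSIXct(origin, tz = "UTC"))
  tg <- seq(t0, src_t[length(src_t)], by = spacing)
  if (!length(tg)) tg <- t0
  v <- approx(src_t, hydroValue(level), xout = tg, rule = 2)$y
  HydroSeries(as.POSIXct(tg, tz = "UTC", origin = "1970-01-01"), v,
              unit = level@unit)
}

#' Align rain and level series to one target grid
#'
#' Rainfall is mass-conservingly rebinned; water level is linearly
#' interpolated at the target instants.
#'
#' @param rain rainfall \linkS4class{HydroSeries}.
#' @param level water-level \linkS4class{HydroSeries}.
#' @param spacing target spacing in seconds (e.g. 1200 for the 20-min
#'   chemistry grid).
#' @param origin optional common grid origin.
#' @return list with elements \code{rain} and \code{level}.
#' @export
alignToGrid <- function(rain, level, spacing, origin = NULL) {
  if (is.null(origin)) origin <- min(hydroTime(rain)[1], hydroTime(level)[1])
  list(rain = rebinRainfall(rain, spacing, origin),
       level = interpolateLevel(level, spacing, origin))
}
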