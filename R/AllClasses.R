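#' @import methods
#' @importFrom stats approx rnorm runif rpois rgamma rlnorm sd quantile cor median setNames
#' @importFrom utils read.csv write.csv head
NULL

## Central S4 containers. Timestamps are timezone-naive local time stored as
## POSIXct/UTC; every interval is half-open [start, end) so composite windows
## tile the record without overlap.

#' Regular-grid hydrological time series
#'
#' A single regularly sampled series, either rainfall depth per step (mm) or
#' stream water level (cm). The value at time \code{t} refers to the half-open
#' interval \code{[t, t + spacing)}.
#'
#' @slot time ordered \code{POSIXct} instants on a constant-spacing grid.
#' @slot value nonnegative numeric values, one per instant.
#' @slot unit free-text unit label (e.g. \code{"mm/10min"}, \code{"cm"}).
#' @export
setClass("HydroSeries",
  representation(time = "POSIXct", value = "numeric", unit = "character"),
  prototype(unit = "")
)

setValidity("HydroSeries", function(object) {
  msg <- character()
  if (length(object@time) != length(object@value))
    msg <- c(msg, "time and value must have equal length")
  if (length(object@time) == 0)
    msg <- c(msg, "empty series")
  if (length(object@time) > 1) {
    d <- diff(as.numeric(object@time))
    if (any(d <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
    if (max(d) - min(d) > 1e-6) msg <- c(msg, "timestamps must lie on a regular grid")
  }
  if (any(!is.na(object@value) & object@value < 0))
    msg <- c(msg, "values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a HydroSeries
#'
#' @param time POSIXct vector on a regular grid.
#' @param value numeric values (rain depth per step or water level).
#' @param unit unit label.
#' @return A \linkS4class{HydroSeries}.
#' @export
HydroSeries <- function(time, value, unit = "") {
  new("HydroSeries", time = as.POSIXct(time, tz = "UTC"),
      value = as.numeric(value), unit = unit)
}

#' @describeIn HydroSeries grid spacing in seconds.
#' @param x a HydroSeries.
#' @export
gridSpacing <- function(x) {
  tt <- if (is(x, "HydroSeries")) x@time else x@time
  if (length(tt) < 2) stop("need at least two instants to infer spacing")
  as.numeric(tt[2]) - as.numeric(tt[1])
}

#' @describeIn HydroSeries timestamps.
#' @export
hydroTime <- function(x) x@time

#' @describeIn HydroSeries values.
#' @export
hydroValue <- function(x) x@value

setMethod("show", "HydroSeries", function(object) {
  cat(sprintf("HydroSeries: %d steps of %.0f s [%s .. %s]%s\n",
              length(object@time),
              if (length(object@time) > 1) gridSpacing(object) else NA_real_,
              format(min(object@time)), format(max(object@time)),
              if (nzchar(object@unit)) paste0(" (", object@unit, ")") else ""))
  cat(sprintf("  range: %.3g .. %.3g, total: %.4g\n",
              min(object@value), max(object@value), sum(object@value)))
})

.meta_required <- c("compound_id", "loq", "error_fraction")

.validate_meta <- function(meta) {
  msg <- character()
  miss <- setdiff(.meta_required, names(meta))
  if (length(miss))
    return(paste("compound metadata lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$compound_id)) msg <- c(msg, "duplicated compound_id")
  if (any(!is.finite(meta$loq) | meta$loq <= 0)) msg <- c(msg, "loq must be > 0")
  ef <- meta$error_fraction
  if (any(!is.finite(ef) | ef < 0 | ef > 1))
    msg <- c(msg, "error_fraction must lie in [0, 1]")
  for (std in c("aqs", "rac")) if (std %in% names(meta)) {
    v <- meta[[std]]
    if (any(!is.na(v) & v <= 0)) msg <- c(msg, paste(std, "must be > 0 when present"))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

#' Per-compound metadata table
#'
#' Builds and validates the compound metadata used throughout the package:
#' limit of quantification (LOQ, ng/l), the per-compound relative measurement
#' error fraction, and the optional acute quality standard (AQS) and
#' regulatory acceptable concentration (RAC) thresholds (ng/l).
#'
#' @param compound_id character compound identifiers (unique).
#' @param loq positive LOQ in ng/l.
#' @param error_fraction measurement error fraction in [0, 1].
#' @param chem_class one of fungicide, herbicide, insecticide, TP_fungicide,
#'   TP_herbicide (recycled; informational).
#' @param legacy logical, withdrawn ("legacy") compound.
#' @param aqs,rac optional standards in ng/l (\code{NA} when absent).
#' @return A validated \code{data.frame} with one row per compound.
#' @export
compoundMeta <- function(compound_id, loq, error_fraction,
                         chem_class = "herbicide", legacy = FALSE,
                         aqs = NA_real_, rac = NA_real_) {
  meta <- data.frame(compound_id = as.character(compound_id),
                     chem_class = chem_class, legacy = legacy,
                     loq = as.numeric(loq),
                     error_fraction = as.numeric(error_fraction),
                     aqs = as.numeric(aqs), rac = as.numeric(rac),
                     stringsAsFactors = FALSE)
  ok <- .validate_meta(meta)
  if (!isTRUE(ok)) stop(ok)
  meta
}

#' High-frequency multi-compound concentration matrix
#'
#' The central container: an \code{n x m} matrix of concentrations (ng/l) on a
#' regular 20-minute (or other) grid, with a below-LOQ mask, a per-row gap
#' mask for maintenance/QC interruptions, and the compound metadata. Raw
#' tables keep the measured value even below LOQ; substitution rules (LOQ/2
#' for factorization, LOQ for composite emulation) are applied downstream.
#'
#' @slot time ordered POSIXct instants, constant spacing.
#' @slot conc numeric matrix, samples x compounds; \code{NA} only in gap rows.
#' @slot belowLoq logical matrix, same shape.
#' @slot gap logical vector flagging gap rows.
#' @slot meta compound metadata \code{data.frame} (see [compoundMeta()]).
#' @export
setClass("ConcentrationMatrix",
  representation(time = "POSIXct", conc = "matrix", belowLoq = "matrix",
                 gap = "logical", meta = "data.frame")
)

setValidity("ConcentrationMatrix", function(object) {
  msg <- character()
  n <- length(object@time); m <- nrow(object@meta)
  if (!all(dim(object@conc) == c(n, m)))
    msg <- c(msg, "conc must be n_samples x n_compounds")
  if (!all(dim(object@belowLoq) == c(n, m)))
    msg <- c(msg, "belowLoq must match conc dimensions")
  if (length(object@gap) != n) msg <- c(msg, "gap must have one flag per sample")
  ok <- .validate_meta(object@meta)
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (n > 1) {
    d <- diff(as.numeric(object@time))
    if (any(d <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
    if (max(d) - min(d) > 1e-6) msg <- c(msg, "timestamps must be regular")
  }
  if (n && m) {
    v <- object@conc[!object@gap, , drop = FALSE]
    if (any(!is.na(v) & v < 0)) msg <- c(msg, "negative concentration outside gap rows")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ConcentrationMatrix
#'
#' @param time POSIXct sample instants (regular grid).
#' @param conc samples x compounds numeric matrix (ng/l).
#' @param meta compound metadata (see [compoundMeta()]); order must match
#'   the columns of \code{conc}.
#' @param gap optional logical gap flags (default: rows that are all \code{NA}).
#' @param belowLoq optional logical mask; recomputed from \code{conc} and the
#'   per-compound LOQ when omitted.
#' @return A \linkS4class{ConcentrationMatrix}.
#' @export
ConcentrationMatrix <- function(time, conc, meta, gap = NULL, belowLoq = NULL) {
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  if (is.null(colnames(conc))) colnames(conc) <- meta$compound_id
  if (!identical(colnames(conc), meta$compound_id))
    stop("column names of conc must match meta$compound_id in order")
  if (is.null(gap)) gap <- apply(conc, 1L, function(r) all(is.na(r)))
  if (is.null(belowLoq)) belowLoq <- loqMask(conc, meta$loq)
  new("ConcentrationMatrix", time = as.POSIXct(time, tz = "UTC"), conc = conc,
      belowLoq = belowLoq, gap = as.logical(gap), meta = meta)
}

#' Below-LOQ mask
#'
#' Pure function of the values and the per-compound LOQ; idempotent.
#'
#' @param conc samples x compounds matrix.
#' @param loq per-compound LOQ vector.
#' @return logical matrix, \code{TRUE} where the value is below the LOQ.
#' @export
loqMask <- function(conc, loq) {
  m <- sweep(conc, 2L, loq, `<`)
  dimnames(m) <- dimnames(conc)
  m
}

#' @describeIn ConcentrationMatrix concentration values (ng/l).
#' @param x a ConcentrationMatrix.
#' @export
concValues <- function(x) x@conc

#' @describeIn ConcentrationMatrix below-LOQ logical mask.
#' @export
belowLoq <- function(x) x@belowLoq

#' @describeIn ConcentrationMatrix per-sample gap flags.
#' @export
gapMask <- function(x) x@gap

#' @describeIn ConcentrationMatrix sample timestamps.
#' @export
sampleTimes <- function(x) x@time

#' @describeIn ConcentrationMatrix compound metadata table.
#' @export
compoundTable <- function(x) x@meta

setMethod("show", "ConcentrationMatrix", function(object) {
  cat(sprintf("ConcentrationMatrix: %d samples x %d compounds [%s .. %s]\n",
              length(object@time), nrow(object@meta),
              format(min(object@time)), format(max(object@time))))
  cat(sprintf("  gap rows: %d (%.1f%%); below-LOQ cells: %.1f%%\n",
              sum(object@gap), 100 * mean(object@gap),
              100 * mean(object@belowLoq[!object@gap, , drop = FALSE], na.rm = TRUE)))
})

setMethod("dim", "ConcentrationMatrix",
          function(x) c(length(x@time), nrow(x@meta)))

#' Catalog of classified hydro-meteorological periods
#'
#' Events are maximal wet spells separated by at least the configured dry gap,
#' classed \code{large}/\code{small} by maximum 10-minute rain intensity; dry
#' periods are merged runs of calendar days with zero rain and quiescent water
#' level. Events never overlap and are time-ordered.
#'
#' @slot events data.frame: start, end, kind, max_intensity, total_rain,
#'   window_end, partial.
#' @slot dryPeriods data.frame: start, end (calendar-day bounds).
#' @slot config the [eventConfig()] list used.
#' @export
setClass("EventCatalog",
  representation(events = "data.frame", dryPeriods = "data.frame",
                 config = "list")
)

setValidity("EventCatalog", function(object) {
  ev <- object@events
  if (nrow(ev) > 1) {
    if (is.unsorted(as.numeric(ev$start))) return("events not time-ordered")
    if (any(as.numeric(ev$start[-1]) < as.numeric(ev$end[-nrow(ev)])))
      return("events overlap")
  }
  if (nrow(ev) && !all(ev$kind %in% c("large", "small")))
    return("kind must be 'large' or 'small'")
  TRUE
})

#' @describeIn EventCatalog the event table.
#' @param x an EventCatalog.
#' @export
eventTable <- function(x) x@events

#' @describeIn EventCatalog the dry-period table.
#' @export
dryPeriods <- function(x) x@dryPeriods

setMethod("show", "EventCatalog", function(object) {
  ev <- object@events
  cat(sprintf("EventCatalog: %d events (%d large, %d small), %d dry periods\n",
              nrow(ev), sum(ev$kind == "large"), sum(ev$kind == "small"),
              nrow(object@dryPeriods)))
})

#' Fitted uncertainty-weighted positive matrix factorization model
#'
#' Holds the nonnegative factor profiles \code{F} (p x m, ng/l per unit
#' contribution), contributions \code{G} (n x p, dimensionless), the input
#' data and uncertainties, and the objective diagnostics. The scale ambiguity
#' is fixed by normalizing each contribution column to mean 1; factors are
#' ordered by decreasing fitted mass.
#'
#' @slot F profiles, p x m.
#' @slot G contributions, n x p.
#' @slot X input (substituted) concentration matrix, n x m.
#' @slot U uncertainty matrix, n x m.
#' @slot Qtrue full weighted least-squares objective.
#' @slot Qrobust objective excluding cells with |e/u| above the robust cutoff.
#' @slot Qexp expected objective n*m - p*(n+m).
#' @slot excluded logical matrix of robust-excluded cells.
#' @slot converged logical.
#' @slot iterations iterations used.
#' @slot runQ Qrobust of every multi-start run (length n_runs; length 1 for a
#'   single fit).
#' @slot seed RNG seed of the retained run.
#' @export
setClass("PMFModel",
  representation(F = "matrix", G = "matrix", X = "matrix", U = "matrix",
                 Qtrue = "numeric", Qrobust = "numeric", Qexp = "numeric",
                 excluded = "matrix", converged = "logical",
                 iterations = "integer", runQ = "numeric", seed = "integer")
)

setValidity("PMFModel", function(object) {
  msg <- character()
  p <- nrow(object@F)
  if (ncol(object@G) != p) msg <- c(msg, "G and F factor counts differ")
  if (any(object@F < 0) || any(object@G < 0)) msg <- c(msg, "F and G must be nonnegative")
  if (length(object@Qrobust) && length(object@Qtrue) &&
      object@Qrobust > object@Qtrue + 1e-8 * (1 + object@Qtrue))
    msg <- c(msg, "Qrobust cannot exceed Qtrue")
  if (length(msg)) msg else TRUE
})

#' @describeIn PMFModel factor profile matrix F (p x m).
#' @param object,x a PMFModel.
#' @export
profiles <- function(x) x@F

#' @describeIn PMFModel factor contribution matrix G (n x p).
#' @export
contributions <- function(x) x@G

#' @describeIn PMFModel number of factors.
#' @export
nFactors <- function(x) nrow(x@F)

#' @describeIn PMFModel robust objective value.
#' @export
qRobust <- function(x) x@Qrobust

#' @describeIn PMFModel full objective value.
#' @export
qTrue <- function(x) x@Qtrue

setMethod("fitted", "PMFModel", function(object) object@G %*% object@F)

setMethod("residuals", "PMFModel", function(object) object@X - fitted(object))

setMethod("show", "PMFModel", function(object) {
  cat(sprintf("PMFModel: p = %d factors, n = %d samples, m = %d species\n",
              nrow(object@F), nrow(object@G), ncol(object@F)))
  cat(sprintf("  Q (true) = %.4g, Q (robust) = %.4g, Q_exp = %.4g, Q_robust/Q_exp = %.3f\n",
              object@Qtrue, object@Qrobust, object@Qexp,
              object@Qrobust / object@Qexp))
  cat(sprintf("  converged: %s after %d iterations (%d runs, seed %d)\n",
              object@converged, object@iterations, length(object@runQ),
              object@seed))
})
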