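## PMF input preparation: below-LOQ substitution, the per-cell uncertainty
## matrix, per-species signal-to-noise and the bad/weak/good classification.
##
## Conventions, applied exactly at the boundaries:
##   substitution   x <  LOQ  ->  LOQ/2           (factorization input only)
##   uncertainty    x >  LOQ  ->  sqrt((a x)^2 + LOQ^2)
##                  x <= LOQ  ->  (5/6) LOQ
##   S/N distance   d = 0 for x <= LOQ, (x - u)/u for x > LOQ
##   classes        bad: S/N <= 0.2, weak: 0.2 < S/N <= 1, good: S/N > 1
## The uncertainty branch and the distance metric use the RAW measured value;
## the LOQ/2 substitution applies only to the data matrix handed to the
## factorization.

#' Substitute below-LOQ values by LOQ/2
#'
#' @param x a \linkS4class{ConcentrationMatrix}, or a plain matrix (then
#'   \code{loq} is required).
#' @param loq per-compound LOQ vector (ignored for a ConcentrationMatrix).
#' @return numeric matrix with every value below the compound's LOQ replaced
#'   by half that LOQ; other values untouched.
#' @export
substituteBelowLoq <- function(x, loq = NULL) {
  if (is(x, "ConcentrationMatrix")) {
    loq <- compoundTable(x)$loq
    x <- concValues(x)
  }
  if (is.null(loq)) stop("loq required for a plain matrix")
  half <- matrix(loq / 2, nrow(x), ncol(x), byrow = TRUE)
  out <- ifelse(!is.na(x) & x < rep(loq, each = nrow(x)), half, x)
  dimnames(out) <- dimnames(x)
  out
}

#' Per-cell measurement uncertainty
#'
#' \code{u = sqrt((a_j x)^2 + LOQ_j^2)} above the LOQ and \code{(5/6) LOQ_j}
#' at or below it, evaluated on the raw measured values.
#'
#' @param x a \linkS4class{ConcentrationMatrix} or plain matrix.
#' @param meta compound metadata (required for a plain matrix).
#' @return list with \code{u} (uncertainty matrix, strictly positive outside
#'   gap rows) and \code{substituted_x} (the LOQ/2-substituted data matrix).
#' @export
computeUncertainty <- function(x, meta = NULL) {
  if (is(x, "ConcentrationMatrix")) {
    meta <- compoundTable(x)
    x <- concValues(x)
  }
  if (is.null(meta)) stop("meta required for a plain matrix")
  if (any(meta$loq <= 0)) stop("loq must be > 0")
  n <- nrow(x)
  loqm <- matrix(meta$loq, n, ncol(x), byrow = TRUE)
  am <- matrix(meta$error_fraction, n, ncol(x), byrow = TRUE)
  u <- ifelse(!is.na(x) & x > loqm, sqrt((am * x)^2 + loqm^2), 5 / 6 * loqm)
  dimnames(u) <- dimnames(x)
  list(u = u, substituted_x = substituteBelowLoq(x, meta$loq))
}

#' Per-species signal-to-noise screening
#'
#' The distance metric is zero for censored values and \code{(x - u)/u}
#' above the LOQ (negative values, where x is between LOQ and u, contribute
#' as computed). S/N is its mean over non-gap samples; classes use the fixed
#' 0.2 and 1 cut-points.
#'
#' @param x a \linkS4class{ConcentrationMatrix} (gap rows are ignored) or a
#'   raw matrix.
#' @param u uncertainty matrix from [computeUncertainty()].
#' @param meta compound metadata (required for a plain matrix).
#' @param cutpoints length-2 numeric, the bad/weak and weak/good boundaries.
#' @return list of class \code{"ScreeningReport"}: \code{sn_ratio},
#'   \code{class} (factor bad/weak/good), and \code{d} (the distance matrix).
#' @export
signalToNoise <- function(x, u, meta = NULL, cutpoints = c(0.2, 1)) {
  if (is(x, "ConcentrationMatrix")) {
    meta <- compoundTable(x)
    keep <- !gapMask(x)
    xv <- concValues(x)[keep, , drop = FALSE]
    u <- u[keep, , drop = FALSE]
  } else xv <- x
  if (is.null(meta)) stop("meta required for a plain matrix")
  loqm <- matrix(meta$loq, nrow(xv), ncol(xv), byrow = TRUE)
  d <- ifelse(xv > loqm, (xv - u) / u, 0)
  sn <- colMeans(d)
  cls <- cut(sn, c(-Inf, cutpoints, Inf), labels = c("bad", "weak", "good"))
  names(sn) <- names(cls) <- meta$compound_id
  structure(list(sn_ratio = sn, class = cls, d = d, cutpoints = cutpoints),
            class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat("ScreeningReport:", length(x$sn_ratio), "species\n")
  print(data.frame(sn_ratio = round(x$sn_ratio, 3), class = x$class))
  invisible(x)
}

#' Assemble the factorization input
#'
#' Drops bad species, triples the uncertainty of weak species, leaves good
#' species untouched, and removes gap rows. The returned \code{m_good}
#' counts the retained species (used in the expected objective).
#'
#' @param x a \linkS4class{ConcentrationMatrix}.
#' @param report a screening report from [signalToNoise()]; computed
#'   internally when omitted.
#' @return list: \code{X} (substituted concentrations, gap rows dropped),
#'   \code{U} (adjusted uncertainties), \code{species} (kept compound ids),
#'   \code{class} (their classes), \code{m_good} (count of good-class species,
#'   the m entering the expected objective), \code{m_kept} (good + weak),
#'   \code{meta} (kept rows), \code{time} (kept sample instants),
#'   \code{report}.
#' @export
preparePmfInput <- function(x, report = NULL) {
  unc <- computeUncertainty(x)
  if (is.null(report)) report <- signalToNoise(x, unc$u)
  keep_sp <- which(report$class != "bad")
  if (length(keep_sp) < 2)
    stop("fewer than 2 non-bad species; factorization input is degenerate")
  rows <- !gapMask(x)
  X <- unc$substituted_x[rows, keep_sp, drop = FALSE]
  U <- unc$u[rows, keep_sp, drop = FALSE]
  weak <- report$class[keep_sp] == "weak"
  U[, weak] <- U[, weak, drop = FALSE] * 3
  list(X = X, U = U, species = compoundTable(x)$compound_id[keep_sp],
       class = report$class[keep_sp],
       m_good = sum(report$class[keep_sp] == "good"),
       m_kept = length(keep_sp),
       meta = compoundTable(x)[keep_sp, , drop = FALSE],
       time = sampleTimes(x)[rows], report = report)
}
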