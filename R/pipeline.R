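## End-to-end orchestration: simulate -> classify -> screen -> factorize ->
## assess, seeded from a single global seed with per-stage derived seeds so
## any stage can be rerun in isolation and reproduce its outputs exactly.

## deterministic 31-bit string hash (polynomial, mod 2^31 - 1)
.stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage seed from the global seed
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31, a deterministic function of both.
#' @export
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + .stable_hash(stage)) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param simulate generate the synthetic campaign (\code{TRUE}) or read the
#'   input files named in \code{paths} (\code{conc}, \code{meta},
#'   \code{rain}, \code{level}).
#' @param days synthetic campaign length.
#' @param p factor count for the retained model.
#' @param scan_range optional integer vector; when non-NULL a factor-number
#'   scan is run and written alongside the chosen-p model.
#' @param n_runs multi-start runs per factor count.
#' @param event_cfg an [eventConfig()].
#' @param pmf_control overrides merged into [pmfControl()].
#' @param schemes list of [samplingScheme()]s for the exposure stage.
#' @param seed global seed.
#' @param paths named list of input paths when \code{simulate = FALSE}.
#' @return configuration list.
#' @export
pipelineConfig <- function(simulate = TRUE, days = 41, p = 6,
                           scan_range = NULL, n_runs = 20,
                           event_cfg = eventConfig(),
                           pmf_control = list(),
                           schemes = list(acute = samplingScheme()),
                           seed = 1L, paths = list()) {
  ctrl <- pmfControl()
  ctrl[names(pmf_control)] <- pmf_control
  ctrl$n_runs <- n_runs
  list(simulate = simulate, days = days, p = p, scan_range = scan_range,
       event_cfg = event_cfg, pmf_control = ctrl, schemes = schemes,
       seed = as.integer(seed), paths = paths)
}

.stage_done <- function(outDir, files)
  all(file.exists(file.path(outDir, files)))

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing every intermediate as CSV/JSON under
#' \code{outDir} plus a manifest with the effective configuration and the
#' derived per-stage seeds. Deterministic given the seed; with
#' \code{resume = TRUE}, stages whose outputs already exist are skipped and
#' missing ones are recomputed identically from their derived seeds.
#'
#' @param config a [pipelineConfig()] list, or the path to a YAML file with
#'   the same fields.
#' @param outDir output directory (created).
#' @param resume skip stages whose outputs exist.
#' @return \code{outDir}, invisibly; stage results as the attribute
#'   \code{"results"}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, resume = FALSE) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- do.call(pipelineConfig, raw)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = deriveSeed(config$seed, "simulate"),
                pmf = deriveSeed(config$seed, "pmf"))
  res <- list()
  stage <- "simulate"
  tryCatch({
    ## ---- stage: inputs ----
    sim_files <- c("conc.csv", "meta.csv", "rain.csv", "level.csv")
    if (config$simulate) {
      if (!(resume && .stage_done(outDir, sim_files))) {
        sim <- simulateCampaign(seed = seeds$simulate, days = config$days)
        writeConcentrationTable(sim$cm, file.path(outDir, "conc.csv"))
        write.csv(compoundTable(sim$cm), file.path(outDir, "meta.csv"),
                  row.names = FALSE)
        writeHydroSeries(sim$rain10, file.path(outDir, "rain.csv"))
        writeHydroSeries(sim$level10, file.path(outDir, "level.csv"))
        write.csv(sim$Gtrue, file.path(outDir, "truth_G.csv"), row.names = FALSE)
        write.csv(sim$Ftrue, file.path(outDir, "truth_F.csv"), row.names = FALSE)
        if (nrow(sim$eventTable))
          write.csv(sim$eventTable, file.path(outDir, "truth_events.csv"),
                    row.names = FALSE)
      }
      meta <- readCompoundMeta(file.path(outDir, "meta.csv"))
      cm <- readConcentrationTable(file.path(outDir, "conc.csv"), meta)
      rain <- readHydroSeries(file.path(outDir, "rain.csv"), "mm/10min")
      level <- readHydroSeries(file.path(outDir, "level.csv"), "cm")
    } else {
      meta <- readCompoundMeta(config$paths$meta)
      cm <- readConcentrationTable(config$paths$conc, meta)
      rain <- readHydroSeries(config$paths$rain, "mm/10min")
      level <- readHydroSeries(config$paths$level, "cm")
    }
    res$cm <- cm

    ## ---- stage: classify ----
    stage <- "classify"
    if (!(resume && .stage_done(outDir, "events.csv"))) {
      catalog <- classifyHydrology(rain, level, config$event_cfg)
      smry <- eventSummary(catalog, rain)
      write.csv(smry$events, file.path(outDir, "events.csv"), row.names = FALSE)
      write.csv(dryPeriods(catalog), file.path(outDir, "dry_periods.csv"),
                row.names = FALSE)
      write.csv(smry$campaign, file.path(outDir, "campaign.csv"),
                row.names = FALSE)
    }
    res$events <- read.csv(file.path(outDir, "events.csv"))

    ## ---- stage: screen ----
    stage <- "screen"
    pin <- preparePmfInput(cm)
    if (!(resume && .stage_done(outDir, "screening.csv"))) {
      write.csv(data.frame(compound = names(pin$report$sn_ratio),
                           sn_ratio = pin$report$sn_ratio,
                           class = pin$report$class),
                file.path(outDir, "screening.csv"), row.names = FALSE)
    }
    res$screening <- read.csv(file.path(outDir, "screening.csv"))

    ## ---- stage: pmf ----
    stage <- "pmf"
    if (!(resume && .stage_done(outDir, c("pmf_F.csv", "pmf_G.csv")))) {
      if (!is.null(config$scan_range)) {
        scan <- scanFactorNumbers(pin$X, pin$U, config$scan_range,
                                  seed = seeds$pmf,
                                  control = config$pmf_control,
                                  m_good = pin$m_good)
        write.csv(scan, file.path(outDir, "pmf_scan.csv"), row.names = FALSE)
      }
      model <- fitPmfMulti(pin$X, pin$U, config$p, seed = seeds$pmf,
                           control = config$pmf_control, m_good = pin$m_good)
      write.csv(profiles(model), file.path(outDir, "pmf_F.csv"),
                row.names = FALSE)
      write.csv(contributions(model), file.path(outDir, "pmf_G.csv"),
                row.names = FALSE)
      fp <- fingerprints(model)
      write.csv(fp$filtered_pairs, file.path(outDir, "fingerprints.csv"),
                row.names = FALSE)
      fitq <- perSpeciesFit(model)
      jsonlite::write_json(
        list(p = config$p, Qtrue = qTrue(model), Qrobust = qRobust(model),
             Qexp = model@Qexp, ratio = qRobust(model) / model@Qexp,
             stability = attr(model, "stability"), runQ = model@runQ,
             mean_r2 = fitq$mean_r2, r2 = as.list(fitq$r2),
             seed = seeds$pmf),
        file.path(outDir, "pmf_diagnostics.json"), auto_unbox = TRUE,
        digits = NA)
      res$model <- model
    }

    ## ---- stage: exposure ----
    stage <- "exposure"
    if (!(resume && .stage_done(outDir, "exceedances.json"))) {
      for (nm in names(config$schemes)) {
        comp <- compositeTable(cm, config$schemes[[nm]])
        write.csv(comp, file.path(outDir, paste0("composites_", nm, ".csv")),
                  row.names = FALSE)
        uf <- do.call(rbind, lapply(compoundTable(cm)$compound_id, function(id)
          cbind(compound = id,
                underestimationFactor(cm, id, scheme = config$schemes[[nm]]))))
        write.csv(uf, file.path(outDir, paste0("underestimation_", nm, ".csv")),
                  row.names = FALSE)
      }
      rep1 <- exceedanceAssessment(cm, scheme = config$schemes[[1]])
      jsonlite::write_json(rep1$counts, file.path(outDir, "exceedances.json"),
                           auto_unbox = TRUE, digits = NA)
      res$exposure <- rep1
    }

    ## manifest
    cfg_str <- paste(deparse(config[c("days", "p", "n_runs", "seed")]),
                     collapse = "")
    jsonlite::write_json(
      list(seed = config$seed, stage_seeds = seeds,
           config_hash = .stable_hash(cfg_str),
           r_version = as.character(getRversion()),
           package_version = as.character(utils::packageVersion("stormPMF"))),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  structure(invisible(outDir), results = res)
}

#' Human-readable run summary
#'
#' Assembles the key tables of a pipeline run directory: event counts,
#' species screening, factor fingerprints, fit diagnostics, underestimation
#' factors and exceedance counts. Missing stage outputs are listed and a
#' partial report is still produced.
#'
#' @param runDir a [runPipeline()] output directory.
#' @return list of class \code{"PipelineReport"}.
#' @export
makeReport <- function(runDir) {
  want <- c(events = "events.csv", campaign = "campaign.csv",
            screening = "screening.csv", fingerprints = "fingerprints.csv",
            diagnostics = "pmf_diagnostics.json",
            exceedances = "exceedances.json")
  out <- list(missing = character())
  for (nm in names(want)) {
    f <- file.path(runDir, want[[nm]])
    if (!file.exists(f)) { out$missing <- c(out$missing, want[[nm]]); next }
    out[[nm]] <- if (grepl("json$", f)) jsonlite::read_json(f, simplifyVector = TRUE)
                 else read.csv(f)
  }
  uf <- list.files(runDir, "^underestimation_.*csv$", full.names = TRUE)
  if (length(uf)) out$underestimation <- read.csv(uf[1])
  class(out) <- "PipelineReport"
  out
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("Pipeline report\n")
  if (!is.null(x$campaign)) {
    cat(sprintf("  events: %d large, %d small; total rain %.1f mm (max %.1f mm/10min)\n",
                x$campaign$n_large, x$campaign$n_small, x$campaign$total_rain,
                x$campaign$max_intensity))
  }
  if (!is.null(x$screening))
    cat(sprintf("  species kept for factorization: %d of %d\n",
                sum(x$screening$class != "bad"), nrow(x$screening)))
  if (!is.null(x$diagnostics))
    cat(sprintf("  PMF: p = %d, Q_robust/Q_exp = %.3f, mean R^2 = %.3f\n",
                x$diagnostics$p, x$diagnostics$ratio, x$diagnostics$mean_r2))
  if (!is.null(x$exceedances))
    cat(sprintf("  PPPs over AQS (20-min): %d, over RAC (20-min): %d\n",
                x$exceedances$ppp_aqs_20min, x$exceedances$ppp_rac_20min))
  if (!is.null(x$underestimation) && any(x$underestimation$defined, na.rm = TRUE))
    cat(sprintf("  worst underestimation factor: %.1f\n",
                max(x$underestimation$factor, na.rm = TRUE)))
  if (length(x$missing))
    cat("  missing stage outputs:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
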