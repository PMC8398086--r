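## End-to-end study pipeline: per-(pH, T) quenching/binding fits, per-pH
## van't Hoff thermodynamics, and report rendering. The structured report
## is the source of truth; the delimited table is a rounded derived view.

#' StudyReport: results of a full pipeline run
#'
#' @slot resultsTable data.frame, one row per (pH, T) titration with the
#'   fitted Ksv, Kq, n, Kb (and SEs/diagnostics) plus the per-pH dH, dS,
#'   dG and driving force merged in.
#' @slot thermo named list (by pH) of [VantHoffFit-class] objects.
#' @slot config the configuration list used for the run.
#' @slot inputHashes named character, md5 of every input file.

#' @exportClass StudyReport
.StudyReport <- setClass("StudyReport",
  representation(resultsTable = "data.frame", thermo = "list",
                 config = "list", inputHashes = "character")
)

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport:", nrow(object@resultsTable), "titrations,",
      length(object@thermo), "van't Hoff fit(s)\n")
  print(object@resultsTable[, intersect(
    c("pH", "temperature_K", "Ksv", "Kq", "n", "Kb", "dH", "dS", "dG"),
    names(object@resultsTable))], digits = 4)
})

#' Run the full binding-study pipeline
#'
#' Each titration (a file readable by [loadTitration()] or an in-memory
#' [TitrationSeries-class]) is analysed with [analyzeTitration()]; the
#' fitted binding constants are then pooled per pH and sent through
#' [runThermoStage()] when at least two temperatures are available
#' (otherwise thermodynamics is skipped with a warning). The run is
#' deterministic given the configuration.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{titrations}{list of file paths and/or `TitrationSeries`.}
#'     \item{tau0}{lifetime, s (default 1e-8).}
#'     \item{threshold}{mechanism threshold, L/(mol s) (default 2e10).}
#'     \item{constrainedIntercept}{logical (default FALSE).}
#'     \item{window}{peak smoothing half-width, nm (default 2).}
#'   }
#' @return a [StudyReport-class].
#' @export
runPipeline <- function(config) {
  tau0 <- config$tau0 %||% 1e-8
  threshold <- config$threshold %||% 2.0e10
  ci <- isTRUE(config$constrainedIntercept)
  window <- config$window %||% 2
  tins <- config$titrations
  if (!length(tins)) stop("config$titrations is empty")
  hashes <- character()
  rows <- list()
  for (k in seq_along(tins)) {
    tin <- tins[[k]]
    if (is.character(tin)) {
      hashes[tin] <- unname(tools::md5sum(tin))
      ser <- loadTitration(tin)
    } else ser <- tin
    res <- analyzeTitration(ser, tau0 = tau0, threshold = threshold,
                            constrainedIntercept = ci, window = window)
    qf <- res$quenching; bf <- res$binding
    rows[[k]] <- data.frame(
      pH = pHValue(ser), temperature_K = temperatureK(ser),
      Ksv = qf@ksv, Ksv_se = qf@ksvSE, Kq = qf@kq,
      intercept = qf@intercept, sv_r2 = qf@r2, mechanism = qf@mechanism,
      n = bf@n, n_se = bf@nSE, Kb = bf@kb, log10Kb_se = bf@log10KbSE,
      dl_r2 = bf@r2, stoichiometry = bf@stoichiometry,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$pH, tab$temperature_K), , drop = FALSE]
  rownames(tab) <- NULL
  thermo <- list()
  okPH <- vapply(unique(tab$pH), function(p)
    length(unique(tab$temperature_K[tab$pH == p])) >= 2, logical(1))
  if (any(okPH)) {
    sub <- tab[tab$pH %in% unique(tab$pH)[okPH], ]
    thermo <- runThermoStage(sub[, c("pH", "temperature_K", "Kb")])
  }
  if (any(!okPH))
    warning("pH value(s) with a single temperature: thermodynamics skipped")
  tab$dH <- NA_real_; tab$dS <- NA_real_; tab$dG <- NA_real_
  tab$drivingForce <- NA_character_
  for (p in names(thermo)) {
    sel <- tab$pH == as.numeric(p)
    vh <- thermo[[p]]
    tab$dH[sel] <- vh@dH
    tab$dS[sel] <- vh@dS
    tab$dG[sel] <- vh@dG[match(tab$temperature_K[sel],
                               as.numeric(names(vh@dG)))]
    tab$drivingForce[sel] <- vh@drivingForce
  }
  .StudyReport(resultsTable = tab, thermo = thermo,
               config = config[setdiff(names(config), "titrations")],
               inputHashes = hashes)
}

#' Render a study report
#'
#' `format = "table"` writes a delimited summary in the conventional
#' column order (pH, T, Ksv, Kq, n, Kb, dH, dS, dG) rounded to 4
#' significant figures; `format = "json"` writes the full-precision
#' structured report (the source of truth).
#'
#' @param report a [StudyReport-class].
#' @param path output file.
#' @param format `"table"` or `"json"`.
#' @return `path`, invisibly.
#' @export
renderReport <- function(report, path, format = c("table", "json")) {
  stopifnot(is(report, "StudyReport"))
  format <- match.arg(format)
  tab <- report@resultsTable
  if (format == "table") {
    cols <- c("pH", "temperature_K", "Ksv", "Kq", "n", "Kb",
              "dH", "dS", "dG")
    out <- tab[, cols]
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = 4)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      results = tab,
      thermo = lapply(report@thermo, function(v) list(
        dH = v@dH, dS = v@dS, dH_se = v@dHSE, dS_se = v@dSSE,
        dG = as.list(v@dG), r2 = v@r2, drivingForce = v@drivingForce)),
      config = report@config,
      inputHashes = as.list(report@inputHashes))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
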