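## Plain-text on-disk formats: CSV spectra with '# key=value' header lines,
## and a JSON run manifest (schema-versioned) grouping spectrum files by
## time point.

MANIFEST_SCHEMA_VERSION <- 1L

parseError <- function(...) {
  stop(errorCondition(paste0(...), class = c("wmrsParseError", "error")))
}

fmtNum <- function(x) sprintf("%.15g", x)

#' Write a spectrum to CSV
#'
#' Raw spectra carry `# excitation_nm`, `# timestamp_h` and
#' `# integration_s` header lines and `detection_nm,counts` columns;
#' differential spectra carry `# timestamp_h` and `# n_source` and
#' `wavenumber_cm1,intensity` columns.
#'
#' @param spectrum a [RawSpectrum-class] or [WMRSpectrum-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  if (is(spectrum, "RawSpectrum")) {
    header <- c(sprintf("# excitation_nm=%s", fmtNum(spectrum@excitationNm)),
                sprintf("# timestamp_h=%s", fmtNum(spectrum@timestampH)),
                sprintf("# integration_s=%s", fmtNum(spectrum@integrationS)),
                "detection_nm,counts")
    body <- paste(fmtNum(spectrum@wavelengthNm), fmtNum(spectrum@counts),
                  sep = ",")
  } else if (is(spectrum, "WMRSpectrum")) {
    header <- c(sprintf("# timestamp_h=%s", fmtNum(spectrum@timestampH)),
                sprintf("# n_source=%d", spectrum@nSource),
                "wavenumber_cm1,intensity")
    body <- paste(fmtNum(spectrum@wavenumber), fmtNum(spectrum@intensity),
                  sep = ",")
  } else stop("unsupported spectrum class: ", class(spectrum))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' The spectrum kind is inferred from the header: an `# excitation_nm` line
#' marks a raw spectrum, an `# n_source` line a differential one.
#' Unrecognised comment lines are ignored. Malformed headers,
#' non-monotonic axes and non-finite values raise a `wmrsParseError`.
#'
#' @param path CSV file path.
#' @return A [RawSpectrum-class] or [WMRSpectrum-class].
#' @export
readSpectrumCsv <- function(path) {
  lines <- readLines(path)
  isComment <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[isComment]) {
    kv <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)\\s*$",
                                l))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- suppressWarnings(as.numeric(kv[3]))
  }
  body <- lines[!isComment]
  if (!length(body)) parseError("no data section in ", path)
  cols <- strsplit(body[1], ",")[[1]]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (ncol(dat) != 2) parseError("expected two data columns in ", path)
  if (anyNA(dat) || any(!is.finite(as.matrix(dat))))
    parseError("non-finite values in ", path)
  if (any(diff(dat[[1]]) <= 0))
    parseError("non-monotonic spectral axis in ", path)
  if (identical(cols, c("detection_nm", "counts"))) {
    if (is.null(meta$excitation_nm))
      parseError("raw spectrum missing '# excitation_nm' header in ", path)
    RawSpectrum(dat[[1]], dat[[2]], meta$excitation_nm,
                timestampH = meta$timestamp_h %||% 0,
                integrationS = meta$integration_s %||% 50)
  } else if (identical(cols, c("wavenumber_cm1", "intensity"))) {
    if (is.null(meta$n_source))
      parseError("differential spectrum missing '# n_source' header in ",
                 path)
    WMRSpectrum(dat[[1]], dat[[2]], timestampH = meta$timestamp_h %||% 0,
                nSource = meta$n_source)
  } else parseError("unrecognised column header in ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated run and its manifest to disk
#'
#' One CSV per raw spectrum under `dir/spectra/`, plus `dir/manifest.json`
#' recording scenario, scheme, seed, schedule and the relative spectrum
#' paths grouped by time point.
#'
#' @param run a [RamanRun-class].
#' @param dir output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
writeRun <- function(run, dir) {
  validObject(run)
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  groups <- lapply(seq_along(run@sets), function(ti) {
    vapply(seq_along(run@sets[[ti]]), function(si) {
      rel <- sprintf("spectra/t%03d_step%d.csv", ti, si)
      writeSpectrumCsv(run@sets[[ti]][[si]], file.path(dir, rel))
      rel
    }, character(1))
  })
  names(groups) <- fmtNum(run@scheduleH)
  manifest <- list(
    schema_version = MANIFEST_SCHEMA_VERSION,
    scenario = run@scenarioName,
    scheme = list(center_nm = run@scheme@centerNm,
                  total_range_nm = run@scheme@totalRangeNm,
                  n_steps = run@scheme@nSteps),
    seed = if (is.na(run@seed)) NULL else run@seed,
    schedule_h = run@scheduleH,
    files = groups)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run back from its manifest
#'
#' Rejects unknown schema versions and missing referenced files.
#'
#' @param manifestPath path to `manifest.json`.
#' @return A [RamanRun-class].
#' @export
readRun <- function(manifestPath) {
  m <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  if (is.null(m$schema_version) ||
      m$schema_version != MANIFEST_SCHEMA_VERSION)
    parseError("unknown manifest schema version: ",
               format(m$schema_version))
  base <- dirname(manifestPath)
  sets <- lapply(m$files, function(paths) {
    lapply(paths, function(p) {
      fp <- file.path(base, p)
      if (!file.exists(fp)) parseError("manifest references missing file ", p)
      readSpectrumCsv(fp)
    })
  })
  names(sets) <- NULL
  new("RamanRun", sets = sets,
      scenarioName = m$scenario,
      scheme = ModulationScheme(m$scheme$center_nm, m$scheme$total_range_nm,
                                m$scheme$n_steps),
      scheduleH = as.numeric(m$schedule_h),
      seed = if (is.null(m$seed)) NA_real_ else as.numeric(m$seed))
}
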