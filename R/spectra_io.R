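#' A single mass spectrum
#'
#' In-memory centroid spectrum. Peaks are stored sorted by m/z; retention
#' time is in minutes throughout the package.
#'
#' @param scan_id Scan identifier string.
#' @param ms_level 1 or 2.
#' @param rt Retention time, minutes.
#' @param mz,intensity Numeric peak vectors of equal length.
#' @param precursor_mz Precursor m/z (MS2 only).
#' @param precursor_z Precursor charge, or `NA` when the acquisition did not
#'   assign one (resolved later by charge enumeration).
#' @param precursor_intensity Optional precursor intensity.
#' @return Object of class `spectrum_record`.
#' @export
spectrum_record <- function(scan_id, ms_level, rt, mz, intensity,
                            precursor_mz = NA_real_, precursor_z = NA_integer_,
                            precursor_intensity = NA_real_) {
  ms_level <- as.integer(ms_level)
  stopifnot(ms_level %in% c(1L, 2L), length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative peak intensity", call. = FALSE)
  if (any(mz <= 0)) stop("non-positive peak m/z", call. = FALSE)
  if (ms_level == 2L && is.na(precursor_mz)) {
    stop("MS2 spectrum '", scan_id, "' lacks a precursor m/z", call. = FALSE)
  }
  ord <- order(mz)
  structure(
    list(scan_id = as.character(scan_id), ms_level = ms_level,
         rt = as.numeric(rt), mz = as.numeric(mz)[ord],
         intensity = as.numeric(intensity)[ord],
         precursor_mz = as.numeric(precursor_mz),
         precursor_z = as.integer(precursor_z),
         precursor_intensity = as.numeric(precursor_intensity)),
    class = "spectrum_record"
  )
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum %s> MS%d rt %.2f min, %d peaks", x$scan_id,
              x$ms_level, x$rt, length(x$mz)))
  if (x$ms_level == 2L) {
    cat(sprintf(", precursor %.4f m/z (z %s)", x$precursor_mz,
                ifelse(is.na(x$precursor_z), "?", x$precursor_z)))
  }
  cat("\n")
  invisible(x)
}

#' An LC-MS/MS run
#'
#' Time-ordered MS1 and MS2 spectra plus the gradient length used to scale
#' retention-time criteria.
#'
#' @param ms1,ms2 Lists of [spectrum_record()] objects.
#' @param gradient_length Gradient length, minutes (> 0).
#' @return Object of class `ms_run`.
#' @export
ms_run <- function(ms1 = list(), ms2 = list(), gradient_length = 120) {
  stopifnot(gradient_length > 0)
  for (s in c(ms1, ms2)) stopifnot(inherits(s, "spectrum_record"))
  if (any(vapply(ms1, function(s) s$ms_level, integer(1)) != 1L)) {
    stop("non-MS1 spectrum in ms1 list", call. = FALSE)
  }
  if (any(vapply(ms2, function(s) s$ms_level, integer(1)) != 2L)) {
    stop("non-MS2 spectrum in ms2 list", call. = FALSE)
  }
  ms1 <- ms1[order(vapply(ms1, function(s) s$rt, numeric(1)))]
  ms2 <- ms2[order(vapply(ms2, function(s) s$rt, numeric(1)))]
  structure(
    list(ms1 = ms1, ms2 = ms2, gradient_length = as.numeric(gradient_length)),
    class = "ms_run"
  )
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf("<ms_run> %d MS1 + %d MS2 spectra, %.0f min gradient\n",
              length(x$ms1), length(x$ms2), x$gradient_length))
  invisible(x)
}

#' Read an LC-MS/MS run from mzML or MGF
#'
#' mzML files are read through mzR and carry both MS levels; retention times
#' are converted from seconds to minutes on read. MGF files carry MS2 only,
#' so the returned run has an empty MS1 list and XIC quantification is
#' unavailable downstream. MS2 scans without a charge assignment are kept
#' with `precursor_z = NA` for later charge enumeration.
#'
#' @param path File path.
#' @param format `"auto"` (from extension), `"mzML"` or `"mgf"`.
#' @param gradient_length Gradient length in minutes; `NULL` takes the
#'   largest observed retention time rounded up to the next 10 minutes.
#' @return An [ms_run()].
#' @export
read_run <- function(path, format = c("auto", "mzML", "mgf"),
                     gradient_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzML", mgf = "mgf",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly", call. = FALSE))
  }
  if (format == "mzML") .read_mzml(path, gradient_length)
  else .read_mgf(path, gradient_length)
}

.read_mzml <- function(path, gradient_length) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L) stop("no spectra in ", path, call. = FALSE)
  ms1 <- list(); ms2 <- list()
  for (i in seq_len(nrow(hd))) {
    pk <- mzR::peaks(fh, i)
    lvl <- hd$msLevel[i]
    if (!lvl %in% c(1L, 2L)) next
    rec <- spectrum_record(
      scan_id = if (!is.null(hd$spectrumId)) hd$spectrumId[i]
                else as.character(hd$acquisitionNum[i]),
      ms_level = lvl,
      rt = hd$retentionTime[i] / 60,
      mz = pk[, 1], intensity = pk[, 2],
      precursor_mz = if (lvl == 2L) hd$precursorMZ[i] else NA_real_,
      precursor_z = if (lvl == 2L && !is.na(hd$precursorCharge[i]) &&
                        hd$precursorCharge[i] > 0L) hd$precursorCharge[i]
                    else NA_integer_,
      precursor_intensity = if (lvl == 2L) hd$precursorIntensity[i]
                            else NA_real_
    )
    if (lvl == 1L) ms1[[length(ms1) + 1L]] <- rec
    else ms2[[length(ms2) + 1L]] <- rec
  }
  if (is.null(gradient_length)) {
    gradient_length <- .default_gradient(c(ms1, ms2))
  }
  ms_run(ms1, ms2, gradient_length)
}

.default_gradient <- function(specs) {
  rt <- vapply(specs, function(s) s$rt, numeric(1))
  rt <- rt[is.finite(rt)]
  if (length(rt) == 0L) return(120)
  max(10, ceiling(max(rt) / 10) * 10)
}

.read_mgf <- function(path, gradient_length) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0L || length(begins) != length(ends)) {
    stop("corrupt MGF (unbalanced BEGIN/END IONS): ", path, call. = FALSE)
  }
  ms2 <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pep <- getv("PEPMASS")
    if (is.na(pep)) {
      stop("MGF spectrum ", k, " lacks PEPMASS", call. = FALSE)
    }
    pep_fields <- strsplit(trimws(pep), "[ \t]+")[[1]]
    charge <- getv("CHARGE")
    z <- if (is.na(charge)) NA_integer_ else {
      as.integer(sub("^([0-9]+)[+-]?$", "\\1", trimws(charge)))
    }
    rt_s <- getv("RTINSECONDS")
    peak_lines <- block[!is_kv]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    if (length(peak_lines) > 0L) {
      m <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                                 function(x) as.numeric(x[1:2])))
    } else {
      m <- matrix(numeric(0), ncol = 2)
    }
    ms2[[k]] <- spectrum_record(
      scan_id = { ttl <- getv("TITLE"); if (is.na(ttl)) paste0("index=", k) else ttl },
      ms_level = 2L,
      rt = if (is.na(rt_s)) NA_real_ else as.numeric(rt_s) / 60,
      mz = m[, 1], intensity = m[, 2],
      precursor_mz = as.numeric(pep_fields[1]),
      precursor_z = z,
      precursor_intensity = if (length(pep_fields) > 1L)
        as.numeric(pep_fields[2]) else NA_real_
    )
  }
  if (is.null(gradient_length)) gradient_length <- .default_gradient(ms2)
  ms_run(ms1 = list(), ms2 = ms2, gradient_length = gradient_length)
}

.write_mgf <- function(run, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (s in run$ms2) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$scan_id), con)
    pep <- if (is.na(s$precursor_intensity)) {
      sprintf("PEPMASS=%.6f", s$precursor_mz)
    } else {
      sprintf("PEPMASS=%.6f %.4f", s$precursor_mz, s$precursor_intensity)
    }
    writeLines(pep, con)
    if (!is.na(s$precursor_z)) {
      writeLines(sprintf("CHARGE=%d+", s$precursor_z), con)
    }
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.3f", s$rt * 60), con)
    if (length(s$mz) > 0L) {
      writeLines(sprintf("%.6f %.4f", s$mz, s$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

.write_mzml <- function(run, path) {
  specs <- c(run$ms1, run$ms2)
  specs <- specs[order(vapply(specs, function(s) s$rt, numeric(1)),
                       vapply(specs, function(s) s$ms_level, integer(1)))]
  n <- length(specs)
  if (n == 0L) stop("cannot write an empty run", call. = FALSE)
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(specs, function(s) s$ms_level, integer(1)),
    polarity = 1L,
    peaksCount = vapply(specs, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(specs, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(specs, function(s) s$rt, numeric(1)) * 60,
    basePeakMZ = vapply(specs, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(specs, function(s)
      if (length(s$mz)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = ifelse(vapply(specs, function(s) s$ms_level,
                                    integer(1)) == 2L, 25, 0),
    ionisationEnergy = 0,
    lowMZ = vapply(specs, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(specs, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = vapply(specs, function(s)
      ifelse(is.na(s$precursor_mz), 0, s$precursor_mz), numeric(1)),
    precursorCharge = vapply(specs, function(s)
      ifelse(is.na(s$precursor_z), 0L, s$precursor_z), integer(1)),
    precursorIntensity = vapply(specs, function(s)
      ifelse(is.na(s$precursor_intensity), 0, s$precursor_intensity),
      numeric(1)),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0,
    filterString = NA_character_,
    spectrumId = vapply(specs, function(s) s$scan_id, character(1)),
    centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(specs, function(s)
      ifelse(is.na(s$precursor_mz), NA_real_, s$precursor_mz), numeric(1)),
    isolationWindowLowerOffset = 0.65,
    isolationWindowUpperOffset = 0.65,
    scanWindowLowerLimit = 100,
    scanWindowUpperLimit = 2000,
    stringsAsFactors = FALSE
  )
  pks <- lapply(specs, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, path, header = hd, outformat = "mzml")
  invisible(path)
}

#' Write a results table as TSV
#'
#' Deterministic column order (as given) and fixed numeric formatting:
#' masses and m/z at 4 decimals, ppm values at 1 decimal, retention times at
#' 2 decimals. An empty table yields a header-only file.
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    low <- tolower(nm)
    if (grepl("ppm", low)) {
      out[[nm]] <- sprintf("%.1f", out[[nm]])
    } else if (grepl("^rt$|_rt$|^rt_|retention", low)) {
      out[[nm]] <- sprintf("%.2f", out[[nm]])
    } else if (grepl("mass|mz|neutral|delta", low)) {
      out[[nm]] <- sprintf("%.4f", out[[nm]])
    }
    if (is.character(out[[nm]])) out[[nm]][out[[nm]] == "NA"] <- ""
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
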