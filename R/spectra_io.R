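# Readers/writers for the spectral and tabular formats the pipeline touches,
# and the in-memory spectrum / quant-table model. MGF and MSP are parsed here
# directly: both are simple line-oriented peak-list dialects.

#' Construct an MS2 spectrum
#'
#' One precursor's fragment peak list. Peaks are sorted ascending by m/z;
#' retention time is stored in minutes.
#'
#' @param spectrum_id Identifier string.
#' @param precursor_mz Precursor (Q1) m/z in Da.
#' @param retention_time Retention time in minutes (>= 0).
#' @param mz,intensity Fragment m/z values (Da) and intensities (>= 0).
#' @return Object of class `ms2_spectrum` with a `peaks` data.frame.
#' @export
ms2_spectrum <- function(spectrum_id, precursor_mz, retention_time, mz,
                         intensity = rep(100, length(mz))) {
  stopifnot(is.character(spectrum_id), length(spectrum_id) == 1L,
            is.numeric(precursor_mz), precursor_mz > 0,
            is.numeric(retention_time), retention_time >= 0,
            length(mz) == length(intensity))
  if (length(mz) > 0L) {
    if (any(mz <= 0)) stop("fragment m/z must be positive", call. = FALSE)
    if (any(intensity < 0)) stop("intensity must be non-negative", call. = FALSE)
    # fragments must not exceed the precursor beyond a small accuracy window
    if (any(mz > precursor_mz + pmax(2e-5 * precursor_mz, 0.01))) {
      stop("fragment m/z exceeds precursor m/z in spectrum '", spectrum_id, "'",
           call. = FALSE)
    }
    ord <- order(mz)
    mz <- mz[ord]; intensity <- intensity[ord]
  }
  structure(list(spectrum_id = spectrum_id,
                 precursor_mz = precursor_mz,
                 retention_time = retention_time,
                 peaks = data.frame(mz = as.numeric(mz),
                                    intensity = as.numeric(intensity))),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s  precursor %.4f m/z  RT %.3f min  %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$retention_time, nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' One `ms2_spectrum` per BEGIN IONS/END IONS block. `RTINSECONDS` is
#' converted to minutes; `RTINMINUTES` is accepted as-is. Blocks lacking
#' `PEPMASS` are skipped with a warning and counted in the parse report
#' (attribute `parse_report`).
#'
#' @param path Path to an MGF file.
#' @return list of [ms2_spectrum()] objects; attribute `parse_report` holds
#'   `n_read` and `n_skipped`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  n_skipped <- 0L
  in_block <- FALSE
  block <- NULL
  block_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (identical(ln, "BEGIN IONS")) {
      if (in_block) stop("nested BEGIN IONS at line ", i, call. = FALSE)
      in_block <- TRUE
      block <- character(0)
      block_start <- i
    } else if (identical(ln, "END IONS")) {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i, call. = FALSE)
      sp <- .parse_mgf_block(block, block_start, length(spectra) + n_skipped + 1L)
      if (is.null(sp)) n_skipped <- n_skipped + 1L else spectra[[length(spectra) + 1L]] <- sp
      in_block <- FALSE
    } else if (in_block) {
      block <- c(block, ln)
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block starting at line ",
                     block_start, call. = FALSE)
  attr(spectra, "parse_report") <- list(n_read = length(spectra),
                                        n_skipped = n_skipped)
  spectra
}

.parse_mgf_block <- function(block, line0, idx) {
  is_kv <- grepl("^[A-Z][A-Z0-9_]*=", block)
  kv <- block[is_kv]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  if (!"PEPMASS" %in% keys) {
    warning("MGF block near line ", line0, " lacks PEPMASS; skipped",
            call. = FALSE)
    return(NULL)
  }
  pep <- suppressWarnings(as.numeric(strsplit(trimws(vals[["PEPMASS"]]),
                                              "[ \t]+")[[1]][1]))
  if (is.na(pep)) stop("unparseable PEPMASS near line ", line0, call. = FALSE)
  rt <- 0
  if ("RTINMINUTES" %in% keys) {
    rt <- as.numeric(vals[["RTINMINUTES"]])
  } else if ("RTINSECONDS" %in% keys) {
    rt <- as.numeric(vals[["RTINSECONDS"]]) / 60
  }
  id <- if ("TITLE" %in% keys) trimws(vals[["TITLE"]]) else sprintf("spectrum_%04d", idx)
  peak_lines <- block[!is_kv]
  mz <- numeric(0); inten <- numeric(0)
  if (length(peak_lines) > 0L) {
    parts <- strsplit(trimws(peak_lines), "[ \t]+")
    bad <- which(vapply(parts, function(p) {
      length(p) < 1L || anyNA(suppressWarnings(as.numeric(p[seq_len(min(2, length(p)))])))
    }, TRUE))
    if (length(bad) > 0L) {
      stop("unparseable peak line near line ", line0 + bad[1], ": '",
           peak_lines[bad[1]], "'", call. = FALSE)
    }
    mz <- vapply(parts, function(p) as.numeric(p[1]), 0.0)
    inten <- vapply(parts, function(p) if (length(p) >= 2) as.numeric(p[2]) else 100, 0.0)
  }
  ms2_spectrum(id, pep, rt, mz, inten)
}

#' Write spectra to an MGF file
#'
#' m/z values are written with 6 decimals, so [read_mgf()] round-trips the
#' peak list exactly at that precision.
#'
#' @param spectra list of [ms2_spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$spectrum_id),
                 sprintf("PEPMASS=%.6f", sp$precursor_mz),
                 sprintf("RTINSECONDS=%.6f", sp$retention_time * 60),
                 sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Read an MSP spectral-library file
#'
#' NIST-style MSP dialect: `Name:`, `PrecursorMZ:` (or `PRECURSORMZ:`),
#' optional `RetentionTime:` (minutes), `Num Peaks:` followed by
#' whitespace-separated m/z intensity pairs. Records lacking a precursor m/z
#' are skipped with a warning, mirroring [read_mgf()].
#'
#' @param path Path to an MSP file.
#' @return list of [ms2_spectrum()]; attribute `parse_report` as in
#'   [read_mgf()].
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # records are separated by blank lines; a record starts at "Name:"
  recs <- split(lines, cumsum(grepl("^Name:", lines, ignore.case = TRUE)))
  recs <- recs[names(recs) != "0"]
  spectra <- list()
  n_skipped <- 0L
  for (rec in recs) {
    rec <- rec[nzchar(trimws(rec))]
    header <- grepl("^[A-Za-z][A-Za-z ]*:", rec)
    keys <- toupper(gsub(" ", "", sub(":.*$", "", rec[header])))
    vals <- trimws(sub("^[^:]*:", "", rec[header]))
    names(vals) <- keys
    pmz_key <- intersect(c("PRECURSORMZ", "PRECURSOR_MZ", "PEPMASS"), keys)
    if (length(pmz_key) == 0L) {
      warning("MSP record '", if ("NAME" %in% keys) vals[["NAME"]] else "?",
              "' lacks PrecursorMZ; skipped", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    pep <- as.numeric(vals[[pmz_key[1]]])
    rt <- if ("RETENTIONTIME" %in% keys) as.numeric(vals[["RETENTIONTIME"]]) else 0
    id <- if ("NAME" %in% keys) vals[["NAME"]] else sprintf("spectrum_%04d", length(spectra) + 1L)
    peak_lines <- trimws(rec[!header])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    parts <- strsplit(peak_lines, "[ \t;]+")
    mz <- vapply(parts, function(p) as.numeric(p[1]), 0.0)
    inten <- vapply(parts, function(p) if (length(p) >= 2) as.numeric(p[2]) else 100, 0.0)
    if (anyNA(mz) || anyNA(inten)) stop("unparseable peak line in MSP record '",
                                        id, "'", call. = FALSE)
    spectra[[length(spectra) + 1L]] <- ms2_spectrum(id, pep, rt, mz, inten)
  }
  attr(spectra, "parse_report") <- list(n_read = length(spectra),
                                        n_skipped = n_skipped)
  spectra
}

#' Write spectra to an MSP file
#' @inheritParams write_mgf
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(paste0("Name: ", sp$spectrum_id),
                 sprintf("PrecursorMZ: %.6f", sp$precursor_mz),
                 sprintf("RetentionTime: %.6f", sp$retention_time),
                 sprintf("Num Peaks: %d", nrow(sp$peaks)),
                 sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity),
                 ""), con)
  }
  invisible(path)
}

.VALID_COLORS <- c("white", "pink", "red", "purple")

#' Construct a feature x sample quantification table
#'
#' @param values Numeric matrix (features x samples), non-negative, with
#'   feature ids as rownames and sample ids as colnames.
#' @param sample_meta data.frame with columns `sample_id`, `variety`,
#'   `color` (white/pink/red/purple), `replicate`.
#' @return Object of class `quant_table`.
#' @export
quant_table <- function(values, sample_meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  need <- c("sample_id", "variety", "color", "replicate")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!identical(colnames(values), as.character(sample_meta$sample_id))) {
    stop("sample_meta rows must match value columns in order", call. = FALSE)
  }
  bad <- setdiff(unique(sample_meta$color), .VALID_COLORS)
  if (length(bad) > 0L) {
    bad_samples <- sample_meta$sample_id[sample_meta$color %in% bad]
    stop("unknown color label(s) '", paste(bad, collapse = "', '"),
         "' for sample(s): ", paste(bad_samples, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature id: ",
         rownames(values)[anyDuplicated(rownames(values))], call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be non-negative", call. = FALSE)
  structure(list(values = values,
                 sample_meta = as.data.frame(sample_meta,
                                             stringsAsFactors = FALSE)),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$sample_meta$color)),
                            table(x$sample_meta$color)), collapse = ", ")))
  invisible(x)
}

#' Read a quant table CSV with embedded sample metadata
#'
#' Expected layout: a header row of sample ids (first cell `feature_id`),
#' then three metadata rows keyed `variety`, `color`, `replicate` in the
#' first column, then one row per feature. Blank or NA cells are imputed at
#' a per-feature floor (default: half the smallest positive value of that
#' feature) and the number of imputations is recorded in the `parse_report`
#' attribute; features and samples keep file order.
#'
#' @param path CSV path.
#' @param impute_floor Function mapping a feature's observed values to the
#'   imputation value used for its missing cells.
#' @return A [quant_table()] with attribute `parse_report`
#'   (`n_imputed`, `floor_values`).
#' @export
read_quant_csv <- function(path,
                           impute_floor = function(v) min(v[v > 0]) / 2) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  key <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  meta_rows <- c("variety", "color", "replicate")
  if (!all(meta_rows %in% key[1:3])) {
    stop("first three rows must be metadata rows: variety, color, replicate",
         call. = FALSE)
  }
  meta <- data.frame(sample_id = sample_ids,
                     variety = as.character(raw[match("variety", key), -1]),
                     color = as.character(raw[match("color", key), -1]),
                     replicate = as.integer(raw[match("replicate", key), -1]),
                     stringsAsFactors = FALSE)
  feat <- raw[-match(meta_rows, key), , drop = FALSE]
  if (anyDuplicated(feat[[1]])) {
    stop("duplicate feature id: ", feat[[1]][anyDuplicated(feat[[1]])],
         call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(feat[, -1, drop = FALSE])),
           nrow = nrow(feat),
           dimnames = list(feat[[1]], sample_ids)))
  n_imputed <- 0L
  floors <- stats::setNames(rep(NA_real_, nrow(vals)), rownames(vals))
  for (r in seq_len(nrow(vals))) {
    miss <- is.na(vals[r, ])
    if (any(miss)) {
      if (all(miss) || all(vals[r, !miss] <= 0)) {
        stop("feature '", rownames(vals)[r],
             "' has no positive value to derive an imputation floor", call. = FALSE)
      }
      fl <- impute_floor(vals[r, !miss])
      vals[r, miss] <- fl
      floors[r] <- fl
      n_imputed <- n_imputed + sum(miss)
    }
  }
  qt <- quant_table(vals, meta)
  attr(qt, "parse_report") <- list(n_imputed = n_imputed,
                                   floor_values = floors[!is.na(floors)])
  qt
}

#' Write a quant table to CSV in the layout [read_quant_csv()] expects
#' @param table A [quant_table()].
#' @param path Output CSV path.
#' @param digits Decimal digits for abundances.
#' @export
write_quant_csv <- function(table, path, digits = 6) {
  m <- table$sample_meta
  header <- paste(c("feature_id", m$sample_id), collapse = ",")
  meta_lines <- c(paste(c("variety", m$variety), collapse = ","),
                  paste(c("color", m$color), collapse = ","),
                  paste(c("replicate", m$replicate), collapse = ","))
  fmt <- paste0("%.", digits, "f")
  feat_lines <- vapply(seq_len(nrow(table$values)), function(r) {
    paste(c(rownames(table$values)[r], sprintf(fmt, table$values[r, ])),
          collapse = ",")
  }, "")
  writeLines(c(header, meta_lines, feat_lines), path)
  invisible(path)
}

#' Construct a calibration series for absolute quantitation
#'
#' @param analyte Analyte name.
#' @param concentrations Known amounts (ug/mL), strictly increasing, >= 2.
#' @param responses Instrument responses, same length.
#' @param sample_mass Extracted sample mass in g.
#' @param extract_volume Extract volume in mL.
#' @export
calibration_series <- function(analyte, concentrations, responses,
                               sample_mass, extract_volume) {
  stopifnot(length(concentrations) == length(responses),
            length(concentrations) >= 2,
            all(diff(concentrations) > 0),
            sample_mass > 0, extract_volume > 0)
  structure(list(analyte = analyte,
                 concentrations = as.numeric(concentrations),
                 responses = as.numeric(responses),
                 sample_mass = sample_mass,
                 extract_volume = extract_volume),
            class = "calibration_series")
}

#' Read calibration series from CSV
#'
#' One series per analyte; columns `analyte`, `concentration`, `response`,
#' `sample_mass`, `extract_volume` (the last two constant within an analyte).
#'
#' @param path CSV path.
#' @return Named list of [calibration_series()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "concentration", "response", "sample_mass", "extract_volume")
  if (!all(need %in% names(df))) {
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$analyte), function(d) {
    d <- d[order(d$concentration), ]
    calibration_series(d$analyte[1], d$concentration, d$response,
                       d$sample_mass[1], d$extract_volume[1])
  })
  out
}
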