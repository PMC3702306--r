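# Spectrum container and MGF (Mascot generic format) reader/writer.

#' Construct an MS/MS spectrum
#'
#' @param id spectrum identifier (MGF TITLE).
#' @param precursor_mz precursor m/z.
#' @param precursor_charge positive integer precursor charge.
#' @param peaks data.frame (or 2-column matrix) with columns `mz` and
#'   `intensity`; stored sorted by ascending m/z.
#' @param metadata named list of additional key-value pairs.
#' @return list of class `spectrum`.
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, peaks,
                     metadata = list()) {
  peaks <- as.data.frame(peaks)
  if (!nrow(peaks)) {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  } else {
    if (ncol(peaks) == 1L) peaks$intensity <- 1
    names(peaks)[1:2] <- c("mz", "intensity")
    if (any(peaks$mz <= 0)) stop("all peak m/z must be positive")
    if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
    peaks <- peaks[order(peaks$mz), 1:2, drop = FALSE]
    rownames(peaks) <- NULL
  }
  stopifnot(precursor_mz > 0, precursor_charge >= 1)
  structure(list(id = as.character(id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 peaks = peaks, metadata = metadata),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s' precursor %.4f (%d+), %d peaks>\n",
              x$id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` (first token
#' is the precursor m/z), `CHARGE` (the `2+` dialect is accepted) and peak
#' lines of one or two whitespace-separated numbers (m/z, optional
#' intensity). Unknown `KEY=value` headers are kept in `metadata`.
#'
#' @param path MGF file.
#' @return list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  title <- pepmass <- charge <- NULL
  meta <- list()
  pk_mz <- pk_int <- numeric(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", ln)
      in_block <- TRUE
      title <- pepmass <- charge <- NULL
      meta <- list()
      pk_mz <- pk_int <- numeric(0)
    } else if (line == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", ln)
      if (is.null(pepmass))
        stop("spectrum ending at line ", ln, " has no PEPMASS")
      if (is.null(charge)) charge <- 2L
      if (is.null(title)) title <- sprintf("spectrum_%d", length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <- spectrum(
        title, pepmass, charge,
        data.frame(mz = pk_mz, intensity = pk_int), meta)
      in_block <- FALSE
    } else if (!in_block) {
      next  # header material outside blocks is ignored
    } else if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") title <- val
      else if (key == "PEPMASS") {
        pepmass <- suppressWarnings(as.numeric(strsplit(trimws(val),
                                                        "\\s+")[[1]][1]))
        if (is.na(pepmass)) stop("unparseable PEPMASS at line ", ln)
      } else if (key == "CHARGE") {
        charge <- suppressWarnings(as.integer(sub("\\+$", "", trimws(val))))
        if (is.na(charge)) stop("unparseable CHARGE at line ", ln)
      } else meta[[key]] <- val
    } else {
      tok <- strsplit(line, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals) || !length(vals) %in% 1:2)
        stop("unparseable peak line ", ln, ": '", line, "'")
      pk_mz <- c(pk_mz, vals[1])
      pk_int <- c(pk_int, if (length(vals) == 2L) vals[2] else 1)
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block in ", path)
  spectra
}

#' Write spectra to an MGF file
#'
#' m/z values are written with 6 decimals so that a write/read round trip
#' preserves them at that precision.
#'
#' @param spectra a [spectrum()] or list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    for (k in names(s$metadata))
      writeLines(sprintf("%s=%s", k, s$metadata[[k]]), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.6f %.6g", s$peaks$mz, s$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
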