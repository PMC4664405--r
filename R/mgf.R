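#' Construct an MS/MS spectrum record
#'
#' @param id spectrum identifier
#' @param precursor_mz precursor m/z (> 0)
#' @param charge declared precursor charge, or NA when undetermined
#' @param peaks data.frame with columns `mz`, `intensity` (intensity >= 0);
#'   stored sorted by m/z
#' @return object of class `xl_spectrum`
#' @export
spectrum_record <- function(id, precursor_mz, charge = NA_integer_, peaks) {
  stopifnot(is.numeric(precursor_mz), precursor_mz > 0,
            all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks)) {
    stopifnot(all(peaks$mz > 0), all(peaks$intensity >= 0))
    peaks <- peaks[order(peaks$mz), c("mz", "intensity")]
    rownames(peaks) <- NULL
  }
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
                 peaks = peaks),
            class = "xl_spectrum")
}

#' Read an MGF (Mascot generic format) peak-list file
#'
#' Parses BEGIN IONS/END IONS blocks with TITLE, PEPMASS (first token is the
#' m/z), optional CHARGE (e.g. `4+`), and `m/z intensity` peak lines.
#' Unparseable blocks are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param path path to an MGF file
#' @return list of [spectrum_record()] objects
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends   <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  out <- list(); skipped <- 0L
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    rec <- tryCatch({
      kv <- grepl("=", block, fixed = TRUE)
      hdr <- strsplit(block[kv], "=", fixed = TRUE)
      keys <- toupper(vapply(hdr, `[`, "", 1L))
      vals <- vapply(hdr, function(x) paste(x[-1], collapse = "="), "")
      title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else
        sprintf("spectrum_%d", k)
      pep <- vals[keys == "PEPMASS"][1]
      pmz <- as.numeric(strsplit(trimws(pep), "\\s+")[[1]][1])
      ch <- NA_integer_
      if ("CHARGE" %in% keys) {
        cv <- vals[keys == "CHARGE"][1]
        ch <- as.integer(sub("^([0-9]+)[+-]?$", "\\1", trimws(cv)))
      }
      pk <- block[!kv]
      pk <- pk[nzchar(trimws(pk))]
      peaks <- if (length(pk)) {
        mat <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"),
                                     function(x) as.numeric(x[1:2])))
        data.frame(mz = mat[, 1], intensity = mat[, 2])
      } else data.frame(mz = numeric(), intensity = numeric())
      spectrum_record(title, pmz, ch, peaks)
    }, error = function(e) NULL)
    if (is.null(rec)) {
      skipped <- skipped + 1L
      warning(sprintf("skipping unreadable MGF block %d", k))
    } else out[[length(out) + 1L]] <- rec
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write spectra to MGF
#'
#' @param spectra list of [spectrum_record()] objects
#' @param path output path
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$id), con)
    writeLines(sprintf("PEPMASS=%.5f", s$precursor_mz), con)
    if (!is.na(s$charge)) writeLines(sprintf("CHARGE=%d+", s$charge), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.5f %.2f", s$peaks$mz, s$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
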