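# Spectrum containers and IO. A spectrum is a centroided peak list: a
# data.frame with columns mz and intensity. Supported on disk as a
# two-column TSV peak list or as MGF (BEGIN IONS / END IONS blocks with
# PEPMASS, optional CHARGE and TITLE). MGF handling is intentionally
# minimal: one peak per line, "m/z intensity".

#' Read a spectrum from a two-column peak list
#'
#' @param path TSV/whitespace-delimited file with columns m/z, intensity.
#' @return Data.frame with columns `mz`, `intensity`, sorted by m/z.
#' @export
read_peak_list <- function(path) {
  df <- read_tsv(path, header = TRUE)
  if (ncol(df) < 2L) stop("peak list needs two columns", call. = FALSE)
  spectrum(df[[1L]], df[[2L]])
}

#' Construct a spectrum
#'
#' @param mz Peak m/z values (positive).
#' @param intensity Peak intensities (non-negative, same length).
#' @return Data.frame with columns `mz`, `intensity`, sorted by m/z.
#' @export
spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ", call. = FALSE)
  }
  if (length(mz) == 0L) stop("empty spectrum", call. = FALSE)
  if (any(mz <= 0) || any(intensity < 0)) {
    stop("mz must be positive and intensity non-negative", call. = FALSE)
  }
  o <- order(mz)
  data.frame(mz = mz[o], intensity = intensity[o])
}

#' Read spectra from an MGF file
#'
#' @param path MGF file.
#' @return Named list of spectra (data.frames with `mz`, `intensity`), one
#'   per `BEGIN IONS` block, named by `TITLE` when present. Each spectrum
#'   carries attributes `pepmass` and `charge` when declared.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0L || length(begins) != length(ends)) {
    stop("malformed MGF: unmatched BEGIN IONS/END IONS", call. = FALSE)
  }
  out <- vector("list", length(begins))
  titles <- character(length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1L), 1L)
    vals <- vapply(kv, `[`, character(1L), 2L)
    peaks <- strsplit(trimws(block[!is_kv & nzchar(block)]), "[[:space:]]+")
    mz <- as.numeric(vapply(peaks, `[`, character(1L), 1L))
    intensity <- as.numeric(vapply(peaks, `[`, character(1L), 2L))
    sp <- spectrum(mz, intensity)
    if ("PEPMASS" %in% keys) {
      attr(sp, "pepmass") <-
        as.numeric(strsplit(vals[keys == "PEPMASS"], " ")[[1L]][1L])
    }
    if ("CHARGE" %in% keys) {
      attr(sp, "charge") <-
        as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1L]))
    }
    titles[i] <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1L] else
      paste0("spectrum_", i)
    out[[i]] <- sp
  }
  names(out) <- titles
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra Named list of spectra; attributes `pepmass`/`charge` are
#'   written when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  nm <- names(spectra) %||% paste0("spectrum_", seq_along(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", nm[i]), con)
    if (!is.null(attr(sp, "pepmass"))) {
      writeLines(sprintf("PEPMASS=%.6f", attr(sp, "pepmass")), con)
    }
    if (!is.null(attr(sp, "charge"))) {
      writeLines(sprintf("CHARGE=%d+", attr(sp, "charge")), con)
    }
    writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
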