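#' Per-voxel quantification result
#'
#' Container for the content of one LCModel .COORD output: the metabolite
#' concentration table (concentration, CRLB \%SD, ratio to the reference
#' metabolite), the global spectral quality numbers, and the fitting curves.
#'
#' @param records Data frame with columns `metabolite`, `concentration`,
#'   `crlb_pct` (>= 0) and `ratio`.
#' @param snr Fit signal-to-noise ratio.
#' @param fwhm_ppm Fitted linewidth in ppm.
#' @param reference Name of the ratio reference metabolite.
#' @param curves `NULL`, or a list of equal-length numeric vectors `ppm`,
#'   `data`, `fit`, `baseline`.
#' @return An object of class `quant_result`.
#' @export
quant_result <- function(records, snr = NA_real_, fwhm_ppm = NA_real_,
                         reference = "Ref", curves = NULL) {
  records <- as.data.frame(records)
  needed <- c("metabolite", "concentration", "crlb_pct", "ratio")
  if (!all(needed %in% names(records)))
    stop("`records` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (any(records$crlb_pct < 0))
    stop("CRLB values must be non-negative", call. = FALSE)
  if (!is.null(curves)) {
    lens <- lengths(curves[c("ppm", "data", "fit", "baseline")])
    if (length(unique(lens)) != 1L)
      stop("curve arrays must share one length", call. = FALSE)
  }
  structure(list(records = records, snr = snr, fwhm_ppm = fwhm_ppm,
                 reference = reference, curves = curves),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result: %d metabolite(s), S/N %.3g, FWHM %.3g ppm>\n",
              nrow(x$records), x$snr, x$fwhm_ppm))
  print(x$records, row.names = FALSE)
  invisible(x)
}

curve_chunk <- function(values) {
  # 8 values per line, fixed width: deterministic bytes
  n <- length(values)
  starts <- seq(1, n, by = 8)
  vapply(starts, function(s)
    paste(sprintf("%13.5E", values[s:min(s + 7, n)]), collapse = ""),
    character(1))
}

#' Write a synthetic .COORD file
#'
#' Emits a [quant_result] in the LCModel 6.3 COORD text layout (a
#' concentration table, the `FWHM = ... S/N = ...` line, and the four curve
#' blocks). Used as the test oracle for [parse_coord()] and by stubbed
#' fitter runs; the output is synthetic, not produced by LCModel itself.
#'
#' @param qr A [quant_result].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coord <- function(qr, path) {
  stopifnot(inherits(qr, "quant_result"))
  rec <- qr$records
  lines <- c(
    " LCModel (Version 6.3-1N) COORD output",
    "",
    sprintf("  %d lines in following concentration table = NCONC+1",
            nrow(rec) + 1L),
    sprintf("  Conc.  %%SD   /%s   Metabolite", qr$reference),
    sprintf(" %11.4E %3d%% %9.3E %s", rec$concentration,
            as.integer(round(rec$crlb_pct)), rec$ratio, rec$metabolite),
    sprintf("  FWHM = %8.3f ppm    S/N = %8.1f", qr$fwhm_ppm, qr$snr))
  if (!is.null(qr$curves)) {
    ny <- length(qr$curves$ppm)
    lines <- c(lines,
               sprintf("  %d points on ppm-axis = NY", ny),
               curve_chunk(qr$curves$ppm),
               sprintf("  NY phased data points follow"),
               curve_chunk(qr$curves$data),
               sprintf("  NY points of the fit to the data follow"),
               curve_chunk(qr$curves$fit),
               sprintf("  NY background values follow"),
               curve_chunk(qr$curves$baseline))
  }
  writeLines(lines, path)
  invisible(path)
}

read_n_numbers <- function(lines, from, n, section, found) {
  vals <- numeric(0)
  i <- from
  while (length(vals) < n && i <= length(lines)) {
    if (grepl("follow|points on ppm-axis|lines in following", lines[i]))
      break
    vals <- c(vals, suppressWarnings(
      as.numeric(regmatches(lines[i],
                            gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?",
                                     lines[i]))[[1]])))
    i <- i + 1
  }
  if (length(vals) < n)
    stop(sprintf(
      "truncated COORD file in section '%s' (%d of %d values); sections recovered so far: %s",
      section, length(vals), n,
      paste(found, collapse = ", ")), call. = FALSE)
  list(values = vals[seq_len(n)], next_line = i)
}

#' Parse an LCModel .COORD file
#'
#' Reads the concentration table (metabolite name, concentration, CRLB \%SD,
#' ratio to the reference), the `FWHM`/`S/N` line, and, when present, the
#' four fitting-curve blocks (ppm axis, phased data, fit, baseline) of an
#' LCModel 6.3 COORD file. Column spacing is free-form; other LCModel
#' versions are handled best-effort. A truncated file raises an error
#' listing the sections recovered up to the truncation point.
#'
#' @param path Path to a `.COORD` file.
#' @return A [quant_result].
#' @export
parse_coord <- function(path) {
  lines <- readLines(path, warn = FALSE)
  found <- character(0)

  tab_at <- grep("lines in following concentration table", lines)
  if (!length(tab_at))
    stop("no concentration table found; sections recovered: none",
         call. = FALSE)
  n_tab <- as.integer(sub(".*?(\\d+)\\s+lines in following.*", "\\1",
                          lines[tab_at[1]]))
  header <- lines[tab_at[1] + 1L]
  reference <- sub(".*/(\\S+)\\s+Metabolite.*", "\\1", header)
  rows <- lines[tab_at[1] + 1L + seq_len(n_tab - 1L)]
  rows <- rows[!is.na(rows)]
  rec <- do.call(rbind, lapply(rows, function(r) {
    m <- regmatches(r, regexec(
      "^\\s*([-+0-9.eE]+)\\s+(\\d+)%\\s+([-+0-9.eE]+)\\s+(\\S.*?)\\s*$", r))[[1]]
    if (length(m) != 5) return(NULL)
    data.frame(metabolite = m[5], concentration = as.numeric(m[2]),
               crlb_pct = as.numeric(m[3]), ratio = as.numeric(m[4]))
  }))
  if (is.null(rec) || nrow(rec) == 0)
    stop("concentration table present but no rows parsed; sections recovered: none",
         call. = FALSE)
  found <- c(found, "concentration table")

  snr <- NA_real_
  fwhm <- NA_real_
  qline <- grep("FWHM\\s*=", lines, value = TRUE)
  if (length(qline)) {
    m <- regmatches(qline[1], regexec(
      "FWHM\\s*=\\s*([-+0-9.eE]+)\\s*ppm\\s+S/N\\s*=\\s*([-+0-9.eE]+)",
      qline[1]))[[1]]
    if (length(m) == 3) {
      fwhm <- as.numeric(m[2])
      snr <- as.numeric(m[3])
      found <- c(found, "quality line")
    }
  }

  curves <- NULL
  ppm_at <- grep("points on ppm-axis", lines)
  if (length(ppm_at)) {
    ny <- as.integer(sub(".*?(\\d+)\\s+points on ppm-axis.*", "\\1",
                         lines[ppm_at[1]]))
    res <- read_n_numbers(lines, ppm_at[1] + 1L, ny, "ppm-axis", found)
    ppm <- res$values
    found <- c(found, "ppm axis")
    sections <- c("phased data", "fit to the data", "background")
    out <- list()
    at <- res$next_line
    for (sec in sections) {
      hit <- grep(sec, lines[at:length(lines)], fixed = TRUE)
      if (!length(hit))
        stop(sprintf("truncated COORD file: section '%s' missing; sections recovered: %s",
                     sec, paste(found, collapse = ", ")), call. = FALSE)
      res <- read_n_numbers(lines, at + hit[1], ny, sec, found)
      out[[sec]] <- res$values
      at <- res$next_line
      found <- c(found, sec)
    }
    curves <- list(ppm = ppm, data = out[["phased data"]],
                   fit = out[["fit to the data"]],
                   baseline = out[["background"]])
  }

  quant_result(rec, snr = snr, fwhm_ppm = fwhm, reference = reference,
               curves = curves)
}
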