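#' Write and read LCModel .RAW ASCII data
#'
#' Emits the time-domain FID of a fully processed (single-transient,
#' single-channel) [transient_set] in the LCModel RAW dialect: a `$NMID`
#' namelist declaring `ID`, `FMTDAT`, `VOLUME` and `TRAMP`, followed by the
#' interleaved real/imaginary pairs in the declared FORTRAN format
#' (`(2E15.6)`: scientific notation, 6-digit mantissa, so the re-read FID
#' matches within format precision). Byte output is deterministic for
#' identical input.
#'
#' @param ts A single-transient, single-channel [transient_set].
#' @param path Output `.RAW` path.
#' @param id Identifier written into the `ID` field.
#' @param volume,tramp Scaling metadata carried in the header.
#' @return `write_lcmodel_raw()`: `path`, invisibly. `read_lcmodel_raw()`:
#'   a list with `fid` (complex vector) and `header` (named list).
#' @export
write_lcmodel_raw <- function(ts, path, id = "mrspipe", volume = 1,
                              tramp = 1) {
  validate_transient_set(ts)
  if (n_transients(ts) != 1L || n_channels(ts) != 1L)
    stop("RAW export needs fully combined and averaged data ",
         "(1 transient, 1 channel)", call. = FALSE)
  fid <- get_fid(ts)
  lines <- c(
    " $NMID",
    sprintf(" ID='%s'", id),
    " FMTDAT='(2E15.6)'",
    sprintf(" VOLUME=%.5E", volume),
    sprintf(" TRAMP=%.5E", tramp),
    " $END",
    sprintf("%15.6E%15.6E", Re(fid), Im(fid)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lcmodel_raw
#' @export
read_lcmodel_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("\\$NMID", lines)[1]
  end <- grep("\\$END", lines)[1]
  if (is.na(start) || is.na(end) || end <= start)
    stop("malformed RAW file: $NMID...$END header not found", call. = FALSE)
  header <- list()
  for (ln in lines[(start + 1):(end - 1)]) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) {
      val <- gsub("^'|'$", "", m[3])
      num <- suppressWarnings(as.numeric(val))
      header[[tolower(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  nums <- scan(text = paste(lines[-seq_len(end)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(nums) %% 2 != 0)
    stop("RAW data section has an odd number of values", call. = FALSE)
  fid <- complex(real = nums[c(TRUE, FALSE)],
                 imaginary = nums[c(FALSE, TRUE)])
  list(fid = fid, header = header)
}

# Compact scientific formatting for control-file values: strips redundant
# mantissa zeros, e.g. 2.5e-04 rather than 2.500000e-04.
fmt_control_number <- function(x) {
  if (x == round(x) && abs(x) < 1e7) return(sprintf("%d", as.integer(x)))
  if (abs(x) >= 0.01 && abs(x) < 1e6) return(sprintf("%.6g", x))
  s <- sprintf("%.6e", x)
  s <- sub("(\\.\\d*?)0+e", "\\1e", s)
  sub("\\.e", "e", s)
}

#' Fill an LCModel control file from a template
#'
#' Takes a control-file template (an LCModel `$LCMODL ... $END` namelist as
#' text or a file path) and substitutes or appends parameters. With a
#' [transient_set] supplied, the acquisition-derived keys are filled
#' automatically: `DELTAT` (dwell time, s), `HZPPPM` (f0, MHz) and `NUNFIL`
#' (points). `overrides` uses friendly names mapped onto LCModel keys:
#' `basis` (`FILBAS`), `water_conc` (`WCONC`), `ppmst`, `ppmend`, `echot`;
#' any other name is uppercased and passed through. Each key ends up on
#' exactly one line; all untouched template lines are preserved verbatim, so
#' calling with no `ts` and no overrides is the identity.
#'
#' @param template Character vector of lines, a single string, or a path.
#' @param ts Optional [transient_set] the fit will consume.
#' @param overrides Named list of parameter overrides.
#' @param path Optional output path.
#' @return Character vector of control-file lines (invisibly when `path`
#'   is given).
#' @export
generate_control_file <- function(template, ts = NULL, overrides = list(),
                                  path = NULL) {
  lines <- if (length(template) == 1 && !grepl("\n", template) &&
                 file.exists(template)) readLines(template, warn = FALSE)
           else unlist(strsplit(template, "\n", fixed = TRUE))
  end_idx <- grep("^\\s*\\$END\\s*$", lines)
  if (!length(grep("\\$LCMODL", lines)) || !length(end_idx))
    stop("malformed control template: $LCMODL ... $END namelist not found",
         call. = FALSE)
  end_idx <- end_idx[length(end_idx)]

  key_map <- c(basis = "FILBAS", water_conc = "WCONC", ppmst = "PPMST",
               ppmend = "PPMEND", echot = "ECHOT", deltat = "DELTAT",
               hzpppm = "HZPPPM", nunfil = "NUNFIL")
  settings <- list()
  if (!is.null(ts)) {
    validate_transient_set(ts)
    settings$DELTAT <- ts$dwell_time
    settings$HZPPPM <- ts$f0
    settings$NUNFIL <- n_points(ts)
  }
  for (nm in names(overrides)) {
    key <- if (nm %in% names(key_map)) key_map[[nm]] else toupper(nm)
    settings[[key]] <- overrides[[nm]]
  }

  for (key in names(settings)) {
    val <- settings[[key]]
    val_str <- if (is.character(val)) sprintf("'%s'", val)
               else if (is.logical(val)) if (val) ".TRUE." else ".FALSE."
               else fmt_control_number(val)
    new_line <- sprintf(" %s = %s", key, val_str)
    hit <- grep(sprintf("^\\s*%s\\s*=", key), lines, ignore.case = TRUE)
    if (length(hit)) {
      lines[hit[1]] <- new_line
      if (length(hit) > 1) {
        lines <- lines[-hit[-1]]
        end_idx <- grep("^\\s*\\$END\\s*$", lines)
        end_idx <- end_idx[length(end_idx)]
      }
    } else {
      lines <- append(lines, new_line, after = end_idx - 1L)
      end_idx <- end_idx + 1L
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
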