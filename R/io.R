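## Plain-text readers and writers for the pipeline's interchange formats.
## Header metadata lines use the comment form "# key = value".

parseHeaderMeta <- function(lines) {
  hd <- grep("^\\s*#", lines, value = TRUE)
  kv <- regmatches(hd, regexec("#\\s*([A-Za-z0-9_.]+)\\s*[=:]\\s*([^#]*)", hd))
  out <- list()
  for (m in kv) {
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      out[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  out
}

#' Read a 1-D diffraction trace from two-column text
#'
#' Whitespace- or comma-delimited (abscissa, counts) with header comment
#' lines declaring the convention, e.g. \code{# units = q} (or
#' \code{twotheta}) and \code{# wavelength = 1.54}.
#'
#' @param path file path.
#' @param units,wavelength overrides for the header declarations.
#' @return a \linkS4class{DiffractionPattern}.
#' @export
readDiffractionPattern <- function(path, units = NULL, wavelength = NULL) {
  lines <- readLines(path)
  meta <- parseHeaderMeta(lines)
  dataLines <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  dataLines <- dataLines[nzchar(trimws(dataLines))]
  xy <- do.call(rbind, lapply(strsplit(trimws(dataLines), "[,[:space:]]+"),
                              function(t) as.numeric(t[1:2])))
  units <- units %||% meta$units %||% "q"
  wavelength <- wavelength %||% meta$wavelength %||%
    stop("wavelength not declared in header or arguments", call. = FALSE)
  diffractionPattern(xy[, 1], xy[, 2], wavelength = wavelength,
                     units = units, metadata = meta)
}

#' Write a diffraction pattern as two-column text
#'
#' @param pattern a \linkS4class{DiffractionPattern}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDiffractionPattern <- function(pattern, path) {
  hd <- c("# units = q", sprintf("# wavelength = %g", pattern@wavelength))
  writeLines(c(hd, sprintf("%.8g %.8g", pattern@q, pattern@counts)), path)
  invisible(path)
}

#' Read a structure-factor table with contrast metadata
#'
#' CSV with columns (h, f, sd) and header comments
#' \code{# d_spacing = }, \code{# d2o_fraction = }, \code{# d7_fraction = },
#' optionally \code{# signed = 1}.
#'
#' @param path file path.
#' @return a \linkS4class{StructureFactorSet}.
#' @export
readStructureFactorSet <- function(path) {
  lines <- readLines(path)
  meta <- parseHeaderMeta(lines)
  tab <- utils::read.csv(text = paste(grep("^\\s*#", lines, invert = TRUE,
                                           value = TRUE), collapse = "\n"))
  names(tab) <- tolower(names(tab))
  structureFactorSet(
    d = meta$d_spacing %||% stop("header must declare d_spacing", call. = FALSE),
    h = tab$h, f = tab$f, sd = tab$sd,
    d2oFraction = meta$d2o_fraction %||% 0,
    d7Fraction = meta$d7_fraction %||% 0,
    signed = isTRUE((meta$signed %||% 0) == 1))
}

#' Write a structure-factor table
#'
#' @param set a \linkS4class{StructureFactorSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructureFactorSet <- function(set, path) {
  hd <- c(sprintf("# d_spacing = %g", set@d),
          sprintf("# d2o_fraction = %g", set@d2oFraction),
          sprintf("# d7_fraction = %g", set@d7Fraction),
          sprintf("# signed = %d", as.integer(set@signed)))
  body <- c("h,f,sd", sprintf("%d,%.8g,%.8g", set@h, set@f, set@sd))
  writeLines(c(hd, body), path)
  invisible(path)
}

#' Write an SLD profile as three-column text (z, rho, sd)
#'
#' @param profile an \linkS4class{SLDProfile}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSLDProfile <- function(profile, path) {
  hd <- c(sprintf("# d_spacing = %g", profile@d),
          sprintf("# hmax = %d", profile@hmax),
          sprintf("# scale = %s", profile@scale))
  sdv <- if (length(profile@sdBand)) profile@sdBand else rep(0, length(profile@z))
  writeLines(c(hd, sprintf("%.6f %.8g %.8g", profile@z, profile@rho, sdv)), path)
  invisible(path)
}
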