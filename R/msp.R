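#' Read and write NIST MSP spectral libraries
#'
#' The MSP text format holds one or more records, each starting with
#' `Name:` and carrying `Num Peaks: n` followed by exactly n
#' `mz intensity` pairs separated by semicolons and/or newlines. Optional
#' header fields `InChIKey:`, `MW:`, `Formula:` and `Comments:` are mapped
#' onto spectrum metadata. Records are separated by blank lines.
#'
#' @param text a single string or character vector of lines.
#' @return `parse_msp()`: a list of [spectrum()] objects (possibly empty).
#' @examples
#' txt <- c("Name: toy", "Num Peaks: 2", "26 10; 82 100", "")
#' parse_msp(txt)
#' @export
parse_msp <- function(text) {
  lines <- .as_lines(text)
  # split into records at blank lines before each "Name:"
  starts <- grep("^[Nn]ame:", lines)
  if (length(starts) == 0L) return(list())
  ends <- c(starts[-1L] - 1L, length(lines))
  mapply(function(a, b) .parse_msp_record(lines[a:b]),
         starts, ends, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

.parse_msp_record <- function(lines) {
  hdr_pat <- "^([A-Za-z][A-Za-z ]*):[[:space:]]*(.*)$"
  meta <- list()
  np <- NA_integer_
  peak_lines <- character()
  past_header <- FALSE
  name <- NULL
  for (ln in lines) {
    if (!past_header && grepl(hdr_pat, ln)) {
      key <- tolower(sub(hdr_pat, "\\1", ln))
      val <- trimws(sub(hdr_pat, "\\2", ln))
      switch(key,
        "name"     = { name <- val; meta$name <- val },
        "inchikey" = meta$inchikey <- val,
        "mw"       = meta$mw <- suppressWarnings(as.numeric(val)),
        "formula"  = meta$formula <- val,
        "comments" = meta$comments <- val,
        "num peaks" = {
          np <- suppressWarnings(as.integer(val))
          past_header <- TRUE
        },
        meta[[gsub(" ", "_", key)]] <- val
      )
    } else if (past_header && nzchar(trimws(ln))) {
      peak_lines <- c(peak_lines, ln)
    }
  }
  if (is.null(name))
    stop("MSP format error: record without Name:", call. = FALSE)
  if (is.na(np))
    stop("MSP format error: record '", name, "' missing Num Peaks:",
         call. = FALSE)
  nums <- if (length(peak_lines)) .parse_xy_pairs(peak_lines)
          else matrix(numeric(), ncol = 2L)
  if (nrow(nums) != np)
    stop("MSP integrity error: record '", name, "' declares ", np,
         " peaks but contains ", nrow(nums), call. = FALSE)
  bin_to_unit_mass(nums[, 1L], nums[, 2L], meta = meta)
}

#' @rdname parse_msp
#' @param spectra a list of [spectrum()] objects.
#' @param path optional output file path.
#' @return `write_msp()`: character vector of file lines (invisible when
#'   `path` given).
#' @export
write_msp <- function(spectra, path = NULL) {
  stopifnot(is.list(spectra), all(vapply(spectra, is_spectrum, logical(1))))
  out <- unlist(lapply(spectra, function(s) {
    m <- s$meta
    c(paste0("Name: ", if (!is.null(m$name)) m$name else "UNKNOWN"),
      if (!is.null(m$inchikey)) paste0("InChIKey: ", m$inchikey),
      if (!is.null(m$mw)) paste0("MW: ", .fmt_num(m$mw)),
      if (!is.null(m$formula)) paste0("Formula: ", m$formula),
      if (!is.null(m$comments)) paste0("Comments: ", m$comments),
      paste0("Num Peaks: ", length(s$mz)),
      paste0(s$mz, " ", .fmt_num(s$intensity), ";"),
      "")
  }))
  if (is.null(out)) out <- character()
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname parse_msp
#' @export
read_msp <- function(path) parse_msp(readLines(path, warn = FALSE))
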