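#' Parse a JCAMP-DX mass spectrum
#'
#' Reads the JCAMP-DX 4.24 subset emitted by common EI exporters: labelled
#' lines `##LABEL=value`, an AFFN `##PEAK TABLE=(XY..XY)` block with one or
#' more comma- or space-separated x,y pairs per line, terminated by
#' `##END=`. Compressed (ASDF) ordinate forms are not supported. Raw m/z
#' values are unit-mass binned with [bin_to_unit_mass()]; all labels other
#' than the structural ones are preserved in order under `meta$labels` so
#' that `parse_jcamp(write_jcamp(s))` is lossless.
#'
#' @param text a single string or character vector of lines containing one
#'   JCAMP-DX document with `##TITLE`, `##NPOINTS`, a peak table and
#'   `##END`.
#' @return An [spectrum()] object. `meta$name` is taken from `##TITLE`.
#' @examples
#' doc <- c("##TITLE=toy", "##JCAMP-DX=4.24", "##DATA TYPE=MASS SPECTRUM",
#'          "##XUNITS=M/Z", "##YUNITS=RELATIVE INTENSITY", "##NPOINTS=3",
#'          "##PEAK TABLE=(XY..XY)", "26,10 54,40 82,100", "##END=")
#' parse_jcamp(doc)
#' @export
parse_jcamp <- function(text) {
  lines <- .as_lines(text)
  lab_idx <- grep("^##", lines)
  if (length(lab_idx) == 0L)
    stop("not a JCAMP-DX document: no ## labels found", call. = FALSE)

  labels <- list()   # ordered label -> value (first occurrence wins)
  peak_lines <- character()
  in_table <- FALSE
  for (ln in lines) {
    if (grepl("^##", ln)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) next
      key <- toupper(trimws(substr(ln, 3L, eq - 1L)))
      val <- trimws(substr(ln, eq + 1L, nchar(ln)))
      in_table <- identical(key, "PEAK TABLE")
      if (key == "END") break
      if (!in_table && is.null(labels[[key]])) labels[[key]] <- val
    } else if (in_table && nzchar(trimws(ln))) {
      peak_lines <- c(peak_lines, ln)
    }
  }
  for (req in c("TITLE", "NPOINTS")) {
    if (is.null(labels[[req]]))
      stop("JCAMP-DX format error: missing required label ##", req,
           call. = FALSE)
  }
  if (length(peak_lines) == 0L)
    stop("JCAMP-DX format error: missing required label ##PEAK TABLE",
         call. = FALSE)

  npoints <- suppressWarnings(as.integer(labels[["NPOINTS"]]))
  if (is.na(npoints))
    stop("JCAMP-DX format error: non-numeric ##NPOINTS", call. = FALSE)

  nums <- .parse_xy_pairs(peak_lines)
  if (nrow(nums) != npoints)
    stop("JCAMP-DX integrity error: ##NPOINTS=", npoints, " but ",
         nrow(nums), " peak pairs found", call. = FALSE)

  meta <- list(name = labels[["TITLE"]])
  mw <- suppressWarnings(as.numeric(labels[["MW"]]))
  if (length(mw) == 1L && !is.na(mw)) meta$mw <- mw
  extra <- labels[setdiff(names(labels),
                          c("TITLE", "JCAMP-DX", "DATA TYPE", "XUNITS",
                            "YUNITS", "NPOINTS"))]
  if (length(extra)) meta$labels <- extra
  bin_to_unit_mass(nums[, 1L], nums[, 2L], meta = meta)
}

#' Write a spectrum as a JCAMP-DX document
#'
#' Emits the fixed label set `##TITLE`, `##JCAMP-DX`, `##DATA TYPE`,
#' `##XUNITS`, `##YUNITS`, any preserved extra labels, `##NPOINTS`,
#' `##PEAK TABLE=(XY..XY)` (one `mz,intensity` pair per line) and `##END=`.
#' Output is byte-identical for identical input.
#'
#' @param s an [spectrum()] object.
#' @param path optional file path; when given the document is written there.
#' @return Invisibly (when `path` given) or visibly, a character vector of
#'   document lines.
#' @export
write_jcamp <- function(s, path = NULL) {
  stopifnot(is_spectrum(s))
  title <- if (!is.null(s$meta$name)) s$meta$name else "UNKNOWN"
  extra <- s$meta$labels
  out <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=MASS SPECTRUM",
    "##XUNITS=M/Z",
    "##YUNITS=RELATIVE INTENSITY",
    if (length(extra)) paste0("##", names(extra), "=", unlist(extra)),
    paste0("##NPOINTS=", length(s$mz)),
    "##PEAK TABLE=(XY..XY)",
    paste0(s$mz, ",", .fmt_num(s$intensity)),
    "##END="
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname parse_jcamp
#' @param path path to a `.jdx` file.
#' @export
read_jcamp <- function(path) parse_jcamp(readLines(path, warn = FALSE))

# -- internal helpers -------------------------------------------------------

.as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

# parse whitespace/comma/semicolon separated x,y pairs from table lines
.parse_xy_pairs <- function(lines) {
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[,;[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals)))
    stop("format error: non-numeric value in peak table: ",
         paste(utils::head(toks[is.na(vals)], 3L), collapse = " "),
         call. = FALSE)
  if (length(vals) %% 2L != 0L)
    stop("format error: odd number of values in peak table", call. = FALSE)
  matrix(vals, ncol = 2L, byrow = TRUE)
}

# stable numeric formatting: integers without decimals, 15 significant
# digits otherwise, never scientific — keeps writes byte-reproducible
.fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15,
         format(round(x), scientific = FALSE, trim = TRUE),
         format(x, digits = 15, scientific = FALSE, trim = TRUE))
}
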