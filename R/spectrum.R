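#' Construct an EI mass spectrum
#'
#' A spectrum is a unit-mass (nominal) peak list: strictly increasing
#' positive integer m/z with non-negative real intensities, at least one of
#' them positive, plus optional compound metadata. This is the common
#' currency of the package: parsers produce it, the assembler produces it,
#' and the similarity scores consume it.
#'
#' @param mz integer vector of nominal masses (Da), strictly increasing
#'   after construction; duplicates are merged by summing intensities.
#' @param intensity non-negative numeric vector, same length as `mz`.
#' @param meta named list of metadata. Recognised fields: `name`,
#'   `inchikey` (27-char standard or 14-char block), `mw` (Da), `formula`,
#'   `class_label`. Unrecognised fields are kept as-is (used for lossless
#'   JCAMP label round-trips).
#' @return An object of class `eims_spectrum`: a list with elements `mz`,
#'   `intensity` and `meta`.
#' @examples
#' s <- spectrum(c(26, 54, 82), c(10, 40, 100), meta = list(name = "toy"))
#' base_peak(s)
#' @export
spectrum <- function(mz, intensity, meta = list()) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (length(mz) == 0L)
    stop("spectrum must contain at least one peak", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("mz and intensity must be finite", call. = FALSE)
  if (any(mz != round(mz)) || any(mz <= 0))
    stop("mz must be positive integers (unit-mass binned)", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  mz <- as.integer(round(mz))
  # merge duplicate nominal masses, then sort
  if (anyDuplicated(mz)) {
    agg <- rowsum(intensity, group = mz)
    mz <- as.integer(rownames(agg))
    intensity <- as.numeric(agg[, 1L])
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- as.numeric(intensity[o])
  if (!any(intensity > 0))
    stop("spectrum must contain at least one peak with intensity > 0",
         call. = FALSE)
  structure(list(mz = mz, intensity = intensity, meta = as.list(meta)),
            class = "eims_spectrum")
}

#' @export
print.eims_spectrum <- function(x, ...) {
  nm <- x$meta$name
  cat("EI mass spectrum", if (!is.null(nm)) paste0("'", nm, "'"), "\n")
  cat("  peaks:", length(x$mz),
      " m/z range:", min(x$mz), "-", max(x$mz),
      " base peak: m/z", base_peak(x), "\n")
  invisible(x)
}

#' @export
format.eims_spectrum <- function(x, ...) {
  paste0("<eims_spectrum: ", length(x$mz), " peaks, base m/z ",
         base_peak(x), ">")
}

#' @rdname spectrum
#' @param x object to test or query.
#' @export
is_spectrum <- function(x) inherits(x, "eims_spectrum")

#' @rdname spectrum
#' @export
base_peak <- function(x) {
  stopifnot(is_spectrum(x))
  x$mz[which.max(x$intensity)]
}

#' @rdname spectrum
#' @export
n_peaks <- function(x) {
  stopifnot(is_spectrum(x))
  length(x$mz)
}

#' Bin a raw peak list to unit (nominal) mass
#'
#' Raw m/z values are mapped to nominal integers by round-half-up
#' (`floor(x + 0.5)`), the deterministic convention of unit-mass EI library
#' spectra. Intensities of peaks falling into the same integer bin are
#' summed, so total intensity is conserved exactly.
#'
#' @param mz numeric vector of raw m/z values, all > 0.5 so that no peak
#'   rounds to a non-positive mass.
#' @param intensity non-negative numeric vector of intensities.
#' @param meta metadata list passed through to the resulting spectrum.
#' @return An [spectrum()] object on the integer m/z grid.
#' @examples
#' bin_to_unit_mass(c(99.8, 100.2), c(30, 50))  # one peak at m/z 100
#' @export
bin_to_unit_mass <- function(mz, intensity, meta = list()) {
  if (any(!is.finite(mz)) || any(mz <= 0.5))
    stop("raw m/z values must be finite and > 0.5", call. = FALSE)
  spectrum(floor(mz + 0.5), intensity, meta = meta)
}

#' Normalize a spectrum to a fixed base-peak intensity
#'
#' Rescales intensities linearly so the base peak equals `scale`
#' (999 by convention for EI library spectra). Both similarity scores are
#' scale-invariant, so this is presentation-only; it never changes the m/z
#' set.
#'
#' @param s an [spectrum()] object with at least one positive intensity.
#' @param scale target base-peak intensity, default 999.
#' @return The rescaled spectrum.
#' @export
normalize_base_peak <- function(s, scale = 999) {
  stopifnot(is_spectrum(s))
  mx <- max(s$intensity)
  if (mx <= 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
  s$intensity <- s$intensity * (scale / mx)
  s
}
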