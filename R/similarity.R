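#' Align two unit-mass spectra on a common m/z grid
#'
#' Builds the sorted union of both m/z sets and places each spectrum's
#' intensities on that grid, with zeros where a peak is absent. This is the
#' standard peak-matching step of library search at unit-mass resolution:
#' peaks match iff their nominal masses are identical.
#'
#' @param a,b [spectrum()] objects (the "unknown" and the "library"
#'   spectrum; both scores are symmetric so the roles are interchangeable).
#' @return An object of class `eims_aligned`: list with `grid` (integer
#'   m/z), `i_u` and `i_l` (intensity vectors on the grid).
#' @export
align_spectra <- function(a, b) {
  stopifnot(is_spectrum(a), is_spectrum(b))
  grid <- sort(unique(c(a$mz, b$mz)))
  i_u <- numeric(length(grid))
  i_l <- numeric(length(grid))
  i_u[match(a$mz, grid)] <- a$intensity
  i_l[match(b$mz, grid)] <- b$intensity
  structure(list(grid = grid, i_u = i_u, i_l = i_l),
            class = "eims_aligned")
}

.score_from_vectors <- function(u, l) {
  su <- sum(u * u)
  sl <- sum(l * l)
  if (su <= 0 || sl <= 0)
    stop("cannot score: zero-norm intensity/weight vector", call. = FALSE)
  cross <- sum(u * l)
  # sqrt(cross^2 / (su*sl)) == |cross|/sqrt(su*sl); clamp for fp safety
  val <- min(1, abs(cross) / sqrt(su * sl))
  as.integer(floor(1000 * val + 0.5))  # round half up to 0..1000
}

#' Cosine similarity match factor
#'
#' The plain spectral cosine on the aligned intensity vectors, reported as
#' an integer match factor on the 0-1000 scale:
#' `round(1000 * |I_U . I_L| / (||I_U|| ||I_L||))`. Symmetric and invariant
#' to rescaling either spectrum.
#'
#' @param a,b [spectrum()] objects, or `a` an `eims_aligned` pair (then `b`
#'   is ignored).
#' @return Integer score in `[0, 1000]`.
#' @examples
#' s1 <- spectrum(c(10, 20), c(100, 50))
#' s2 <- spectrum(c(10, 20), c(50, 100))
#' cosine_score(s1, s2)  # 800
#' @export
cosine_score <- function(a, b = NULL) {
  p <- if (inherits(a, "eims_aligned")) a else align_spectra(a, b)
  .score_from_vectors(p$i_u, p$i_l)
}

#' Mass-weighted dot-product match factor
#'
#' The weighted dot product of GC-MS library search: each aligned peak is
#' replaced by the weight `W = intensity^m * mz^n` (zero where the peak is
#' absent) and the cosine of the weight vectors is reported on the 0-1000
#' scale. With the defaults `m = 0.6`, `n = 3` high-m/z, structure-specific
#' fragments dominate the score, which is why a prediction that loses or
#' misweights peaks near the molecular ion is penalized much harder by this
#' score than by [cosine_score()]. With `m = 1`, `n = 0` it reduces exactly
#' to the cosine.
#'
#' @inheritParams cosine_score
#' @param m intensity exponent (>= 0), default 0.6.
#' @param n mass exponent (>= 0), default 3.
#' @return Integer score in `[0, 1000]`.
#' @examples
#' s1 <- spectrum(c(10, 20), c(100, 50))
#' s2 <- spectrum(c(10, 20), c(50, 100))
#' weighted_dot_score(s1, s2)            # 994: both high peaks at m/z 20
#' weighted_dot_score(s1, s2, m = 1, n = 0)  # 800 == cosine
#' @export
weighted_dot_score <- function(a, b = NULL, m = 0.6, n = 3) {
  stopifnot(m >= 0, n >= 0)
  p <- if (inherits(a, "eims_aligned")) a else align_spectra(a, b)
  mzp <- as.numeric(p$grid)^n
  w_u <- ifelse(p$i_u > 0, p$i_u^m * mzp, 0)
  w_l <- ifelse(p$i_l > 0, p$i_l^m * mzp, 0)
  .score_from_vectors(w_u, w_l)
}

#' Score a spectrum pair with both match factors
#'
#' @inheritParams weighted_dot_score
#' @return Named numeric vector `c(dot = ..., cos = ...)`.
#' @export
score_pair <- function(a, b, m = 0.6, n = 3) {
  p <- align_spectra(a, b)
  c(dot = weighted_dot_score(p, m = m, n = n), cos = cosine_score(p))
}
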