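#' Construct a CD spectrum
#'
#' A `cd_spectrum` is an ellipticity trace on a strictly ascending, uniform
#' wavelength grid.  Units are arbitrary (instrument ellipticity); the only
#' requirement downstream is that a spectrum and the basis it is decomposed
#' against share consistent units.
#'
#' @param wavelengths Wavelength grid in nm, strictly ascending, uniform
#'   spacing.
#' @param ellipticity Ellipticity values, one per wavelength.
#' @param metadata Named list of free-form metadata (salt, crowder, ...).
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, ellipticity, metadata = list()) {
  wavelengths <- as.numeric(wavelengths)
  ellipticity <- as.numeric(ellipticity)
  if (length(wavelengths) != length(ellipticity) || length(wavelengths) < 3L)
    stop("wavelengths and ellipticity must have equal length >= 3")
  if (!all(is.finite(wavelengths)) || !all(is.finite(ellipticity)))
    stop("non-finite values in spectrum")
  d <- diff(wavelengths)
  if (any(d <= 0) || diff(range(d)) > 1e-9)
    stop("wavelength grid must be strictly ascending and uniform")
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity,
                 metadata = metadata),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d points, %.0f-%.0f nm (step %.3g nm)\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$wavelengths[2] - x$wavelengths[1]))
  invisible(x)
}

#' Pair of reference GQ spectra used as an unmixing basis
#'
#' The antiparallel (GQ-AP) reference is measured in K+ alone; the parallel
#' (GQ-P) reference in K+ with 30% PEG-200, where the parallel topology
#' dominates.  Both must share an identical wavelength grid.
#'
#' @param ap,p `cd_spectrum` objects for the GQ-AP and GQ-P references.
#' @return An object of class `basis_set` with elements `ap` and `p`.
#' @export
basis_set <- function(ap, p) {
  stopifnot(inherits(ap, "cd_spectrum"), inherits(p, "cd_spectrum"))
  if (!isTRUE(all.equal(ap$wavelengths, p$wavelengths, tolerance = 1e-9)))
    stop("basis spectra must share an identical wavelength grid")
  structure(list(ap = ap, p = p), class = "basis_set")
}

#' Savitzky-Golay smoothing of a CD spectrum
#'
#' Local polynomial smoothing with a symmetric window of `neighbors` points
#' on each side and a polynomial of degree `order` (defaults: 4 neighbors,
#' 2nd order).  A degree-`order` polynomial passes through the filter
#' unchanged, so smoothing does not bias peak positions of slowly varying
#' spectra.
#'
#' @param s A [cd_spectrum].
#' @param neighbors Points on each side of the window centre.
#' @param order Polynomial degree, `< 2 * neighbors + 1`.
#' @return Smoothed [cd_spectrum] on the same grid.
#' @export
smooth_spectrum <- function(s, neighbors = 4L, order = 2L) {
  stopifnot(inherits(s, "cd_spectrum"))
  win <- 2L * as.integer(neighbors) + 1L
  if (win > length(s$wavelengths))
    stop("smoothing window (", win, " points) exceeds spectrum length")
  if (order >= win)
    stop("polynomial order must be smaller than the window")
  sm <- signal::sgolayfilt(s$ellipticity, p = order, n = win)
  cd_spectrum(s$wavelengths, sm, s$metadata)
}

#' Decompose a CD spectrum into GQ-AP / GQ-P fractional components
#'
#' Models the spectrum as the constrained linear combination
#' `S(lambda) = x * AP(lambda) + y * P(lambda)` with `x + y = 1`, and finds
#' the `x` minimising the squared residual sum.  Substituting `y = 1 - x`
#' gives the closed form
#' `x* = sum((S - P) * (AP - P)) / sum((AP - P)^2)`.
#'
#' Only the sum constraint is imposed; `x` may leave `[0, 1]` for spectra
#' outside the basis span.  With `clip = TRUE` the coefficient is truncated
#' to `[0, 1]` (and `clipped` is flagged), for the interpretation that the
#' components are physical fractions.
#'
#' @param s A [cd_spectrum] on the basis grid (use [resample_spectrum()]
#'   first otherwise).
#' @param basis A [basis_set].
#' @param clip Truncate `x` to `[0, 1]`?
#' @return A list of class `cd_decomposition`: `x`, `y` (= 1 - x),
#'   `residual_ss`, `clipped`.
#' @examples
#' b <- gen_basis_spectra()
#' decompose_spectrum(b$ap, b)$x  # 1
#' @export
decompose_spectrum <- function(s, basis, clip = FALSE) {
  stopifnot(inherits(s, "cd_spectrum"), inherits(basis, "basis_set"))
  if (!isTRUE(all.equal(s$wavelengths, basis$ap$wavelengths, tolerance = 1e-9)))
    stop("grid mismatch: spectrum is not on the basis wavelength grid")
  a <- basis$ap$ellipticity
  p <- basis$p$ellipticity
  d <- a - p
  denom <- sum(d^2)
  if (denom < 1e-12 * max(1, sum(a^2)))
    stop("degenerate basis: AP and P spectra are identical")
  x <- sum((s$ellipticity - p) * d) / denom
  clipped <- FALSE
  if (clip && (x < 0 || x > 1)) {
    warning(sprintf("coefficient x = %.4f clipped to [0, 1]", x))
    x <- min(max(x, 0), 1)
    clipped <- TRUE
  }
  resid <- s$ellipticity - x * a - (1 - x) * p
  structure(list(x = x, y = 1 - x, residual_ss = sum(resid^2),
                 clipped = clipped),
            class = "cd_decomposition")
}

#' @export
print.cd_decomposition <- function(x, ...) {
  cat(sprintf("<cd_decomposition> x (GQ-AP) = %.4f, y (GQ-P) = %.4f, RSS = %.4g%s\n",
              x$x, x$y, x$residual_ss, if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; extrapolation beyond the measured range is refused.
#'
#' @param s A [cd_spectrum].
#' @param wavelengths Target grid (nm).
#' @return A [cd_spectrum] on the target grid.
#' @export
resample_spectrum <- function(s, wavelengths) {
  stopifnot(inherits(s, "cd_spectrum"))
  if (min(wavelengths) < min(s$wavelengths) - 1e-9 ||
      max(wavelengths) > max(s$wavelengths) + 1e-9)
    stop("resampling would extrapolate beyond the measured range")
  y <- stats::approx(s$wavelengths, s$ellipticity, xout = wavelengths)$y
  cd_spectrum(wavelengths, y, s$metadata)
}

# Signed diagnostic value: grid point of largest |ellipticity| within
# +/- window nm of the nominal wavelength.
.peak_value <- function(s, lambda, window = 3) {
  sel <- which(abs(s$wavelengths - lambda) <= window + 1e-9)
  if (!length(sel))
    stop("coverage error: grid does not cover the diagnostic wavelength ",
         lambda, " nm")
  v <- s$ellipticity[sel]
  v[which.max(abs(v))]
}

#' Classify GQ topology from CD peak signatures
#'
#' Rule-based call from the diagnostic wavelengths: an antiparallel GQ shows
#' a strong positive 295 nm peak with a negative 260 nm trough; a parallel
#' GQ a positive 260 nm peak with a negative 240 nm trough.  Each diagnostic
#' value is read as the extremum within +/- 3 nm.  With threshold
#' `tau = tau_frac * max(|S|)`:
#' AP-like requires `S295 > tau` and `S295 > S260`; P-like requires
#' `S260 > tau` and `S240 < -tau / 4`.  Both patterns give `"mixed"`,
#' neither `"non-GQ"`.  Quantitative population calls should use
#' [decompose_spectrum()] instead.
#'
#' @param s A [cd_spectrum] covering at least 235-300 nm.
#' @param tau_frac Threshold as a fraction of the maximum absolute
#'   ellipticity (default 0.1).
#' @return One of `"GQ-AP"`, `"GQ-P"`, `"mixed"`, `"non-GQ"`.
#' @export
classify_topology <- function(s, tau_frac = 0.1) {
  stopifnot(inherits(s, "cd_spectrum"))
  if (min(s$wavelengths) > 235 || max(s$wavelengths) < 300)
    stop("coverage error: classification needs the 235-300 nm range")
  s295 <- .peak_value(s, 295)
  s260 <- .peak_value(s, 260)
  s240 <- .peak_value(s, 240)
  tau <- tau_frac * max(abs(s$ellipticity))
  ap_like <- s295 > tau && s295 > s260
  p_like  <- s260 > tau && s240 < -tau / 4
  if (ap_like && p_like) "mixed"
  else if (ap_like) "GQ-AP"
  else if (p_like) "GQ-P"
  else "non-GQ"
}

#' Decompose a titration series of CD spectra
#'
#' Applies [decompose_spectrum()] to each spectrum of a series (e.g. a
#' PEG-200 crowding titration) and assembles a tidy table in input order.
#'
#' @param series List of [cd_spectrum] objects on the basis grid.
#' @param basis A [basis_set].
#' @param conditions Optional character vector of condition labels; defaults
#'   to each spectrum's `metadata$condition`, else its index.
#' @param clip Passed to [decompose_spectrum()].
#' @return A `data.frame` with columns `condition`, `x`, `y`, `residual_ss`.
#' @export
titration_fractions <- function(series, basis, conditions = NULL, clip = FALSE) {
  if (!length(series))
    return(data.frame(condition = character(0), x = numeric(0),
                      y = numeric(0), residual_ss = numeric(0)))
  if (is.null(conditions))
    conditions <- vapply(seq_along(series), function(i) {
      md <- series[[i]]$metadata
      if (!is.null(md$condition)) as.character(md$condition) else as.character(i)
    }, character(1))
  stopifnot(length(conditions) == length(series))
  res <- lapply(series, decompose_spectrum, basis = basis, clip = clip)
  data.frame(condition = conditions,
             x = vapply(res, `[[`, numeric(1), "x"),
             y = vapply(res, `[[`, numeric(1), "y"),
             residual_ss = vapply(res, `[[`, numeric(1), "residual_ss"))
}

#' Read / write two-column CD spectrum CSV
#'
#' Format: header `wavelength_nm,ellipticity`, one row per grid point.
#'
#' @param path CSV path.
#' @param s A [cd_spectrum] (for writing).
#' @return `read_spectrum_csv` returns a [cd_spectrum].
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "ellipticity")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "))
  cd_spectrum(df$wavelength_nm, df$ellipticity)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "cd_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = s$wavelengths,
                              ellipticity = s$ellipticity),
                   path, row.names = FALSE)
  invisible(path)
}
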