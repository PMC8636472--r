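#' Construct a thermal melt curve
#'
#' The 295 nm CD/absorbance signal followed over an ascending temperature
#' ramp; the 295 nm band reports specifically on antiparallel GQ folding, so
#' its loss traces GQ unfolding.
#'
#' @param temperatures Temperatures in degrees C, strictly ascending.
#' @param signal Signal at 295 nm, one value per temperature (a.u.).
#' @param replicate_id Replicate label.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperatures, signal, replicate_id = "rep1") {
  temperatures <- as.numeric(temperatures)
  signal <- as.numeric(signal)
  if (length(temperatures) != length(signal))
    stop("temperatures and signal must have equal length")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  if (!all(is.finite(temperatures)) || !all(is.finite(signal)))
    stop("non-finite values in melt curve")
  structure(list(temperatures = temperatures, signal = signal,
                 replicate_id = as.character(replicate_id)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %s: %d points, %.1f-%.1f C\n", x$replicate_id,
              length(x$temperatures), min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Average replicate melt curves pointwise
#'
#' @param curves List of [melt_curve] objects on identical temperature grids.
#' @return A [melt_curve] with the pointwise mean signal.
#' @export
average_replicates <- function(curves) {
  stopifnot(length(curves) >= 1L)
  t0 <- curves[[1]]$temperatures
  for (cv in curves)
    if (!isTRUE(all.equal(cv$temperatures, t0, tolerance = 1e-9)))
      stop("grid mismatch: replicates are not on identical temperature grids")
  m <- rowMeans(vapply(curves, `[[`, numeric(length(t0)), "signal"))
  melt_curve(t0, m, replicate_id = "mean")
}

# Four-parameter Boltzmann sigmoid.  With width > 0 the curve moves from
# `upper` (low T) to `lower` (high T); upper/lower are free, so rising
# transitions are fitted with upper < lower.
.boltzmann <- function(temp, lower, upper, tm, width) {
  lower + (upper - lower) / (1 + exp((temp - tm) / width))
}

#' Fit a two-state Boltzmann sigmoid to a melt curve
#'
#' Least-squares fit of
#' `S(T) = lower + (upper - lower) / (1 + exp((T - tm) / width))`,
#' the four-parameter Boltzmann form; `tm` is the transition midpoint
#' (melting temperature) and `width > 0` the transition breadth.  The
#' transition direction is taken from the data (`upper`/`lower` are free
#' plateau parameters, named for the GQ case where the 295 nm signal falls
#' on unfolding).  Starting values: plateaus from the 10th/90th percentile
#' signal, `tm` from the steepest finite-difference slope, `width` a tenth
#' of the temperature span.  Curves without a resolvable transition are
#' reported with `converged = FALSE` and `tm = NA` rather than an error.
#'
#' @param curve A [melt_curve] with at least 8 points.
#' @return A list of class `melt_fit`: `tm`, `width`, `upper_plateau`,
#'   `lower_plateau`, `residual_ss`, `converged`.
#' @examples
#' cv <- gen_melt_curve(tm = 84.3, noise_sd = 0)[[1]]
#' fit_melt_curve(cv)$tm
#' @export
fit_melt_curve <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  temp <- curve$temperatures
  sig <- curve$signal
  if (length(temp) < 8L)
    stop("need at least 8 points to fit a melt transition")

  qs <- stats::quantile(sig, c(0.1, 0.9), names = FALSE)
  decreasing <- sig[1] >= sig[length(sig)]
  upper0 <- if (decreasing) qs[2] else qs[1]
  lower0 <- if (decreasing) qs[1] else qs[2]
  slope <- diff(sig) / diff(temp)
  tm0 <- temp[which.max(abs(slope))]
  width0 <- diff(range(temp)) / 10

  fail <- structure(list(tm = NA_real_, width = NA_real_,
                         upper_plateau = NA_real_, lower_plateau = NA_real_,
                         residual_ss = NA_real_, converged = FALSE),
                    class = "melt_fit")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      sig ~ .boltzmann(temp, pl_low, pl_high, tm, width),
      start = list(pl_low = lower0, pl_high = upper0, tm = tm0, width = width0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  if (cf[["width"]] < 0) {   # sign convention: width > 0, plateaus swapped
    cf[c("pl_low", "pl_high")] <- cf[c("pl_high", "pl_low")]
    cf[["width"]] <- -cf[["width"]]
  }
  # a transition is resolved only if the fitted amplitude clears the noise
  resid <- stats::resid(fit)
  amp <- abs(cf[["pl_high"]] - cf[["pl_low"]])
  noise <- stats::sd(resid)
  tss <- sum((sig - mean(sig))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else 0
  converged <- isTRUE(fit$convInfo$isConv) && amp > 5 * noise && r2 > 0.8 &&
    cf[["tm"]] > min(temp) - 10 && cf[["tm"]] < max(temp) + 10
  if (!converged) return(fail)
  structure(list(tm = unname(cf[["tm"]]), width = unname(abs(cf[["width"]])),
                 upper_plateau = unname(cf[["pl_high"]]),
                 lower_plateau = unname(cf[["pl_low"]]),
                 residual_ss = sum(resid^2), converged = TRUE),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (!x$converged) cat("<melt_fit> not converged (no resolvable transition)\n")
  else cat(sprintf("<melt_fit> Tm = %.2f C, width = %.2f C, plateaus [%.3g, %.3g]\n",
                   x$tm, x$width, x$lower_plateau, x$upper_plateau))
  invisible(x)
}

#' Compare melting temperatures between two groups of fits
#'
#' Unpaired two-tailed t-test on the fitted Tm values (Student
#' pooled-variance by default; `welch = TRUE` switches to the
#' unequal-variance form).  Degenerate input where both groups have zero
#' variance and equal means is reported as `t = 0, p = 1`.
#'
#' @param group_a,group_b Lists of [melt_fit] objects (or numeric vectors of
#'   Tm values), at least 2 values per group.
#' @param welch Use the Welch unequal-variance test instead of Student?
#' @return A list: `t`, `p_value`, `df`, `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `method`.
#' @export
compare_tm <- function(group_a, group_b, welch = FALSE) {
  as_tm <- function(g) {
    if (is.numeric(g)) return(g)
    v <- vapply(g, function(f) {
      stopifnot(inherits(f, "melt_fit"))
      f$tm
    }, numeric(1))
    v
  }
  a <- as_tm(group_a); b <- as_tm(group_b)
  if (anyNA(a) || anyNA(b))
    stop("non-converged fits (tm = NA) cannot be compared")
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 Tm values per group")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- list(mean_a = mean(a), mean_b = mean(b),
              sem_a = sem(a), sem_b = sem(b),
              method = if (welch) "Welch two-sample t-test"
                       else "Student two-sample t-test (pooled variance)")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      out$t <- 0; out$p_value <- 1
      out$df <- length(a) + length(b) - 2
      return(out)
    }
    stop("zero variance in both groups with different means: t is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  out$t <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}

#' Read / write melt-curve CSV
#'
#' Format: header `temperature_C,signal,replicate`; one file can hold
#' several replicates.
#'
#' @param path CSV path.
#' @param curves List of [melt_curve] objects (for writing).
#' @return `read_melt_csv` returns a list of [melt_curve] objects, one per
#'   replicate label.
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("temperature_C", "signal", "replicate")
  if (!all(need %in% names(df)))
    stop("melt CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$replicate), function(d)
    melt_curve(d$temperature_C, d$signal, replicate_id = d$replicate[1]))
}

#' @rdname read_melt_csv
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(temperature_C = cv$temperatures, signal = cv$signal,
               replicate = cv$replicate_id)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
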