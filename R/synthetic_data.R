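# run code with a local RNG stream; the global .Random.seed is untouched
.with_seed <- function(seed, code) {
  saved <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(saved)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", saved, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.gaussian_peak <- function(wl, center, width, amplitude)
  amplitude * exp(-0.5 * ((wl - center) / width)^2)

#' Generate synthetic GQ-AP / GQ-P CD basis spectra
#'
#' Deterministic reference spectra built from Gaussian bands carrying the
#' canonical GQ CD signatures: the antiparallel basis has a strong positive
#' 295 nm peak and a negative 260 nm trough; the parallel basis a positive
#' 260 nm peak and a negative 240 nm trough.  Peak positions and signs are
#' the constrained features; widths (8-12 nm) and the arbitrary amplitude
#' units are free cosmetic choices.
#'
#' @param wavelengths Wavelength grid in nm (default 220-320 step 1); must
#'   cover the peak positions.
#' @param amplitude Overall amplitude scale (a.u.).
#' @param ap_peaks,p_peaks `data.frame`s of `(center, width, amp)` Gaussian
#'   band parameters, in units of `amplitude`.
#' @return A [basis_set].
#' @examples
#' b <- gen_basis_spectra()
#' b$ap$wavelengths[which.max(b$ap$ellipticity)]  # 295
#' @export
gen_basis_spectra <- function(wavelengths = seq(220, 320, by = 1),
                              amplitude = 1,
                              ap_peaks = data.frame(
                                center = c(295, 260),
                                width = c(9, 11),
                                amp = c(1, -0.55)),
                              p_peaks = data.frame(
                                center = c(260, 240),
                                width = c(10, 8),
                                amp = c(1, -0.45))) {
  needed <- c(ap_peaks$center, p_peaks$center)
  if (length(needed) && (min(wavelengths) > min(needed) ||
                         max(wavelengths) < max(needed)))
    stop("coverage error: grid does not cover the basis peak positions")
  mk <- function(peaks, cond) {
    y <- rep(0, length(wavelengths))
    for (i in seq_len(nrow(peaks)))
      y <- y + .gaussian_peak(wavelengths, peaks$center[i], peaks$width[i],
                              amplitude * peaks$amp[i])
    cd_spectrum(wavelengths, y, metadata = list(condition = cond))
  }
  basis_set(ap = mk(ap_peaks, "GQ-AP reference (100 mM KCl)"),
            p = mk(p_peaks, "GQ-P reference (100 mM KCl + 30% PEG)"))
}

#' Generate a synthetic crowding-titration spectrum series
#'
#' Emulates a PEG titration: spectrum `i` is the mixture
#' `f_i * AP + (1 - f_i) * P` plus iid Gaussian noise.  The generating
#' fractions are the ground truth that [titration_fractions()] should
#' recover.
#'
#' @param basis A [basis_set].
#' @param fractions AP fractions in `[0, 1]`, one per series member
#'   (default mimics a 0/10/20/30% PEG series).
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param seed RNG seed; fixes the noise realisation.
#' @param conditions Optional labels stored in each spectrum's metadata.
#' @return List of [cd_spectrum] objects.
#' @export
gen_titration_series <- function(basis, fractions = c(1, 0.6, 0.3, 0.05),
                                 noise_sd = 0.02, seed = 1,
                                 conditions = NULL) {
  stopifnot(inherits(basis, "basis_set"),
            all(fractions >= 0 & fractions <= 1), noise_sd >= 0)
  if (is.null(conditions)) conditions <- sprintf("frac_ap=%.2f", fractions)
  wl <- basis$ap$wavelengths
  .with_seed(seed, {
    lapply(seq_along(fractions), function(i) {
      y <- fractions[i] * basis$ap$ellipticity +
        (1 - fractions[i]) * basis$p$ellipticity +
        stats::rnorm(length(wl), 0, noise_sd)
      cd_spectrum(wl, y, metadata = list(condition = conditions[i],
                                         true_fraction = fractions[i]))
    })
  })
}

#' Generate synthetic 295 nm melt-curve replicates
#'
#' Two-state Boltzmann sigmoid
#' `S(T) = lower + (upper - lower) / (1 + exp((T - tm) / width))` on the
#' instrument's 25-90 degC range, plus iid Gaussian noise, replicated
#' `n_reps` times.  The defaults emulate a GQ unfolding melt followed at
#' 295 nm (signal falling from `upper` to `lower` through the midpoint
#' `tm`).
#'
#' @param tm Generator melting temperature (degC).
#' @param width Transition width (degC).
#' @param upper,lower Folded / unfolded plateau signals (a.u.).
#' @param temperatures Temperature grid (degC), default 25-90 step 0.5.
#' @param noise_sd Noise standard deviation (a.u.); 1% of the amplitude by
#'   default.
#' @param seed RNG seed.
#' @param n_reps Number of replicates.
#' @return List of [melt_curve] objects.
#' @export
gen_melt_curve <- function(tm = 84.3, width = 3, upper = 1, lower = 0,
                           temperatures = seq(25, 90, by = 0.5),
                           noise_sd = 0.01 * abs(upper - lower),
                           seed = 1, n_reps = 1) {
  stopifnot(width > 0, noise_sd >= 0, n_reps >= 1)
  clean <- .boltzmann(temperatures, lower, upper, tm, width)
  .with_seed(seed, {
    lapply(seq_len(n_reps), function(r)
      melt_curve(temperatures,
                 clean + stats::rnorm(length(temperatures), 0, noise_sd),
                 replicate_id = sprintf("rep%d", r)))
  })
}

#' Generate a rigid-tetrad / mobile-loop toy trajectory
#'
#' Emulates the qualitative behaviour of GQ MD simulations -- rigid stacked
#' tetrads, mobile cytosine loops -- without any physics: each frame is the
#' ideal structure plus iid Gaussian displacement per atom, with standard
#' deviation `sigma_tetrad` for tetrad-guanine atoms and `sigma_loop` for
#' everything else, optionally preceded by a random global rigid motion.
#' Residue classes come from [detect_tetrads()] on the input model, not from
#' hard-coded indices.
#'
#' @param ideal A [gq_structure] with detectable tetrads (e.g. from
#'   [build_ideal_gq()]).
#' @param sigma_tetrad,sigma_loop Displacement SDs in Angstrom per
#'   coordinate (`sigma_loop >= sigma_tetrad >= 0`).
#' @param n_frames Number of frames.
#' @param rigid_motion Apply a random global rotation + translation per
#'   frame?
#' @param seed RNG seed.
#' @param frame_interval_ps Frame spacing metadata.
#' @return A [gq_trajectory].
#' @export
gen_gq_trajectory <- function(ideal, sigma_tetrad = 0.2, sigma_loop = 1.0,
                              n_frames = 100, rigid_motion = FALSE, seed = 1,
                              frame_interval_ps = 100) {
  stopifnot(inherits(ideal, "gq_structure"),
            sigma_loop >= sigma_tetrad, sigma_tetrad >= 0, n_frames >= 1)
  tetrads <- detect_tetrads(ideal)
  if (!length(tetrads))
    stop("classification error: no tetrads detected in the input model")
  at <- ideal$atom
  tet_keys <- unlist(lapply(tetrads, function(tt)
    paste(tt$residues$chain, tt$residues$resno)))
  sigma <- ifelse(paste(at$chain, at$resno) %in% tet_keys,
                  sigma_tetrad, sigma_loop)
  X0 <- .coords(at)
  n <- nrow(X0)
  .with_seed(seed, {
    coords <- array(NA_real_, c(n, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      X <- X0 + matrix(stats::rnorm(3L * n, 0, sigma), n, 3L)
      if (rigid_motion) {
        R <- .random_rotation()
        tr <- stats::runif(3, -5, 5)
        X <- sweep(X %*% t(R), 2, tr, "+")
      }
      coords[, , f] <- X
    }
    gq_trajectory(ideal, coords, frame_interval_ps)
  })
}

# uniform random rotation via QR of a Gaussian matrix (sign-corrected)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
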