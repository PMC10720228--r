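# Parcel-level confound modelling and denoising: framewise displacement,
# DVARS, 24+8 confound expansion, spike regressors, nuisance regression,
# band-pass filtering, and subject-level motion exclusion.

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus `head_radius` times the sum of absolute backward
#' differences of the three rotations (radians), which converts angular to
#' arc displacement on a sphere approximating the head.
#'
#' @param motion T x 6 matrix: 3 translations (mm) then 3 rotations (radians).
#' @param head_radius Assumed head radius in mm (default 50).
#' @return Length-T numeric FD series in mm, with `fd[1] = 0` by convention.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("framewise displacement needs at least 2 frames")
  stopifnot(ncol(motion) == 6)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS of a parcel time-series matrix
#'
#' Root-mean-square over parcels of the backward temporal difference. With
#' `standardize = TRUE` (default) the series is divided by its own median so
#' that a threshold such as 3 is scale-free; the raw RMS series is available
#' with `standardize = FALSE`.
#'
#' @param timeseries T x P numeric matrix.
#' @param standardize Divide by the median of the nonzero-frame series?
#' @return Length-T numeric series with first frame 0.
#' @export
dvars <- function(timeseries, standardize = TRUE) {
  x <- as.matrix(timeseries)
  if (nrow(x) < 2) stop("DVARS needs at least 2 frames")
  d <- sqrt(rowMeans(diff(x)^2))
  if (standardize) {
    med <- stats::median(d)
    if (med <= .Machine$double.eps)
      stop("cannot standardize DVARS: median of the difference series is zero ",
           "(constant input?)")
    d <- d / med
  }
  c(0, d)
}

# Backward-difference derivative with first row 0 (column-wise).
backward_diff <- function(x) rbind(0, diff(as.matrix(x)))

#' Expand motion and tissue signals into the 24 + 8 confound set
#'
#' Motion: the 6 rigid-body parameters, their 6 backward-difference temporal
#' derivatives, and the 12 squares of those (24 columns). Tissue: white
#' matter and CSF mean signals, their 2 derivatives, and the 4 squares
#' (8 columns). Column order: parameters, derivatives, squared parameters,
#' squared derivatives.
#'
#' @param motion T x 6 matrix (trans_x..rot_z).
#' @param tissue_signals T x 2 matrix (wm, csf).
#' @return T x 32 matrix with deterministic column names.
#' @export
expand_confounds <- function(motion, tissue_signals) {
  motion <- as.matrix(motion); tissue_signals <- as.matrix(tissue_signals)
  stopifnot(ncol(motion) == 6, ncol(tissue_signals) == 2,
            nrow(motion) == nrow(tissue_signals))
  mot_names <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  tis_names <- c("wm", "csf")
  expand <- function(x, nm) {
    d <- backward_diff(x)
    out <- cbind(x, d, x^2, d^2)
    colnames(out) <- c(nm, paste0(nm, "_derivative1"),
                       paste0(nm, "_power2"),
                       paste0(nm, "_derivative1_power2"))
    out
  }
  cbind(expand(motion, mot_names), expand(tissue_signals, tis_names))
}

#' Motion/artifact spike regressors
#'
#' One indicator column per frame exceeding either the FD or the DVARS
#' threshold (union of the two criteria), for inclusion in the nuisance
#' regression so flagged frames are effectively censored.
#'
#' @param fd,dvars Equal-length per-frame series.
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @param dvars_thresh DVARS threshold in standardized units (default 3).
#' @return T x S binary matrix (S = number of flagged frames; 0 columns when
#'   no frame is flagged), each column summing to 1.
#' @export
spike_regressors <- function(fd, dvars, fd_thresh = 0.5, dvars_thresh = 3) {
  stopifnot(length(fd) == length(dvars))
  flagged <- which(fd > fd_thresh | dvars > dvars_thresh)
  out <- matrix(0, length(fd), length(flagged))
  if (length(flagged)) {
    out[cbind(flagged, seq_along(flagged))] <- 1
    colnames(out) <- paste0("spike_", flagged)
  }
  out
}

#' Regress confounds out of parcel time series
#'
#' Per-parcel ordinary least squares on the confound matrix plus an
#' intercept; returns the residuals, which are orthogonal to every retained
#' confound column. Collinear confound columns are dropped with a warning
#' rather than failing the subject.
#'
#' @param timeseries T x P matrix.
#' @param confounds T x C confound matrix (no intercept column needed).
#' @return T x P residual matrix with the input's column names.
#' @export
nuisance_regression <- function(timeseries, confounds) {
  x <- as.matrix(timeseries)
  cf <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(x) <= ncol(cf))
    stop("need more time points than confounds + intercept")
  qr_cf <- qr(cf)
  if (qr_cf$rank < ncol(cf)) {
    drop_idx <- qr_cf$pivot[(qr_cf$rank + 1):ncol(cf)]
    warning("dropping ", length(drop_idx), " collinear confound column(s): ",
            paste(colnames(cf)[drop_idx], collapse = ", "))
    cf <- cf[, -drop_idx, drop = FALSE]
    qr_cf <- qr(cf)
  }
  res <- qr.resid(qr_cf, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Zero-phase band-pass filter for parcel time series
#'
#' Order-2 Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`) for zero phase shift. Defaults match the
#' conventional resting-state band of 0.008-0.08 Hz.
#'
#' @param timeseries T x P matrix.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < 1/(2 tr)`.
#' @return Filtered T x P matrix.
#' @export
bandpass <- function(timeseries, tr_seconds, low = 0.008, high = 0.08) {
  x <- as.matrix(timeseries)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low > 0 && low < high && high < nyquist))
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
                 low, high, nyquist))
  bf <- signal::butter(2, c(low, high) / nyquist, type = "pass")
  # demean first: the mean is outside the passband anyway, and removing it
  # up front keeps the forward-backward pass free of large edge transients
  x <- scale(x, scale = FALSE)
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  dimnames(out) <- dimnames(x)
  out
}

#' Subject-level motion exclusion decision
#'
#' A subject is excluded when mean FD exceeds `mean_fd_thresh`, maximum FD
#' exceeds `max_fd_thresh`, or more than `outlier_fraction_thresh` of frames
#' exceed the spike threshold `fd_spike_thresh`. All triggered rules are
#' reported.
#'
#' @param fd Per-frame FD series, mm.
#' @param subject_id Identifier carried into the decision.
#' @param fd_spike_thresh Per-frame outlier threshold, mm (default 0.5).
#' @param mean_fd_thresh,max_fd_thresh,outlier_fraction_thresh Exclusion
#'   thresholds (defaults 0.3 mm, 5 mm, 0.20).
#' @return List of class `exclusion_decision`: `subject_id`, `excluded`,
#'   `reasons` (character vector among `mean_fd`, `max_fd`,
#'   `outlier_fraction`), and the measured quantities.
#' @export
motion_exclusion <- function(fd, subject_id = NA_character_,
                             fd_spike_thresh = 0.5, mean_fd_thresh = 0.3,
                             max_fd_thresh = 5, outlier_fraction_thresh = 0.20) {
  reasons <- character(0)
  m <- mean(fd); mx <- max(fd); frac <- mean(fd > fd_spike_thresh)
  if (m > mean_fd_thresh) reasons <- c(reasons, "mean_fd")
  if (mx > max_fd_thresh) reasons <- c(reasons, "max_fd")
  if (frac > outlier_fraction_thresh) reasons <- c(reasons, "outlier_fraction")
  structure(list(subject_id = subject_id, excluded = length(reasons) > 0,
                 reasons = reasons, mean_fd = m, max_fd = mx,
                 outlier_fraction = frac),
            class = "exclusion_decision")
}

#' Denoise one subject's parcel time series
#'
#' Full parcel-level denoising chain: expand the 24 + 8 confound set, add
#' FD/DVARS spike regressors, regress everything out, then band-pass filter
#' the residuals (regression first, filtering second).
#'
#' @param timeseries T x P matrix of raw parcel signals.
#' @param motion T x 6 motion matrix.
#' @param tissue_signals T x 2 tissue-signal matrix.
#' @param tr_seconds Repetition time in seconds.
#' @param fd_thresh,dvars_thresh Spike thresholds.
#' @param low,high Band-pass edges in Hz.
#' @param standardize_dvars Use median-standardized DVARS for spike flagging?
#' @return List with `series` (denoised T x P matrix), `fd`, `dvars` and the
#'   number of spike regressors used.
#' @export
denoise_subject <- function(timeseries, motion, tissue_signals, tr_seconds,
                            fd_thresh = 0.5, dvars_thresh = 3,
                            low = 0.008, high = 0.08,
                            standardize_dvars = TRUE) {
  fd <- framewise_displacement(motion)
  dv <- dvars(timeseries, standardize = standardize_dvars)
  conf <- cbind(expand_confounds(motion, tissue_signals),
                spike_regressors(fd, dv, fd_thresh, dvars_thresh))
  resid <- nuisance_regression(timeseries, conf)
  list(series = bandpass(resid, tr_seconds, low, high),
       fd = fd, dvars = dv,
       n_spikes = ncol(conf) - 32L)
}
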