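#' Discard initial volumes
#'
#' Drops the first `n_discard` frames of a BOLD run (the conventional guard
#' against unstable initial magnetization and subject adaptation; 10 frames
#' by default in the pipeline).  The caller is responsible for trimming the
#' motion trace to match ([trim_motion()]).
#'
#' @param bold A [bold4d].
#' @param n_discard Number of leading volumes to drop (0 <= n < t).
#' @return A [bold4d] with `t - n_discard` volumes.
#' @export
discard_initial <- function(bold, n_discard = 10L) {
  nt <- n_volumes(bold)
  if (n_discard < 0) stop_input("`n_discard` must be >= 0")
  if (n_discard >= nt)
    stop_input("cannot discard %d of %d volumes", n_discard, nt)
  if (n_discard == 0L) return(bold)
  bold4d(bold$data[, , , (n_discard + 1):nt, drop = FALSE],
         affine = bold$affine, tr = bold$tr)
}

#' @param motion A `motion_trace`.
#' @rdname discard_initial
#' @export
trim_motion <- function(motion, n_discard = 10L) {
  nt <- nrow(motion$params)
  if (n_discard >= nt) stop_input("cannot discard %d of %d frames", n_discard, nt)
  if (n_discard == 0L) return(motion)
  motion_trace(motion$params[(n_discard + 1):nt, , drop = FALSE])
}

#' Frame-wise displacement
#'
#' Power-style FD: for each frame t >= 2, the sum of absolute backward
#' differences of the three translations plus the rotational differences
#' converted to arc length on a sphere of `head_radius_mm`; the first frame
#' is 0 by convention.
#'
#' @param motion A `motion_trace` (>= 2 frames).
#' @param head_radius_mm Sphere radius for rotation-to-displacement
#'   conversion (default 50 mm).
#' @return List with `fd` (length-T series, mm) and `mean_fd`.
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  p <- motion$params
  if (nrow(p) < 2L) stop_input("FD needs at least 2 frames")
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd))
}

#' Head-motion quality control
#'
#' A subject fails QC if any translation exceeds `trans_limit_mm` or any
#' rotation exceeds `rot_limit_deg`, strictly, relative to the first frame
#' (rotations are stored in radians and converted to degrees).
#'
#' @param motion A `motion_trace`.
#' @param trans_limit_mm Maximum absolute translation (default 2 mm).
#' @param rot_limit_deg Maximum absolute rotation (default 2 degrees).
#' @return List with `pass` (logical), `offending_frames` (integer vector),
#'   `max_trans_mm`, `max_rot_deg`.
#' @export
motion_qc <- function(motion, trans_limit_mm = 2, rot_limit_deg = 2) {
  p <- sweep(motion$params, 2, motion$params[1, ])  # relative to frame 0
  trans <- abs(p[, 1:3, drop = FALSE])
  rot_deg <- abs(p[, 4:6, drop = FALSE]) * 180 / pi
  bad <- apply(trans, 1, max) > trans_limit_mm |
         apply(rot_deg, 1, max) > rot_limit_deg
  list(pass = !any(bad), offending_frames = which(bad),
       max_trans_mm = max(trans), max_rot_deg = max(rot_deg))
}

# project columns of y (t x V matrix) off the column space of X
residualize <- function(y, X) {
  qr.resid(qr(X), y)
}

#' Linear detrending
#'
#' Removes each voxel's least-squares line (intercept + slope); residuals are
#' orthogonal to both regressors, and the operation is idempotent.
#'
#' @param bold A [bold4d] with at least 3 volumes.
#' @return A detrended [bold4d].
#' @export
detrend_linear <- function(bold) {
  nt <- n_volumes(bold)
  if (nt < 3L) stop_input("detrending needs at least 3 volumes")
  X <- cbind(1, seq_len(nt))
  d <- dim(bold$data)
  m <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = nt))  # t x V
  r <- residualize(m, X)
  bold4d(array(t(r), dim = d), affine = bold$affine, tr = bold$tr)
}

# ideal (rectangular) frequency-domain band-pass of one series
ideal_bandpass_series <- function(x, tr, low, high) {
  nt <- length(x)
  keep <- bandpass_keep_bins(nt, tr, low, high)
  mu <- mean(x)
  X <- fft(x - mu)
  X[!keep] <- 0
  Re(fft(X, inverse = TRUE)) / nt
}

# logical vector over FFT bins: TRUE where |f| lies in [low, high]
bandpass_keep_bins <- function(nt, tr, low, high) {
  f <- (seq_len(nt) - 1) / (nt * tr)
  f <- pmin(f, 1 / tr - f)  # two-sided frequency of each bin
  tol <- 1e-12
  f >= low - tol & f <= high + tol
}

#' Temporal band-pass filter
#'
#' Retains fluctuations in `[low_hz, high_hz]` (default 0.01-0.08 Hz, the
#' conventional resting-state band).  The default `"ideal"` method demeans
#' each series and zeroes FFT bins strictly outside the band, matching the
#' rectangular filter used by the common resting-state toolboxes; a
#' zero-phase 2nd-order Butterworth alternative (`method = "butterworth"`)
#' is available.
#'
#' @param bold A [bold4d].
#' @param low_hz,high_hz Pass-band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 TR)`.
#' @param method `"ideal"` or `"butterworth"`.
#' @return A filtered [bold4d] of identical shape.
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08, method = "ideal") {
  nyq <- 1 / (2 * bold$tr)
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= nyq)
    stop_config("band [%g, %g] Hz invalid for Nyquist %g Hz",
                low_hz, high_hz, nyq)
  d <- dim(bold$data)
  nt <- d[4]
  m <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = nt))  # t x V
  if (method == "ideal") {
    keep <- bandpass_keep_bins(nt, bold$tr, low_hz, high_hz)
    mu <- colMeans(m)
    M <- mvfft(sweep(m, 2, mu))
    M[!keep, ] <- 0
    out <- Re(mvfft(M, inverse = TRUE)) / nt
  } else if (method == "butterworth") {
    if (!requireNamespace("signal", quietly = TRUE))
      stop_config("the Butterworth filter requires the 'signal' package")
    bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
    mu <- colMeans(m)
    mc <- sweep(m, 2, mu)
    out <- apply(mc, 2, function(x) signal::filtfilt(bf, x))
  } else stop_config("unknown band-pass method '%s'", method)
  bold4d(array(t(out), dim = d), affine = bold$affine, tr = bold$tr)
}

#' Friston 24-parameter motion regressors
#'
#' The 6 rigid-body parameters R(t), their one-frame lags R(t-1) (first row
#' zero-padded), and the element-wise squares of both: 24 columns.
#'
#' @param motion A `motion_trace` with >= 2 frames.
#' @return T x 24 numeric matrix with named columns.
#' @export
friston24 <- function(motion) {
  p <- motion$params
  if (nrow(p) < 2L) stop_input("Friston-24 needs at least 2 frames")
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag, p^2, lag^2)
  colnames(out) <- c(colnames(p), paste0(colnames(p), "_lag"),
                     paste0(colnames(p), "_sq"), paste0(colnames(p), "_lag_sq"))
  out
}

#' Mean time series of a tissue compartment
#'
#' @param bold A [bold4d].
#' @param compartment_mask Logical 3D array on the same grid.
#' @return Numeric length-t series: the per-frame arithmetic mean over mask
#'   voxels.
#' @export
extract_compartment_mean <- function(bold, compartment_mask) {
  d <- dim(bold$data)
  if (!identical(dim(compartment_mask), d[1:3]))
    stop_input("compartment mask grid %s does not match image grid %s",
               paste(dim(compartment_mask), collapse = "x"),
               paste(d[1:3], collapse = "x"))
  if (!any(compartment_mask)) stop_input("compartment mask is empty")
  m <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(m[which(compartment_mask), , drop = FALSE])
}

#' Build the nuisance design matrix
#'
#' Columns: intercept, the Friston-24 motion expansion, and (optionally) the
#' mean white-matter and ventricular-CSF series.  The global (whole-brain
#' mean) signal is deliberately not offered as a column.
#'
#' @param motion Trimmed `motion_trace` aligned with the retained volumes.
#' @param wm_mean,csf_mean Optional length-t compartment mean series.
#' @return T x K matrix with named columns (K = 27 with both compartments).
#' @export
nuisance_design <- function(motion, wm_mean = NULL, csf_mean = NULL) {
  X <- cbind(intercept = 1, friston24(motion))
  if (!is.null(wm_mean)) X <- cbind(X, wm_mean = wm_mean)
  if (!is.null(csf_mean)) X <- cbind(X, csf_mean = csf_mean)
  X
}

#' Regress nuisance signals out of a BOLD image
#'
#' Per-voxel least-squares residuals against the given design; residuals are
#' orthogonal to every design column.  Constant (zero-variance) design
#' columns other than the intercept are dropped with a warning; genuinely
#' collinear designs are an error naming the offending columns.
#'
#' @param bold A [bold4d].
#' @param design T x K numeric matrix (rows = frames).
#' @return A [bold4d] of residuals.
#' @export
nuisance_regress <- function(bold, design) {
  d <- dim(bold$data)
  nt <- d[4]
  design <- as.matrix(design)
  if (nrow(design) != nt)
    stop_input("design has %d rows but image has %d frames", nrow(design), nt)
  cn <- colnames(design) %||% paste0("V", seq_len(ncol(design)))
  colnames(design) <- cn
  # drop non-intercept constant columns (e.g. all-zero motion); the first
  # constant column is treated as the intercept if none is named
  is_const <- apply(design, 2, function(x) diff(range(x)) == 0)
  is_zero <- apply(design, 2, function(x) all(x == 0))
  is_intercept <- cn == "intercept"
  if (!any(is_intercept)) {
    cand <- which(is_const & !is_zero)
    if (length(cand)) is_intercept[cand[1]] <- TRUE
  }
  keep <- !is_const | is_intercept
  if (!any(keep)) stop_input("nuisance design has no usable columns")
  if (any(!keep))
    warn(paste("dropping constant nuisance columns:",
               paste(cn[!keep], collapse = ", ")))
  X <- design[, keep, drop = FALSE]
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- cn[keep][setdiff(seq_len(ncol(X)), q$pivot[seq_len(q$rank)])]
    stop_input("nuisance design is rank deficient (collinear: %s)",
               paste(bad, collapse = ", "))
  }
  m <- t(matrix(bold$data, nrow = prod(d[1:3]), ncol = nt))
  r <- qr.resid(q, m)
  bold4d(array(t(r), dim = d), affine = bold$affine, tr = bold$tr)
}

#' Run the default preprocessing chain on one subject
#'
#' Order: discard initial volumes, trim motion to match, linear detrend,
#' band-pass, nuisance regression (Friston-24 + compartment means +
#' intercept).  The order is configurable through the arguments of the
#' individual stages; this wrapper records the applied parameters in its
#' output.
#'
#' @param bold A [bold4d].
#' @param motion The subject's full-length `motion_trace`.
#' @param template Tissue template (for compartment means); may be `NULL` to
#'   skip compartment regressors.
#' @param n_discard Leading volumes to drop.
#' @param low_hz,high_hz Band-pass edges.
#' @param filter_method `"ideal"` or `"butterworth"`.
#' @return List with `bold` (preprocessed [bold4d]), `motion` (trimmed),
#'   `fd` (from [compute_fd()]), `qc` (from [motion_qc()]), and `params`.
#' @export
preprocess_bold <- function(bold, motion, template = NULL, n_discard = 10L,
                            low_hz = 0.01, high_hz = 0.08,
                            filter_method = "ideal") {
  b <- discard_initial(bold, n_discard)
  m <- trim_motion(motion, n_discard)
  qc <- motion_qc(m)
  fd <- compute_fd(m)
  b <- detrend_linear(b)
  b <- bandpass(b, low_hz, high_hz, method = filter_method)
  wm <- if (!is.null(template)) extract_compartment_mean(b, template$wm_mask)
  csf <- if (!is.null(template)) extract_compartment_mean(b, template$csf_mask)
  X <- nuisance_design(m, wm_mean = wm, csf_mean = csf)
  b <- nuisance_regress(b, X)
  list(bold = b, motion = m, fd = fd, qc = qc,
       params = list(n_discard = n_discard, low_hz = low_hz, high_hz = high_hz,
                     filter_method = filter_method,
                     nuisance_columns = colnames(X)))
}
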