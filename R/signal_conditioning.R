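#' Moving-RMS envelope of raw sEMG
#'
#' Rectifies the two sEMG channels with a centred moving root-mean-square
#' of `window` samples (29 ms at 1926 Hz). At the series edges the window
#' shrinks to the available samples (no zero padding).
#'
#' @param emg data frame with columns `t`, `extensor`, `flexor`.
#' @param window odd window length in samples, at most the series length.
#' @return Data frame `t`, `extensor`, `flexor` holding the envelope, of
#'   class `vm_envelope`.
#' @export
emg_envelope <- function(emg, window = 57L) {
  n <- nrow(emg)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > n) stop("series shorter than the RMS window", call. = FALSE)
  out <- data.frame(t = emg$t,
                    extensor = moving_rms(emg$extensor, window),
                    flexor = moving_rms(emg$flexor, window))
  class(out) <- c("vm_envelope", "data.frame")
  out
}

# Centered moving RMS with shrinking edge windows, via cumulative sums.
moving_rms <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x * x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Rest-period sEMG baseline
#'
#' Mean envelope per channel over the rest period from 2 s to 1 s before
#' the end of the vocal instruction (a half-open window
#' `[stimulus_end - 2, stimulus_end - 1)`).
#'
#' @param envelope a [`vm_envelope`][emg_envelope].
#' @param stimulus_end time of the end of the vocal instruction (s).
#' @param rest_offset rest window relative to `stimulus_end` (s).
#' @return Named numeric `c(extensor=, flexor=)`, or `NULL` when the trial
#'   does not cover the rest window (the muscle event is then
#'   undetectable).
#' @export
emg_baseline <- function(envelope, stimulus_end = 0,
                         rest_offset = c(-2, -1)) {
  lo <- stimulus_end + rest_offset[1]
  hi <- stimulus_end + rest_offset[2]
  if (min(envelope$t) > lo || max(envelope$t) < hi) return(NULL)
  sel <- envelope$t >= lo & envelope$t < hi
  c(extensor = mean(envelope$extensor[sel]),
    flexor = mean(envelope$flexor[sel]))
}

#' Rest-referenced acceleration
#'
#' Expresses the 3-axis accelerations relative to the inertial frame of the
#' trial's initial position: the mean acceleration vector over the rest
#' window is subtracted per axis, so that the deviation norm is ~0 at rest
#' and reflects movement afterwards (the raw norm at rest is ~1 g from
#' gravity and would trivially exceed any movement threshold).
#'
#' @param acc data frame `t`, `x`, `y`, `z` (g).
#' @param stimulus_end,rest_offset as in [emg_baseline()].
#' @return List with `deviation` (data frame `t`, `x`, `y`, `z`, `norm`)
#'   and `rest_mean` (length-3 vector), or `NULL` when the rest window is
#'   not covered (arm event undetectable).
#' @export
normalize_acc <- function(acc, stimulus_end = 0, rest_offset = c(-2, -1)) {
  lo <- stimulus_end + rest_offset[1]
  hi <- stimulus_end + rest_offset[2]
  if (min(acc$t) > lo || max(acc$t) < hi) return(NULL)
  sel <- acc$t >= lo & acc$t < hi
  m <- cbind(acc$x, acc$y, acc$z)
  rest_mean <- colMeans(m[sel, , drop = FALSE])
  dev <- sweep(m, 2, rest_mean)
  list(deviation = data.frame(t = acc$t, x = dev[, 1], y = dev[, 2],
                              z = dev[, 3], norm = row_norm(dev)),
       rest_mean = rest_mean)
}

#' The common 20 ms analysis grid
#'
#' Bin centres every `step` seconds across the analysis window, the first
#' bin starting at the window start (centres at `window[1] + step/2 + k*step`).
#'
#' @param window analysis window (s relative to stimulus end).
#' @param step grid resolution (s).
#' @return Numeric vector of bin centres.
#' @export
analysis_grid <- function(window = c(-2, 2.5), step = 0.02) {
  stopifnot(step > 0, window[1] < window[2])
  nbins <- floor((window[2] - window[1]) / step + 1e-9)
  window[1] + step / 2 + step * (seq_len(nbins) - 1L)
}

#' Resample a signal onto the analysis grid
#'
#' Continuous signals (`method = "bin_mean"`) are averaged over the native
#' samples falling in each bin (`[centre - step/2, centre + step/2)`),
#' giving `NA` for bins without non-missing samples. Frame-rate series
#' (`method = "nearest"`) take the value of the nearest sample within
#' `tol` seconds (one grid step), `NA` otherwise; a present-but-missing
#' nearest sample stays missing.
#'
#' @param t,x native sample times and values.
#' @param grid bin centres from [analysis_grid()].
#' @param method `"bin_mean"` or `"nearest"`.
#' @param step grid step (s), used for bin edges.
#' @param tol tolerance for `"nearest"` (s).
#' @return Numeric vector, one value per grid bin.
#' @export
resample_to_grid <- function(t, x, grid, method = c("bin_mean", "nearest"),
                             step = 0.02, tol = 0.02) {
  method <- match.arg(method)
  nb <- length(grid)
  out <- rep(NA_real_, nb)
  if (!length(t)) return(out)
  if (method == "bin_mean") {
    start <- grid[1] - step / 2
    bin <- floor((t - start) / step + 1e-9) + 1L
    keep <- bin >= 1L & bin <= nb & !is.na(x)
    if (any(keep)) {
      sums <- rowsum(x[keep], bin[keep])
      cnts <- rowsum(rep(1, sum(keep)), bin[keep])
      out[as.integer(rownames(sums))] <- sums / cnts
    }
  } else {
    idx <- findInterval(grid, t)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(t))
    pick <- ifelse(abs(grid - t[lo]) <= abs(t[hi] - grid), lo, hi)
    ok <- abs(t[pick] - grid) <= tol
    out[ok] <- x[pick[ok]]
  }
  out
}
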