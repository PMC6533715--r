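#' Construct an MEFV curve
#'
#' An MEFV (maximal expiratory flow-volume) curve is the sampled trace of one
#' forced expiration: expiratory flow against cumulative expired volume. The
#' constructor validates the physiological invariants the downstream shape
#' model relies on and returns a tibble subclass.
#'
#' @param data A data frame with numeric columns `volume_l` (expired volume in
#'   litres, monotone non-decreasing from 0) and `flow_l_s` (expiratory flow in
#'   L/s, non-negative).
#' @param validate Logical; skip invariant checks when `FALSE` (internal use).
#'
#' @details Invariants enforced: at least 30 samples; a single global flow
#'   maximum (peak expiratory flow, PEF; ties resolved to the first index);
#'   final flow at most 5% of PEF so that the expiration is complete; positive
#'   volume span (FVC).
#'
#' @return A tibble of class `mefv_curve` with columns `volume_l`, `flow_l_s`.
#' @examples
#' v <- seq(0, 4.8, length.out = 60)
#' q <- ifelse(v <= 0.8, 8 * v / 0.8, 8 * (4.8 - v) / 4)
#' curve <- mefv_curve(data.frame(volume_l = v, flow_l_s = q))
#' @export
mefv_curve <- function(data, validate = TRUE) {
  if (!is.data.frame(data))
    abort_malformed("`data` must be a data frame")
  if (!all(c("volume_l", "flow_l_s") %in% names(data)))
    abort_malformed("`data` must have columns `volume_l` and `flow_l_s`")
  out <- tibble::as_tibble(data[c("volume_l", "flow_l_s")])
  if (validate) validate_mefv_curve(out)
  class(out) <- c("mefv_curve", class(tibble::tibble()))
  out
}

validate_mefv_curve <- function(x) {
  v <- x$volume_l
  q <- x$flow_l_s
  if (!is.numeric(v) || !is.numeric(q) || anyNA(v) || anyNA(q) ||
      any(!is.finite(v)) || any(!is.finite(q)))
    abort_malformed("curve samples must be finite numbers")
  if (length(v) < 30L)
    abort_malformed("an MEFV curve needs at least 30 samples")
  if (any(diff(v) < 0))
    abort_malformed("expired volume must be monotone non-decreasing")
  if (any(q < 0))
    abort_malformed("expiratory flow must be non-negative")
  if (max(v) - min(v) <= 0)
    abort_malformed("volume span (FVC) must be positive")
  pef <- max(q)
  if (pef <= 0) abort_malformed("curve has no positive flow")
  if (q[length(q)] > 0.05 * pef)
    abort_malformed("final flow exceeds 5% of PEF; expiration incomplete")
  invisible(x)
}

#' Read / write MEFV curve CSV files
#'
#' Curve files are plain CSV with header `volume_l,flow_l_s`, one sample per
#' row. Lines starting with `#` are treated as comments and ignored.
#'
#' @param path File path.
#' @param curve An [mefv_curve()] object.
#' @return `read_mefv_curve()` returns an [mefv_curve()]; `write_mefv_curve()`
#'   returns `path` invisibly.
#' @export
read_mefv_curve <- function(path) {
  if (!file.exists(path)) abort_malformed(paste0("no such file: ", path))
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort_malformed(paste0("cannot parse ", path, ": ",
                                               conditionMessage(e))))
  if (nrow(df) == 0L)
    abort_malformed(paste0(path, ": no data rows (header only?)"))
  mefv_curve(df)
}

#' @rdname read_mefv_curve
#' @export
write_mefv_curve <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(unclass(curve)), path)
  invisible(path)
}

#' Spirometric indices of an MEFV curve
#'
#' Reconstructs the timed indices of the forced expiration from the
#' flow-volume trace: time is recovered as t(V) = integral of dV'/Q(V'),
#' evaluated by the trapezoid rule on the sampled reciprocal flow. FEV1 is the
#' expired volume at t = 1 s (linear interpolation), FVC the total volume
#' span, PEF the maximum sampled flow.
#'
#' Samples with zero flow carry no usable reciprocal; segments with one
#' zero-flow endpoint use the positive endpoint's reciprocal (rectangle rule)
#' and the clock starts at the first sample, so the near-instantaneous initial
#' rise contributes the volume of its first segment at the flow reached there.
#'
#' @param curve An [mefv_curve()].
#' @return A one-row tibble: `fev1`, `fvc`, `pef`, `fev1_fvc_ratio`,
#'   `fev1_capped` (`TRUE` when cumulative time never reached 1 s and FEV1 was
#'   set to FVC).
#' @examples
#' v <- seq(0, 4, length.out = 41)
#' curve <- mefv_curve(data.frame(volume_l = v, flow_l_s = rep(1, 41)),
#'                     validate = FALSE)
#' spirometric_indices(curve) # FEV1 = 1 L, FVC = 4 L
#' @export
spirometric_indices <- function(curve) {
  v <- curve$volume_l
  q <- curve$flow_l_s
  n <- length(v)
  dv <- diff(v)
  q1 <- q[-n]
  q2 <- q[-1L]
  dt <- numeric(n - 1L)
  both <- q1 > 0 & q2 > 0
  dt[both] <- dv[both] * 0.5 * (1 / q1[both] + 1 / q2[both])
  one <- xor(q1 > 0, q2 > 0)
  dt[one] <- dv[one] / pmax(q1[one], q2[one])
  # both endpoints stalled: no flow, no elapsed-time estimate for that volume
  t_cum <- c(0, cumsum(dt))
  fvc <- max(v) - min(v)
  pef <- max(q)
  if (max(t_cum) < 1) {
    fev1 <- fvc
    capped <- TRUE
  } else {
    fev1 <- stats::approx(t_cum, v - v[1L], xout = 1, ties = "ordered")$y
    capped <- FALSE
  }
  tibble::tibble(fev1 = fev1, fvc = fvc, pef = pef,
                 fev1_fvc_ratio = fev1 / fvc, fev1_capped = capped)
}

#' @exportS3Method ggplot2::autoplot
autoplot.mefv_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(.data$volume_l, .data$flow_l_s)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Expired volume (L)", y = "Flow (L/s)",
                  title = "Maximal expiratory flow-volume curve") +
    ggplot2::theme_minimal()
}
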