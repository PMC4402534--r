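# default t threshold: two-sided p < 1e-4 on 2*window - 2 degrees of freedom
.step_threshold <- function(window) stats::qt(1 - 1e-4 / 2, df = 2 * window - 2)

# centered rolling median with an (even or odd) window; edges use the
# available samples only
.rolling_median <- function(x, window) {
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  vapply(seq_len(n), function(i)
    stats::median(x[max(1L, i - half_lo):min(n, i + half_hi)]), numeric(1))
}

#' Detect rupture steps with a running t-test
#'
#' Slides two adjacent windows of `window` samples along the extension
#' series and computes the pooled two-sample t statistic between them at
#' every candidate boundary. Local maxima of |t| above `threshold` are
#' reported as steps, with non-maximum suppression so that no two events lie
#' within `window` samples of each other. The step size is the difference of
#' the window means (positive for an extension gain on a pulling trace).
#'
#' @param trace A [fiber_trace()] with at least `2 * window` samples.
#' @param window Number of samples on each side of the candidate boundary.
#'   Default 10.
#' @param threshold Minimum |t|; default corresponds to a two-sided
#'   p < 1e-4 on `2 * window - 2` degrees of freedom (about 5.0 for the
#'   10-point window).
#' @return Data frame of class `step_events` with columns `index` (first
#'   sample after the step), `force_pN`, `step_nm`, `t_stat`; zero rows when
#'   no step is found.
#' @export
find_steps <- function(trace, window = 10, threshold = NULL) {
  stopifnot(inherits(trace, "fiber_trace"), window >= 2)
  if (is.null(threshold)) threshold <- .step_threshold(window)
  x <- trace$extension_nm
  n <- length(x)
  if (n < 2 * window) stop("trace too short for a ", window, "-point window")
  # running sums over the window before (ending at i-1) and after (starting i)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  idx <- (window + 1L):(n - window + 1L)      # candidate boundaries
  s_before  <- cs[idx - 1L] - c(0, cs)[idx - window]
  s2_before <- cs2[idx - 1L] - c(0, cs2)[idx - window]
  s_after   <- cs[idx + window - 1L] - cs[idx - 1L]
  s2_after  <- cs2[idx + window - 1L] - cs2[idx - 1L]
  m1 <- s_before / window; m2 <- s_after / window
  ss1 <- s2_before - window * m1^2; ss2 <- s2_after - window * m2^2
  sp2 <- (ss1 + ss2) / (2 * window - 2)
  tstat <- (m2 - m1) / sqrt(pmax(sp2, .Machine$double.eps) * 2 / window)
  at <- abs(tstat)
  cand <- which(at > threshold)
  # local maxima of |t| only
  cand <- cand[vapply(cand, function(i) {
    lo <- max(1L, i - 1L); hi <- min(length(at), i + 1L)
    at[i] >= max(at[lo:hi])
  }, logical(1))]
  # non-maximum suppression within one window
  keep <- integer(0)
  for (i in cand[order(at[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(idx[keep] - idx[i]) >= window))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  out <- data.frame(index = idx[keep],
                    force_pN = trace$force_pN[idx[keep]],
                    step_nm = m2[keep] - m1[keep],
                    t_stat = tstat[keep])
  class(out) <- c("step_events", "data.frame")
  out
}

#' Align the extension offset against the bare-DNA WLC
#'
#' Magnetic-tweezers extensions carry an arbitrary offset from off-center
#' bead attachment. After the last rupture all nucleosomal DNA is released,
#' so the tail of the trace must follow the WLC of the full contour length;
#' a constant is subtracted so that the mean residual of the post-last-step
#' segment against `wlc_extension(f, total_contour * rise)` is zero. When no
#' step is detected the whole trace is treated as bare DNA.
#'
#' @param trace A [fiber_trace()].
#' @param total_contour Total DNA contour length in bp.
#' @param mech A [mechanics_params()].
#' @param window,threshold Passed to [find_steps()].
#' @return The aligned trace; the subtracted offset (nm) is stored in
#'   `attr(, "offset")`.
#' @export
align_offset <- function(trace, total_contour, mech = mechanics_params(),
                         window = 10, threshold = NULL) {
  stopifnot(inherits(trace, "fiber_trace"))
  steps <- find_steps(trace, window = window, threshold = threshold)
  first <- if (nrow(steps)) max(steps$index) + window else 1L
  post <- seq(first, nrow(trace))
  if (length(post) < 5L)
    stop("no usable segment after the last rupture; cannot align offset")
  f <- trace$force_pN[post]
  ok <- f > 0
  if (!any(ok)) stop("post-rupture segment has no positive-force samples")
  resid <- trace$extension_nm[post][ok] -
    wlc_extension(f[ok], total_contour * mech$rise_per_bp, mech)
  offset <- mean(resid)
  trace$extension_nm <- trace$extension_nm - offset
  attr(trace, "offset") <- offset
  trace
}

#' Subtract linear drift using a reference trace
#'
#' Successive pulls (or a pull and its release) of the same tether must
#' overlap where the transitions are reversible; a slow linear drift of the
#' setup breaks that overlap. The reference extension is interpolated as a
#' function of force, the residual of this trace against it is regressed on
#' time, and the fitted linear-in-time term is subtracted.
#'
#' @param trace,reference [fiber_trace()] objects with time stamps.
#' @return The corrected trace; the fitted drift rate (nm/s) is stored in
#'   `attr(, "drift_rate")`.
#' @export
correct_drift <- function(trace, reference) {
  stopifnot(inherits(trace, "fiber_trace"), inherits(reference, "fiber_trace"))
  if (!("time_s" %in% names(trace)) || !("time_s" %in% names(reference)))
    stop("correct_drift requires time stamps in both traces")
  o <- order(reference$force_pN)
  zref <- stats::approx(reference$force_pN[o], reference$extension_nm[o],
                        xout = trace$force_pN, rule = 2, ties = mean)$y
  r <- trace$extension_nm - zref
  fit <- stats::lm(r ~ trace$time_s)
  trace$extension_nm <- trace$extension_nm - stats::fitted(fit)
  attr(trace, "drift_rate") <- unname(stats::coef(fit)[2L])
  trace
}

# extension ladder of the states composed of extended and unwrapped
# nucleosomes: m = number unwrapped, columns of the returned matrix
.state_ladder <- function(f, model) {
  n <- round(model$n_fiber + model$n_unfolded)
  rise <- model$mech$rise_per_bp
  zh <- if (model$handle_contour > 0)
    wlc_extension(f, model$handle_contour * rise, model$mech) else 0
  ze <- wlc_extension(f, (model$nrl - model$l_wrap) * rise, model$mech) +
    model$z_ext
  zu <- wlc_extension(f, model$nrl * rise, model$mech)
  m <- 0:n
  outer(zh + n * ze, rep(1, n + 1)) + outer(zu - ze, m)
}

#' Calibrate the extended-state extension from the high-force ladder
#'
#' The extra extension `z_ext` of the extended conformation shifts the whole
#' ladder of extended/unwrapped states; the value is obtained by scanning
#' candidate offsets and keeping the one whose ladder, with every sample
#' assigned to its nearest state, leaves the smallest total squared
#' residual across one or more staircase traces.
#'
#' @param traces A [fiber_trace()] or list of them (high-force staircases).
#' @param model A [fiber_model()]; its `z_ext` is ignored.
#' @param candidates Candidate `z_ext` values in nm.
#' @return The residual-minimising candidate, with the full residual profile
#'   in `attr(, "profile")`.
#' @export
calibrate_z_ext <- function(traces, model, candidates = seq(0, 10, by = 0.05)) {
  if (inherits(traces, "fiber_trace")) traces <- list(traces)
  rss <- vapply(candidates, function(ze) {
    m <- model; m$z_ext <- ze
    sum(vapply(traces, function(tr) {
      ladder <- .state_ladder(tr$force_pN, m)
      sum(apply(abs(ladder - tr$extension_nm), 1L, min)^2)
    }, numeric(1)))
  }, numeric(1))
  best <- candidates[which.min(rss)]
  attr(best, "profile") <- data.frame(z_ext = candidates, rss = rss)
  best
}

#' Assign high-force samples to the unwrapping state ladder
#'
#' Above the first rupture the fiber is no longer in equilibrium; each
#' sample is matched to the nearest member of the extension ladder of states
#' composed of extended and fully unwrapped nucleosomes. Ties are broken
#' toward fewer unwrapped nucleosomes (the earlier pathway state). The
#' assigned model extension is then smoothed with a 10-point median filter
#' to suppress spurious reassignments driven by thermal fluctuations.
#'
#' @param trace A [fiber_trace()] (typically restricted to forces above the
#'   first detected rupture).
#' @param model A [fiber_model()]; the ladder has
#'   `round(n_fiber + n_unfolded) + 1` rungs.
#' @param median_window Samples in the median filter. Default 10.
#' @return Data frame with columns `n_unwrapped` (per-sample state label)
#'   and `extension_model_nm` (median-filtered ladder extension).
#' @export
assign_states <- function(trace, model, median_window = 10) {
  stopifnot(inherits(trace, "fiber_trace"), inherits(model, "fiber_model"))
  n <- round(model$n_fiber + model$n_unfolded)
  if (n < 1) stop("assign_states needs a model with at least one particle")
  ladder <- .state_ladder(trace$force_pN, model)
  d <- abs(ladder - trace$extension_nm)
  lab <- max.col(-d, ties.method = "first") - 1L   # first = fewer unwrapped
  zfit <- ladder[cbind(seq_len(nrow(d)), lab + 1L)]
  zfit <- .rolling_median(zfit, median_window)
  data.frame(n_unwrapped = lab, extension_model_nm = zfit)
}
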