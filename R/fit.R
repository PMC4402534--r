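# fittable parameters, their boxes, and where they live in the model
.FIT_PARS <- c("n_fiber", "n_unfolded", "k", "z0", "z_ext", "dG1", "dG2", "offset")

.par_bounds <- function(n_max) {
  list(n_fiber    = c(0, 2 * n_max),
       n_unfolded = c(0, 2 * n_max),
       k          = c(1e-3, 5),
       z0         = c(0, 5),
       z_ext      = c(0, 15),
       dG1        = c(0, 60),
       dG2       = c(0, 30),
       offset     = c(-Inf, Inf))
}

.apply_pars <- function(model, pars) {
  for (nm in setdiff(names(pars), "offset")) model[[nm]] <- unname(pars[[nm]])
  model
}

#' Fit the equilibrium force-extension regime
#'
#' Levenberg-Marquardt least-squares fit of the partition-function mean
#' extension ([mean_extension_fractional()] plus a constant offset) to the
#' below-first-rupture part of a trace. Composition parameters (`n_fiber`,
#' `n_unfolded`) are continuous through bilinear interpolation over the
#' bracketing integer state sums. Points below `f_min` (default 0.5 pN, to
#' exclude bead-surface artifacts) and at or above `f_max` (default: the
#' force of the first detected rupture step) are excluded. Several jittered
#' starts are run and the best residual kept.
#'
#' @param trace A preprocessed (offset-aligned, drift-corrected)
#'   [fiber_trace()].
#' @param initial A [fiber_model()] holding starting values and all fixed
#'   parameters.
#' @param free Character vector of parameters to fit, from
#'   `n_fiber, n_unfolded, k, z0, z_ext, dG1, dG2, offset`.
#' @param f_min,f_max Force window in pN. When `f_max` is `NULL` the trace
#'   is scanned for rupture steps at forces above `f_search_min` and the
#'   first one bounds the window; the steep but smooth unfolding plateau at
#'   lower force must not be mistaken for a rupture, so the search starts in
#'   the regime where the hysteretic last transition occurs.
#' @param f_search_min Smallest force (pN) at which a rupture step is
#'   searched for the default `f_max`. Default 7.
#' @param allowed Equilibrium conformation set (see [mean_extension()]).
#' @param n_starts Number of multi-start replicates. Default 5.
#' @param offset_init Starting value of the co-fitted constant offset (nm).
#' @return An object of class `fiber_fit`: fitted model, coefficient table
#'   with asymptotic standard errors from the Jacobian, residuals,
#'   convergence flag and a clean-composition indicator (fitted counts
#'   within 0.1 of an integer).
#' @seealso [fit_mononucleosome()], [stability_report()]
#' @export
fit_equilibrium <- function(trace, initial,
                            free = c("dG1", "dG2", "k", "z0", "offset"),
                            f_min = 0.5, f_max = NULL,
                            allowed = c("fiber", "single_wrap", "extended"),
                            n_starts = 5, offset_init = 0, f_search_min = 7) {
  stopifnot(inherits(trace, "fiber_trace"), inherits(initial, "fiber_model"))
  free <- match.arg(free, .FIT_PARS, several.ok = TRUE)
  if (is.null(f_max)) {
    steps <- tryCatch(find_steps(trace), error = function(e) NULL)
    if (!is.null(steps)) steps <- steps[steps$force_pN >= f_search_min, ]
    f_max <- if (!is.null(steps) && nrow(steps)) min(steps$force_pN) else Inf
  }
  sel <- trace$force_pN >= f_min & trace$force_pN < f_max
  fdat <- trace$force_pN[sel]; zdat <- trace$extension_nm[sel]
  if (length(fdat) <= length(free))
    stop("fewer usable data points (", length(fdat),
         ") than free parameters (", length(free), ")")
  n_max <- max(1, initial$n_fiber + initial$n_unfolded)
  bounds <- .par_bounds(n_max)
  start0 <- stats::setNames(vapply(free, function(p)
    if (p == "offset") offset_init else initial[[p]], numeric(1)), free)
  lower <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  upper <- vapply(free, function(p) bounds[[p]][2], numeric(1))

  resid_fn <- function(p) {
    p <- stats::setNames(p, free)
    m <- .apply_pars(initial, as.list(p))
    off <- if ("offset" %in% free) p[["offset"]] else offset_init
    zdat - (mean_extension_fractional(fdat, m, allowed) + off)
  }

  # deterministic multi-start: multiplicative jitter on free parameters
  jit <- list(1, 0.85, 1.15, 0.7, 1.3, 0.9, 1.1)
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    st <- start0
    if (s > 1) {
      fac <- jit[[1 + (s - 1) %% length(jit)]]
      st <- start0 * fac
      if ("offset" %in% free)
        st["offset"] <- start0["offset"] + 20 * (fac - 1)
      st <- pmin(pmax(st, lower + 1e-9), ifelse(is.finite(upper), upper, st))
    }
    ans <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(ans) &&
        (is.null(best) || sum(ans$fvec^2) < sum(best$fvec^2)))
      best <- ans
  }
  if (is.null(best)) stop("all optimizer starts failed")

  est <- stats::setNames(as.numeric(best$par), free)
  rss <- sum(best$fvec^2)
  dfree <- length(fdat) - length(free)
  se <- rep(NA_real_, length(free))
  cv <- tryCatch(solve(best$hessian) * rss / max(dfree, 1),
                 error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  names(se) <- free
  model_fit <- .apply_pars(initial, as.list(est))
  offset <- if ("offset" %in% free) est[["offset"]] else offset_init
  fitted_z <- mean_extension_fractional(fdat, model_fit, allowed) + offset
  ns <- c(model_fit$n_fiber, model_fit$n_unfolded)
  structure(list(
    coefficients = est,
    stderr = se,
    fixed = stats::setNames(vapply(setdiff(.FIT_PARS, free), function(p)
      if (p == "offset") offset_init else initial[[p]], numeric(1)),
      setdiff(.FIT_PARS, free)),
    model = model_fit,
    offset = offset,
    allowed = allowed,
    force = fdat,
    observed = zdat,
    fitted = fitted_z,
    residuals = zdat - fitted_z,
    rss = rss,
    sigma = sqrt(rss / max(dfree, 1)),
    npoints = length(fdat),
    f_window = c(f_min, f_max),
    converged = best$info %in% 1:4,
    info = best$info,
    clean_composition = all(abs(ns - round(ns)) <= 0.1)),
    class = "fiber_fit")
}

#' Fit a mononucleosome force-extension curve
#'
#' Same machinery as [fit_equilibrium()] for a single particle whose
#' equilibrium state space is fully wrapped (147 bp on the core), single
#' wrap and extended; the fully wrapped conformation is the energy
#' reference. `dG1` is then the unwrapping free energy of a nucleosome
#' without neighbours, directly comparable with the fiber value.
#'
#' @inheritParams fit_equilibrium
#' @param initial A [fiber_model()] with `n_fiber = 1`, `n_unfolded = 0`;
#'   `handle_contour + nrl` is the substrate length in bp.
#' @return A `fiber_fit` object.
#' @export
fit_mononucleosome <- function(trace, initial,
                               free = c("dG1", "dG2", "z_ext", "offset"),
                               f_min = 0.5, f_max = NULL, n_starts = 5,
                               offset_init = 0) {
  stopifnot(inherits(initial, "fiber_model"))
  initial$n_fiber <- 1; initial$n_unfolded <- 0
  fit_equilibrium(trace, initial, free = free, f_min = f_min, f_max = f_max,
                  allowed = c("wrapped", "single_wrap", "extended"),
                  n_starts = n_starts, offset_init = offset_init)
}

#' Compare fitted composition with step count and positioning elements
#'
#' The number of high-force rupture steps counts every particle that wraps
#' at least one turn (nucleosomes plus tetrasomes), while the fitted
#' `n_fiber` counts only fiber-folded nucleosomes, and the DNA substrate
#' carries a fixed number of positioning elements. Disagreement between the
#' three flags compositional heterogeneity of the reconstitution.
#'
#' @param fit A `fiber_fit`.
#' @param n_positioning_elements Number of positioning-sequence repeats in
#'   the substrate.
#' @param n_steps Number of detected high-force rupture steps (from
#'   [find_steps()]).
#' @return List with the three counts, `n_total` from the fit, and a logical
#'   `heterogeneous` flag; printed as a short report.
#' @export
stability_report <- function(fit, n_positioning_elements, n_steps) {
  stopifnot(inherits(fit, "fiber_fit"))
  nf <- round(fit$model$n_fiber); nu <- round(fit$model$n_unfolded)
  het <- (n_steps != n_positioning_elements) || (nf != n_positioning_elements) ||
    (nf + nu != n_steps)
  structure(list(n_fiber = nf, n_unfolded = nu, n_total = nf + nu,
                 n_steps = n_steps,
                 n_positioning_elements = n_positioning_elements,
                 heterogeneous = het),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Composition: n_fiber = %d, n_unfolded = %d (total %d)\n",
              x$n_fiber, x$n_unfolded, x$n_total))
  cat(sprintf("High-force steps: %d; positioning elements: %d\n",
              x$n_steps, x$n_positioning_elements))
  cat(if (x$heterogeneous) "Heterogeneous composition flagged.\n"
      else "Composition consistent with substrate.\n")
  invisible(x)
}

#' @export
print.fiber_fit <- function(x, ...) {
  cat("Equilibrium force-extension fit (", x$npoints, " points, ",
      sprintf("%.2f-%.2f pN", x$f_window[1],
              min(x$f_window[2], max(x$force))), ")\n", sep = "")
  print(data.frame(estimate = x$coefficients, std_error = x$stderr))
  cat(sprintf("Residual sd: %.3g nm; converged: %s\n", x$sigma, x$converged))
  invisible(x)
}

#' @export
summary.fiber_fit <- function(object, ...) {
  cat("Fitted chromatin model\n")
  print(object)
  fx <- object$fixed
  cat("Fixed: ", paste(sprintf("%s = %g", names(fx), fx), collapse = ", "),
      "\n", sep = "")
  cat("Clean composition (counts within 0.1 of integer): ",
      object$clean_composition, "\n", sep = "")
  invisible(object)
}

#' @export
coef.fiber_fit <- function(object, ...) object$coefficients

#' @export
residuals.fiber_fit <- function(object, ...) object$residuals

#' @export
predict.fiber_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$force else {
    if (is.data.frame(newdata)) newdata$force_pN else as.numeric(newdata)
  }
  mean_extension_fractional(f, object$model, object$allowed) + object$offset
}

#' @export
plot.fiber_fit <- function(x, ...) {
  graphics::plot(x$observed, x$force, pch = 16, cex = 0.4, col = "grey50",
                 xlab = "extension (nm)", ylab = "force (pN)", ...)
  o <- order(x$force)
  graphics::lines(x$fitted[o], x$force[o], col = "black", lwd = 2)
  invisible(x)
}

#' @export
simulate.fiber_fit <- function(object, nsim = 1, seed = 1, ...) {
  proto <- pull_protocol(forces = object$force,
                         noise_sigma = object$sigma, seed = seed)
  out <- lapply(seq_len(nsim), function(i) {
    p <- proto; p$seed <- as.integer(seed + i - 1)
    m <- object$model
    tr <- generate_equilibrium_segment(m, p, allowed = object$allowed)
    tr$extension_nm <- tr$extension_nm + object$offset
    tr
  })
  if (nsim == 1) out[[1]] else out
}
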