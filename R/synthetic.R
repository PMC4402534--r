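# run code with a private, restorable RNG state so generators are
# bit-reproducible without clobbering the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pulling protocol for synthetic traces
#'
#' Describes an emulated magnetic-tweezers experiment: the force schedule,
#' camera rate, extension noise, instrumental drift and the law from which
#' the (non-equilibrium) last-rupture forces of individual particles are
#' drawn.
#'
#' @param forces Force schedule in pN (a ramp, or ramp up plus ramp down);
#'   all values in (0, 40].
#' @param sample_rate Sampling rate in Hz. Default 60 (camera rate).
#' @param noise_sigma Gaussian extension noise, nm. Default 5.
#' @param drift_rate Linear drift, nm/s. Default 0.
#' @param rupture Rupture-force law for the last unwrapping step: either
#'   `list(family = "uniform", f_min =, f_max =)` (default 9-25 pN, the
#'   force range in which the discrete high-force steps are observed) or
#'   `list(family = "bell", k0 =, x_dagger =, loading_rate =)` for a
#'   Bell-Evans escape under a linear force ramp (k0 in 1/s, x_dagger in nm,
#'   loading_rate in pN/s).
#' @param seed Integer seed; identical seed + protocol + model give a
#'   bit-identical trace.
#' @return An object of class `pull_protocol`.
#' @export
pull_protocol <- function(forces, sample_rate = 60, noise_sigma = 5,
                          drift_rate = 0,
                          rupture = list(family = "uniform", f_min = 9, f_max = 25),
                          seed = 1L) {
  stopifnot(is.numeric(forces), all(forces > 0), all(forces <= 40),
            sample_rate > 0, noise_sigma >= 0)
  structure(list(forces = forces, sample_rate = sample_rate,
                 noise_sigma = noise_sigma, drift_rate = drift_rate,
                 rupture = rupture, seed = as.integer(seed)),
            class = "pull_protocol")
}

#' Linear force ramp helper
#'
#' @param f_start,f_end Ramp end points in pN.
#' @param duration_s Ramp duration in s.
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric force schedule.
#' @export
force_ramp <- function(f_start, f_end, duration_s = 60, sample_rate = 60) {
  n <- max(2L, round(duration_s * sample_rate))
  seq(f_start, f_end, length.out = n)
}

.draw_rupture_forces <- function(n, rupture) {
  fam <- if (is.null(rupture$family)) "uniform" else rupture$family
  if (fam == "uniform") {
    stats::runif(n, rupture$f_min, rupture$f_max)
  } else if (fam == "bell") {
    # survival S(f) = exp(-k0 kT/(x r) [exp(f x/kT) - 1]) under ramp rate r
    kT <- if (is.null(rupture$thermal_energy)) 4.10 else rupture$thermal_energy
    u <- stats::runif(n)
    a <- rupture$k0 * kT / (rupture$x_dagger * rupture$loading_rate)
    kT / rupture$x_dagger * log(1 - log(u) / a)
  } else stop("unknown rupture family: ", fam)
}

#' Simulate the equilibrium (below-rupture) part of a pulling trace
#'
#' Extension at each scheduled force is the equilibrium mean of the
#' partition-function model ([mean_extension_fractional()]) plus Gaussian
#' noise and optional linear drift. The construction is time-reversible:
#' running the schedule up or down gives statistically identical extensions,
#' matching the absence of hysteresis below the rupture regime.
#'
#' @param model A [fiber_model()].
#' @param protocol A [pull_protocol()]; forces should stay below the rupture
#'   regime.
#' @param allowed Equilibrium conformation set (see [mean_extension()]); use
#'   `c("wrapped", "single_wrap", "extended")` for a mononucleosome.
#' @return A [fiber_trace()] with time stamps.
#' @export
generate_equilibrium_segment <- function(model, protocol,
                                         allowed = c("fiber", "single_wrap", "extended")) {
  stopifnot(inherits(model, "fiber_model"), inherits(protocol, "pull_protocol"))
  f <- protocol$forces
  t <- (seq_along(f) - 1) / protocol$sample_rate
  z <- mean_extension_fractional(f, model, allowed)
  .with_seed(protocol$seed, {
    z <- z + stats::rnorm(length(f), 0, protocol$noise_sigma) +
      protocol$drift_rate * t
  })
  fiber_trace(force = f, extension = z, time = t)
}

# extension of a staircase given per-particle rupture forces
.staircase_extension <- function(f, model, f_rup) {
  rise <- model$mech$rise_per_bp
  zh <- if (model$handle_contour > 0)
    wlc_extension(f, model$handle_contour * rise, model$mech) else 0
  ze <- wlc_extension(f, (model$nrl - model$l_wrap) * rise, model$mech) +
    model$z_ext
  zu <- wlc_extension(f, model$nrl * rise, model$mech)
  m <- vapply(f, function(fi) sum(f_rup <= fi), numeric(1))
  n <- length(f_rup)
  zh + (n - m) * ze + m * zu
}

#' Simulate the high-force rupture staircase
#'
#' Each of the `round(n_fiber + n_unfolded)` particles is assigned an
#' independent rupture force from the protocol's rupture law; below it the
#' particle contributes the extended-conformation extension, above it the
#' unwrapped extension, producing the staircase of discrete steps seen in a
#' force clamp. Gaussian noise is added, and the ground-truth events are
#' returned alongside the trace.
#'
#' @param model A [fiber_model()].
#' @param protocol A [pull_protocol()] whose schedule covers the rupture
#'   regime (roughly 7-25 pN).
#' @return A [fiber_trace()] with attributes `events` (data frame of true
#'   steps: `index`, `force_pN`, `step_nm`) and `rupture_forces`.
#' @export
generate_rupture_staircase <- function(model, protocol) {
  stopifnot(inherits(model, "fiber_model"), inherits(protocol, "pull_protocol"))
  f <- protocol$forces
  t <- (seq_along(f) - 1) / protocol$sample_rate
  n <- round(model$n_fiber + model$n_unfolded)
  .with_seed(protocol$seed, {
    f_rup <- .draw_rupture_forces(n, protocol$rupture)
    noise <- stats::rnorm(length(f), 0, protocol$noise_sigma)
  })
  z <- .staircase_extension(f, model, f_rup) + noise + protocol$drift_rate * t
  tr <- fiber_trace(force = f, extension = z, time = t)
  rise <- model$mech$rise_per_bp
  idx <- vapply(f_rup, function(fr) {
    i <- which(f >= fr)
    if (length(i)) min(i) else NA_integer_
  }, integer(1))
  step <- wlc_extension(pmax(f_rup, 1e-6), model$l_wrap * rise, model$mech) -
    model$z_ext
  ev <- data.frame(index = idx, force_pN = f_rup, step_nm = step)
  ev <- ev[order(ev$force_pN), , drop = FALSE]
  rownames(ev) <- NULL
  attr(tr, "events") <- ev
  attr(tr, "rupture_forces") <- sort(f_rup)
  tr
}

#' Simulate a full pulling experiment
#'
#' Concatenates the equilibrium response and the rupture staircase into one
#' consistent trace: below its rupture force every pathway nucleosome
#' follows the equilibrium state sum, above it it is unwrapped; `n_unfolded`
#' particles contribute the extended extension until their own rupture.
#' Optionally appends a release ramp on which ruptured particles stay
#' unwrapped until the force drops below `rewrap_force`, reproducing the
#' hysteresis of the last transition only.
#'
#' @param model A [fiber_model()].
#' @param protocol A [pull_protocol()] spanning the full force range
#'   (roughly 0.3-25 pN).
#' @param release Logical; append the mirrored release schedule. Default
#'   FALSE.
#' @param rewrap_force Force (pN) below which ruptured nucleosomes rewrap on
#'   release. Default 3.
#' @return A [fiber_trace()] with attributes `events` and `rupture_forces`
#'   as in [generate_rupture_staircase()].
#' @export
generate_full_experiment <- function(model, protocol, release = FALSE,
                                     rewrap_force = 3) {
  stopifnot(inherits(model, "fiber_model"), inherits(protocol, "pull_protocol"))
  f <- protocol$forces
  nf <- round(model$n_fiber); nu <- round(model$n_unfolded)
  n <- nf + nu
  if (release) f <- c(f, rev(f))
  t <- (seq_along(f) - 1) / protocol$sample_rate
  .with_seed(protocol$seed, {
    f_rup <- sort(.draw_rupture_forces(n, protocol$rupture))
    noise <- stats::rnorm(length(f), 0, protocol$noise_sigma)
  })
  rise <- model$mech$rise_per_bp
  zu <- wlc_extension(pmax(f, 1e-6), model$nrl * rise, model$mech)
  np <- length(protocol$forces)
  m <- vapply(seq_along(f), function(i) {
    if (i <= np) sum(f_rup <= f[i])             # pull: ruptured so far
    else if (f[i] >= rewrap_force) sum(f_rup <= max(f[seq_len(np)]))
    else 0                                       # release below rewrap force
  }, numeric(1))
  # fiber nucleosomes and tetrasomes rupture interleaved; assign particle
  # types to the rupture-force order reproducibly
  is_unf <- rep(c(FALSE, TRUE), c(nf, nu))
  .with_seed(protocol$seed + 1L, is_unf <- sample(is_unf))
  z <- numeric(length(f))
  eq_cache <- new.env(parent = emptyenv())  # equilibrium curve per composition
  for (i in seq_along(f)) {
    ruptured <- seq_len(m[i])               # f_rup is sorted ascending
    nf_rem <- nf - sum(!is_unf[ruptured])
    nu_rem <- nu - sum(is_unf[ruptured])
    key <- sprintf("%d_%d", nf_rem, nu_rem)
    if (is.null(eq_cache[[key]])) {
      mm <- model; mm$n_fiber <- nf_rem; mm$n_unfolded <- nu_rem
      eq_cache[[key]] <- mean_extension(pmax(f, 1e-6), mm)
    }
    z[i] <- eq_cache[[key]][i] + m[i] * zu[i]
  }
  z <- z + noise + protocol$drift_rate * t
  tr <- fiber_trace(force = f, extension = z, time = t)
  idx <- vapply(f_rup, function(fr) {
    i <- which(f[seq_len(np)] >= fr)
    if (length(i)) min(i) else NA_integer_
  }, integer(1))
  step <- wlc_extension(f_rup, model$l_wrap * rise, model$mech) - model$z_ext
  attr(tr, "events") <- data.frame(index = idx, force_pN = f_rup,
                                   step_nm = step)
  attr(tr, "rupture_forces") <- f_rup
  tr
}
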