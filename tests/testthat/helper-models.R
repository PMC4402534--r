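# shared fixtures: reference parameter sets and protocols used across tests

# 15x197-NRL fiber with the reference constrained-fit energetics
fiber_197 <- function(...) {
  args <- list(nrl = 197, n_fiber = 15, n_unfolded = 0, handle_contour = 2000,
               k = 0.28, z0 = 1.2, z_ext = 4.6, dG1 = 21.2, dG2 = 4.3)
  do.call(fiber_model, utils::modifyList(args, list(...)))
}

# 30x167-NRL fiber (zig-zag type: first transition non-degenerate)
fiber_167 <- function(...) {
  args <- list(nrl = 167, n_fiber = 30, n_unfolded = 0, handle_contour = 2000,
               k = 0.6, z0 = 1.2, z_ext = 4.6, dG1 = 18, dG2 = 5.0,
               degeneracy_mode = "non_degenerate_first")
  do.call(fiber_model, utils::modifyList(args, list(...)))
}

# mononucleosome on a 3000-bp substrate
mono_model <- function(...) {
  args <- list(nrl = 197, n_fiber = 1, n_unfolded = 0, handle_contour = 2803,
               z_ext = 6.5, dG1 = 8.8, dG2 = 3.5)
  do.call(fiber_model, utils::modifyList(args, list(...)))
}

MONO_STATES <- c("wrapped", "single_wrap", "extended")

eq_protocol <- function(seed, noise_sigma = 5, f_max = 7, duration_s = 60,
                        sample_rate = 10)
  pull_protocol(forces = force_ramp(0.5, f_max, duration_s, sample_rate),
                noise_sigma = noise_sigma, seed = seed)

stair_protocol <- function(seed, noise_sigma = 3, f_min = 7, f_max = 25,
                           duration_s = 60, sample_rate = 60)
  pull_protocol(forces = force_ramp(f_min, f_max, duration_s, sample_rate),
                noise_sigma = noise_sigma, seed = seed)

# literal Boltzmann double loop over enumerated states, no matrix shortcuts;
# the independent oracle for mean_extension
brute_mean_extension <- function(f, model,
                                 allowed = c("fiber", "single_wrap", "extended")) {
  S <- enumerate_states(model$n_fiber, allowed)
  kT <- model$mech$thermal_energy
  rise <- model$mech$rise_per_bp
  vapply(f, function(fi) {
    num <- 0; den <- 0
    for (r in seq_len(nrow(S))) {
      z <- 0; g <- 0
      for (j in seq_along(allowed)) {
        z <- z + S[r, j] * conformation_extension(fi, allowed[j], model)
        g <- g + S[r, j] * conformation_energy(fi, allowed[j], model)
      }
      w <- degeneracy(stats::setNames(S[r, ], allowed),
                      model$degeneracy_mode) * exp(-g / kT)
      num <- num + w * z
      den <- den + w
    }
    zfix <- wlc_extension(fi, model$handle_contour * rise, model$mech) +
      model$n_unfolded *
        (wlc_extension(fi, (model$nrl - model$l_wrap) * rise, model$mech) +
           model$z_ext)
    num / den + zfix
  }, numeric(1))
}
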