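#' Nucleosome conformation labels, ordered along the unfolding pathway
#'
#' `"fiber"` (folded in the fiber, Hookean), `"wrapped"` (fully wrapped
#' mononucleosome, 147 bp on the core), `"single_wrap"` (one full turn, 89 bp
#' remaining), `"extended"` (single wrap plus a constant extra extension
#' `z_ext`) and `"unwrapped"` (all nucleosomal DNA released). A chromatin
#' fiber explores fiber/single_wrap/extended in equilibrium; a mononucleosome
#' explores wrapped/single_wrap/extended; the unwrapped conformation is
#' reached only through the non-equilibrium high-force ruptures.
#'
#' @format Character vector of the five labels.
#' @export
CONFORMATIONS <- c("fiber", "wrapped", "single_wrap", "extended", "unwrapped")

#' Chromatin fiber model
#'
#' Composition and energetics of a nucleosome array under tension. The array
#' holds `n_fiber` nucleosomes that follow the full unfolding pathway
#' (fiber -> single wrap -> extended -> unwrapped) and `n_unfolded` particles
#' (interpreted as tetrasomes) that sit in the extended conformation and only
#' undergo the last, non-equilibrium unwrapping step. Counts may be
#' non-integer; the equilibrium extension is then interpolated bilinearly
#' between the bracketing integer compositions.
#'
#' @param nrl Nucleosome repeat length in bp (DNA per nucleosome including
#'   linker), e.g. 197 or 167.
#' @param n_fiber Number of fiber-folded nucleosomes (may be fractional).
#' @param n_unfolded Number of particles pinned to the extended conformation
#'   below their rupture (may be fractional).
#' @param handle_contour Bare DNA handles in bp (total of both sides).
#' @param l_wrap DNA in a single full wrap, bp. Default 89.
#' @param wrap_full DNA in a fully wrapped nucleosome, bp. Default 147.
#' @param k Fiber stiffness per nucleosome, pN/nm.
#' @param z0 Fiber contour length per nucleosome, nm.
#' @param z_ext Extra extension of the extended conformation, nm.
#' @param dG1 Free energy of the first transition (fiber or wrapped ->
#'   single wrap), in kBT.
#' @param dG2 Free energy of the second transition (single wrap -> extended),
#'   in kBT.
#' @param dG3 Free energy of the last transition (extended -> unwrapped), in
#'   kBT. Not measurable from equilibrium fits (the last step is hysteretic);
#'   kept only for bookkeeping and excluded from the equilibrium state space.
#' @param degeneracy_mode One of `"degenerate"` (pairwise-binomial product
#'   over conformation pairs), `"non_degenerate_first"` (the
#'   fiber/single-wrap pair contributes no degeneracy, as for cooperative
#'   rupture from the fiber ends), `"fully_non_degenerate"` (D = 1 for every
#'   state) or `"multinomial"` (exact count of orderings; sensitivity
#'   alternative to the pairwise product).
#' @param mech A [mechanics_params()] object.
#'
#' @return An object of class `fiber_model`.
#' @examples
#' m <- fiber_model(nrl = 197, n_fiber = 15, dG1 = 21.2, dG2 = 4.3)
#' mean_extension(3.5, m)
#' @export
fiber_model <- function(nrl = 197,
                        n_fiber = 15,
                        n_unfolded = 0,
                        handle_contour = 2000,
                        l_wrap = 89,
                        wrap_full = 147,
                        k = 0.28,
                        z0 = 1.2,
                        z_ext = 4.6,
                        dG1 = 21.2,
                        dG2 = 4.3,
                        dG3 = NA_real_,
                        degeneracy_mode = c("degenerate", "non_degenerate_first",
                                            "fully_non_degenerate", "multinomial"),
                        mech = mechanics_params()) {
  degeneracy_mode <- match.arg(degeneracy_mode)
  stopifnot(inherits(mech, "mechanics_params"),
            n_fiber >= 0, n_unfolded >= 0,
            l_wrap > 0, l_wrap < wrap_full, wrap_full <= nrl,
            handle_contour >= 0, k > 0, z_ext >= 0)
  structure(list(nrl = nrl, n_fiber = n_fiber, n_unfolded = n_unfolded,
                 handle_contour = handle_contour, l_wrap = l_wrap,
                 wrap_full = wrap_full, k = k, z0 = z0, z_ext = z_ext,
                 dG1 = dG1, dG2 = dG2, dG3 = dG3,
                 degeneracy_mode = degeneracy_mode, mech = mech),
            class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat("Chromatin fiber model\n")
  cat(sprintf("  composition: n_fiber = %g, n_unfolded = %g on %g-bp NRL, %g bp handles\n",
              x$n_fiber, x$n_unfolded, x$nrl, x$handle_contour))
  cat(sprintf("  fiber: k = %g pN/nm, z0 = %g nm; extended: z_ext = %g nm\n",
              x$k, x$z0, x$z_ext))
  cat(sprintf("  energies: dG1 = %g kBT, dG2 = %g kBT; degeneracy: %s\n",
              x$dG1, x$dG2, x$degeneracy_mode))
  invisible(x)
}

# contour length in nm of the free DNA for one nucleosome in each conformation
.conf_contour_nm <- function(conformation, model) {
  rise <- model$mech$rise_per_bp
  switch(conformation,
         fiber       = NA_real_,
         wrapped     = (model$nrl - model$wrap_full) * rise,
         single_wrap = (model$nrl - model$l_wrap) * rise,
         extended    = (model$nrl - model$l_wrap) * rise,
         unwrapped   = model$nrl * rise,
         stop("unknown conformation: ", conformation))
}

#' Per-nucleosome extension of a conformation
#'
#' Extension contributed by one nucleosome in a given conformation: the
#' Hookean fiber element for `"fiber"`, otherwise the extensible WLC of the
#' free DNA in that conformation, plus `z_ext` for the extended state.
#'
#' @param f Force in pN, positive (vectorised).
#' @param conformation One of [CONFORMATIONS].
#' @param model A [fiber_model()].
#' @return Extension per nucleosome in nm.
#' @export
conformation_extension <- function(f, conformation, model) {
  stopifnot(inherits(model, "fiber_model"))
  if (any(f <= 0)) stop("conformation_extension requires f > 0")
  conformation <- match.arg(conformation, CONFORMATIONS)
  if (conformation == "fiber") return(fiber_extension(f, model$k, model$z0))
  z <- wlc_extension(f, .conf_contour_nm(conformation, model), model$mech)
  if (conformation == "extended") z <- z + model$z_ext
  z
}

#' Per-nucleosome free energy of a conformation
#'
#' Free energy (in pN nm) of one nucleosome in a given conformation, relative
#' to the fiber conformation at zero force: the integrated force-extension
#' work of the element plus the accumulated transition energies
#' (`dG1`, `dG2`, `dG3`, converted from kBT) and the mechanical coupling
#' \eqn{-f z_{ext}} of the extended state. The fully wrapped mononucleosome
#' conformation is the pathway's energy reference (no transition cost).
#'
#' @inheritParams conformation_extension
#' @param f Force in pN, non-negative (vectorised).
#' @return Free energy in pN nm.
#' @export
conformation_energy <- function(f, conformation, model) {
  stopifnot(inherits(model, "fiber_model"))
  if (any(f < 0)) stop("conformation_energy requires f >= 0")
  conformation <- match.arg(conformation, CONFORMATIONS)
  kT <- model$mech$thermal_energy
  if (conformation == "fiber")
    return(fiber_free_energy(f, model$k, model$z0))
  g <- wlc_free_energy(f, .conf_contour_nm(conformation, model), model$mech)
  g + switch(conformation,
             wrapped     = 0,
             single_wrap = model$dG1 * kT,
             extended    = (model$dG1 + model$dG2) * kT - f * model$z_ext,
             unwrapped   = (model$dG1 + model$dG2 + model$dG3) * kT)
}
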