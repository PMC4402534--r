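#' Enumerate conformational states of an array
#'
#' All ways to distribute `n` indistinguishable-by-extension nucleosomes over
#' the allowed conformations, i.e. all compositions of `n` into
#' `length(allowed)` parts. There are `choose(n + k - 1, k - 1)` such states
#' for `k` allowed conformations.
#'
#' @param n Number of particles (non-negative integer).
#' @param allowed Character vector of conformation labels (subset of
#'   [CONFORMATIONS]), in pathway order.
#' @return Integer matrix, one row per state, columns named by `allowed`.
#' @export
enumerate_states <- function(n, allowed = c("fiber", "single_wrap", "extended")) {
  stopifnot(length(allowed) >= 1, n >= 0, n == round(n))
  allowed <- match.arg(allowed, CONFORMATIONS, several.ok = TRUE)
  k <- length(allowed)
  if (k == 1L) {
    m <- matrix(as.integer(n), 1L, 1L)
  } else {
    rec <- function(n, k) {
      if (k == 1L) return(matrix(as.integer(n), 1L, 1L))
      do.call(rbind, lapply(0:n, function(i)
        cbind(as.integer(i), rec(n - i, k - 1L))))
    }
    m <- rec(as.integer(n), k)
  }
  colnames(m) <- allowed
  m
}

#' Degeneracy factor of a state
#'
#' Multiplicity of arrangements of a state along the array, computed as a
#' product of binomial coefficients over all pairs of conformations:
#' \deqn{D = \prod_{i<j} \binom{n_i + n_j}{n_i}.}
#' When at most two conformations are occupied this equals the number of
#' distinct orderings; with three or more occupied conformations the pairwise
#' product over-counts orderings (e.g. counts (1,1,1) give 8 vs 6), which is
#' why the `"multinomial"` mode (exact ordering count
#' \eqn{n!/\prod_i n_i!}) is offered as a sensitivity alternative.
#' `"non_degenerate_first"` sets the (fiber, single_wrap) pair factor to 1,
#' modelling cooperative first-transition rupture from the fiber ends;
#' `"fully_non_degenerate"` returns 1 for every state.
#'
#' @param state Named integer vector (or single row of
#'   [enumerate_states()]): counts per conformation.
#' @param mode Degeneracy mode, see [fiber_model()].
#' @return A positive number.
#' @export
degeneracy <- function(state, mode = "degenerate") {
  mode <- match.arg(mode, c("degenerate", "non_degenerate_first",
                            "fully_non_degenerate", "multinomial"))
  n <- as.numeric(state)
  labs <- names(state)
  if (is.null(labs)) labs <- rep(NA_character_, length(n))
  if (any(n < 0) || any(n != round(n))) stop("state counts must be non-negative integers")
  if (mode == "fully_non_degenerate") return(1)
  if (mode == "multinomial")
    return(round(exp(lgamma(sum(n) + 1) - sum(lgamma(n + 1)))))
  d <- 1
  k <- length(n)
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (mode == "non_degenerate_first" &&
          identical(sort(c(labs[i], labs[j])), sort(c("fiber", "single_wrap"))))
        next
      d <- d * choose(n[i] + n[j], n[i])
    }
  }
  d
}

# degeneracy for every row of a state matrix
.degeneracy_vec <- function(states, mode) {
  apply(states, 1L, function(s) degeneracy(stats::setNames(s, colnames(states)), mode))
}

# extension (nm) and energy (pN nm) matrices, length(f) x length(allowed)
.conf_matrices <- function(f, model, allowed) {
  Z <- vapply(allowed, function(cf) conformation_extension(f, cf, model),
              numeric(length(f)))
  G <- vapply(allowed, function(cf) conformation_energy(f, cf, model),
              numeric(length(f)))
  if (length(f) == 1L) { Z <- matrix(Z, 1L); G <- matrix(G, 1L) }
  list(Z = Z, G = G)
}

# extension contributed by DNA handles plus the n_unfolded particles
# (pinned to the extended conformation); their energy is state-independent
# and cancels from the Boltzmann average.
.fixed_extension <- function(f, model) {
  rise <- model$mech$rise_per_bp
  zh <- if (model$handle_contour > 0)
    wlc_extension(f, model$handle_contour * rise, model$mech) else 0
  zu <- if (model$n_unfolded > 0)
    model$n_unfolded *
      (wlc_extension(f, (model$nrl - model$l_wrap) * rise, model$mech) +
         model$z_ext) else 0
  zh + zu
}

# state matrices and degeneracies depend only on (n, allowed, mode);
# memoised because the optimiser re-evaluates them thousands of times
.state_cache <- new.env(parent = emptyenv())

.states_and_degeneracy <- function(n, allowed, mode) {
  key <- paste(n, paste(allowed, collapse = ","), mode, sep = "|")
  hit <- .state_cache[[key]]
  if (!is.null(hit)) return(hit)
  states <- enumerate_states(n, allowed)
  out <- list(states = states, D = .degeneracy_vec(states, mode))
  .state_cache[[key]] <- out
  out
}

# Boltzmann weights over states at each force; returns list(W, Z) with W the
# length(f) x n_states weight matrix (normalised rows) and Z the matching
# per-state fiber-part extensions.
.state_weights <- function(f, model, allowed, n = NULL) {
  if (is.null(n)) n <- model$n_fiber
  if (n != round(n)) stop("internal: .state_weights needs integer n")
  sd <- .states_and_degeneracy(n, allowed, model$degeneracy_mode)
  states <- sd$states
  D <- sd$D
  cm <- .conf_matrices(f, model, allowed)
  Zs <- cm$Z %*% t(states)                     # F x S
  Gs <- cm$G %*% t(states)                     # F x S
  kT <- model$mech$thermal_energy
  # subtract the row minimum before exponentiating for numerical stability
  Gs <- Gs - apply(Gs, 1L, min)
  W <- sweep(exp(-Gs / kT), 2L, D, `*`)
  W <- W / rowSums(W)
  list(W = W, Zs = Zs, states = states)
}

#' Equilibrium mean extension of the tether
#'
#' Boltzmann-weighted mean extension at force `f`: the per-state extension
#' (sum of conformation extensions plus the WLC of the DNA handles) averaged
#' over all enumerated states with weights
#' \eqn{D(\mathrm{state}) \exp(-G_{tot}(f)/k_B T)}. The `n_unfolded`
#' particles contribute a fixed extended-conformation extension each. The
#' unwrapped conformation is excluded from the default equilibrium state
#' space because the last transition is hysteretic and its energy `dG3`
#' cannot be measured at equilibrium.
#'
#' Requires integer composition; see [mean_extension_fractional()] for the
#' interpolated version used during fitting.
#'
#' @param f Force in pN (vectorised); the fitting window starts at 0.5 pN.
#' @param model A [fiber_model()] with integer `n_fiber`.
#' @param allowed Conformations making up the equilibrium state space.
#' @return Extension in nm, same length as `f`.
#' @export
mean_extension <- function(f, model,
                           allowed = c("fiber", "single_wrap", "extended")) {
  stopifnot(inherits(model, "fiber_model"), length(allowed) >= 1)
  if (model$n_fiber == 0)
    return(.fixed_extension(f, model) + 0 * f)
  sw <- .state_weights(f, model, allowed)
  rowSums(sw$W * sw$Zs) + .fixed_extension(f, model)
}

#' Conformational occupancy probabilities
#'
#' Expected fraction of the `n_fiber` pathway nucleosomes in each
#' conformation at force `f`:
#' \eqn{P_i(f) = \sum_{states} (n_i/n) D e^{-G/k_B T} / Z}. Fractions sum to
#' one at every force.
#'
#' @inheritParams mean_extension
#' @return Matrix with `length(f)` rows and one column per conformation in
#'   `allowed`.
#' @export
occupancies <- function(f, model,
                        allowed = c("fiber", "single_wrap", "extended")) {
  stopifnot(inherits(model, "fiber_model"), model$n_fiber >= 1)
  sw <- .state_weights(f, model, allowed)
  P <- sw$W %*% (sw$states / model$n_fiber)
  colnames(P) <- allowed
  P
}

#' Mean extension for fractional composition
#'
#' The fitted numbers of nucleosomes are continuous parameters; the discrete
#' state sum is made continuous by bilinear interpolation of
#' [mean_extension()] between the floor/ceiling integer values of `n_fiber`
#' and `n_unfolded` independently. (The `n_unfolded` direction is exactly
#' linear by construction, so the bilinear scheme is exact there.)
#'
#' @inheritParams mean_extension
#' @param model A [fiber_model()]; `n_fiber` and `n_unfolded` may be
#'   non-integer.
#' @return Extension in nm, same length as `f`.
#' @export
mean_extension_fractional <- function(f, model,
                                      allowed = c("fiber", "single_wrap", "extended")) {
  stopifnot(inherits(model, "fiber_model"))
  nf <- model$n_fiber; nu <- model$n_unfolded
  nf0 <- floor(nf); nf1 <- ceiling(nf); wf <- nf - nf0
  nu0 <- floor(nu); nu1 <- ceiling(nu); wu <- nu - nu0
  at <- function(a, b) {
    m <- model; m$n_fiber <- a; m$n_unfolded <- b
    mean_extension(f, m, allowed)
  }
  z00 <- at(nf0, nu0)
  z10 <- if (wf > 0) at(nf1, nu0) else z00
  z01 <- if (wu > 0) at(nf0, nu1) else z00
  z11 <- if (wf > 0 && wu > 0) at(nf1, nu1) else if (wf > 0) z10 else z01
  (1 - wf) * (1 - wu) * z00 + wf * (1 - wu) * z10 +
    (1 - wf) * wu * z01 + wf * wu * z11
}
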