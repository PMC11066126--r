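# Mass-action equilibrium of the dimerization system.
#
# Pre-duplication: one gene, species A and AA.  Post-duplication: two paralogs
# A and B forming homodimers AA and BB and the heterodimer AB.  Folded
# subunits are produced at rate s * w (w = folded fraction), every species
# decays at its own first-order rate, and dimer concentrations follow from
# association constants at steady state.

#' @keywords internal
.GAS_CONSTANT <- 1.987e-3 # kcal K^-1 mol^-1

#' @keywords internal
.TEMPERATURE <- 298 # K

#' Parameters of one locus pair (or a single locus before duplication)
#'
#' Container for every evolvable parameter of the system: synthesis rates,
#' folding free energies, the three binding free energies, decay rates and
#' specific activities.  Leave the B-gene arguments `NULL` for the
#' pre-duplication, single-gene system.
#'
#' @param s_A,s_B Gene-level synthesis rates (concentration units / h).
#'   These are the raw rates; the rate of properly folded subunits used by
#'   the equilibrium equations is `s * folded_fraction(dG_fold)`.
#' @param dG_fold_A,dG_fold_B Folding free energies (kcal/mol); more negative
#'   means more stable.
#' @param dG_bind_AA,dG_bind_BB,dG_bind_AB Binding free energies (kcal/mol)
#'   of the two homodimers and the heterodimer.
#' @param decay Decay rates (1/h) for the five species, recycled from a
#'   scalar; order `A, B, AA, AB, BB`.
#' @param specific_activity Unitless activity per concentration unit for
#'   monomers (both), AA, AB, BB.
#' @param temperature_K,gas_constant Thermodynamic constants used to convert
#'   binding free energies into association constants.
#' @return An object of class `system_state`.
#' @examples
#' ref <- reference_state()
#' solve_pre_duplication(ref)
#' @export
system_state <- function(s_A, dG_fold_A, dG_bind_AA,
                         s_B = NULL, dG_fold_B = NULL,
                         dG_bind_AB = NULL, dG_bind_BB = NULL,
                         decay = 1.3,
                         specific_activity = c(monomer = 0.1, AA = 1,
                                               AB = 1, BB = 1),
                         temperature_K = .TEMPERATURE,
                         gas_constant = .GAS_CONSTANT) {
  duplicated <- !is.null(s_B)
  if (duplicated && (is.null(dG_fold_B) || is.null(dG_bind_AB) ||
                     is.null(dG_bind_BB)))
    stop("post-duplication state needs dG_fold_B, dG_bind_AB and dG_bind_BB")
  decay <- rep_len(decay, 5L)
  names(decay) <- c("A", "B", "AA", "AB", "BB")
  if (any(decay <= 0)) stop("decay rates must be positive")
  if (s_A < 0 || (duplicated && s_B < 0))
    stop("synthesis rates must be non-negative")
  if (length(specific_activity) != 4L || any(specific_activity < 0))
    stop("specific_activity must be 4 non-negative values (monomer, AA, AB, BB)")
  names(specific_activity) <- c("monomer", "AA", "AB", "BB")
  structure(list(
    s_A = s_A, s_B = if (duplicated) s_B else NA_real_,
    dG_fold_A = dG_fold_A,
    dG_fold_B = if (duplicated) dG_fold_B else NA_real_,
    dG_bind_AA = dG_bind_AA,
    dG_bind_AB = if (duplicated) dG_bind_AB else NA_real_,
    dG_bind_BB = if (duplicated) dG_bind_BB else NA_real_,
    decay = decay, specific_activity = specific_activity,
    temperature_K = temperature_K, gas_constant = gas_constant,
    duplicated = duplicated), class = "system_state")
}

#' Reference parameterization of the model
#'
#' Typical starting values: synthesis 100 units/h per gene, folding free
#' energy -5 kcal/mol, binding free energy -10 kcal/mol, all decay rates
#' 1.3/h, specific activity 0.1 for monomers and 1 for all dimers.  With
#' these values total activity is 38.2/h before and 76.4/h after duplication.
#'
#' @param duplicated If `TRUE`, return the two-gene state with identical
#'   paralogs; otherwise the single-gene ancestral state.
#' @inheritParams system_state
#' @param s,dG_fold,dG_bind Shared values applied to both paralogs.
#' @return A `system_state`.
#' @export
reference_state <- function(duplicated = FALSE, s = 100, dG_fold = -5,
                            dG_bind = -10, decay = 1.3,
                            specific_activity = c(monomer = 0.1, AA = 1,
                                                  AB = 1, BB = 1)) {
  if (duplicated)
    system_state(s_A = s, dG_fold_A = dG_fold, dG_bind_AA = dG_bind,
                 s_B = s, dG_fold_B = dG_fold, dG_bind_AB = dG_bind,
                 dG_bind_BB = dG_bind, decay = decay,
                 specific_activity = specific_activity)
  else
    system_state(s_A = s, dG_fold_A = dG_fold, dG_bind_AA = dG_bind,
                 decay = decay, specific_activity = specific_activity)
}

#' Fraction of properly folded protein
#'
#' Boltzmann (logistic) form `w = 1 / (1 + exp(dG_fold))`: half the copies
#' are folded at dG_fold = 0 and w decreases as folding becomes less stable.
#' Misfolded copies are removed and never enter complexes.
#'
#' @param dG_fold Folding free energy (kcal/mol); vectorized.
#' @return Folded fraction in (0, 1).
#' @examples
#' folded_fraction(c(-5, 0, 5))
#' @export
folded_fraction <- function(dG_fold) {
  if (!all(is.finite(dG_fold))) stop("dG_fold must be finite")
  1 / (1 + exp(dG_fold))
}

#' Association constant of a dimer
#'
#' `K = exp(-dG_bind / (R T))`, with a statistical factor of 2 for the
#' heterodimer that corrects for the mixing entropy inherently favoring
#' heteromers when two subunit pools mix.  This placement of the factor is
#' what makes two identical paralogs settle at the 1:2:1 (AA:AB:BB)
#' binomial equilibrium.
#'
#' @param dG_bind Binding free energy (kcal/mol); vectorized.
#' @param heterodimer Apply the mixing-entropy factor of 2?
#' @param gas_constant,temperature_K Thermodynamic constants.
#' @return Association constant (per concentration unit), capped at
#'   `exp(700)` to avoid overflow for unphysically strong binding.
#' @examples
#' association_constant(-10)
#' association_constant(-10, heterodimer = TRUE)
#' @export
association_constant <- function(dG_bind, heterodimer = FALSE,
                                 gas_constant = .GAS_CONSTANT,
                                 temperature_K = .TEMPERATURE) {
  if (!all(is.finite(dG_bind))) stop("dG_bind must be finite")
  if (temperature_K <= 0) stop("temperature_K must be positive")
  x <- pmin(-dG_bind / (gas_constant * temperature_K), 700)
  k <- exp(x)
  if (heterodimer) 2 * k else k
}

#' @keywords internal
.state_constants <- function(state) {
  list(
    sA = state$s_A * folded_fraction(state$dG_fold_A),
    sB = if (state$duplicated)
      state$s_B * folded_fraction(state$dG_fold_B) else 0,
    kAA = association_constant(state$dG_bind_AA, FALSE,
                               state$gas_constant, state$temperature_K),
    kAB = if (state$duplicated)
      association_constant(state$dG_bind_AB, TRUE,
                           state$gas_constant, state$temperature_K) else 0,
    kBB = if (state$duplicated)
      association_constant(state$dG_bind_BB, FALSE,
                           state$gas_constant, state$temperature_K) else 0)
}

#' @keywords internal
.conc_vector <- function(A = 0, B = 0, AA = 0, AB = 0, BB = 0) {
  c(A = A, B = B, AA = AA, AB = AB, BB = BB)
}

#' Equilibrium concentrations before duplication
#'
#' For the single-gene system the monomer concentration is the positive root
#' of the quadratic mass balance
#' `c_A = (-d_A + sqrt(d_A^2 + 8 d_AA k_AA s_A)) / (4 d_AA k_AA)` and the
#' homodimer follows as `c_AA = k_AA c_A^2`, where `s_A` is the synthesis
#' rate of properly folded subunits.
#'
#' @param state A pre-duplication `system_state` (`gene B` absent).
#' @return Named numeric vector of concentrations `A, B, AA, AB, BB`
#'   (B-species entries zero).
#' @examples
#' solve_pre_duplication(reference_state())
#' @export
solve_pre_duplication <- function(state) {
  stopifnot(inherits(state, "system_state"))
  if (state$duplicated) stop("state already duplicated; use solve_post_duplication")
  k <- .state_constants(state)
  if (k$kAA <= 0) stop("association constant must be positive")
  dA <- state$decay[["A"]]; dAA <- state$decay[["AA"]]
  if (k$sA == 0) return(.conc_vector())
  # stable form of the quadratic root (no cancellation for weak binding)
  cA <- 2 * k$sA / (dA + sqrt(dA^2 + 8 * dAA * k$kAA * k$sA))
  .conc_vector(A = cA, AA = k$kAA * cA^2)
}

#' @keywords internal
.post_quartic_coefficients <- function(sA, sB, decay, kAA, kAB, kBB) {
  a <- decay[["AA"]] * kAA
  b <- decay[["BB"]] * kBB
  h <- decay[["AB"]] * kAB
  dA <- decay[["A"]]; dB <- decay[["B"]]
  # increasing powers of c_A
  c(2 * sA^2 * b / h,
    sA * (dB - 4 * dA * b / h),
    2 * b * dA^2 / h + sA * (h - 8 * a * b / h) - dA * dB - h * sB,
    dA * (8 * a * b / h - h) - 2 * dB * a,
    2 * a * (4 * a * b / h - h))
}

#' @keywords internal
.flux_balance_root <- function(s, q, a) {
  # stable positive root of 2 a c^2 + q c - s = 0
  if (s <= 0) return(0)
  if (a < 1e-300) return(s / q)
  2 * s / (q + sqrt(q^2 + 8 * a * s))
}

#' @keywords internal
# Damped Newton iteration on the two subunit flux balances; polishes the
# quartic root and recovers the equilibrium when root extraction loses
# precision at extreme parameter scales.  Returns NULL if not converged.
.post_newton <- function(sA, sB, decay, kAA, kAB, kBB, cA0, cB0) {
  a <- decay[["AA"]] * kAA; b <- decay[["BB"]] * kBB; h <- decay[["AB"]] * kAB
  dA <- decay[["A"]]; dB <- decay[["B"]]
  if (sA <= 0 || sB <= 0) {
    cA <- .flux_balance_root(sA, dA, a)
    cB <- .flux_balance_root(sB, dB, b)
    return(.conc_vector(A = cA, B = cB, AA = kAA * cA^2, BB = kBB * cB^2))
  }
  cA <- max(cA0, 1e-300); cB <- max(cB0, 1e-300)
  for (it in 1:200) {
    F1 <- dA * cA + 2 * a * cA^2 + h * cA * cB - sA
    F2 <- dB * cB + 2 * b * cB^2 + h * cA * cB - sB
    J11 <- dA + 4 * a * cA + h * cB; J12 <- h * cA
    J21 <- h * cB; J22 <- dB + 4 * b * cB + h * cA
    det <- J11 * J22 - J12 * J21
    dcA <- (F1 * J22 - F2 * J12) / det
    dcB <- (J11 * F2 - J21 * F1) / det
    damp <- 1
    if (dcA > 0.5 * cA) damp <- min(damp, 0.5 * cA / dcA)
    if (dcB > 0.5 * cB) damp <- min(damp, 0.5 * cB / dcB)
    cA <- cA - damp * dcA; cB <- cB - damp * dcB
    if (damp == 1 && abs(dcA) <= 1e-13 * cA && abs(dcB) <= 1e-13 * cB)
      return(.conc_vector(A = cA, B = cB, AA = kAA * cA^2,
                          AB = kAB * cA * cB, BB = kBB * cB^2))
  }
  # step-size test can chatter in the last bits; accept on residuals
  F1 <- dA * cA + 2 * a * cA^2 + h * cA * cB - sA
  F2 <- dB * cB + 2 * b * cB^2 + h * cA * cB - sB
  if (abs(F1) <= 1e-10 * sA && abs(F2) <= 1e-10 * sB)
    return(.conc_vector(A = cA, B = cB, AA = kAA * cA^2,
                        AB = kAB * cA * cB, BB = kBB * cB^2))
  NULL
}

#' Equilibrium concentrations after duplication
#'
#' The monomer concentration c_A solves a quartic polynomial; the remaining
#' species follow by back-substitution:
#' `c_B = (s_A / c_A - 2 d_AA k_AA c_A - d_A) / (d_AB k_AB)`,
#' `c_AA = k_AA c_A^2`, `c_BB = k_BB c_B^2`, `c_AB = k_AB c_A c_B`.
#' All four roots are computed and the unique root giving positive
#' concentrations for all five species is returned; zero or several such
#' roots raise an error rather than being silently resolved.  When the
#' heterodimer association constant underflows (below 1e-12) the system
#' decouples into two independent single-gene systems (continuous limit,
#' `c_AB = 0`).
#'
#' @param state A post-duplication `system_state`.
#' @return Named numeric vector of concentrations `A, B, AA, AB, BB`.
#' @examples
#' solve_post_duplication(reference_state(duplicated = TRUE))
#' @export
solve_post_duplication <- function(state) {
  stopifnot(inherits(state, "system_state"))
  if (!state$duplicated) stop("state is pre-duplication; use solve_pre_duplication")
  k <- .state_constants(state)
  if (k$kAA <= 0 || k$kBB <= 0) stop("association constants must be positive")
  if (k$kAB < 1e-12) { # degenerate heterodimer binding: decoupled limit
    half_A <- system_state(state$s_A, state$dG_fold_A, state$dG_bind_AA,
                           decay = state$decay,
                           specific_activity = state$specific_activity)
    half_B <- system_state(state$s_B, state$dG_fold_B, state$dG_bind_BB,
                           decay = state$decay[c(2, 1, 5, 4, 3)],
                           specific_activity = state$specific_activity)
    cA <- solve_pre_duplication(half_A)
    cB <- solve_pre_duplication(half_B)
    return(.conc_vector(A = cA[["A"]], B = cB[["A"]],
                        AA = cA[["AA"]], BB = cB[["AA"]]))
  }
  coefs <- .post_quartic_coefficients(k$sA, k$sB, state$decay,
                                      k$kAA, k$kAB, k$kBB)
  scale <- max(abs(coefs))
  nz <- rev(cumsum(rev(abs(coefs) > 1e-14 * scale)) > 0)
  roots <- polyroot(coefs[seq_len(max(which(nz)))])
  real <- Re(roots[abs(Im(roots)) <= 1e-9 * pmax(1, abs(Re(roots)))])
  dA <- state$decay[["A"]]
  a <- state$decay[["AA"]] * k$kAA
  b <- state$decay[["BB"]] * k$kBB
  h <- state$decay[["AB"]] * k$kAB
  sols <- list()
  for (cA in real[real > 0]) {
    cB <- (k$sA / cA - 2 * a * cA - dA) / h
    if (cB < -1e-9 * max(cA, abs(cB))) next
    # the A-side back-substitution for c_B cancels catastrophically under
    # strong binding; re-derive c_B from the B-side balance and polish —
    # every admissible root must converge to the unique equilibrium
    cB0 <- .flux_balance_root(k$sB, state$decay[["B"]] + h * cA, b)
    cand <- .post_newton(k$sA, k$sB, state$decay, k$kAA, k$kAB, k$kBB,
                         cA, cB0)
    if (!is.null(cand)) sols[[length(sols) + 1L]] <- cand
  }
  if (length(sols) == 0L) {
    # recover via the flux-balance iteration from the decoupled solution
    cA0 <- .flux_balance_root(k$sA, dA, a)
    cB0 <- .flux_balance_root(k$sB, state$decay[["B"]], b)
    it <- .post_newton(k$sA, k$sB, state$decay, k$kAA, k$kAB, k$kBB, cA0, cB0)
    if (!is.null(it)) return(it)
    stop("no all-positive equilibrium root found")
  }
  if (length(sols) > 1L) {
    spread <- max(vapply(sols, function(s) max(abs(s - sols[[1]])), 0)) /
      max(abs(sols[[1]]), 1e-300)
    if (spread > 1e-6)
      stop("multiple distinct all-positive equilibrium roots found")
  }
  sols[[1]]
}

#' Equilibrium concentrations (dispatcher)
#'
#' Calls [solve_pre_duplication()] or [solve_post_duplication()] depending on
#' whether the state carries a second gene.
#'
#' @inheritParams solve_pre_duplication
#' @return Named numeric vector of concentrations.
#' @export
solve_equilibrium <- function(state) {
  if (state$duplicated) solve_post_duplication(state)
  else solve_pre_duplication(state)
}

#' Total activity of the system
#'
#' Specific-activity-weighted sum of the equilibrium concentrations
#' (default weights: 0.1 for monomers, 1 for the homodimers and the
#' heterodimer).  This is the single quantity selection acts on.
#'
#' @param conc Named concentration vector as returned by the solvers.
#' @param specific_activity Weights for monomer, AA, AB, BB.
#' @return Total activity (1/h).
#' @examples
#' total_activity(solve_pre_duplication(reference_state()))
#' @export
total_activity <- function(conc,
                           specific_activity = c(monomer = 0.1, AA = 1,
                                                 AB = 1, BB = 1)) {
  stopifnot(length(conc) == 5L, all(is.finite(conc)))
  specific_activity[["monomer"]] * (conc[["A"]] + conc[["B"]]) +
    specific_activity[["AA"]] * conc[["AA"]] +
    specific_activity[["AB"]] * conc[["AB"]] +
    specific_activity[["BB"]] * conc[["BB"]]
}

#' Lognormal fitness function
#'
#' Unimodal map from total activity to fitness,
#' `f(a) = beta ^ (log2(a / alpha)^2)`: maximal fitness 1 at `a = alpha`,
#' symmetric on the log scale, and equal to `beta` when activity is half or
#' twice the optimum.  Non-positive activity returns fitness 0 (convention:
#' a system producing nothing is inviable).
#'
#' @param activity Total activity (1/h); vectorized.
#' @param alpha Activity with maximal fitness (1/h).
#' @param beta Fitness at `alpha / 2` and `2 * alpha`, in (0, 1).
#' @return Fitness in \[0, 1\].
#' @examples
#' fitness_lognormal(c(40, 80, 160), alpha = 80, beta = 0.5)
#' @export
fitness_lognormal <- function(activity, alpha = 80, beta = 0.5) {
  if (alpha <= 0) stop("alpha must be positive")
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  out <- numeric(length(activity))
  ok <- activity > 0
  out[ok] <- beta^(log2(activity[ok] / alpha)^2)
  out
}

#' Evaluate the model over a parameter grid
#'
#' Sweeps one or two parameters of a `system_state` over dense grids and
#' tabulates the equilibrium concentrations, the heterodimer share among
#' dimers, total activity and fitness at every grid point.  Reproduces the
#' fitness-landscape views of the model (e.g. heterodimer percentage as a
#' function of the two folding energies or of two binding energies).
#'
#' @param state Template `system_state`; swept parameters override its
#'   values.
#' @param axes Named list of numeric vectors.  Valid names: `s_A`, `s_B`,
#'   `dG_fold_A`, `dG_fold_B`, `dG_bind_AA`, `dG_bind_AB`, `dG_bind_BB`.
#'   A name may contain several comma-separated parameters
#'   (e.g. `"dG_fold_A,dG_fold_B"`) that are swept jointly with the same
#'   values.
#' @param alpha,beta Fitness parameters passed to [fitness_lognormal()].
#' @param fitness_fn Fitness strategy; any function of `(activity)`
#'   returning fitness.  Defaults to the lognormal form.
#' @return A long-format `data.frame`: one row per grid point with the swept
#'   values, the five concentrations, `het_pct_dimers`, `activity` and
#'   `fitness`.
#' @examples
#' grid <- landscape_grid(reference_state(duplicated = TRUE),
#'                        list(dG_bind_AB = seq(-12, -8, length.out = 5)))
#' grid[, c("dG_bind_AB", "het_pct_dimers", "activity")]
#' @export
landscape_grid <- function(state, axes, alpha = 80, beta = 0.5,
                           fitness_fn = function(a)
                             fitness_lognormal(a, alpha, beta)) {
  valid <- c("s_A", "s_B", "dG_fold_A", "dG_fold_B",
             "dG_bind_AA", "dG_bind_AB", "dG_bind_BB")
  if (length(axes) < 1L || length(axes) > 2L)
    stop("axes must name 1 or 2 swept parameters")
  axis_params <- lapply(names(axes), function(nm) {
    parts <- trimws(strsplit(nm, ",", fixed = TRUE)[[1]])
    bad <- setdiff(parts, valid)
    if (length(bad))
      stop("unknown axis parameter(s): ", paste(bad, collapse = ", "))
    parts
  })
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vapply(axis_params, paste, "", collapse = ",")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    st <- state
    for (j in seq_along(axis_params))
      for (p in axis_params[[j]]) st[[p]] <- grid[i, j]
    conc <- solve_equilibrium(st)
    act <- total_activity(conc, st$specific_activity)
    dimers <- conc[["AA"]] + conc[["AB"]] + conc[["BB"]]
    data.frame(c_A = conc[["A"]], c_B = conc[["B"]], c_AA = conc[["AA"]],
               c_AB = conc[["AB"]], c_BB = conc[["BB"]],
               het_pct_dimers = if (dimers > 0) 100 * conc[["AB"]] / dimers
                                else NA_real_,
               activity = act, fitness = fitness_fn(act))
  })
  cbind(grid, do.call(rbind, res))
}
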