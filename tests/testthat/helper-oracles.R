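# Independent oracles used across the suite.

# Mass-action ODE steady state of the five-species system, with explicit
# association/dissociation rates chosen so that k = r_on / (d + r_off).
# Integrated from empty initial conditions to t_end (all relaxation times
# are ~1/d = 0.8 h, so t_end = 80 h is deep in the steady state).
ode_steady_state_post <- function(state, t_end = 80) {
  k <- dimerevol:::.state_constants(state)
  d <- state$decay
  r_off <- c(AA = 1, AB = 1, BB = 1)
  r_on <- c(AA = k$kAA * (d[["AA"]] + r_off[["AA"]]),
            AB = k$kAB * (d[["AB"]] + r_off[["AB"]]),
            BB = k$kBB * (d[["BB"]] + r_off[["BB"]]))
  rhs <- function(t, y, p) {
    cA <- y[1]; cB <- y[2]; cAA <- y[3]; cAB <- y[4]; cBB <- y[5]
    list(c(
      k$sA - d[["A"]] * cA - 2 * r_on[["AA"]] * cA^2 + 2 * r_off[["AA"]] * cAA -
        r_on[["AB"]] * cA * cB + r_off[["AB"]] * cAB,
      k$sB - d[["B"]] * cB - 2 * r_on[["BB"]] * cB^2 + 2 * r_off[["BB"]] * cBB -
        r_on[["AB"]] * cA * cB + r_off[["AB"]] * cAB,
      r_on[["AA"]] * cA^2 - (r_off[["AA"]] + d[["AA"]]) * cAA,
      r_on[["AB"]] * cA * cB - (r_off[["AB"]] + d[["AB"]]) * cAB,
      r_on[["BB"]] * cB^2 - (r_off[["BB"]] + d[["BB"]]) * cBB))
  }
  out <- deSolve::ode(rep(0, 5), c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-16)
  stats::setNames(out[2, 2:6], c("A", "B", "AA", "AB", "BB"))
}

ode_steady_state_pre <- function(state, t_end = 80) {
  k <- dimerevol:::.state_constants(state)
  d <- state$decay
  r_off <- 1
  r_on <- k$kAA * (d[["AA"]] + r_off)
  rhs <- function(t, y, p) {
    cA <- y[1]; cAA <- y[2]
    list(c(k$sA - d[["A"]] * cA - 2 * r_on * cA^2 + 2 * r_off * cAA,
           r_on * cA^2 - (r_off + d[["AA"]]) * cAA))
  }
  out <- deSolve::ode(c(0, 0), c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-16)
  stats::setNames(c(out[2, 2], 0, out[2, 3], 0, 0),
                  c("A", "B", "AA", "AB", "BB"))
}

# Random valid post-duplication state: binding energies log-uniform-ish in
# [-15, -2] kcal/mol, synthesis in [10, 500] units/h, folding in [-10, 0].
random_post_state <- function() {
  system_state(s_A = runif(1, 10, 500), dG_fold_A = -runif(1, 0, 10),
               dG_bind_AA = -runif(1, 2, 15),
               s_B = runif(1, 10, 500), dG_fold_B = -runif(1, 0, 10),
               dG_bind_AB = -runif(1, 2, 15),
               dG_bind_BB = -runif(1, 2, 15))
}

# Per-subunit steady-state flux balance: synthesis of folded subunits equals
# decay through monomer + 2x homodimer + heterodimer.
flux_imbalance <- function(state, conc) {
  k <- dimerevol:::.state_constants(state)
  d <- state$decay
  outA <- d[["A"]] * conc[["A"]] + 2 * d[["AA"]] * conc[["AA"]] +
    d[["AB"]] * conc[["AB"]]
  outB <- d[["B"]] * conc[["B"]] + 2 * d[["BB"]] * conc[["BB"]] +
    d[["AB"]] * conc[["AB"]]
  max(abs(outA - k$sA) / max(k$sA, 1e-300),
      if (state$duplicated) abs(outB - k$sB) / max(k$sB, 1e-300) else 0)
}

# Brute-force Wright-Fisher fixation frequency for a new mutant at initial
# frequency 1/N under relative selection coefficient s (haploid sampling).
wf_fixation_freq <- function(s, N, n_runs) {
  p <- rep(1 / N, n_runs)
  fixed <- rep(NA, n_runs)
  while (anyNA(fixed)) {
    act <- which(is.na(fixed))
    pa <- p[act] * (1 + s) / (1 + p[act] * s)
    cnt <- stats::rbinom(length(act), N, pa)
    p[act] <- cnt / N
    fixed[act[cnt == 0L]] <- FALSE
    fixed[act[cnt == N]] <- TRUE
  }
  mean(fixed)
}

# Rank correlation computed from first principles (mid-ranks by counting).
brute_force_spearman <- function(x, y) {
  rank_of <- function(v) vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, 0)
  rx <- rank_of(x); ry <- rank_of(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Recompute equilibrium, activity and fitness for one trajectory row through
# the R-level API (independent of the compiled path that produced it).
recompute_trajectory_row <- function(row, config) {
  st <- system_state(row$s_A, row$dG_fold_A, row$dG_bind_AA,
                     s_B = row$s_B, dG_fold_B = row$dG_fold_B,
                     dG_bind_AB = row$dG_bind_AB,
                     dG_bind_BB = row$dG_bind_BB,
                     decay = config$decay,
                     specific_activity = dimerevol:::.activities_from_bias(
                       config$monomer_activity, config$het_activity_bias))
  conc <- solve_post_duplication(st)
  act <- total_activity(conc, st$specific_activity)
  list(conc = conc, activity = act,
       fitness = fitness_lognormal(act, config$alpha, config$beta))
}
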