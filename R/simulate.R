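# Origin-fixation Monte-Carlo simulation.  Mutations arise one at a time,
# the equilibrium and fitness are recomputed from scratch, and the mutation
# fixes with a probability given by the fixation model.  The duplication is
# always the first fixed event; afterwards only coding and expression
# mutations are proposed.  The inner loop runs in compiled code
# (src/simulate.cpp); this file holds the configuration, the R-level
# reference operations used for testing, and the replicate drivers.

#' Fixation probability of a new mutation
#'
#' Default model: Kimura's diffusion approximation for a new semidominant
#' mutation with relative selection coefficient
#' `s = fitness_new / fitness_old - 1`:
#' `p = (1 - exp(-2 s)) / (1 - exp(-2 N s))`, continuous in `s` with the
#' neutral limit `1/N`.  A Metropolis-style alternative
#' (`p = min(1, fitness_new / fitness_old)`) is available behind the same
#' interface.
#'
#' @param fitness_old,fitness_new Fitness before/after the mutation;
#'   vectorized.
#' @param population_size Effective population size `N` (Kimura model only).
#' @param model `"kimura"` (default) or `"metropolis"`.
#' @return Fixation probability in \[0, 1\].
#' @examples
#' fixation_probability(0.5, 0.5, 1000)   # neutral: 1/N
#' fixation_probability(0.5, 0.55, 1000)  # beneficial
#' @export
fixation_probability <- function(fitness_old, fitness_new,
                                 population_size = 1000,
                                 model = c("kimura", "metropolis")) {
  model <- match.arg(model)
  n <- max(length(fitness_old), length(fitness_new))
  fo <- rep_len(fitness_old, n); fn <- rep_len(fitness_new, n)
  if (model == "metropolis")
    return(ifelse(fo <= 0, as.numeric(fn > 0), pmin(1, fn / fo)))
  if (population_size < 2) stop("population_size must be at least 2")
  s <- ifelse(fo <= 0, ifelse(fn > 0, Inf, 0), fn / fo - 1)
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.finite(s[i])) { p[i] <- 1; next }
    if (abs(s[i]) < 1e-12) { p[i] <- 1 / population_size; next }
    den <- -expm1(-2 * population_size * s[i])
    p[i] <- if (den == 0) 1 / population_size else -expm1(-2 * s[i]) / den
  }
  pmin(pmax(p, 0), 1)
}

#' A single mutational event
#'
#' @param kind `"coding"`, `"expression"` or `"duplication"`.
#' @param target Affected paralog, `"A"` or `"B"` (not used for
#'   duplication).
#' @param ddG_fold,ddG_bind_HM,ddG_bind_HET Coding effects (kcal/mol).
#' @param expr_eps Expression effect; the synthesis rate is multiplied by
#'   `1 + expr_eps`.
#' @return Object of class `mutation_effect`.
#' @export
mutation_effect <- function(kind = c("coding", "expression", "duplication"),
                            target = c("A", "B"),
                            ddG_fold = 0, ddG_bind_HM = 0, ddG_bind_HET = 0,
                            expr_eps = 0) {
  kind <- match.arg(kind)
  target <- if (kind == "duplication") NA_character_ else match.arg(target)
  structure(list(kind = kind, target = target, ddG_fold = ddG_fold,
                 ddG_bind_HM = ddG_bind_HM, ddG_bind_HET = ddG_bind_HET,
                 expr_eps = expr_eps), class = "mutation_effect")
}

#' Apply a mutational event to a system state
#'
#' Coding effects add `ddG_fold` to the target paralog's folding energy,
#' `ddG_bind_HM` to that paralog's homodimer binding energy (the other
#' homodimer is untouched) and `ddG_bind_HET` to the shared heterodimer
#' binding energy.  Expression effects multiply the target's synthesis rate
#' by `1 + expr_eps`.  A duplication turns a single-gene state into a
#' two-gene state with identical parameters.
#'
#' @param state A `system_state`.
#' @param effect A [mutation_effect()].
#' @return The mutated `system_state`.
#' @export
apply_mutation <- function(state, effect) {
  stopifnot(inherits(state, "system_state"),
            inherits(effect, "mutation_effect"))
  if (effect$kind == "duplication") {
    if (state$duplicated) stop("state is already duplicated")
    return(system_state(state$s_A, state$dG_fold_A, state$dG_bind_AA,
                        s_B = state$s_A, dG_fold_B = state$dG_fold_A,
                        dG_bind_AB = state$dG_bind_AA,
                        dG_bind_BB = state$dG_bind_AA,
                        decay = state$decay,
                        specific_activity = state$specific_activity,
                        temperature_K = state$temperature_K,
                        gas_constant = state$gas_constant))
  }
  if (!state$duplicated && effect$target == "B")
    stop("pre-duplication state has no paralog B")
  if (effect$kind == "expression") {
    fld <- if (effect$target == "A") "s_A" else "s_B"
    state[[fld]] <- max(0, state[[fld]] * (1 + effect$expr_eps))
    return(state)
  }
  if (effect$target == "A") {
    state$dG_fold_A <- state$dG_fold_A + effect$ddG_fold
    state$dG_bind_AA <- state$dG_bind_AA + effect$ddG_bind_HM
  } else {
    state$dG_fold_B <- state$dG_fold_B + effect$ddG_fold
    state$dG_bind_BB <- state$dG_bind_BB + effect$ddG_bind_HM
  }
  if (state$duplicated)
    state$dG_bind_AB <- state$dG_bind_AB + effect$ddG_bind_HET
  state
}

#' Simulation configuration
#'
#' @param n_fixed Number of fixed mutations per replicate, the duplication
#'   counting as the first.
#' @param n_replicates Number of independent replicates.
#' @param alpha,beta Fitness parameters ([fitness_lognormal()]); alpha is
#'   the optimal total activity (1/h), typically 60 or 80.
#' @param p_exp Per-event probability that a mutation alters the synthesis
#'   rate rather than the coding sequence, in \[0, 0.9\] practice range.
#' @param het_activity_bias Percentage difference between the specific
#'   activity of the heterodimer and the homodimers.  Negative values lower
#'   the heterodimer activity to `1 + bias/100` (homodimers stay at 1);
#'   positive values lower both homodimers to `1 - bias/100`.  Set once at
#'   the start of each replicate, never mutated.
#' @param population_size Effective population size for the Kimura fixation
#'   model.
#' @param fixation_model `"kimura"` or `"metropolis"`.
#' @param neutral If `TRUE`, selection is switched off: every proposal
#'   (including the duplication) fixes with the neutral probability of the
#'   chosen fixation model.  Used to isolate the contribution of mutational
#'   bias from that of selection.
#' @param seed Integer master seed; per-replicate seeds are derived from it.
#' @param s_init,dG_fold_init,dG_bind_init,decay Ancestral single-gene
#'   parameters (see [reference_state()]).
#' @param monomer_activity Specific activity of monomers.
#' @param expression_model [expression_effect_model()] used when
#'   `p_exp > 0`.
#' @param max_proposals Per-replicate cap on proposed mutations (guards
#'   against pathological parameter combinations).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_fixed = 200, n_replicates = 50,
                              alpha = 80, beta = 0.5, p_exp = 0,
                              het_activity_bias = 0,
                              population_size = 1000,
                              fixation_model = c("kimura", "metropolis"),
                              neutral = FALSE, seed = 1L,
                              s_init = 100, dG_fold_init = -5,
                              dG_bind_init = -10, decay = 1.3,
                              monomer_activity = 0.1,
                              expression_model = expression_effect_model(),
                              max_proposals = 5e6) {
  fixation_model <- match.arg(fixation_model)
  if (n_fixed < 1) stop("n_fixed must be at least 1")
  if (p_exp < 0 || p_exp >= 1) stop("p_exp must be in [0, 1)")
  if (abs(het_activity_bias) > 90)
    stop("het_activity_bias must be within [-90, 90]")
  if (alpha <= 0 || beta <= 0 || beta >= 1)
    stop("alpha must be positive and beta in (0, 1)")
  structure(list(n_fixed = as.integer(n_fixed),
                 n_replicates = as.integer(n_replicates),
                 alpha = alpha, beta = beta, p_exp = p_exp,
                 het_activity_bias = het_activity_bias,
                 population_size = population_size,
                 fixation_model = fixation_model, neutral = isTRUE(neutral),
                 seed = as.integer(seed),
                 s_init = s_init, dG_fold_init = dG_fold_init,
                 dG_bind_init = dG_bind_init,
                 decay = rep_len(decay, 5L),
                 monomer_activity = monomer_activity,
                 expression_model = expression_model,
                 max_proposals = max_proposals),
            class = "simulation_config")
}

#' @keywords internal
.activities_from_bias <- function(monomer_activity, bias) {
  hm <- if (bias > 0) 1 - bias / 100 else 1
  het <- if (bias < 0) 1 + bias / 100 else 1
  c(monomer_activity, hm, het, hm) # monomer, AA, AB, BB
}

#' Run one origin-fixation replicate
#'
#' Starts from the pre-duplication reference state; the duplication is
#' proposed repeatedly until it fixes and is recorded as fixation #1.
#' Thereafter coding/expression mutations are proposed (target paralog
#' chosen at random), the equilibrium and fitness recomputed, and each
#' proposal accepted with its fixation probability, until `n_fixed`
#' mutations have fixed.  Uses the current R random-number stream.
#'
#' @param config A [simulation_config()].
#' @param effect_source A [parametric_effect_model()] or an
#'   [effect_table()].
#' @return A `data.frame` of class `dimer_trajectory` with one row per
#'   fixation: event descriptors (`kind`, `target`, effect sizes,
#'   `table_row`), the full post-fixation state, the five concentrations,
#'   `activity`, `fitness` and `n_proposed` (proposals spent on this
#'   fixation, including the accepted one).
#' @export
run_replicate <- function(config, effect_source = parametric_effect_model()) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(effect_source, "parametric_effect_model")) {
    src_type <- 0L
    mu <- unname(effect_source$mu); fac <- effect_source$sqrt_factor
    tab <- matrix(0, 0, 3)
  } else if (inherits(effect_source, "effect_table")) {
    src_type <- 1L
    mu <- numeric(3); fac <- matrix(0, 3, 3)
    tab <- as.matrix(as.data.frame(effect_source)[
      c("ddG_fold", "ddG_bind_HM", "ddG_bind_HET")])
    if (nrow(tab) == 0L) stop("effect table is empty")
  } else stop("effect_source must be a parametric_effect_model or effect_table")
  em <- config$expression_model
  res <- .sim_replicate_cpp(
    config$s_init, config$dG_fold_init, config$dG_bind_init,
    config$decay,
    .activities_from_bias(config$monomer_activity, config$het_activity_bias),
    .GAS_CONSTANT * .TEMPERATURE, config$alpha, config$beta,
    config$population_size,
    if (config$fixation_model == "metropolis") 1L else 0L,
    config$neutral, config$p_exp, config$n_fixed, src_type, mu, fac, tab,
    em$xi, em$omega, em$delta, config$max_proposals)
  kinds <- c("duplication", "coding", "expression")[res$kind + 1L]
  coding <- res$kind == 1L
  traj <- data.frame(
    fixation = seq_len(config$n_fixed),
    kind = kinds,
    target = c(NA, "A", "B")[ifelse(is.na(res$target), 0L, res$target) + 1L],
    ddG_fold = ifelse(coding, res$eff[, 1], NA_real_),
    ddG_bind_HM = ifelse(coding, res$eff[, 2], NA_real_),
    ddG_bind_HET = ifelse(coding, res$eff[, 3], NA_real_),
    expr_eps = ifelse(res$kind == 2L, res$eff[, 1], NA_real_),
    table_row = res$table_row,
    s_A = res$state[, 1], s_B = res$state[, 2],
    dG_fold_A = res$state[, 3], dG_fold_B = res$state[, 4],
    dG_bind_AA = res$state[, 5], dG_bind_AB = res$state[, 6],
    dG_bind_BB = res$state[, 7],
    c_A = res$conc[, 1], c_B = res$conc[, 2], c_AA = res$conc[, 3],
    c_AB = res$conc[, 4], c_BB = res$conc[, 5],
    activity = res$activity, fitness = res$fitness,
    n_proposed = res$n_proposed)
  attr(traj, "config") <- config
  attr(traj, "total_proposed") <- res$total_proposed
  class(traj) <- c("dimer_trajectory", "data.frame")
  traj
}

#' Run a replicated simulation
#'
#' Runs `config$n_replicates` independent replicates (each on its own seed
#' derived from `config$seed`) and summarizes the final states.  A replicate
#' whose equilibrium solver fails is reported in `failures` and excluded
#' from the summary; failures are not fatal to the batch.
#'
#' @inheritParams run_replicate
#' @return Object of class `dimer_simulation`: a list with
#'   `trajectories` (list of `dimer_trajectory`), `replicates` (per-replicate
#'   final-state summary, see [summarize_replicate()]), `summary`
#'   (across-replicate means and outcome counts, see [summarize_run()]),
#'   `failures` (character vector of error messages, named by replicate),
#'   and `config`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_fixed = 20, n_replicates = 2, seed = 7)
#' sim <- run_simulation(cfg, parametric_effect_model())
#' sim$summary$mean_het_pct_dimers
#' }
#' @export
run_simulation <- function(config, effect_source = parametric_effect_model()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  trajectories <- vector("list", config$n_replicates)
  failures <- character(0)
  for (i in seq_len(config$n_replicates)) {
    set.seed(seeds[i])
    t <- tryCatch(run_replicate(config, effect_source),
                  error = function(e) e)
    if (inherits(t, "error")) {
      failures[as.character(i)] <- conditionMessage(t)
    } else {
      trajectories[[i]] <- t
    }
  }
  ok <- !vapply(trajectories, is.null, TRUE)
  replicates <- if (any(ok))
    do.call(rbind, lapply(which(ok), function(i) {
      s <- summarize_replicate(trajectories[[i]],
                               table = if (inherits(effect_source,
                                                    "effect_table"))
                                 effect_source)
      cbind(replicate = i, seed = seeds[i], s)
    }))
  structure(list(trajectories = trajectories[ok],
                 replicates = replicates,
                 summary = if (any(ok)) summarize_run(replicates),
                 failures = failures, config = config,
                 seeds = seeds),
            class = "dimer_simulation")
}

#' @export
print.dimer_simulation <- function(x, ...) {
  cat("Origin-fixation simulation:",
      length(x$trajectories), "replicate(s),",
      x$config$n_fixed, "fixations each\n")
  if (length(x$failures))
    cat("  failed replicates:", length(x$failures), "\n")
  if (!is.null(x$summary)) {
    cat(sprintf("  mean final heterodimer %% (among dimers): %.1f\n",
                x$summary$mean_het_pct_dimers))
    cnt <- x$summary$outcome_counts
    cat("  outcomes:", paste(names(cnt), cnt, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}
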