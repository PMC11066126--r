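# Post-processing of simulated trajectories: relative concentrations,
# outcome classification, replicate and run summaries, sequence divergence
# in empirical mode, and the residual/enrichment statistics linking
# mutational biases to simulation outcomes.

#' Relative concentrations of the molecular species
#'
#' `p_X = 100 * c_X / (c_A + c_B + c_AA + c_AB + c_BB)`; the percentages sum
#' to 100 and are invariant under uniform rescaling of the concentrations.
#'
#' @param conc Named concentration vector (`A, B, AA, AB, BB`).
#' @return Named percentages `p_A, p_B, p_AA, p_AB, p_BB`.
#' @examples
#' relative_concentrations(solve_post_duplication(reference_state(TRUE)))
#' @export
relative_concentrations <- function(conc) {
  stopifnot(length(conc) == 5L, all(is.finite(conc)), all(conc >= 0))
  tot <- sum(conc)
  if (tot <= 0) stop("all concentrations are zero")
  setNames(100 * conc / tot, paste0("p_", c("A", "B", "AA", "AB", "BB")))
}

#' Heterodimer share among dimers
#'
#' `100 * c_AB / (c_AA + c_AB + c_BB)` — the variant of "percentage of
#' heterodimers" whose starting value after a duplication with identical
#' paralogs is exactly 50%.
#'
#' @inheritParams relative_concentrations
#' @return Percentage in \[0, 100\], `NA` if there are no dimers.
#' @export
het_share_dimers <- function(conc) {
  dimers <- conc[["AA"]] + conc[["AB"]] + conc[["BB"]]
  if (dimers <= 0) return(NA_real_)
  100 * conc[["AB"]] / dimers
}

.OUTCOME_LEVELS <- c("HET_dominant", "HM_dominant", "both_HM_and_HET",
                     "monomers", "ambiguous")

#' Classify the outcome of a replicate
#'
#' Applies the five classification rules to final-state relative
#' concentrations, in order of precedence:
#' HET dominant (`p_AB >= 70`), HM dominant (`p_AA + p_BB >= 70`),
#' both HM and HET (`p_AA + p_AB + p_BB >= 70` with neither class alone
#' at 70), monomers (`p_A + p_B >= 70`), else ambiguous.  Ties at exactly
#' 70 count as reaching the threshold.
#'
#' @param percentages Named vector from [relative_concentrations()] (or any
#'   vector with elements `p_A, p_B, p_AA, p_AB, p_BB` summing to 100).
#' @return One of `"HET_dominant"`, `"HM_dominant"`, `"both_HM_and_HET"`,
#'   `"monomers"`, `"ambiguous"`.
#' @examples
#' classify_outcome(c(p_A = 0, p_B = 0, p_AA = 25, p_AB = 50, p_BB = 25))
#' @export
classify_outcome <- function(percentages) {
  p <- percentages
  stopifnot(abs(sum(p) - 100) < 1e-6)
  hm <- p[["p_AA"]] + p[["p_BB"]]
  het <- p[["p_AB"]]
  mono <- p[["p_A"]] + p[["p_B"]]
  if (het >= 70) return("HET_dominant")
  if (hm >= 70) return("HM_dominant")
  if (het + hm >= 70) return("both_HM_and_HET")
  if (mono >= 70) return("monomers")
  "ambiguous"
}

#' Cumulative sum of fixed binding residuals
#'
#' Running sum of `ddG_bind_HET - 0.5 * ddG_bind_HM` over the fixed coding
#' mutations of a trajectory, indexed by fixation number (duplication and
#' expression fixations contribute zero).  Increasingly negative values
#' mean the fixed mutations have favored the heterodimer.
#'
#' @param trajectory A `dimer_trajectory` from [run_replicate()].
#' @return Numeric vector, one value per fixation.
#' @export
cumulative_fixed_residuals <- function(trajectory) {
  r <- ifelse(trajectory$kind == "coding",
              binding_residuals(trajectory$ddG_bind_HET,
                                trajectory$ddG_bind_HM), 0)
  cumsum(r)
}

#' @keywords internal
.apply_substitutions <- function(sequence, positions, mutants) {
  chars <- strsplit(sequence, "")[[1]]
  for (i in seq_along(positions)) chars[positions[i]] <- mutants[i]
  paste(chars, collapse = "")
}

#' @keywords internal
.seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Reconstruct paralog sequences from an empirical-mode trajectory
#'
#' Replays the fixed coding substitutions (recorded as rows of the effect
#' table) on each paralog's copy of the wild-type sequence.
#'
#' @param trajectory A `dimer_trajectory` run with an `effect_table` source.
#' @param table The `effect_table` the simulation sampled from.
#' @return List with sequences `A` and `B` and identities `identity_A_wt`,
#'   `identity_B_wt`, `identity_A_B` (fractions in \[0, 1\]).
#' @export
reconstruct_sequences <- function(trajectory, table) {
  stopifnot(inherits(table, "effect_table"))
  wt <- attr(table, "sequence")
  out <- list(A = wt, B = wt)
  idx <- which(trajectory$kind == "coding")
  if (length(idx) && all(is.na(trajectory$table_row[idx])))
    stop("trajectory does not record table rows; was it run with an effect_table?")
  for (i in idx) {
    row <- trajectory$table_row[i]
    tgt <- trajectory$target[i]
    out[[tgt]] <- .apply_substitutions(out[[tgt]], table$position[row],
                                       table$mut_aa[row])
  }
  out$identity_A_wt <- .seq_identity(out$A, wt)
  out$identity_B_wt <- .seq_identity(out$B, wt)
  out$identity_A_B <- .seq_identity(out$A, out$B)
  out
}

#' Final-state summary of one replicate
#'
#' @param trajectory A `dimer_trajectory`.
#' @param table Optional `effect_table`; when given, paralog sequence
#'   identities are reconstructed from the recorded substitutions.
#' @return One-row `data.frame` with the final relative concentrations
#'   (`p_A` ... `p_BB`), the heterodimer share among dimers
#'   (`het_pct_dimers`), the outcome label, final activity and fitness,
#'   the final cumulative fixed residual, counts of fixed coding and
#'   expression mutations, and (empirical mode) sequence identities.
#' @export
summarize_replicate <- function(trajectory, table = NULL) {
  last <- trajectory[nrow(trajectory), ]
  conc <- c(A = last$c_A, B = last$c_B, AA = last$c_AA, AB = last$c_AB,
            BB = last$c_BB)
  # a system driven to complete loss of folded protein has no defined
  # composition; report NA rather than failing the whole run
  p <- if (sum(conc) > 0) relative_concentrations(conc)
       else setNames(rep(NA_real_, 5), paste0("p_", names(conc)))
  out <- data.frame(t(p),
                    het_pct_dimers = if (sum(conc) > 0)
                      het_share_dimers(conc) else NA_real_,
                    outcome = if (sum(conc) > 0) classify_outcome(p)
                              else NA_character_,
                    activity = last$activity, fitness = last$fitness,
                    cum_residual =
                      cumulative_fixed_residuals(trajectory)[nrow(trajectory)],
                    n_coding = sum(trajectory$kind == "coding"),
                    n_expression = sum(trajectory$kind == "expression"),
                    stringsAsFactors = FALSE)
  if (!is.null(table)) {
    ids <- reconstruct_sequences(trajectory, table)
    out$identity_A_wt <- ids$identity_A_wt
    out$identity_B_wt <- ids$identity_B_wt
    out$identity_A_B <- ids$identity_A_B
  }
  out
}

#' Across-replicate summary of a simulation
#'
#' @param replicates A `data.frame` of per-replicate summaries (rows from
#'   [summarize_replicate()], e.g. the `replicates` element of a
#'   [run_simulation()] result).
#' @return List with `mean_p` (species-wise mean final percentages),
#'   `mean_het_pct_dimers`, `outcome_counts` and `outcome_fractions` (per
#'   label), mean sequence identities when available, and `n_replicates`.
#' @export
summarize_run <- function(replicates) {
  if (is.null(replicates) || nrow(replicates) == 0L)
    stop("no successful replicates to summarize")
  pcols <- paste0("p_", c("A", "B", "AA", "AB", "BB"))
  counts <- table(factor(replicates$outcome, levels = .OUTCOME_LEVELS))
  out <- list(mean_p = colMeans(replicates[pcols], na.rm = TRUE),
              mean_het_pct_dimers = mean(replicates$het_pct_dimers,
                                         na.rm = TRUE),
              outcome_counts = counts,
              outcome_fractions = counts / nrow(replicates),
              n_replicates = nrow(replicates))
  if ("identity_A_B" %in% names(replicates)) {
    out$mean_identity_wt <- mean(c(replicates$identity_A_wt,
                                   replicates$identity_B_wt))
    out$mean_identity_A_B <- mean(replicates$identity_A_B)
  }
  out
}

#' Spearman correlation between mutational bias and simulation outcome
#'
#' Rank correlation between per-structure enrichment scores and the mean
#' final heterodimer percentage of the corresponding simulations, with the
#' p-value from the asymptotic t approximation
#' (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom).
#'
#' @param scores Per-structure enrichment scores ([enrichment_score()]).
#' @param het_pct Per-structure mean final heterodimer percentages.
#' @return List with `rho`, `p_value` and `n`.  `rho` is `NA` (with
#'   p-value `NA`) when either vector is constant.
#' @export
enrichment_outcome_correlation <- function(scores, het_pct) {
  if (length(scores) != length(het_pct))
    stop("scores and het_pct must have the same length")
  n <- length(scores)
  if (n < 4L) stop("need at least 4 paired observations")
  if (sd(scores) == 0 || sd(het_pct) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- cor(rank(scores), rank(het_pct))
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tval), df = n - 2), n = n)
}
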