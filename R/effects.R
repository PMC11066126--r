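# Sources of mutational effects: correlated parametric draws, empirical
# per-substitution ddG tables, the synthetic-table generator, the skew-normal
# model of expression effects, and the residual/enrichment statistics used to
# quantify mutational biases between homodimer and heterodimer interfaces.

.AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Correlated parametric model of coding-mutation effects
#'
#' Trivariate normal distribution of the effect of one amino-acid
#' substitution on folding free energy (ddG_fold), on the binding free
#' energy of the mutated paralog's homodimer (ddG_bind_HM) and on the
#' heterodimer (ddG_bind_HET), all in kcal/mol.  Defaults match the moments
#' of structure-based mutational scans of homodimers: destabilizing on
#' average, effects on the heterodimer about half those on the homodimer,
#' and a strong (0.9) correlation between the two binding effects.
#'
#' @param mean_fold,sd_fold Marginal of ddG_fold (kcal/mol).
#' @param mean_bind_HM,sd_bind_HM Marginal of ddG_bind_HM (kcal/mol).
#' @param mean_bind_HET,sd_bind_HET Marginal of ddG_bind_HET (kcal/mol).
#' @param corr_HM_HET,corr_fold_HM,corr_fold_HET Pairwise correlations.
#' @return An object of class `parametric_effect_model` holding the mean
#'   vector, the covariance matrix and a square-root factor `F` (with
#'   `t(F) %*% F` equal to the covariance; degenerate models with zero
#'   variance are handled exactly) in the order fold, bind_HM, bind_HET.
#' @examples
#' m <- parametric_effect_model()
#' head(sample_parametric_effects(m, 5))
#' @export
parametric_effect_model <- function(mean_fold = 2.6, sd_fold = 4.6,
                                    mean_bind_HM = 0.4, sd_bind_HM = 2.4,
                                    mean_bind_HET = 0.2, sd_bind_HET = 1.2,
                                    corr_HM_HET = 0.9,
                                    corr_fold_HM = 0.3,
                                    corr_fold_HET = 0.3) {
  sds <- c(sd_fold, sd_bind_HM, sd_bind_HET)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  corr <- matrix(c(1, corr_fold_HM, corr_fold_HET,
                   corr_fold_HM, 1, corr_HM_HET,
                   corr_fold_HET, corr_HM_HET, 1), 3, 3)
  if (any(abs(corr) > 1)) stop("correlations must be in [-1, 1]")
  sigma <- diag(sds) %*% corr %*% diag(sds)
  evc <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(evc) < -1e-10)
    stop("correlation matrix is not positive semi-definite")
  # eigen square-root factor: exact for singular (zero-variance) models,
  # where a Cholesky factorization would need a distorting ridge
  es <- eigen(sigma, symmetric = TRUE)
  sqrt_factor <- diag(sqrt(pmax(es$values, 0))) %*% t(es$vectors)
  structure(list(mu = c(fold = mean_fold, bind_HM = mean_bind_HM,
                        bind_HET = mean_bind_HET),
                 sigma = sigma, sqrt_factor = sqrt_factor),
            class = "parametric_effect_model")
}

#' Sample coding-mutation effects from a parametric model
#'
#' @param model A [parametric_effect_model()].
#' @param n Number of draws.
#' @return `data.frame` with columns `ddG_fold`, `ddG_bind_HM`,
#'   `ddG_bind_HET` (kcal/mol).  Uses the current R random-number stream.
#' @export
sample_parametric_effects <- function(model, n) {
  stopifnot(inherits(model, "parametric_effect_model"), n >= 1)
  z <- matrix(rnorm(3L * n), n, 3L) %*% model$sqrt_factor
  out <- sweep(z, 2L, model$mu, "+")
  data.frame(ddG_fold = out[, 1], ddG_bind_HM = out[, 2],
             ddG_bind_HET = out[, 3])
}

#' Skew-normal model of mutational effects on synthesis rate
#'
#' Expression mutations multiply the current synthesis rate by `1 + eps`,
#' with `eps` drawn from a skew-normal distribution.  The model is
#' parameterized by its moments — mean, standard deviation and (sample)
#' skewness — and the direct (location, scale, shape) parameters are solved
#' in closed form from them.  Defaults follow measured distributions of
#' promoter-mutation effects on expression: mean 0, SD 0.025, skewness
#' -0.125.
#'
#' @param mean,sd,skewness Target moments of `eps`.
#' @return Object of class `expression_effect_model` with elements
#'   `xi` (location), `omega` (scale), `delta` (shape, as
#'   `alpha / sqrt(1 + alpha^2)`), plus the target moments.
#' @examples
#' m <- expression_effect_model()
#' summary(sample_expression_effects(m, 1000))
#' @export
expression_effect_model <- function(mean = 0, sd = 0.025,
                                    skewness = -0.125) {
  if (sd <= 0) stop("sd must be positive")
  max_skew <- 0.5 * (4 - pi) * (2 / pi)^1.5 / (1 - 2 / pi)^1.5 # ~0.9953
  if (abs(skewness) >= max_skew)
    stop("|skewness| of a skew-normal cannot reach ", round(max_skew, 4))
  # invert gamma1 = (4 - pi)/2 * c^3 / (1 - c^2)^(3/2), c = delta*sqrt(2/pi)
  t <- 2 * abs(skewness) / (4 - pi)
  u <- t^(1 / 3)
  cc <- sign(skewness) * u / sqrt(1 + u^2)
  delta <- cc * sqrt(pi / 2)
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)
  xi <- mean - omega * delta * sqrt(2 / pi)
  structure(list(xi = xi, omega = omega, delta = delta,
                 mean = mean, sd = sd, skewness = skewness),
            class = "expression_effect_model")
}

#' Sample synthesis-rate effects
#'
#' Draws `eps` from the skew-normal model; the caller applies the effect as
#' `s_new = s_old * (1 + eps)`.
#'
#' @param model An [expression_effect_model()].
#' @param n Number of draws.
#' @return Numeric vector of `eps` values.
#' @export
sample_expression_effects <- function(model, n) {
  stopifnot(inherits(model, "expression_effect_model"), n >= 1)
  z0 <- rnorm(n); z1 <- rnorm(n)
  model$xi + model$omega *
    (model$delta * abs(z0) + sqrt(1 - model$delta^2) * z1)
}

#' Residual of a mutation's binding effects
#'
#' Deviation of the heterodimer binding effect from the expectation that a
#' mutation on one subunit perturbs the heterodimer (one mutated interface
#' side) half as much as the homodimer (both sides):
#' `residual = ddG_bind_HET - 0.5 * ddG_bind_HM`.  Negative residuals favor
#' the heterodimer, positive ones the homodimer.
#'
#' @param ddG_bind_HET,ddG_bind_HM Binding effects (kcal/mol); vectorized.
#' @return Residuals in kcal/mol.
#' @examples
#' binding_residuals(c(1, 0, 0.6), c(2, 1, 0.4))
#' @export
binding_residuals <- function(ddG_bind_HET, ddG_bind_HM) {
  ddG_bind_HET - 0.5 * ddG_bind_HM
}

#' Enrichment of heterodimer-favoring mutations
#'
#' Fraction of residuals below `-threshold` (heterodimer-favoring) minus the
#' fraction above `+threshold` (homodimer-favoring).  Positive scores mean
#' the mutational spectrum is biased toward the heterodimer.
#'
#' @param residuals Numeric vector of residuals (kcal/mol).
#' @param threshold Magnitude cut-off (kcal/mol), default 0.2.
#' @return Score in \[-1, 1\].
#' @examples
#' enrichment_score(c(-0.3, -0.25, 0.1, 0.25))
#' @export
enrichment_score <- function(residuals, threshold = 0.2) {
  if (length(residuals) == 0L) stop("residuals must be non-empty")
  if (threshold <= 0) stop("threshold must be positive")
  mean(residuals < -threshold) - mean(residuals > threshold)
}

.TABLE_COLUMNS <- c("position", "wt_aa", "mut_aa",
                    "ddG_fold", "ddG_bind_HM", "ddG_bind_HET")

#' @keywords internal
.validate_effect_table <- function(df, sequence = NULL, where = "table") {
  missing_cols <- setdiff(.TABLE_COLUMNS, names(df))
  if (length(missing_cols))
    stop(where, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[.TABLE_COLUMNS]
  num <- c("ddG_fold", "ddG_bind_HM", "ddG_bind_HET")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop(where, ": non-numeric ", cl, " at row ", bad[1])
    if (anyNA(v)) stop(where, ": missing ", cl, " at row ", which(is.na(v))[1])
    df[[cl]] <- v
  }
  df$position <- as.integer(df$position)
  if (anyNA(df$position) || any(df$position < 1L))
    stop(where, ": positions must be positive integers")
  same <- which(df$wt_aa == df$mut_aa)
  if (length(same))
    stop(where, ": wt_aa equals mut_aa at row ", same[1])
  dup <- which(duplicated(df[c("position", "mut_aa")]))
  if (length(dup))
    stop(where, ": duplicated (position, mut_aa) at row ", dup[1])
  wt_by_pos <- tapply(df$wt_aa, df$position, function(x) length(unique(x)))
  if (any(wt_by_pos > 1L))
    stop(where, ": conflicting wt_aa within a position")
  if (is.null(sequence)) {
    pos <- sort(unique(df$position))
    seq_chars <- rep("X", max(pos))
    seq_chars[pos] <- vapply(pos, function(p) df$wt_aa[df$position == p][1], "")
    sequence <- paste(seq_chars, collapse = "")
  } else {
    if (any(df$position > nchar(sequence)))
      stop(where, ": position beyond sequence length")
    seq_chars <- strsplit(sequence, "")[[1]]
    mism <- which(seq_chars[df$position] != df$wt_aa)
    if (length(mism))
      stop(where, ": wt_aa disagrees with sequence at row ", mism[1])
  }
  structure(df, sequence = sequence,
            class = c("effect_table", "data.frame"))
}

#' Build an empirical table of per-substitution effects
#'
#' @param position 1-based residue indices.
#' @param wt_aa,mut_aa Wild-type and mutant amino-acid codes (must differ).
#' @param ddG_fold,ddG_bind_HM,ddG_bind_HET Effects in kcal/mol.
#' @param sequence Optional wild-type sequence; reconstructed from
#'   `position`/`wt_aa` when absent.
#' @return An `effect_table` (a validated `data.frame` with a `sequence`
#'   attribute).
#' @export
effect_table <- function(position, wt_aa, mut_aa, ddG_fold, ddG_bind_HM,
                         ddG_bind_HET, sequence = NULL) {
  .validate_effect_table(
    data.frame(position = position, wt_aa = wt_aa, mut_aa = mut_aa,
               ddG_fold = ddG_fold, ddG_bind_HM = ddG_bind_HM,
               ddG_bind_HET = ddG_bind_HET, stringsAsFactors = FALSE),
    sequence = sequence)
}

#' Read a per-substitution effect table
#'
#' Reads a UTF-8 tab-separated table with header columns `position`,
#' `wt_aa`, `mut_aa`, `ddG_fold`, `ddG_bind_HM`, `ddG_bind_HET` (one row per
#' substitution, the dialect written by [write_effect_table()]).  Other
#' column names/orders — e.g. tables exported from FoldX/MutateX pipelines —
#' are accepted through `col_map`.
#'
#' @param path File path.
#' @param sequence Optional wild-type sequence to validate positions against.
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(ddG_bind_HM = "ddG_bind_homodimer")`.
#' @return An `effect_table`.
#' @export
read_effect_table <- function(path, sequence = NULL, col_map = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df))
        stop(basename(path), ": mapped column not found: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  .validate_effect_table(df, sequence = sequence, where = basename(path))
}

#' Write a per-substitution effect table
#'
#' Writes the canonical tab-separated dialect read by [read_effect_table()];
#' reading the file back yields an identical table.
#'
#' @param table An `effect_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(table, path) {
  stopifnot(inherits(table, "effect_table"))
  write.table(as.data.frame(table)[.TABLE_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample coding-mutation effects from an empirical table
#'
#' Uniform draws over the rows of the table (every substitution equally
#' likely).  The sampled substitution identity is kept so that sequence
#' divergence can be tracked along a simulation.
#'
#' @param table An `effect_table`.
#' @param n Number of draws.
#' @return `data.frame` with the sampled rows plus a `row` column (the
#'   1-based row index in `table`).
#' @export
sample_empirical_effects <- function(table, n) {
  stopifnot(inherits(table, "effect_table"), n >= 1)
  if (nrow(table) == 0L) stop("effect table is empty")
  idx <- sample.int(nrow(table), n, replace = TRUE)
  out <- as.data.frame(table)[idx, , drop = FALSE]
  out$row <- idx
  rownames(out) <- NULL
  out
}

#' Generate a synthetic per-substitution effect table
#'
#' Emulates the structure-level output of an exhaustive mutational scan of a
#' homodimer: all 19 substitutions at each position of a random wild-type
#' sequence, with (ddG_fold, ddG_bind_HM, ddG_bind_HET) drawn from a
#' parametric model.  `residual_bias` shifts every ddG_bind_HET by a
#' constant relative to the half-slope diagonal, creating a tunable excess
#' of heterodimer-favoring (negative bias) or homodimer-favoring (positive
#' bias) mutations; the marginal ddG distributions are otherwise untouched.
#'
#' @param n_positions Number of residues (>= 10).
#' @param model Base [parametric_effect_model()].
#' @param residual_bias Constant added to ddG_bind_HET (kcal/mol).
#' @param seed Optional integer; when given the table is reproducible and
#'   the surrounding RNG state is left untouched.
#' @return An `effect_table` with `19 * n_positions` rows.
#' @examples
#' tab <- generate_synthetic_structure(12, residual_bias = -0.3, seed = 1)
#' enrichment_score(binding_residuals(tab$ddG_bind_HET, tab$ddG_bind_HM))
#' @export
generate_synthetic_structure <- function(n_positions,
                                         model = parametric_effect_model(),
                                         residual_bias = 0, seed = NULL) {
  if (n_positions < 10L) stop("n_positions must be at least 10")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  wt <- sample(.AA_CODES, n_positions, replace = TRUE)
  pos <- rep(seq_len(n_positions), each = 19L)
  mut <- unlist(lapply(wt, function(a) setdiff(.AA_CODES, a)),
                use.names = FALSE)
  eff <- sample_parametric_effects(model, length(pos))
  effect_table(position = pos, wt_aa = rep(wt, each = 19L), mut_aa = mut,
               ddG_fold = round(eff$ddG_fold, 6),
               ddG_bind_HM = round(eff$ddG_bind_HM, 6),
               ddG_bind_HET = round(eff$ddG_bind_HET + residual_bias, 6),
               sequence = paste(wt, collapse = ""))
}
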