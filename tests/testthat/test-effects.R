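test_that("parametric sampler recovers the default marginals and correlations", {
  set.seed(501)
  m <- parametric_effect_model()
  n <- 2e5
  x <- sample_parametric_effects(m, n)
  means <- colMeans(x)
  sds <- vapply(x, sd, 0)
  # means within 3 standard errors, SDs within 2%
  expect_lt(abs(means[["ddG_fold"]] - 2.6), 3 * 4.6 / sqrt(n))
  expect_lt(abs(means[["ddG_bind_HM"]] - 0.4), 3 * 2.4 / sqrt(n))
  expect_lt(abs(means[["ddG_bind_HET"]] - 0.2), 3 * 1.2 / sqrt(n))
  expect_equal(unname(sds), c(4.6, 2.4, 1.2), tolerance = 0.02)
  expect_lt(abs(cor(x$ddG_bind_HM, x$ddG_bind_HET) - 0.9), 0.01)
  expect_lt(abs(cor(x$ddG_fold, x$ddG_bind_HM) - 0.3), 0.02)
  expect_lt(abs(cor(x$ddG_fold, x$ddG_bind_HET) - 0.3), 0.02)
})

test_that("degenerate parametric model (zero SDs) is deterministic at the means", {
  m <- parametric_effect_model(sd_fold = 0, sd_bind_HM = 0, sd_bind_HET = 0)
  x <- sample_parametric_effects(m, 5)
  expect_equal(x$ddG_fold, rep(2.6, 5), tolerance = 1e-5)
  expect_equal(x$ddG_bind_HM, rep(0.4, 5), tolerance = 1e-5)
  expect_equal(x$ddG_bind_HET, rep(0.2, 5), tolerance = 1e-5)
})

test_that("invalid correlation structures are rejected at construction", {
  expect_error(parametric_effect_model(corr_HM_HET = 1.4), "\\[-1, 1\\]")
  # jointly infeasible correlations: not positive semi-definite
  expect_error(parametric_effect_model(corr_HM_HET = -0.9,
                                       corr_fold_HM = 0.9,
                                       corr_fold_HET = 0.9),
               "positive semi-definite")
  expect_error(parametric_effect_model(sd_fold = -1), "non-negative")
})

test_that("skew-normal expression model matches its target moments", {
  m <- expression_effect_model()
  # closed-form moments of the solved (location, scale, shape)
  mu_z <- m$delta * sqrt(2 / pi)
  expect_equal(m$xi + m$omega * mu_z, 0, tolerance = 1e-12)
  expect_equal(m$omega * sqrt(1 - mu_z^2), 0.025, tolerance = 1e-12)
  skew_theo <- (4 - pi) / 2 * mu_z^3 / (1 - mu_z^2)^1.5
  expect_equal(skew_theo, -0.125, tolerance = 1e-10)

  set.seed(502)
  n <- 1e5
  eps <- sample_expression_effects(m, n)
  expect_lt(abs(mean(eps)), 3 * 0.025 / sqrt(n))
  expect_equal(sd(eps), 0.025, tolerance = 0.02)
  # negative sample skewness
  expect_lt(mean((eps - mean(eps))^3) / sd(eps)^3, 0)
})

test_that("skewness beyond the skew-normal bound is rejected", {
  expect_error(expression_effect_model(skewness = 1), "skew")
  expect_error(expression_effect_model(sd = 0), "positive")
})

test_that("binding residuals measure deviation from the half-slope diagonal", {
  expect_equal(binding_residuals(1, 2), 0)
  expect_equal(binding_residuals(0, 1), -0.5)
  expect_equal(binding_residuals(0.6, 0.4), 0.4)
  expect_equal(binding_residuals(c(1, 0), c(2, 1)), c(0, -0.5))
})

test_that("enrichment score counts heterodimer- minus homodimer-favoring residuals", {
  expect_equal(enrichment_score(c(-0.5, 0.5)), 0)
  expect_equal(enrichment_score(c(-0.3, -0.4, -5)), 1)
  expect_equal(enrichment_score(c(-0.3, -0.25, 0.1, 0.25)), 0.25)
  expect_error(enrichment_score(numeric(0)), "non-empty")
  expect_error(enrichment_score(1, threshold = 0), "positive")
  # antisymmetry under sign flip
  set.seed(503)
  r <- rnorm(500, sd = 0.4)
  expect_equal(enrichment_score(-r), -enrichment_score(r))
})

test_that("effect tables round-trip through write/read byte-identically", {
  tab <- effect_table(position = c(1L, 1L, 2L), wt_aa = c("A", "A", "G"),
                      mut_aa = c("V", "L", "P"),
                      ddG_fold = c(0.5, -0.25, 3),
                      ddG_bind_HM = c(1, 0, -0.5),
                      ddG_bind_HET = c(0.5, 0.1, -0.2))
  expect_s3_class(tab, "effect_table")
  expect_equal(nrow(tab), 3L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_effect_table(tab, f1)
  back <- read_effect_table(f1)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  write_effect_table(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("malformed effect tables are rejected with informative errors", {
  expect_error(effect_table(1L, "A", "A", 0, 0, 0), "wt_aa equals mut_aa")
  expect_error(effect_table(c(1L, 1L), c("A", "A"), c("V", "V"),
                            0:1, 0:1, 0:1), "duplicated")
  expect_error(effect_table(c(1L, 1L), c("A", "G"), c("V", "L"),
                            0:1, 0:1, 0:1), "conflicting wt_aa")
  expect_error(effect_table(2L, "A", "V", 0, 0, 0, sequence = "A"),
               "beyond sequence length")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\twt_aa\tmut_aa\tddG_fold\tddG_bind_HM",
               "1\tA\tV\t0.1\t0.2"), f)
  expect_error(read_effect_table(f), "missing column")
  writeLines(c(paste("position", "wt_aa", "mut_aa", "ddG_fold",
                     "ddG_bind_HM", "ddG_bind_HET", sep = "\t"),
               "1\tA\tV\t0.1\tzzz\t0.3"), f)
  expect_error(read_effect_table(f), "non-numeric ddG_bind_HM at row 1")
})

test_that("alternative column layouts are readable through col_map", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("pos", "wt", "mut", "ddG_het", "ddG_hm", "ddG_f",
                     sep = "\t"),
               "3\tK\tR\t0.2\t0.6\t1.1"), f)
  tab <- read_effect_table(f, col_map = c(position = "pos", wt_aa = "wt",
                                          mut_aa = "mut",
                                          ddG_bind_HET = "ddG_het",
                                          ddG_bind_HM = "ddG_hm",
                                          ddG_fold = "ddG_f"))
  expect_equal(tab$ddG_bind_HM, 0.6)
  expect_equal(tab$position, 3L)
})

test_that("empirical sampling is uniform over rows and tracks substitutions", {
  one <- effect_table(1L, "A", "V", 0.1, 0.2, 0.3)
  x <- sample_empirical_effects(one, 10)
  expect_true(all(x$row == 1L))
  expect_true(all(x$ddG_bind_HET == 0.3))

  set.seed(504)
  tab <- effect_table(position = rep(1:2, each = 5),
                      wt_aa = rep(c("A", "G"), each = 5),
                      mut_aa = c("C", "D", "E", "F", "H",
                                 "I", "K", "L", "M", "N"),
                      ddG_fold = rnorm(10), ddG_bind_HM = rnorm(10),
                      ddG_bind_HET = rnorm(10))
  n <- 1e4
  draws <- sample_empirical_effects(tab, n)
  counts <- tabulate(draws$row, nbins = 10)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
  expect_equal(mean(draws$ddG_fold), mean(tab$ddG_fold), tolerance = 0.05)
})

test_that("synthetic structures have full substitution coverage and tunable bias", {
  tab <- generate_synthetic_structure(20, residual_bias = 0, seed = 7)
  expect_equal(nrow(tab), 19L * 20L)
  expect_true(all(table(tab$position) == 19L))
  expect_false(any(tab$wt_aa == tab$mut_aa))
  expect_equal(nchar(attr(tab, "sequence")), 20L)
  # centered base model: near-zero mean residual (defaults: 0.2 - 0.5*0.4 = 0)
  res0 <- binding_residuals(tab$ddG_bind_HET, tab$ddG_bind_HM)
  expect_lt(abs(mean(res0)), 3 * sd(res0) / sqrt(length(res0)))
  # heterodimer-favoring bias shows up in the enrichment score
  biased <- generate_synthetic_structure(20, residual_bias = -0.3, seed = 7)
  res_b <- binding_residuals(biased$ddG_bind_HET, biased$ddG_bind_HM)
  expect_gt(enrichment_score(res_b), 0)
  expect_equal(mean(res_b) - mean(res0), -0.3, tolerance = 1e-9)
})

test_that("synthetic generation is deterministic under a seed and leaves the RNG alone", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_effect_table(generate_synthetic_structure(15, seed = 99), f1)
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  write_effect_table(generate_synthetic_structure(15, seed = 99), f2)
  after <- rnorm(1)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(before, after) # surrounding RNG stream untouched
})

test_that("generator -> writer -> reader preserves the enrichment statistics", {
  tab <- generate_synthetic_structure(25, residual_bias = -0.15, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_effect_table(tab, f)
  back <- read_effect_table(f)
  s1 <- enrichment_score(binding_residuals(tab$ddG_bind_HET,
                                           tab$ddG_bind_HM))
  s2 <- enrichment_score(binding_residuals(back$ddG_bind_HET,
                                           back$ddG_bind_HM))
  expect_equal(s1, s2, tolerance = 1e-12)
})
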