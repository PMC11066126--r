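test_that("Kimura fixation probability has the right limits and matches Wright-Fisher", {
  # neutral limit
  expect_equal(fixation_probability(0.5, 0.5, 1000), 1 / 1000)
  # strongly deleterious mutations essentially never fix
  expect_lt(fixation_probability(1, 0.5, 1000), 1e-10)
  # continuity around s = 0
  eps <- 1e-9
  expect_equal(fixation_probability(1, 1 + eps, 1000),
               fixation_probability(1, 1, 1000), tolerance = 1e-2)
  # brute-force Wright-Fisher oracle at s = 0.01, N = 1000
  set.seed(601)
  wf <- wf_fixation_freq(s = 0.01, N = 1000, n_runs = 1e5)
  kim <- fixation_probability(1, 1.01, 1000)
  se <- sqrt(wf * (1 - wf) / 1e5)
  expect_lt(abs(wf - kim), 3 * se)
})

test_that("Metropolis fixation model accepts improvements and scales down losses", {
  expect_equal(fixation_probability(0.5, 0.8, model = "metropolis"), 1)
  expect_equal(fixation_probability(0.8, 0.4, model = "metropolis"), 0.5)
  expect_equal(fixation_probability(0, 0.4, model = "metropolis"), 1)
})

test_that("mutations are applied to the right parameters", {
  st <- reference_state(duplicated = TRUE)
  m <- mutation_effect("coding", "A", ddG_fold = 1, ddG_bind_HM = 2,
                       ddG_bind_HET = 1)
  st2 <- apply_mutation(st, m)
  expect_equal(st2$dG_fold_A, -4)
  expect_equal(st2$dG_bind_AA, -8)
  expect_equal(st2$dG_bind_AB, -9)
  expect_equal(st2$dG_bind_BB, -10) # other homodimer untouched
  expect_equal(st2$dG_fold_B, -5)

  st3 <- apply_mutation(st, mutation_effect("expression", "B",
                                            expr_eps = 0.1))
  expect_equal(st3$s_B, 110)
  expect_equal(st3$s_A, 100)
  expect_equal(st3$dG_bind_AB, -10)

  dup <- apply_mutation(reference_state(), mutation_effect("duplication"))
  expect_true(dup$duplicated)
  expect_equal(dup$s_B, 100)
  expect_equal(dup$dG_bind_BB, -10)
  # a zero-effect mutation leaves the state (and hence fitness) unchanged
  z <- apply_mutation(st, mutation_effect("coding", "B"))
  expect_equal(z, st)
})

test_that("replicates start with the duplication and its printed activity step", {
  set.seed(602)
  cfg <- simulation_config(n_fixed = 10, n_replicates = 1, seed = 11)
  tr <- run_replicate(cfg)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr$kind[1], "duplication")
  expect_false(any(tr$kind[-1] == "duplication"))
  expect_equal(tr$activity[1], 76.4, tolerance = 0.1 / 76.4)
  expect_equal(tr$c_AB[1], 2 * tr$c_AA[1], tolerance = 1e-8)
})

test_that("trajectories are deterministic under a fixed seed", {
  cfg <- simulation_config(n_fixed = 30, n_replicates = 1, p_exp = 0.3)
  set.seed(603); t1 <- run_replicate(cfg)
  set.seed(603); t2 <- run_replicate(cfg)
  expect_identical(t1, t2)
  sim1 <- run_simulation(simulation_config(n_fixed = 20, n_replicates = 2,
                                           seed = 77))
  sim2 <- run_simulation(simulation_config(n_fixed = 20, n_replicates = 2,
                                           seed = 77))
  expect_identical(sim1$trajectories, sim2$trajectories)
})

test_that("a zero-effect source keeps the system at the 1:2:1 equilibrium", {
  null_src <- parametric_effect_model(mean_fold = 0, sd_fold = 0,
                                      mean_bind_HM = 0, sd_bind_HM = 0,
                                      mean_bind_HET = 0, sd_bind_HET = 0)
  set.seed(604)
  tr <- run_replicate(simulation_config(n_fixed = 25, n_replicates = 1),
                      null_src)
  last <- tr[25, ]
  expect_equal(last$c_AB, 2 * last$c_AA, tolerance = 1e-6)
  expect_equal(last$c_AA, last$c_BB, tolerance = 1e-6)
  expect_equal(last$activity, 76.4, tolerance = 0.01)
})

test_that("stored trajectory states are recomputable through the R API", {
  set.seed(605)
  cfg <- simulation_config(n_fixed = 40, n_replicates = 1, p_exp = 0.4)
  tr <- run_replicate(cfg)
  for (i in c(1, 7, 20, 40)) {
    rec <- recompute_trajectory_row(tr[i, ], cfg)
    expect_equal(unname(rec$conc),
                 unname(unlist(tr[i, c("c_A", "c_B", "c_AA", "c_AB",
                                       "c_BB")])), tolerance = 1e-9)
    expect_equal(rec$activity, tr$activity[i], tolerance = 1e-9)
    expect_equal(rec$fitness, tr$fitness[i], tolerance = 1e-9)
  }
})

test_that("coding fixations update the recorded energies consistently", {
  set.seed(606)
  tr <- run_replicate(simulation_config(n_fixed = 60, n_replicates = 1))
  cod <- which(tr$kind == "coding")
  for (i in cod[seq_len(min(10, length(cod)))]) {
    prev <- tr[i - 1, ]
    cur <- tr[i, ]
    if (cur$target == "A") {
      expect_equal(cur$dG_fold_A - prev$dG_fold_A, cur$ddG_fold)
      expect_equal(cur$dG_bind_AA - prev$dG_bind_AA, cur$ddG_bind_HM)
      expect_equal(cur$dG_bind_BB, prev$dG_bind_BB)
    } else {
      expect_equal(cur$dG_fold_B - prev$dG_fold_B, cur$ddG_fold)
      expect_equal(cur$dG_bind_BB - prev$dG_bind_BB, cur$ddG_bind_HM)
      expect_equal(cur$dG_bind_AA, prev$dG_bind_AA)
    }
    expect_equal(cur$dG_bind_AB - prev$dG_bind_AB, cur$ddG_bind_HET)
  }
})

test_that("expression mutations only rescale one synthesis rate", {
  set.seed(607)
  tr <- run_replicate(simulation_config(n_fixed = 60, n_replicates = 1,
                                        p_exp = 0.8))
  ex <- which(tr$kind == "expression")
  expect_gt(length(ex), 10)
  for (i in ex[seq_len(min(10, length(ex)))]) {
    prev <- tr[i - 1, ]; cur <- tr[i, ]
    if (cur$target == "A") {
      expect_equal(cur$s_A / prev$s_A, 1 + cur$expr_eps, tolerance = 1e-12)
      expect_equal(cur$s_B, prev$s_B)
    } else {
      expect_equal(cur$s_B / prev$s_B, 1 + cur$expr_eps, tolerance = 1e-12)
      expect_equal(cur$s_A, prev$s_A)
    }
    expect_equal(cur$dG_bind_AB, prev$dG_bind_AB)
  }
})

test_that("with selection off the acceptance rate is the neutral expectation", {
  set.seed(608)
  N <- 100
  cfg <- simulation_config(n_fixed = 80, n_replicates = 1, neutral = TRUE,
                           population_size = N, p_exp = 0.5)
  tr <- run_replicate(cfg)
  total <- attr(tr, "total_proposed")
  # proposals to reach 80 fixations ~ Negative binomial: mean 80*N
  expect_gt(total, 80 * N * 0.6)
  expect_lt(total, 80 * N * 1.6)
})

test_that("empirical-mode replicates record substitutions for sequence tracking", {
  tab <- generate_synthetic_structure(40, seed = 15)
  set.seed(609)
  cfg <- simulation_config(n_fixed = 30, n_replicates = 1)
  tr <- run_replicate(cfg, tab)
  cod <- tr$kind == "coding"
  expect_true(all(!is.na(tr$table_row[cod])))
  expect_true(all(tr$table_row[cod] >= 1 & tr$table_row[cod] <= nrow(tab)))
  # recorded effects equal the table rows they cite
  rows <- tr$table_row[cod]
  expect_equal(tr$ddG_fold[cod], tab$ddG_fold[rows])
  expect_equal(tr$ddG_bind_HET[cod], tab$ddG_bind_HET[rows])
  seqs <- reconstruct_sequences(tr, tab)
  expect_true(seqs$identity_A_wt <= 1 && seqs$identity_A_B <= 1)
  expect_lt(seqs$identity_A_B, 1) # some divergence accumulated
})

test_that("failed replicates are reported without aborting the batch", {
  # a run driven to immediate solver trouble: absurd starting synthesis
  cfg <- simulation_config(n_fixed = 5, n_replicates = 3, seed = 13,
                           max_proposals = 50, neutral = TRUE,
                           population_size = 1e6)
  sim <- run_simulation(cfg)
  expect_equal(length(sim$failures), 3L)
  expect_null(sim$summary)
})
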