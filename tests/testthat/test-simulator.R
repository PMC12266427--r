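test_that("mutation models honour their mean and degenerate cases", {
  set.seed(1)
  expect_true(all(draw_mutations(mutation_model("poisson", 0), 100) == 0L))
  expect_true(all(draw_mutations(mutation_model("fixed", 2), 100) == 2L))
  # CLT bound on the Poisson sample mean
  x <- draw_mutations(mutation_model("poisson", 2), 1e5)
  expect_lt(abs(mean(x) - 2), 3 * sqrt(2 / 1e5))
  g <- draw_mutations(mutation_model("geometric", 2), 1e5)
  expect_lt(abs(mean(g) - 2), 3 * sqrt(6 / 1e5))  # var = mu (1 + mu)
  tab <- mutation_model("table", values = c(0, 3), probs = c(0.5, 0.5))
  expect_equal(tab$mean, 1.5)
  expect_true(all(draw_mutations(tab, 100) %in% c(0L, 3L)))
  expect_error(mutation_model("poisson", -1), "non-negative")
  expect_error(mutation_model("fixed", 1.5), "integer")
  expect_error(mutation_model("nonsense"))
})

test_that("configuration validation rejects shrinking populations and bad stops", {
  expect_error(sim_config(beta = 0.4, stop_n = 10), "growing")
  expect_error(sim_config(beta = 0.5, stop_n = 10), "growing")
  expect_error(sim_config(beta = 1), "exactly one")
  expect_error(sim_config(beta = 1, stop_n = 10, stop_steps = 5), "exactly one")
  expect_error(sim_config(beta = 1, n0 = 5, stop_n = 3), "stop_n")
})

test_that("pure birth is deterministic in size: N = i + 1 from one cell", {
  s <- sim_run(sim_config(beta = 1, mu = 0, stop_n = 5), seed = 1)
  expect_equal(s$step, 4L)
  expect_equal(s$n, 5L)
  s2 <- sim_run(sim_config(beta = 1, mu = 0, stop_n = 100), seed = 2)
  expect_equal(s2$step, 99L)
  expect_equal(s2$m, 0L)
  expect_true(all(s2$burden == 0L))
  expect_equal(hist_total(mbd(s2)), 100)
  expect_equal(as.data.frame(mbd(s2)), data.frame(index = 0L, count = 100))
})

test_that("every division adds one block per daughter, even without mutations", {
  s <- sim_run(sim_config(beta = 1, mu = 0, stop_n = 40), seed = 3)
  # 39 divisions, two blocks each, all placeholders
  expect_length(s$blocks, 2L * 39L)
  expect_true(all(lengths(s$blocks) == 0L))
  expect_equal(vapply(s$cell_blocks, length, integer(1)), s$divisions)
})

test_that("daughters inherit the parent's mutations plus their own draw", {
  # with a fixed 2-mutations-per-daughter model, burden = 2 * divisions
  s <- sim_run(sim_config(beta = 1, mu = 2, mutation_dist = "fixed",
                          stop_n = 64), seed = 4)
  expect_equal(s$burden, 2L * s$divisions)
  expect_equal(vapply(s$mutations, length, integer(1)), s$burden)
  s_bd <- sim_run(sim_config(beta = 2 / 3, mu = 1, mutation_dist = "fixed",
                             stop_n = 50), seed = 5)
  expect_equal(s_bd$burden, s_bd$divisions)
})

test_that("mutation ids are unique across a run and M counts living mutations", {
  s <- sim_run(sim_config(beta = 2 / 3, mu = 2, stop_n = 80), seed = 6)
  ids <- unlist(s$mutations)
  expect_false(any(vapply(s$mutations, anyDuplicated, integer(1)) > 0))
  expect_lte(max(c(ids, 0L)), s$n_mut_total)
  expect_equal(length(unique(ids)), s$m)
  # per-id abundance bookkeeping equals a fresh tally
  tallied <- tabulate(ids, nbins = s$n_mut_total)
  expect_equal(tallied, s$abundance)
})

test_that("compact and full tracking give identical histograms on one seed", {
  for (beta in c(1, 2 / 3)) {
    cfg_f <- sim_config(beta = beta, mu = 2, stop_n = 60, track = "full")
    cfg_c <- sim_config(beta = beta, mu = 2, stop_n = 60, track = "compact")
    sf <- sim_run(cfg_f, seed = 9)
    sc <- sim_run(cfg_c, seed = 9)
    expect_identical(sf$step, sc$step)
    expect_identical(sf$discarded, sc$discarded)
    expect_identical(as.data.frame(dd(sf)), as.data.frame(dd(sc)))
    expect_identical(as.data.frame(mbd(sf)), as.data.frame(mbd(sc)))
  }
})

test_that("step-count stopping rule fires exactly, with survival conditioning", {
  s <- sim_run(sim_config(beta = 2 / 3, mu = 0, stop_steps = 40,
                          track = "compact"), seed = 10)
  expect_equal(s$step, 40L)
  expect_gt(s$n, 0L)
  s0 <- sim_run(sim_config(beta = 1, stop_steps = 0L), seed = 1)
  expect_equal(s0$step, 0L)
  expect_equal(s0$n, 1L)
})

test_that("trajectories record N and M stepwise with the right dynamics", {
  s <- sim_run(sim_config(beta = 1, mu = 2, stop_n = 50), seed = 11,
               trajectory = TRUE)
  tr <- s$trajectory
  expect_equal(nrow(tr), 49L)
  expect_equal(tr$N, tr$step + 1L)          # pure birth: N_i = i + 1
  expect_true(all(diff(tr$M) >= 0L))        # no loss without death
  expect_equal(tr$M[nrow(tr)], s$m)
  sb <- sim_run(sim_config(beta = 2 / 3, mu = 2, stop_n = 40), seed = 12,
                trajectory = TRUE)
  expect_true(all(abs(diff(sb$trajectory$N)) == 1L))  # +/- 1 per step
  s_mu0 <- sim_run(sim_config(beta = 1, mu = 0, stop_n = 30), seed = 13,
                   trajectory = TRUE)
  expect_true(all(s_mu0$trajectory$M == 0L))
})

test_that("restart fraction approximates the extinction probability delta/beta", {
  ens <- run_ensemble(sim_config(beta = 2 / 3, mu = 0, stop_n = 30,
                                 track = "compact"),
                      reps = 800, master_seed = 14, stats = "dd")
  frac <- ens$discarded / ens$attempts
  # extinction probability from one cell is delta/beta = 1/2 (the chance of
  # dying out after already reaching 30 cells is negligible)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / ens$attempts) + 0.01)
})

test_that("progenitors with n0 > 1 start mutation-free and undivided", {
  s <- sim_run(sim_config(beta = 1, mu = 3, n0 = 4L, stop_n = 4L), seed = 15)
  expect_equal(s$step, 0L)
  expect_true(all(s$burden == 0L))
  expect_true(all(s$divisions == 0L))
  s2 <- sim_run(sim_config(beta = 1, mu = 3, n0 = 4L, stop_n = 20L), seed = 16)
  expect_equal(s2$step, 16L)  # pure birth: N - n0 steps
})
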