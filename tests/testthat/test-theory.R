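test_that("Stirling numbers satisfy their boundary conditions and recurrence", {
  expect_equal(stirling1(1, 1), 1)
  expect_equal(stirling1(3, 1:3), c(2, 3, 1))
  expect_equal(stirling1(3, 2), 3)          # 2*[2,2] + [2,1] = 2 + 1
  expect_equal(stirling1(5, 7), 0)          # l > i
  expect_equal(stirling1(4, 0), 0)          # l = 0
  expect_error(stirling1(4, -1), "non-negative")
  expect_error(stirling1(200, 1), "log")    # beyond exact double range
})

test_that("log-space Stirling values agree with exact big integers", {
  for (i in c(20, 60, 120, 200)) {
    big_row <- mutburden:::.stirling_big_row(i)
    exact_log <- vapply(big_row, mutburden:::.big_log, numeric(1))
    expect_equal(stirling_log_row(i), exact_log, tolerance = 1e-12)
  }
  # table rows match the row-only variant
  L <- stirling_log_table(40)
  expect_equal(L[40, 1:40], stirling_log_row(40))
  expect_true(all(L[10, 11:40] == -Inf))
})

test_that("Stirling row identity sum_l [i,l] 2^l = (i+1)! holds in log space", {
  for (i in c(10, 100, 500, 2000)) {
    r <- stirling_log_row(i)
    lhs <- mutburden:::.logsumexp(r + seq_len(i) * log(2))
    expect_equal(lhs, lfactorial(i + 1), tolerance = 1e-10)
  }
})

test_that("pure-birth SFS closed form solves the recurrence", {
  expect_equal(expected_sfs_pure_birth(2, 4, 1), 10)     # iterates 4,6,8,10
  expect_equal(expected_sfs_pure_birth(0, 10, 1:5), rep(0, 5))
  S <- sfs_recurrence(2, 50)
  # j = 1 is linear: E[S_1,i] = mu (i + 1) for i >= 1
  expect_equal(unname(S[-1, 1]), 2 * (1:50 + 1), tolerance = 1e-12)
  # j = 2 at i = 2 equals mu, matching the closed form 2 mu * 3 / 6
  mu <- 0.7
  S2 <- sfs_recurrence(mu, 2)
  expect_equal(unname(S2[3, 2]), mu)
  # all-zero boundary
  expect_true(all(S[1, ] == 0))
  # above the diagonal the recurrence is authoritative and gives zero
  expect_true(all(S[6, 6:51] == 0))
  expect_gt(expected_sfs_pure_birth(2, 5, 7), 0)
  expect_error(sfs_recurrence(2, 10, delta = 0.1), "pure birth")
})

test_that("birth-death SFS series reduces termwise to pure birth at delta = 0", {
  j <- 1:20
  bd <- expected_sfs_birth_death(2, 1, 0, i = 10, j = j)
  pb <- expected_sfs_pure_birth(2, 10, j)
  expect_equal(bd, pb, tolerance = 1e-14)
  # positive, decreasing in j, finite for delta > 0
  v <- expected_sfs_birth_death(2, 2 / 3, 1 / 3, i = 100, j = j)
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
  # explicit popsize overrides the conditioned chain
  v2 <- expected_sfs_birth_death(2, 2 / 3, 1 / 3, i = NULL, j = 1,
                                 popsize = 1000)
  expect_gt(v2, 2000)  # exceeds the pure-birth 2 mu N / 2 because of death
})

test_that("pure-birth DD closed form: small cases and mass conservation", {
  expect_equal(expected_dd_pure_birth(1), 2)
  expect_equal(expected_dd_pure_birth(2), c(1, 2))
  for (i in c(10, 100, 999))
    expect_equal(sum(expected_dd_pure_birth(i)), i + 1, tolerance = 1e-10)
})

test_that("DD recurrence conserves mass and matches the closed form", {
  D <- dd_recurrence(60)
  expect_equal(unname(D[1, 1]), 1)
  expect_equal(unname(D[3, 2:3]), c(1, 2))
  expect_equal(unname(rowSums(D)), 0:60 + 1, tolerance = 1e-12)
  for (i in c(10, 40, 60))
    expect_equal(unname(D[i + 1, 2:(i + 1)]), expected_dd_pure_birth(i),
                 tolerance = 1e-10)
})

test_that("birth-death DD reduces to pure birth and partitions the population", {
  i <- 50
  expect_equal(expected_dd_birth_death(i, 1, 0, popsize = i + 1),
               expected_dd_pure_birth(i), tolerance = 1e-12)
  for (beta in c(0.6, 2 / 3, 0.9)) {
    v <- expected_dd_birth_death(i, beta, 1 - beta, popsize = 77)
    expect_equal(sum(v), 77, tolerance = 1e-12)  # fractions sum to unity
  }
})

test_that("pure-birth MBD mixture: point values, mass and mean", {
  mb <- expected_mbd_pure_birth(2, 1)
  expect_equal(mb$value[mb$index == 0], 2 * exp(-2), tolerance = 1e-14)
  mb0 <- expected_mbd_pure_birth(0, 10)
  expect_equal(mb0$value[mb0$index == 0], 11)
  for (i in c(5, 50, 200)) {
    m <- expected_mbd_pure_birth(1.5, i)
    expect_equal(sum(m$value), i + 1, tolerance = 1e-8)
    expect_equal(sum(m$index * m$value) / sum(m$value),
                 expected_mean_burden(1.5, i), tolerance = 1e-8)
  }
})

test_that("survival-conditioned population size: exact cases and linear regime", {
  pc0 <- expected_popsize_conditioned(1, 0, 20)
  expect_equal(pc0$expected, 0:20 + 1)
  for (beta in c(0.6, 2 / 3, 0.9)) {
    pc <- expected_popsize_conditioned(beta, 1 - beta, 1)
    expect_equal(pc$expected[2], 2)  # the only surviving path is a birth
  }
  pc <- expected_popsize_conditioned(2 / 3, 1 / 3, 200)
  gap <- abs(pc$expected - pc$linear) / pc$expected
  expect_lt(gap[201], gap[51])  # relative gap to (beta-delta) i + 1 shrinks
  expect_lt(gap[201], 0.05)
  expect_error(expected_popsize_conditioned(0.4, 0.6, 10), "growing")
})

test_that("mean burden closed form matches the occurrence recurrence", {
  # independent oracle: total divisions T satisfy
  # T_{i+1} = T_i (1 + 1/(i+1)) + 2 with T_0 = 0; mean = T_i / (i + 1)
  i_max <- 500
  Tv <- numeric(i_max + 1)
  for (i in 0:(i_max - 1)) Tv[i + 2] <- Tv[i + 1] * (1 + 1 / (i + 1)) + 2
  mean_div <- Tv / (0:i_max + 1)
  mu <- 2.3
  expect_equal(expected_mean_burden(mu, 0:i_max), mu * mean_div,
               tolerance = 1e-12)
  expect_equal(expected_mean_burden(1, 1), 1)
  expect_equal(expected_mean_burden(3, 2), 5)        # 3 * 5/3
  expect_equal(expected_mean_burden(6, 3), 13)       # 6 * 13/6
})
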