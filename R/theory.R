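# Expected SFS / DD / MBD curves. Pure-birth results are exact (closed forms
# and the recurrences they solve); with death they are first-order
# approximations valid in the low-death and large-population limits. All
# Stirling-number assemblies happen in log space and are exponentiated last.
# Every formula here assumes N0 = 1 (a single mutation-free progenitor) and
# refuses other initial conditions rather than silently mis-applying.

.check_bd <- function(beta, delta) {
  stopifnot(is.numeric(beta), is.numeric(delta),
            length(beta) == 1L, length(delta) == 1L)
  if (delta < 0 || !(beta > delta))
    stop("requires the growing case beta > delta >= 0")
  if (abs(beta + delta - 1) > 1e-12)
    stop("beta + delta must equal 1")
}

#' Expected site frequency spectrum, pure birth
#'
#' Closed form for the expected number of j-abundant mutations after i steps
#' of the pure-birth (Yule) process with mutational mean `mu`:
#' `E[S_j] = 2 mu (i + 1) / (j (j + 1))`. The closed form agrees with the
#' defining recurrence ([sfs_recurrence()]) exactly for `j <= i`; for
#' `j > i` the true expectation is 0 while the closed form stays positive,
#' so the recurrence is authoritative there.
#'
#' @param mu mutational mean per daughter per division (>= 0).
#' @param i step count (>= 0); equals N - 1 for a pure-birth population of
#'   size N grown from one cell.
#' @param j abundance, vectorised, >= 1.
#' @return Numeric vector of expected counts.
#' @export
expected_sfs_pure_birth <- function(mu, i, j) {
  stopifnot(mu >= 0, i >= 0, all(j >= 1))
  2 * mu * (i + 1) / (j * (j + 1))
}

#' Iterate the pure-birth SFS recurrence
#'
#' Forward-iterates
#' `E[S_j, i+1] = E[S_j, i] - j E[S_j, i]/(i+1) + (j-1) E[S_{j-1}, i]/(i+1)
#' + 2 mu 1{j = 1}` from the all-zero state at `i = 0`. Exact for pure birth,
#' where the population size i + 1 is deterministic; with death the
#' analogous recurrence involves expectations of ratios and is only solved
#' to first order (see [expected_sfs_birth_death()]), so this function
#' refuses `delta > 0`.
#'
#' @param mu mutational mean.
#' @param i_max number of steps to iterate.
#' @param delta must be 0 (argument exists so that mis-use fails loudly).
#' @return A matrix with `i_max + 1` rows (i = 0..i_max) and `i_max + 1`
#'   columns (j = 1..i_max + 1); entry (i + 1, j) is `E[S_j, i]`.
#' @export
sfs_recurrence <- function(mu, i_max, delta = 0) {
  stopifnot(mu >= 0, i_max >= 0)
  if (delta != 0)
    stop("the SFS recurrence is exact only for pure birth (delta = 0)")
  jmax <- i_max + 1L
  j <- seq_len(jmax)
  out <- matrix(0, i_max + 1L, jmax,
                dimnames = list(i = 0:i_max, j = j))
  s <- numeric(jmax)
  if (i_max >= 1) for (i in 0:(i_max - 1L)) {
    snew <- s - j * s / (i + 1) + (j - 1) * c(0, s[-jmax]) / (i + 1)
    snew[1L] <- snew[1L] + 2 * mu
    s <- snew
    out[i + 2L, ] <- s
  }
  out
}

#' Expected site frequency spectrum with death, first order
#'
#' First-order approximation for the growing birth-death process:
#' `E[S_j, i] ~ sum_{j' >= 0} 2 mu (delta/beta)^j' / ((j+j')(j+j'+1)) E[N_i]`,
#' with all expectations conditioned on survival of the population. The
#' geometric ratio `delta/beta` guarantees convergence; the series is
#' truncated once a term falls below `tol` times the running sum. At
#' `delta = 0` only the `j' = 0` term survives and the pure-birth closed
#' form is recovered termwise.
#'
#' @param mu mutational mean.
#' @param beta,delta birth and death probabilities, `beta > delta >= 0`,
#'   `beta + delta = 1`.
#' @param i step count, used to evaluate the conditioned expected population
#'   size unless `popsize` is given.
#' @param j abundances (vectorised, >= 1).
#' @param tol relative truncation tolerance for the series.
#' @param popsize expected population size E[N_i] to use. Defaults to the
#'   numerically exact survival-conditioned value
#'   ([expected_popsize_conditioned()]); pass `(beta - delta) * i + 1` for
#'   the linear low-death approximation, or the known final size N when
#'   comparing against ensembles stopped at fixed N.
#' @return Numeric vector of expected counts, one per `j`.
#' @export
expected_sfs_birth_death <- function(mu, beta, delta, i, j, tol = 1e-12,
                                     popsize = NULL) {
  .check_bd(beta, delta)
  stopifnot(mu >= 0, all(j >= 1), tol > 0)
  if (is.null(popsize)) {
    pc <- expected_popsize_conditioned(beta, delta, i_max = i)
    popsize <- pc$expected[pc$i == i]
  }
  r <- delta / beta
  vapply(j, function(jj) {
    total <- 0
    jp <- 0
    w <- 1
    repeat {
      term <- 2 * mu * w / ((jj + jp) * (jj + jp + 1))
      total <- total + term
      if (r == 0 || term <= tol * total) break
      jp <- jp + 1
      w <- w * r
    }
    total * popsize
  }, numeric(1))
}

#' Expected division distribution, pure birth
#'
#' The exact Yule-process leaf-depth result
#' `E[D_l, i] = [i, l] 2^l / i!` for the number of cells with `l` divisions
#' in their history after `i` steps, where `[i, l]` is the unsigned Stirling
#' number of the first kind. Assembled in log space. The row identity
#' `sum_l [i, l] 2^l = (i + 1)!` makes the curve sum to the population size
#' `i + 1`.
#'
#' @param i step count >= 1.
#' @param log_row optional precomputed [stirling_log_row()] for `i`.
#' @return Numeric vector over `l = 1..i` of expected counts.
#' @export
expected_dd_pure_birth <- function(i, log_row = NULL) {
  stopifnot(i >= 1)
  lr <- log_row %||% stirling_log_row(i)
  l <- seq_len(i)
  exp(lr + l * log(2) - lfactorial(i))
}

#' Iterate the pure-birth DD recurrence
#'
#' Forward-iterates
#' `E[D_l, i+1] = E[D_l, i] - E[D_l, i]/(i+1) + 2 E[D_{l-1}, i]/(i+1)` from
#' `D_0 = 1` at `i = 0`. The closed form of [expected_dd_pure_birth()]
#' satisfies this recurrence and the two agree for all `l <= i` (the
#' uniqueness of solutions made numeric). Mass `i + 1` is conserved at every
#' step. With `log = TRUE` the iteration runs in log space (all terms are
#' positive), which keeps deep tails comparable far below the double
#' underflow threshold.
#'
#' @param i_max number of steps.
#' @param log iterate in log space and return log expected counts.
#' @return A matrix with rows i = 0..i_max and columns l = 0..i_max.
#' @export
dd_recurrence <- function(i_max, log = FALSE) {
  stopifnot(i_max >= 0)
  cols <- i_max + 1L
  if (!log) {
    out <- matrix(0, i_max + 1L, cols, dimnames = list(i = 0:i_max, l = 0:i_max))
    d <- c(1, numeric(i_max))
    out[1L, ] <- d
    if (i_max >= 1) for (i in 0:(i_max - 1L)) {
      d <- d - d / (i + 1) + 2 * c(0, d[-cols]) / (i + 1)
      out[i + 2L, ] <- d
    }
  } else {
    out <- matrix(-Inf, i_max + 1L, cols,
                  dimnames = list(i = 0:i_max, l = 0:i_max))
    d <- c(0, rep(-Inf, i_max))
    out[1L, ] <- d
    if (i_max >= 1) for (i in 0:(i_max - 1L)) {
      keep <- d + log(i / (i + 1))          # -Inf at i = 0: all mass moves on
      gain <- c(-Inf, d[-cols]) + log(2 / (i + 1))
      d <- .logaddexp(keep, gain)
      out[i + 2L, ] <- d
    }
  }
  out
}

#' Expected division distribution with death, first order
#'
#' First-order approximation
#' `E[D_l, i] ~ f(i, l) / sum_l' f(i, l') * E[N_i]` with
#' `f(i, l) = [i, l] 2^l (1 - delta/beta)^{-l}`; the normalisation is a
#' log-sum-exp, so the fractions sum to one by construction. At `delta = 0`
#' this reduces exactly to the pure-birth closed form.
#'
#' @inheritParams expected_sfs_birth_death
#' @param i step count >= 1.
#' @return Numeric vector over `l = 1..i`.
#' @export
expected_dd_birth_death <- function(i, beta, delta, popsize = NULL) {
  .check_bd(beta, delta)
  stopifnot(i >= 1)
  if (is.null(popsize)) {
    pc <- expected_popsize_conditioned(beta, delta, i_max = i)
    popsize <- pc$expected[pc$i == i]
  }
  l <- seq_len(i)
  w <- stirling_log_row(i) + l * (log(2) - log1p(-delta / beta))
  exp(w - .logsumexp(w)) * popsize
}

#' Expected mutational burden distribution, pure birth
#'
#' A cell with `l` divisions in its history carries a Poisson(`l mu`) burden
#' (a sum of `l` independent Poisson(`mu`) draws), so the expected MBD is the
#' Poisson mixture of the expected DD:
#' `E[B_k, i] = sum_l [i, l] 2^l / i! * exp(-l mu) (l mu)^k / k!`.
#' Computed via [dd_to_mbd()] with log-space Poisson terms; the k-support is
#' truncated adaptively with a reported mass defect below `1e-8`.
#'
#' @param mu mutational mean.
#' @param i step count >= 1.
#' @param k_max truncation of the burden support; `NULL` chooses
#'   mean + 10 sd of the widest mixture component.
#' @return A data frame with columns `index` (k) and `value` (`E[B_k, i]`);
#'   attribute `mass_defect` records the truncated mass.
#' @export
expected_mbd_pure_birth <- function(mu, i, k_max = NULL) {
  stopifnot(mu >= 0, i >= 1)
  ddc <- expected_dd_pure_birth(i)
  dd_to_mbd(data.frame(index = seq_len(i), value = ddc), mu, k_max = k_max)
}

#' Survival-conditioned expected population size
#'
#' Numerically exact `E[N_i | N_i > 0, N_0 = 1]` for the discrete-time
#' birth-death chain, by forward-propagating the finite-state distribution
#' with an absorbing state at 0 and renormalising over the non-absorbed
#' mass. The state space is truncated at `cap`; the mass sitting at the
#' truncation boundary is checked and an error raised if it is large enough
#' to bias the result. The linear low-death approximation
#' `(beta - delta) i + 1` is returned alongside for comparison.
#'
#' @inheritParams expected_sfs_birth_death
#' @param i_max largest step count.
#' @param cap state-space truncation; default `20 (beta - delta) i_max + 50`.
#' @return A data frame with columns `i` (0..i_max), `expected`
#'   (conditioned numeric value) and `linear`.
#' @export
expected_popsize_conditioned <- function(beta, delta, i_max, cap = NULL) {
  .check_bd(beta, delta)
  stopifnot(i_max >= 0)
  cap <- as.integer(cap %||% ceiling(20 * (beta - delta) * i_max + 50))
  q <- numeric(cap + 1L)   # q[n + 1] = P(N_i = n)
  q[2L] <- 1
  states <- 0:cap
  expected <- numeric(i_max + 1L)
  expected[1L] <- 1
  if (i_max >= 1) for (i in seq_len(i_max)) {
    qn <- numeric(cap + 1L)
    qn[1L] <- q[1L] + delta * q[2L]
    # births n -> n + 1 for n = 1..cap-1; the top state holds its mass
    qn[3:(cap + 1L)] <- qn[3:(cap + 1L)] + beta * q[2:cap]
    qn[cap + 1L] <- qn[cap + 1L] + beta * q[cap + 1L]
    # deaths n -> n - 1 for n = 2..cap
    qn[2:cap] <- qn[2:cap] + delta * q[3:(cap + 1L)]
    q <- qn
    expected[i + 1L] <- sum(states * q) / (1 - q[1L])
  }
  if (q[cap + 1L] > 1e-9)
    stop("state-space cap too small: boundary mass ", format(q[cap + 1L]),
         "; increase cap")
  data.frame(i = 0:i_max, expected = expected,
             linear = (beta - delta) * (0:i_max) + 1)
}

#' Expected mean single-cell burden, pure birth
#'
#' The mean of the MBD (equivalently, mutational occurrences divided by the
#' population size) grows logarithmically with the step count: in the
#' pure-birth case it is a rescaling of the harmonic numbers,
#' `mu * 2 * (H_{i+1} - 1)`, because the mean number of divisions in a
#' cell's history is `2 (H_{i+1} - 1)` and each division adds `mu` mutations
#' on average.
#'
#' @param mu mutational mean.
#' @param i step count(s), vectorised, >= 0.
#' @return Numeric vector of expected mean burdens.
#' @export
expected_mean_burden <- function(mu, i) {
  stopifnot(mu >= 0, all(i >= 0))
  h <- function(n) sum(1 / seq_len(n))
  mu * 2 * (vapply(i + 1, h, numeric(1)) - 1)
}
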