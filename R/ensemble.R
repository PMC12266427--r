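#' Run an ensemble of survival-conditioned replicates
#'
#' Runs `reps` surviving realisations of the configured process. Replicate
#' seeds are derived deterministically from `master_seed`, so an identical
#' (config, master_seed, reps) triple reproduces the ensemble exactly.
#' Extinct attempts are discarded and tallied (`reps` counts survivors).
#'
#' @param config a [sim_config()].
#' @param reps number of surviving replicates (>= 1).
#' @param master_seed integer master seed.
#' @param stats which histograms to collect: subset of
#'   `c("sfs", "dd", "mbd")`. The SFS needs `track = "full"`.
#' @return An object of class `bd_ensemble`: for each requested statistic a
#'   list with `index`, `mean` and `se` (per-bin across-replicate mean and
#'   standard error, zero-filled over the union support; `se` is 0 with
#'   `se_defined = FALSE` when `reps = 1`), plus `reps`, `discarded`,
#'   `attempts`, `final_n`, `final_step`, `config`, `master_seed`.
#' @examples
#' ens <- run_ensemble(sim_config(beta = 1, mu = 2, stop_n = 50,
#'                                track = "compact"),
#'                     reps = 20, master_seed = 1, stats = c("dd", "mbd"))
#' @export
run_ensemble <- function(config, reps, master_seed,
                         stats = c("dd", "mbd")) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  stats <- match.arg(stats, c("sfs", "dd", "mbd"), several.ok = TRUE)
  if ("sfs" %in% stats && config$track != "full")
    stop("collecting the SFS requires track = \"full\"")
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, reps)
  hists <- lapply(stats, function(s) vector("list", reps))
  names(hists) <- stats
  discarded <- 0L
  final_n <- integer(reps)
  final_step <- integer(reps)
  for (r in seq_len(reps)) {
    sim <- sim_run(config, seed = seeds[r])
    discarded <- discarded + sim$discarded
    final_n[r] <- sim$n
    final_step[r] <- sim$step
    for (s in stats) hists[[s]][[r]] <- switch(s, sfs = sfs(sim),
                                               dd = dd(sim), mbd = mbd(sim))
  }
  out <- list(reps = reps, discarded = discarded,
              attempts = reps + discarded,
              final_n = final_n, final_step = final_step,
              config = config, master_seed = master_seed, seeds = seeds)
  for (s in stats) {
    from <- if (s == "sfs") 1L else 0L
    hi <- max(vapply(hists[[s]],
                     function(h) if (length(h$index)) max(h$index) else from,
                     numeric(1)))
    m <- vapply(hists[[s]], .hist_dense, numeric(hi - from + 1L),
                from = from, to = hi)
    m <- matrix(m, nrow = hi - from + 1L)
    out[[s]] <- list(index = from:hi,
                     mean = rowMeans(m),
                     se = if (reps > 1) apply(m, 1, sd) / sqrt(reps)
                          else numeric(hi - from + 1L),
                     se_defined = reps > 1)
  }
  class(out) <- "bd_ensemble"
  out
}

#' @exportS3Method base::print
print.bd_ensemble <- function(x, ...) {
  cat(sprintf(
    "<bd_ensemble %d surviving replicates, %d extinct attempts discarded (%.3f of %d)>\n",
    x$reps, x$discarded, x$discarded / x$attempts, x$attempts))
  invisible(x)
}

#' Ensemble-mean histogram as a data frame or int_hist
#'
#' @param ens a [run_ensemble()] result.
#' @param stat `"sfs"`, `"dd"` or `"mbd"`.
#' @return A data frame with columns `index`, `mean`, `se`.
#' @export
ensemble_mean <- function(ens, stat = c("dd", "mbd", "sfs")) {
  stat <- match.arg(stat)
  s <- ens[[stat]]
  if (is.null(s)) stop("statistic not collected in this ensemble: ", stat)
  data.frame(index = s$index, mean = s$mean, se = s$se)
}

#' Ensemble of population-size trajectories
#'
#' Runs `reps` surviving replicates under a step-count stopping rule and
#' records the population size at every step, returning the per-step
#' across-replicate mean and standard error. All replicates are conditioned
#' on surviving to the final step, so the mean at the final step is the
#' quantity comparable with [expected_popsize_conditioned()] at that step.
#'
#' @param config a [sim_config()] with a `stop_steps` rule.
#' @param reps number of surviving replicates.
#' @param master_seed integer master seed.
#' @return A data frame with columns `step`, `mean_n`, `se_n`, plus
#'   attributes `discarded` and `attempts`.
#' @export
ensemble_trajectory <- function(config, reps, master_seed) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$stop_steps))
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, reps)
  nmat <- matrix(0L, config$stop_steps, reps)
  discarded <- 0L
  for (r in seq_len(reps)) {
    sim <- sim_run(config, seed = seeds[r], trajectory = TRUE)
    discarded <- discarded + sim$discarded
    nmat[, r] <- sim$trajectory$N
  }
  out <- data.frame(step = seq_len(config$stop_steps),
                    mean_n = rowMeans(nmat),
                    se_n = if (reps > 1) apply(nmat, 1, sd) / sqrt(reps)
                           else 0)
  attr(out, "discarded") <- discarded
  attr(out, "attempts") <- reps + discarded
  out
}

#' Compare an ensemble against a theoretical expected curve
#'
#' Per-bin z-scores of the ensemble mean against an expected curve, using
#' the across-replicate standard errors. Bins whose expected count falls
#' below `count_floor` are excluded from the pass decision (they are
#' Poisson-noisy and the normal approximation fails); the pass flag requires
#' every scored bin within `z_max` standard errors.
#'
#' @param ens a [run_ensemble()] result.
#' @param expected a data frame with columns `index` and `value` (e.g. from
#'   the theory functions), or an [int_hist].
#' @param stat which collected statistic to compare.
#' @param count_floor minimum expected count for a bin to be scored.
#' @param z_max pass threshold on |z|.
#' @return A list with `table` (index, mean, se, expected, z, scored),
#'   `n_scored`, `frac_within`, `max_z`, `pass`.
#' @export
compare_to_theory <- function(ens, expected, stat = c("dd", "mbd", "sfs"),
                              count_floor = 5, z_max = 3) {
  stat <- match.arg(stat)
  s <- ens[[stat]]
  if (is.null(s)) stop("statistic not collected in this ensemble: ", stat)
  exp_df <- .curve_in(expected)
  idx <- sort(union(s$index, exp_df$index))
  mean_v <- se_v <- ev <- numeric(length(idx))
  mean_v[match(s$index, idx)] <- s$mean
  se_v[match(s$index, idx)] <- s$se
  ev[match(exp_df$index, idx)] <- exp_df$value
  z <- ifelse(se_v > 0, (mean_v - ev) / se_v, ifelse(mean_v == ev, 0, Inf))
  scored <- ev >= count_floor
  tab <- data.frame(index = idx, mean = mean_v, se = se_v, expected = ev,
                    z = z, scored = scored)
  list(table = tab,
       n_scored = sum(scored),
       frac_within = if (any(scored)) mean(abs(z[scored]) < z_max) else NA_real_,
       max_z = if (any(scored)) max(abs(z[scored])) else NA_real_,
       pass = all(abs(z[scored]) < z_max))
}
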