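#' Simulation configuration
#'
#' Parameters of the discrete-time birth-death process with mutation
#' accumulation. At every step one uniformly chosen cell either divides
#' (probability `beta`) or dies (probability `delta = 1 - beta`). On a
#' division each daughter inherits all parental mutations and acquires an
#' independent number of new, globally unique mutations drawn from the
#' mutation model (infinite-sites approximation). Only the growing case
#' `beta > delta` is supported, and all runs are conditioned on survival:
#' a realisation whose population hits zero before the stopping rule fires
#' is discarded and restarted with fresh randomness.
#'
#' @param beta birth probability in (0.5, 1]; the death probability is
#'   always `delta = 1 - beta`, never stored independently.
#' @param mu mean number of new mutations per daughter cell per division.
#' @param n0 initial population size (progenitors are mutation-free with
#'   zero divisions in their history).
#' @param stop_n stopping rule: stop at the first step at which the
#'   population size equals `stop_n`. Exactly one of `stop_n`, `stop_steps`
#'   must be given.
#' @param stop_steps stopping rule: stop after exactly `stop_steps` steps
#'   (conditioned on the population surviving that long).
#' @param mutation_dist either a [mutation_model] or one of its type names
#'   (`"poisson"`, `"fixed"`, `"geometric"`, `"table"`), parameterised by
#'   `mu` (and `dist_values`/`dist_probs` for `"table"`).
#' @param dist_values,dist_probs support and probabilities when
#'   `mutation_dist = "table"`.
#' @param track `"full"` keeps per-cell mutation-id sets and the division
#'   block registry (required for the SFS and the genotype matrix);
#'   `"compact"` keeps only per-cell (burden, divisions) counters, which is
#'   much lighter and suffices for the DD and the MBD. Both modes consume
#'   randomness identically, so the same seed yields the same realisation.
#' @param max_restarts safety cap on extinction restarts per run.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(beta = 1, mu = 2, stop_n = 100)
#' @export
sim_config <- function(beta = 1, mu = 0, n0 = 1L,
                       stop_n = NULL, stop_steps = NULL,
                       mutation_dist = "poisson",
                       dist_values = NULL, dist_probs = NULL,
                       track = c("full", "compact"),
                       max_restarts = 1e6L) {
  track <- match.arg(track)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0, beta <= 1)
  delta <- 1 - beta
  if (!(beta > delta))
    stop("only the growing-population case beta > delta = 1 - beta is supported")
  n0 <- as.integer(n0)
  stopifnot(n0 >= 1L)
  if (is.null(stop_n) == is.null(stop_steps))
    stop("exactly one of stop_n, stop_steps must be given")
  if (!is.null(stop_n)) {
    stop_n <- as.integer(stop_n)
    if (stop_n < n0) stop("stop_n must be >= n0")
  }
  if (!is.null(stop_steps)) {
    stop_steps <- as.integer(stop_steps)
    if (stop_steps < 0L) stop("stop_steps must be >= 0")
  }
  model <- if (inherits(mutation_dist, "mutation_model")) mutation_dist
           else mutation_model(mutation_dist, mean = mu,
                               values = dist_values, probs = dist_probs)
  structure(list(beta = beta, delta = delta, mu = model$mean, n0 = n0,
                 stop_n = stop_n, stop_steps = stop_steps,
                 model = model, track = track,
                 max_restarts = as.integer(max_restarts)),
            class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  stop_desc <- if (!is.null(x$stop_n)) sprintf("N = %d", x$stop_n)
               else sprintf("i = %d", x$stop_steps)
  cat(sprintf(
    "<sim_config beta=%g delta=%g mu=%g n0=%d stop at %s, %s dist, %s tracking>\n",
    x$beta, x$delta, x$mu, x$n0, stop_desc, x$model$type, x$track))
  invisible(x)
}

#' Read a simulation configuration from a JSON or YAML file
#'
#' Flat key-value files mirroring the arguments of [sim_config()], e.g.
#' `{"beta": 0.6667, "mu": 2, "stop_n": 1000}`. Keys in `override` (typically
#' parsed command-line flags) take precedence over file values.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @param override named list of values overriding the file's.
#' @return A [sim_config].
#' @export
read_sim_config <- function(path, override = list()) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configuration files")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  vals <- modifyList(as.list(vals), override)
  do.call(sim_config, vals[names(vals) %in% names(formals(sim_config))])
}

# One attempt at the process; returns NULL on extinction before the stopping
# rule fires. Full and compact tracking consume the RNG identically.
.sim_attempt <- function(cfg, record_traj = FALSE) {
  beta <- cfg$beta
  full <- cfg$track == "full"
  pure_birth <- cfg$delta == 0
  stop_n <- cfg$stop_n
  stop_i <- cfg$stop_steps
  model <- cfg$model

  n <- cfg$n0
  i <- 0L
  cap <- if (!is.null(stop_n)) stop_n + 2L else cfg$n0 + stop_i + 2L
  div <- integer(cap)
  bur <- integer(cap)
  next_mut <- 0L
  next_blk <- 0L
  if (full) {
    muts <- rep(list(integer(0)), cap)
    blks <- rep(list(integer(0)), cap)
    acap <- 1024L
    abund <- integer(acap)
    bcap <- 1024L
    blocks <- vector("list", bcap)
    m_live <- 0L
  }
  if (record_traj) {
    tcap <- if (!is.null(stop_i)) max(stop_i, 1L) else 8L * stop_n + 64L
    t_n <- integer(tcap)
    t_m <- integer(tcap)
    tlen <- 0L
  }

  done <- (!is.null(stop_n) && n == stop_n) || (!is.null(stop_i) && stop_i == 0L)
  while (!done) {
    birth <- if (beta >= 1) TRUE else runif(1L) < beta
    cell <- if (n == 1L) 1L else sample.int(n, 1L)
    if (birth) {
      u <- draw_mutations(model, 2L)
      u1 <- u[[1L]]
      u2 <- u[[2L]]
      d <- div[cell] + 1L
      if (full) {
        pm <- muts[[cell]]
        pb <- blks[[cell]]
        utot <- u1 + u2
        if (next_mut + utot > acap) {
          acap <- max(2L * acap, next_mut + utot)
          abund <- c(abund, integer(acap - length(abund)))
        }
        if (next_blk + 2L > bcap) {
          bcap <- 2L * bcap
          blocks <- c(blocks, vector("list", bcap - length(blocks)))
        }
        id1 <- if (u1 > 0L) next_mut + seq_len(u1) else integer(0)
        id2 <- if (u2 > 0L) next_mut + u1 + seq_len(u2) else integer(0)
        next_mut <- next_mut + utot
        b1 <- next_blk + 1L
        b2 <- next_blk + 2L
        next_blk <- b2
        blocks[[b1]] <- id1
        blocks[[b2]] <- id2
        muts[[cell]] <- c(pm, id1)
        blks[[cell]] <- c(pb, b1)
        n <- n + 1L
        muts[[n]] <- c(pm, id2)
        blks[[n]] <- c(pb, b2)
        if (length(pm)) abund[pm] <- abund[pm] + 1L
        if (utot > 0L) {
          abund[(next_mut - utot + 1L):next_mut] <- 1L
          m_live <- m_live + utot
        }
      } else {
        next_mut <- next_mut + u1 + u2
        n <- n + 1L
      }
      bur[n] <- bur[cell] + u2
      bur[cell] <- bur[cell] + u1
      div[cell] <- d
      div[n] <- d
    } else {
      if (full) {
        pm <- muts[[cell]]
        if (length(pm)) {
          abund[pm] <- abund[pm] - 1L
          m_live <- m_live - sum(abund[pm] == 0L)
        }
        muts[[cell]] <- muts[[n]]
        blks[[cell]] <- blks[[n]]
      }
      div[cell] <- div[n]
      bur[cell] <- bur[n]
      n <- n - 1L
    }
    i <- i + 1L
    if (record_traj) {
      tlen <- tlen + 1L
      if (tlen > tcap) {
        tcap <- 2L * tcap
        t_n <- c(t_n, integer(tcap - length(t_n)))
        t_m <- c(t_m, integer(tcap - length(t_m)))
      }
      t_n[tlen] <- n
      t_m[tlen] <- if (full) m_live else if (pure_birth) next_mut else NA_integer_
    }
    if (n == 0L) return(NULL)
    done <- (!is.null(stop_n) && n == stop_n) || (!is.null(stop_i) && i == stop_i)
  }

  out <- list(
    step = i, n = n,
    m = if (full) m_live else if (pure_birth) next_mut else NA_integer_,
    divisions = div[seq_len(n)],
    burden = bur[seq_len(n)],
    n_mut_total = next_mut
  )
  if (full) {
    out$mutations <- muts[seq_len(n)]
    out$cell_blocks <- blks[seq_len(n)]
    out$blocks <- blocks[seq_len(next_blk)]
    out$abundance <- abund[seq_len(next_mut)]
  }
  if (record_traj) {
    out$trajectory <- data.frame(step = seq_len(tlen),
                                 N = t_n[seq_len(tlen)],
                                 M = t_m[seq_len(tlen)])
  }
  out
}

#' Run one survival-conditioned realisation
#'
#' Iterates the birth-death process until the stopping rule of the
#' configuration fires. If the population goes extinct first, the whole run
#' is discarded and restarted with fresh randomness (rejection conditioning
#' on survival); the number of discarded attempts is reported in the result.
#'
#' @param config a [sim_config].
#' @param seed optional integer seed (set before the first attempt; restarts
#'   continue from the same stream, so one seed reproduces the whole run
#'   including its discarded attempts).
#' @param trajectory if `TRUE`, record the time series of the population
#'   size `N` and the number of unique mutations `M` at every step. `M` is
#'   `NA` in compact tracking with death (lost mutations cannot be counted
#'   without id sets).
#' @return An object of class `bd_sim`: a list with `step` (the final step
#'   count i), `n` (final population size), `m` (number of unique mutations
#'   carried by living cells), per-cell `divisions` and `burden` vectors,
#'   `discarded` (number of extinct attempts rejected), and under full
#'   tracking the per-cell mutation-id sets, the division-block registry and
#'   the per-mutation abundance vector. With `trajectory = TRUE`, a
#'   `trajectory` data frame (step, N, M).
#' @examples
#' s <- sim_run(sim_config(beta = 1, mu = 2, stop_n = 50), seed = 1)
#' s$n
#' sfs(s)
#' @export
sim_run <- function(config, seed = NULL, trajectory = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > config$max_restarts)
      stop("restart limit exceeded: population kept going extinct before ",
           "the stopping rule fired")
    st <- .sim_attempt(config, record_traj = trajectory)
    if (!is.null(st)) break
  }
  st$discarded <- attempts - 1L
  st$config <- config
  st$seed <- seed
  class(st) <- "bd_sim"
  st
}

#' @exportS3Method base::print
print.bd_sim <- function(x, ...) {
  cat(sprintf(
    "<bd_sim %s tracking: i=%d N=%d M=%s, %d extinct attempt(s) discarded>\n",
    x$config$track, x$step, x$n,
    if (is.na(x$m)) "NA" else format(x$m), x$discarded))
  invisible(x)
}
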