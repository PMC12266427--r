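# DD <-> MBD conversions. A cell with l divisions carries a Poisson(l mu)
# burden, so a division distribution maps to a burden distribution by a
# Poisson mixture; only the mean of the per-division mutational distribution
# enters, never its higher moments.

.curve_in <- function(x) {
  if (inherits(x, "int_hist")) data.frame(index = x$index, value = x$count)
  else if (is.data.frame(x)) {
    val <- x$value %||% x$count
    stopifnot(!is.null(x$index), !is.null(val))
    data.frame(index = x$index, value = val)
  } else stop("expected an int_hist or a data frame with index and value/count")
}

#' Convert a division distribution to a mutational burden distribution
#'
#' `out(k) = sum_l dd(l) * exp(-l mu) (l mu)^k / k!`: each DD element is
#' translated into a Poisson distribution with mean `l mu`, weighted by
#' `dd(l)`, and the components are summed. The map is linear in `dd`,
#' conserves total mass (up to the reported truncation defect, kept below
#' `1e-8` of the input mass) and maps the mean exactly:
#' `mean(out) = mu * mean(dd)`.
#'
#' @param x the DD: an [int_hist] or a data frame with columns `index` and
#'   `value` (or `count`), e.g. an expected curve.
#' @param mu mutational mean (>= 0).
#' @param k_max burden-support truncation; `NULL` (default) chooses
#'   mean + 10 sd of the widest Poisson component.
#' @return A data frame with columns `index` (k = 0..k_max) and `value`,
#'   with attribute `mass_defect` (input mass minus output mass).
#' @examples
#' dd_to_mbd(int_hist(1, 2, role = "dd"), mu = 2)[1, ]  # k = 0: 2 exp(-2)
#' @export
dd_to_mbd <- function(x, mu, k_max = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0)
  cur <- .curve_in(x)
  if (any(cur$value < 0)) stop("negative DD weights")
  total <- sum(cur$value)
  if (total == 0 || mu == 0) {
    out <- data.frame(index = 0L, value = total)
    attr(out, "mass_defect") <- 0
    return(out)
  }
  # drop negligible components (guarded so the dropped mass stays < 1e-9)
  keep <- cur$value > 1e-14 * total
  if (sum(cur$value[!keep]) > 1e-9 * total) keep <- keep | TRUE
  cur <- cur[keep, , drop = FALSE]
  lmu_max <- max(cur$index) * mu
  if (is.null(k_max))
    k_max <- ceiling(lmu_max + 10 * sqrt(lmu_max + 1)) + 10
  k <- 0:k_max
  comp <- vapply(seq_len(nrow(cur)), function(r) {
    dpois(k, cur$index[r] * mu) * cur$value[r]
  }, numeric(length(k)))
  value <- if (is.matrix(comp)) rowSums(comp) else comp
  out <- data.frame(index = k, value = value)
  attr(out, "mass_defect") <- total - sum(value)
  out
}

#' Approximately invert an MBD into a division distribution
#'
#' Bins each burden `k` into the division class `l = round(k / mu)`
#' (boundaries at half-integer multiples of `mu`, ties to even) - the
#' maximum-likelihood class assignment for a Poisson(`l mu`) observation
#' when the component means are well separated. Total mass is conserved
#' exactly. The inversion is approximate: it recovers the DD faithfully only
#' when `mu` is large compared to the spread of each Poisson component.
#'
#' @param x the MBD: an [int_hist] or data frame (`index`, `count`/`value`).
#' @param mu mutational mean, strictly positive (`mu = 0` is non-invertible).
#' @return An [int_hist] with role `"dd"`.
#' @export
mbd_to_dd <- function(x, mu) {
  stopifnot(is.numeric(mu), length(mu) == 1L)
  if (mu <= 0) stop("mbd_to_dd requires mu > 0")
  cur <- .curve_in(x)
  l <- round(cur$index / mu)
  agg <- tapply(cur$value, l, sum)
  int_hist(as.integer(names(agg)), as.numeric(agg), role = "dd")
}

#' Score an observed MBD against a converted one
#'
#' Compares a simulated ensemble-mean MBD with the MBD obtained by
#' converting the ensemble-mean DD ([dd_to_mbd()]): per-bin z-scores against
#' the per-bin standard errors, the largest |z|, and the total-variation
#' distance `0.5 * sum |a - b|` between the two mass vectors. Bins with zero
#' standard error but non-zero discrepancy are flagged degenerate and fail.
#'
#' @param observed the simulated mean MBD ([int_hist] or data frame).
#' @param converted the converted MBD (data frame from [dd_to_mbd()]).
#' @param se per-bin standard errors: a data frame (`index`, `value`) or a
#'   numeric vector aligned with `observed`'s indices.
#' @param z_max pass threshold on |z|.
#' @param count_floor bins whose converted expectation falls below this are
#'   reported but excluded from the pass decision (the normal approximation
#'   is unreliable at low counts).
#' @return A list with `table` (index, observed, converted, se, z),
#'   `max_z`, `tv`, `n_scored`, `pass`, `degenerate`.
#' @export
compare_mbd_sources <- function(observed, converted, se, z_max = 3,
                                count_floor = 5) {
  obs <- .curve_in(observed)
  con <- .curve_in(converted)
  if (is.numeric(se) && !is.data.frame(se)) {
    stopifnot(length(se) == nrow(obs))
    se <- data.frame(index = obs$index, value = se)
  } else se <- .curve_in(se)
  idx <- sort(union(obs$index, con$index))
  at <- function(df) {
    v <- numeric(length(idx))
    v[match(df$index, idx)] <- df$value
    v
  }
  a <- at(obs); b <- at(con); s <- at(se)
  z <- ifelse(s > 0, (a - b) / s, ifelse(a == b, 0, Inf))
  degenerate <- s == 0 & a != b
  scored <- b >= count_floor
  tab <- data.frame(index = idx, observed = a, converted = b, se = s, z = z)
  list(table = tab,
       max_z = if (any(scored)) max(abs(z[scored])) else NA_real_,
       tv = 0.5 * sum(abs(a - b)),
       n_scored = sum(scored),
       pass = !any(degenerate & scored) &&
         (!any(scored) || all(abs(z[scored]) < z_max)),
       degenerate = any(degenerate))
}
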