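# Unsigned Stirling numbers of the first kind [i, l]:
#   [i+1, l] = i*[i, l] + [i, l-1],  [1, 1] = 1,  [i, l] = 0 for l > i or l = 0.
# They count permutations of i elements with l cycles and, here, govern the
# leaf-depth (division) distribution of the pure-birth lineage tree. The
# magnitudes reach i!, so three representations are kept: exact doubles while
# values stay below 2^53, exact arbitrary-precision integers (for identity
# checks), and log-space tables for everything assembled into expectations.

# ---- minimal non-negative big integers --------------------------------------
# little-endian digit vectors in base 1e9; scalar multipliers must keep
# digit * k below 2^53, i.e. k <= ~9e6 per call.
.big_base <- 1e9

.big <- function(x) {
  stopifnot(x >= 0, x < 2^53)
  v <- numeric(0)
  x <- as.numeric(x)
  repeat {
    v <- c(v, x %% .big_base)
    x <- x %/% .big_base
    if (x == 0) break
  }
  v
}

.big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  .big_carry(a + b)
}

.big_carry <- function(v) {
  repeat {
    q <- floor(v / .big_base)
    if (all(q == 0)) break
    v <- v - q * .big_base
    v <- c(v, 0)
    v[seq_along(q) + 1L] <- v[seq_along(q) + 1L] + q
  }
  while (length(v) > 1 && v[length(v)] == 0) v <- v[-length(v)]
  v
}

.big_smul <- function(a, k) {
  stopifnot(k >= 0, k <= 9e6)
  if (k == 0) return(0)
  .big_carry(a * k)
}

# multiply by 2^l via chunks of 2^20
.big_mul_pow2 <- function(a, l) {
  while (l > 0) {
    k <- min(l, 20L)
    a <- .big_smul(a, 2^k)
    l <- l - k
  }
  a
}

.big_eq <- function(a, b) length(a) == length(b) && all(a == b)

.big_factorial <- function(n) {
  v <- .big(1)
  if (n >= 2) for (k in 2:n) v <- .big_smul(v, k)
  v
}

.big_dec <- function(v) {
  digits <- rev(v)
  paste0(format(digits[1], scientific = FALSE, trim = TRUE),
         paste(sprintf("%09.0f", digits[-1]), collapse = ""))
}

.big_log <- function(v) {
  # natural log; top three digits give ~ 1e-18 relative accuracy
  n <- length(v)
  if (n == 1 && v == 0) return(-Inf)
  top <- v[n]
  if (n >= 2) top <- top + v[n - 1] / .big_base
  if (n >= 3) top <- top + v[n - 2] / .big_base^2
  log(top) + (n - 1) * log(.big_base)
}

# exact Stirling rows as big integers: list over l = 1..i
.stirling_big_row <- function(i) {
  row <- list(.big(1))
  if (i == 1) return(row)
  for (ii in seq_len(i - 1)) {
    new <- vector("list", ii + 1L)
    new[[1L]] <- .big_smul(row[[1L]], ii)
    if (ii > 1) for (l in 2:ii)
      new[[l]] <- .big_add(.big_smul(row[[l]], ii), row[[l - 1L]])
    new[[ii + 1L]] <- row[[ii]]
    row <- new
  }
  row
}

# ---- public interface -------------------------------------------------------

#' Unsigned Stirling numbers of the first kind
#'
#' `stirling1(i, l)` returns the exact value of the unsigned Stirling number
#' of the first kind as a double, erroring once the value exceeds 2^53
#' (where doubles stop being exact integers); use the log-space variants
#' beyond that. `stirling_log_row(i)` returns the vector
#' `log([i, l])` for `l = 1..i`, computed stably by running the defining
#' recurrence in log space; `stirling_log_table(i_max)` returns the full
#' lower-triangular `log` table as an `i_max` x `i_max` matrix (entries with
#' `l > i` are `-Inf`).
#'
#' @param i first index (number of steps / tree size minus one), >= 1.
#' @param l second index (number of divisions), vectorised; values outside
#'   `1..i` give 0 (`-Inf` in log space).
#' @param i_max largest row of the table.
#' @return `stirling1`: double vector of exact values; `stirling_log_row`:
#'   numeric vector of length `i`; `stirling_log_table`: numeric matrix.
#' @examples
#' stirling1(3, 1:3)   # 2, 3, 1
#' exp(stirling_log_row(3))
#' @export
stirling1 <- function(i, l) {
  stopifnot(length(i) == 1L, i >= 1)
  i <- as.integer(i)
  row <- 1
  if (i > 1) for (ii in seq_len(i - 1)) {
    row <- c(ii * row, 0) + c(0, row)
  }
  if (any(row >= 2^53))
    stop("stirling1 exceeds exact double range at i = ", i,
         "; use stirling_log_row")
  out <- numeric(length(l))
  ok <- l >= 1 & l <= i
  out[ok] <- row[l[ok]]
  if (any(l < 0)) stop("l must be non-negative")
  out
}

#' @rdname stirling1
#' @export
stirling_log_row <- function(i) {
  stopifnot(length(i) == 1L, i >= 1)
  r <- 0
  if (i == 1) return(r)
  for (ii in seq_len(i - 1)) {
    new <- numeric(ii + 1L)
    new[1L] <- log(ii) + r[1L]
    if (ii > 1) new[2:ii] <- .logaddexp(log(ii) + r[2:ii], r[1:(ii - 1L)])
    new[ii + 1L] <- r[ii]
    r <- new
  }
  r
}

#' @rdname stirling1
#' @export
stirling_log_table <- function(i_max) {
  stopifnot(i_max >= 1)
  L <- matrix(-Inf, i_max, i_max)
  L[1, 1] <- 0
  r <- 0
  if (i_max > 1) for (ii in seq_len(i_max - 1)) {
    new <- numeric(ii + 1L)
    new[1L] <- log(ii) + r[1L]
    if (ii > 1) new[2:ii] <- .logaddexp(log(ii) + r[2:ii], r[1:(ii - 1L)])
    new[ii + 1L] <- r[ii]
    r <- new
    L[ii + 1L, seq_len(ii + 1L)] <- r
  }
  L
}

.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  out[m == -Inf] <- -Inf
  out
}

.logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}
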