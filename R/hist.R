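#' Integer-indexed histograms
#'
#' The three summary statistics of the process are all histograms over
#' non-negative integers: the site frequency spectrum (SFS, indexed by
#' abundance j >= 1), the division distribution (DD, indexed by the number of
#' divisions l >= 0 in a cell's history) and the single-cell mutational
#' burden distribution (MBD, indexed by burden k >= 0). `int_hist` is their
#' common carrier: a sparse index -> count map with a role tag.
#'
#' @param index integer vector of histogram indices (non-negative; for role
#'   `"sfs"` indices must be >= 1).
#' @param count numeric vector of counts, same length as `index`; must be
#'   non-negative.
#' @param role one of `"sfs"`, `"dd"`, `"mbd"`, or `"generic"`.
#' @return An object of class `int_hist`: a list with elements `index`,
#'   `count` (sorted by index, zero-count entries dropped) and `role`.
#' @examples
#' h <- int_hist(c(0, 1, 2), c(1, 0, 2), role = "dd")
#' hist_total(h)
#' hist_mean(h)
#' @export
int_hist <- function(index, count, role = c("generic", "sfs", "dd", "mbd")) {
  role <- match.arg(role)
  stopifnot(length(index) == length(count), !anyNA(index), !anyNA(count))
  index <- as.integer(index)
  count <- as.numeric(count)
  if (any(index < 0L)) stop("histogram indices must be non-negative")
  if (role == "sfs" && any(index < 1L)) stop("SFS indices start at 1")
  if (any(count < 0)) stop("histogram counts must be non-negative")
  if (anyDuplicated(index)) stop("duplicate histogram indices")
  keep <- count > 0
  index <- index[keep]; count <- count[keep]
  o <- order(index)
  structure(list(index = index[o], count = count[o], role = role),
            class = "int_hist")
}

#' @exportS3Method base::print
print.int_hist <- function(x, ...) {
  cat(sprintf("<int_hist role=%s bins=%d mass=%g mean=%g>\n",
              x$role, length(x$index), hist_total(x),
              if (hist_total(x) > 0) hist_mean(x) else NA_real_))
  if (length(x$index)) print(data.frame(index = x$index, count = x$count))
  invisible(x)
}

#' @export
as.data.frame.int_hist <- function(x, ...) {
  data.frame(index = x$index, count = x$count)
}

#' Total mass and mean of an integer histogram
#'
#' @param h an [int_hist] (or any list with `index` and `count` fields).
#' @return `hist_total`: the sum of counts. `hist_mean`: the count-weighted
#'   mean index (NaN for an empty histogram).
#' @export
hist_total <- function(h) sum(h$count)

#' @rdname hist_total
#' @export
hist_mean <- function(h) sum(h$index * h$count) / sum(h$count)

# tabulate non-negative integer observations into an int_hist
.hist_of <- function(values, role, from = 0L) {
  if (length(values) == 0L) return(int_hist(integer(0), numeric(0), role))
  counts <- tabulate(values + 1L - from, nbins = max(values) + 1L - from)
  int_hist(seq_along(counts) - 1L + from, counts, role)
}

# dense count vector over from:to (zero-filled)
.hist_dense <- function(h, from, to) {
  out <- numeric(to - from + 1L)
  keep <- h$index >= from & h$index <= to
  out[h$index[keep] - from + 1L] <- h$count[keep]
  out
}

#' Read and write histogram TSV files
#'
#' Histograms are exchanged as two-column tab-separated files
#' (`index<TAB>count`) with a leading `# role: <role>` comment line.
#'
#' @param h an [int_hist].
#' @param path file path.
#' @return `write_hist` returns `path` invisibly; `read_hist` returns an
#'   [int_hist].
#' @export
write_hist <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# role: %s", h$role), con)
  writeLines("index\tcount", con)
  if (length(h$index))
    writeLines(paste(h$index, format(h$count, digits = 17, scientific = FALSE,
                                     trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_hist
#' @export
read_hist <- function(path) {
  first <- readLines(path, n = 1L)
  role <- "generic"
  if (grepl("^# role: ", first)) role <- sub("^# role: ", "", first)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  int_hist(df$index, df$count, role = role)
}
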