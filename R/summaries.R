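#' Site frequency spectrum, division distribution and mutational burden
#' distribution
#'
#' The three single-population summary statistics, computable either from a
#' simulation result ([sim_run()]) or from a [genotype_matrix()]:
#'
#' * `sfs(x)`: the site frequency spectrum `{S_j}` - the number of mutations
#'   carried by exactly `j` living cells (j >= 1; mutations lost to death
#'   are excluded). Requires full tracking. `sum(S_j) = M`, the number of
#'   unique mutations in the living population.
#' * `dd(x)`: the division distribution `{D_l}` - the number of living cells
#'   whose lineage has undergone exactly `l` divisions (leaf depth in the
#'   lineage tree). `sum(D_l) = N`.
#' * `mbd(x)`: the single-cell mutational burden distribution `{B_k}` - the
#'   number of living cells carrying exactly `k` mutations. `sum(B_k) = N`.
#'
#' @param x a `bd_sim` or `genotype_matrix` object.
#' @param ... unused.
#' @return An [int_hist] with the matching role tag.
#' @seealso [mutational_occurrences()] for the identity linking SFS and MBD.
#' @export
sfs <- function(x, ...) UseMethod("sfs")

#' @rdname sfs
#' @export
dd <- function(x, ...) UseMethod("dd")

#' @rdname sfs
#' @export
mbd <- function(x, ...) UseMethod("mbd")

#' @export
sfs.bd_sim <- function(x, ...) {
  if (is.null(x$abundance))
    stop("the SFS requires full tracking (mutation-id sets); ",
         "rerun with track = \"full\"")
  ab <- x$abundance[x$abundance > 0L]
  .hist_of(ab, "sfs", from = 1L)
}

#' @export
dd.bd_sim <- function(x, ...) .hist_of(x$divisions, "dd")

#' @export
mbd.bd_sim <- function(x, ...) .hist_of(x$burden, "mbd")

#' Mutational occurrences
#'
#' The total number of 1-entries of the genotype matrix: every (cell,
#' mutation) incidence counted once. By construction it equals both
#' `sum_j j * S_j` (summing the SFS) and `sum_k k * B_k` (summing the MBD);
#' the function computes both sides and raises an error if they disagree,
#' since that would indicate corrupted state. Dividing by the number of
#' unique mutations `M` gives the SFS mean; dividing by the population size
#' `N` gives the MBD mean (the mean single-cell burden).
#'
#' @param x a `bd_sim` (full tracking) or `genotype_matrix` object.
#' @return The number of occurrences, as a double.
#' @export
mutational_occurrences <- function(x) {
  s <- sfs(x)
  b <- mbd(x)
  lhs <- sum(as.numeric(s$index) * s$count)
  rhs <- sum(as.numeric(b$index) * b$count)
  if (lhs != rhs)
    stop(sprintf(
      "internal consistency failure: sum_j j*S_j = %g but sum_k k*B_k = %g",
      lhs, rhs))
  lhs
}

#' Dynamical genotype matrix of a realisation
#'
#' Builds the binary cell-by-mutation incidence matrix of the living
#' population: entry (n, m) is 1 if cell n carries mutation m. Columns are
#' grouped into division blocks: the set of mutations one daughter acquired
#' in one division. A division that contributed no mutations to a daughter
#' still owns a placeholder all-zero column, so the block structure records
#' every division along every lineage. Columns whose incidence has become
#' all-zero through cell death are retained (they record history) but do not
#' contribute to the SFS.
#'
#' @param sim a `bd_sim` run with `track = "full"`.
#' @return An object of class `genotype_matrix`: a list with
#'   * `incidence`: sparse cells x columns 0/1 matrix;
#'   * `block_membership`: sparse cells x blocks 0/1 matrix (cell n is a
#'     member of block b if b lies on n's lineage); row sums are the
#'     per-cell division counts;
#'   * `columns`: data frame mapping column -> (mutation_id, block_id), with
#'     `mutation_id = NA` for placeholder columns.
#' @export
genotype_matrix <- function(sim) {
  stopifnot(inherits(sim, "bd_sim"))
  if (is.null(sim$mutations))
    stop("genotype matrices require full tracking; rerun with track = \"full\"")
  n <- sim$n
  nb <- length(sim$blocks)
  sizes <- lengths(sim$blocks)
  ncols_per_block <- pmax(sizes, 1L)
  col_block <- rep.int(seq_len(nb), ncols_per_block)
  col_mut <- unlist(lapply(sim$blocks,
                           function(b) if (length(b)) b else NA_integer_),
                    use.names = FALSE)
  col_mut <- as.integer(col_mut %||% integer(0))
  ncol_total <- length(col_mut)
  col_of_mut <- integer(sim$n_mut_total)
  real <- !is.na(col_mut)
  col_of_mut[col_mut[real]] <- which(real)

  cell_ids <- unlist(sim$mutations, use.names = FALSE)
  ii <- rep.int(seq_len(n), lengths(sim$mutations))
  jj <- if (length(cell_ids)) col_of_mut[cell_ids] else integer(0)
  incidence <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                    dims = c(n, max(ncol_total, 0L)))
  bi <- rep.int(seq_len(n), lengths(sim$cell_blocks))
  bj <- unlist(sim$cell_blocks, use.names = FALSE) %||% integer(0)
  block_membership <- Matrix::sparseMatrix(i = bi, j = bj, x = 1,
                                           dims = c(n, nb))
  structure(list(incidence = incidence,
                 block_membership = block_membership,
                 columns = data.frame(column = seq_len(ncol_total),
                                      mutation_id = col_mut,
                                      block_id = col_block)),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix %d cells x %d columns (%d blocks, %d placeholder columns)>\n",
    nrow(x$incidence), ncol(x$incidence), ncol(x$block_membership),
    sum(is.na(x$columns$mutation_id))))
  invisible(x)
}

#' @export
sfs.genotype_matrix <- function(x, ...) {
  ab <- Matrix::colSums(x$incidence)
  ab <- ab[!is.na(x$columns$mutation_id)]
  ab <- as.integer(ab[ab > 0])
  .hist_of(ab, "sfs", from = 1L)
}

#' @export
dd.genotype_matrix <- function(x, ...) {
  .hist_of(as.integer(Matrix::rowSums(x$block_membership)), "dd")
}

#' @export
mbd.genotype_matrix <- function(x, ...) {
  .hist_of(as.integer(Matrix::rowSums(x$incidence)), "mbd")
}

#' Export and re-import a genotype matrix
#'
#' Writes the incidence and block-membership matrices in MatrixMarket
#' coordinate format plus a tab-separated column annotation table
#' (`column`, `mutation_id`, `block_id`). `read_genotype_matrix` reverses
#' the operation; the round trip reproduces all three histograms exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix; files `<prefix>_incidence.mtx`,
#'   `<prefix>_blocks.mtx` and `<prefix>_columns.tsv` are written.
#' @return `export_genotype_matrix` returns `prefix` invisibly;
#'   `read_genotype_matrix` returns a `genotype_matrix`.
#' @export
export_genotype_matrix <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  Matrix::writeMM(methods::as(gm$incidence, "CsparseMatrix"),
                  paste0(prefix, "_incidence.mtx"))
  Matrix::writeMM(methods::as(gm$block_membership, "CsparseMatrix"),
                  paste0(prefix, "_blocks.mtx"))
  write.table(gm$columns, paste0(prefix, "_columns.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname export_genotype_matrix
#' @export
read_genotype_matrix <- function(prefix) {
  incidence <- methods::as(Matrix::readMM(paste0(prefix, "_incidence.mtx")),
                           "CsparseMatrix")
  blocks <- methods::as(Matrix::readMM(paste0(prefix, "_blocks.mtx")),
                        "CsparseMatrix")
  columns <- read.table(paste0(prefix, "_columns.tsv"),
                        sep = "\t", header = TRUE)
  structure(list(incidence = incidence, block_membership = blocks,
                 columns = columns),
            class = "genotype_matrix")
}
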