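#' Mutation-count models
#'
#' Number of new mutations acquired by one daughter cell in one division.
#' The canonical choice is Poisson with mean `mu` (point mutations during
#' genome duplication occur at constant rate, independently, so their count
#' per division is Poisson). Alternatives with the same mean are provided to
#' probe the claim that only the mean of the mutational distribution shapes
#' the expected burden distribution:
#'
#' * `"poisson"`: `Pois(mean)`.
#' * `"fixed"`: degenerate at `mean` (must be a non-negative integer).
#' * `"geometric"`: geometric on 0, 1, 2, ... with the given mean
#'   (success probability `1 / (1 + mean)`).
#' * `"table"`: arbitrary finite distribution given by `values`/`probs`;
#'   its mean is computed from the table.
#'
#' @param type distribution family, see above.
#' @param mean mean number of mutations per daughter per division (>= 0).
#'   Ignored (computed) for `"table"`.
#' @param values,probs support and probabilities for `type = "table"`.
#' @return An object of class `mutation_model` with fields `type` and `mean`.
#' @examples
#' m <- mutation_model("poisson", mean = 2)
#' draw_mutations(m, 5)
#' @export
mutation_model <- function(type = c("poisson", "fixed", "geometric", "table"),
                           mean = 0, values = NULL, probs = NULL) {
  type <- match.arg(type)
  if (type == "table") {
    stopifnot(!is.null(values), !is.null(probs),
              length(values) == length(probs))
    values <- as.integer(values)
    if (any(values < 0L)) stop("table values must be non-negative integers")
    if (any(probs < 0) || sum(probs) <= 0) stop("invalid table probabilities")
    probs <- probs / sum(probs)
    mean <- sum(values * probs)
  } else {
    if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean < 0)
      stop("mutation model mean must be a single non-negative number")
    if (type == "fixed" && mean != round(mean))
      stop("a fixed mutation count must be a non-negative integer")
  }
  structure(list(type = type, mean = as.numeric(mean),
                 values = values, probs = probs),
            class = "mutation_model")
}

#' @exportS3Method base::print
print.mutation_model <- function(x, ...) {
  cat(sprintf("<mutation_model %s mean=%g>\n", x$type, x$mean))
  invisible(x)
}

#' Draw mutation counts
#'
#' @param model a [mutation_model].
#' @param n number of independent draws.
#' @return integer vector of `n` non-negative draws.
#' @rdname mutation_model
#' @export
draw_mutations <- function(model, n = 1L) {
  switch(model$type,
    poisson   = rpois(n, model$mean),
    fixed     = rep.int(as.integer(model$mean), n),
    geometric = rgeom(n, 1 / (1 + model$mean)),
    table     = sample(model$values, n, replace = TRUE, prob = model$probs),
    stop("unknown mutation model type: ", model$type)
  )
}
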