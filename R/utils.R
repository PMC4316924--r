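#' @importFrom stats approx cor dist fisher.test hclust kmeans p.adjust
#'   pchisq pt quantile rbeta rbinom rgamma rnorm runif sd setNames var
#' @importFrom utils combn head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a reproducible state, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so seeded generators are pure functions of
#' their inputs and never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed and a label
#'
#' Deterministic, label-sensitive seed derivation so that every stochastic
#' stage of a pipeline run is fully determined by one master seed. Uses a
#' small polynomial string hash; results stay below 2^31.
#'
#' @param master Integer master seed.
#' @param ... Character labels identifying the stage (and, e.g., grid cell).
#' @return A single integer seed.
#' @export
#' @examples
#' stage_seed(1, "enrich", "IBD")
stage_seed <- function(master, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
}
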