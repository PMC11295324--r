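#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores whatever stream was active before.  Every generator in the
#' package routes its randomness through this helper so that identical
#' seeds give bitwise-identical artifacts without disturbing the caller's
#' RNG state.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# scalar-check helpers used across the package
.check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  x
}

.check_image <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 1) {
    stop(sprintf("`%s` intensities must lie in [0, 1] with no NA", name),
         call. = FALSE)
  }
  image
}

#' Validate a probability vector
#'
#' Checks that `p` is a finite nonnegative vector summing to 1 (within
#' `tol`), the simplex contract assumed by every Bhattacharyya routine.
#'
#' @param p numeric vector.
#' @param tol tolerance on `|sum(p) - 1|`.
#' @param name label used in error messages.
#' @return `p`, invisibly validated.
#' @export
check_prob_vector <- function(p, tol = 1e-6, name = "p") {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(!is.finite(p))) {
    stop(sprintf("`%s` must be a finite numeric vector", name), call. = FALSE)
  }
  if (min(p) < -1e-12) {
    stop(sprintf("`%s` has negative entries", name), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.12g)", name, sum(p)), call. = FALSE)
  }
  invisible(p)
}
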