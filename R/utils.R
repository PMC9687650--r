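#' @keywords internal
"_PACKAGE"

## Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("distecg_invalid_argument", "error")))
}

## clamp scores into the open unit interval used by all log-losses
clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))
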