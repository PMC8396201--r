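#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix crossprod colSums rowSums
#' @importFrom methods as is
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed_eval <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < .Machine$double.eps^0.5

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
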