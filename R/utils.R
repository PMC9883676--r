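# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' that seeded package functions do not disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG state untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
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
  force(code)
}

# Deterministic stream of 31-bit sub-seeds derived from one master seed, so
# that every simulated object can record the seed it was produced from.
split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + 113 * as.numeric(i)) %%
               2147483629)
}

# Canonical key of an equivalence class: members sorted ascending, comma-joined.
ec_key <- function(members) paste(sort(as.character(members)), collapse = ",")

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
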