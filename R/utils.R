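# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations. seed = NULL leaves the current stream untouched.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_proportion <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

is_positive_scalar <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0
}

# Validate a survival record table (columns time/event, optional sample).
validate_surv <- function(records) {
  if (is.null(dim(records))) stopf("survival records must be a data frame")
  records <- as.data.frame(records)
  if (!all(c("time", "event") %in% names(records))) {
    stopf("survival records need columns 'time' and 'event'")
  }
  if (nrow(records) < 1L) stopf("at least one survival record is required")
  if (any(!is.finite(records$time)) || any(records$time < 0)) {
    stopf("survival times must be finite and nonnegative")
  }
  if (!all(records$event %in% c(0, 1))) stopf("event indicator must be 0/1")
  records
}
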