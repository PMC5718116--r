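# Typed error conditions so callers and tests can distinguish failure modes.

abort_typed <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hccradiomics_error"), call = call))
}

geometry_error  <- function(msg) abort_typed("geometry_error", msg)
empty_roi_error <- function(msg) abort_typed("empty_roi_error", msg)
data_error      <- function(msg) abort_typed("data_error", msg)
parameter_error <- function(msg) abort_typed("parameter_error", msg)
class_error     <- function(msg) abort_typed("class_error", msg)
no_events_error <- function(msg) abort_typed("no_events_error", msg)
degenerate_error <- function(msg) abort_typed("degenerate_error", msg)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
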