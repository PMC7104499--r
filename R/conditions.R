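# Classed error conditions; the CLI maps these onto exit codes
# (usage -> 1, data validation -> 2, numeric failure -> 3).

gtx_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gtx_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_usage <- function(msg) gtx_abort(msg, "gtx_usage_error")
abort_data <- function(msg) gtx_abort(msg, "gtx_data_error")
abort_numeric <- function(msg) gtx_abort(msg, "gtx_numeric_error")

#' @keywords internal
gtx_log <- function(...) {
  if (isTRUE(getOption("gtxpanel.verbose", FALSE))) {
    message("[INFO] ", sprintf(...))
  }
  invisible(NULL)
}

# Run `expr` under a fixed RNG state, restoring the caller's state after.
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
    })
    set.seed(as.integer(seed))
  }
  expr
}
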