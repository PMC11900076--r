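# Internal helpers shared across modules.

#' @importFrom withr with_seed
run_seeded <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# stop() with a consistent header naming the offending field/value
abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic order: primary key descending, gene id ascending as tie-break
order_desc_then_id <- function(score, ids) {
  order(-score, ids, method = "radix")
}
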