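# internal helpers shared across modules

#' @importFrom data.table data.table := setkeyv as.data.table rbindlist setorderv
#' @importFrom stats rbinom runif rbeta rnorm plogis qlogis setNames
#' @importFrom utils read.table write.table
NULL

# gated logger: quiet by default so pipelines/tests stay clean
pa_log <- function(fmt, ...) {
  if (isTRUE(getOption("popaf.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

# round half away from zero (printed percentages follow this convention;
# base round() is banker's rounding)
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

is_dna <- function(x) {
  grepl("^[ACGTN]+$", x)
}

# run code with a temporary RNG state so generators are deterministic
# under their own seed without clobbering the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
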