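# Internal helpers shared across modules.

#' Recognized experimental group labels
#'
#' Canonical group labels of the four-group design: untreated controls,
#' the challenge agent alone, challenge plus drug, and drug alone.
#'
#' @return Character vector of the four canonical labels, in design order.
#' @export
groupLevels <- function() c("control", "challenge", "treated", "drug_alone")

# Signal a validation error (bad user input / malformed file) so callers --
# in particular the command-line wrapper -- can distinguish it from runtime
# failure. The condition carries class "metaboValidationError".
validationError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("metaboValidationError", "validationError")))
}

isValidationError <- function(e) inherits(e, "metaboValidationError")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sample standard deviation (n - 1 denominator) per column, NA-tolerant.
colSds <- function(x) {
  apply(x, 2L, stats::sd, na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic, locale-independent ordering helper (C collation).
radixOrder <- function(...) order(..., method = "radix")
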