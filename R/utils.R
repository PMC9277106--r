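# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Gas constant in kcal/(mol K); kT = 0.59616 kcal/mol at 300 K.
.R_KCAL <- 0.0019872041

# Structured errors: every named failure mode raises a condition of class
# c(paste0("ededock_", class), "ededock_error", "error").
abort_eded <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("ededock_", class), "ededock_error"),
                      call = call))
}

# log(sum(exp(x))) with max-shift; -Inf terms drop out cleanly.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML with enough significant digits that doubles survive a round trip
write_yaml_full <- function(x, path) yaml::write_yaml(x, path, precision = 15L)
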