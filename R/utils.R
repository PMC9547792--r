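# Internal helpers shared across modules.

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "nichevar_error_schema", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "nichevar_error_validation", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "nichevar_error_data", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "nichevar_error_config", ...)
}

# Deterministic child-seed derivation: a counter-based integer mix so that
# per-(stage, lake) streams are stable under lake insertion order. All
# arithmetic in doubles (exact below 2^53), folded into [1, 2^31 - 2].
derive_seed <- function(master, stage, index = 0L) {
  stages <- c("simulate", "metrics", "isotope", "ordinate", "regress", "report")
  stage_i <- match(stage, stages)
  if (is.na(stage_i)) abort_config(paste0("unknown pipeline stage: ", stage))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + stage_i * 69621 + as.numeric(index) * 40692) %% m
  as.integer(x %% (m - 1) + 1)
}

# Entropy of a proportion vector in a given log base, with 0 * log(0) == 0.
shannon_entropy <- function(p, base = exp(1)) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
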