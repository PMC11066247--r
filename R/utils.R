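# Internal helpers shared across modules.

stop_afpheno <- function(message, class, ...) {
  abort(message, class = c(paste0("afpheno_", class), "afpheno_error"), ...)
}

# Evaluate `expr` with a local RNG seeded at `seed`, leaving .Random.seed alone.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Stage seeds are fanned out from one global seed so each pipeline stage is
# independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage_index) {
  (as.integer(seed) * 101L + as.integer(stage_index) * 7919L) %% 2147483399L + 1L
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

# The two pixel classes, fixed order everywhere (factor levels, priors,
# confusion tables).
pixel_classes <- function() c("non_stressed", "stressed")

as_class_factor <- function(x) factor(as.character(x), levels = pixel_classes())
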