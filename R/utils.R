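# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# FNV-1a 32-bit hash of an R object's deparsed form; used to stamp report
# headers so a run's configuration is auditable.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h as a double so the
    # 32-bit state never hits R's signed-integer limit
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# Deterministic spawn of sub-seeds from one master seed; keeps derived
# seeds inside the 32-bit integer range.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
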