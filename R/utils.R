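# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical key for an unordered node pair.  The unit separator  cannot
# occur in sane node labels, so keys never collide across label boundaries.
edge_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  ifelse(a < b, paste(a, b, sep = ""), paste(b, a, sep = ""))
}

key_to_pair <- function(keys) {
  parts <- strsplit(keys, "", fixed = TRUE)
  data.frame(
    from = vapply(parts, `[[`, character(1), 1L),
    to   = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Deterministic sub-seed derivation: one master seed per run, every stochastic
# sub-task hashed from (master, string keys).  Adding a variant or repeat does
# not perturb the streams of the others.  Result always fits a 32-bit integer.
derive_seed <- function(master, ...) {
  key <- paste(c(...), collapse = "|")
  h <- as.double(as.integer(master) %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483587) + 1L
}

new_edge_env <- function(from, to) {
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(29L, 2L * length(from)))
  if (length(from)) {
    keys <- edge_key(from, to)
    for (i in seq_along(keys)) assign(keys[i], i, envir = env)
  }
  env
}

env_has <- function(env, key) {
  exists(key, envir = env, inherits = FALSE)
}

stop_arg <- function(...) stop(..., call. = FALSE)
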