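# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed and a key
#'
#' Stage- and unit-level seeds are derived from one top-level seed by hashing
#' the seed together with a descriptive key (for example
#' `("physio", participant, day)`), so that every simulated unit is
#' reproducible in isolation and stages do not share RNG streams.
#'
#' @param seed Integer base seed.
#' @param ... Key components (coerced to character).
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = "/"),
                  character(1))
  key <- paste(c(as.character(as.integer(seed)), parts), collapse = "::")
  # FNV-1a, 32-bit, with an overflow-safe modular multiply
  h <- 2166136261
  for (ch in utf8ToInt(key)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(ch %% 256))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483646 + 1)
}

# stop with a configuration error naming the offending field
stop_config <- function(field, msg) {
  stop(structure(
    class = c("stressweek_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = NULL)
  ))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a probability in [0, 1]")
  x
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop_config(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    stop_config(field, "must be a positive number")
  x
}
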