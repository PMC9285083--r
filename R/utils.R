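# Internal helpers shared across modules.

# Round half away from zero at .5 (record boundaries use this, not banker's
# rounding).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic 31-bit seed for a named substream. Streams are labelled by
# arbitrary key pieces (e.g. "weather", county, year) so that adding pixels
# does not perturb weather draws.
substream_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(parts)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_primecrop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "primecrop_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
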