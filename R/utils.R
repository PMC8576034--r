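# Internal helpers shared across modules.

# Locale-independent lexicographic order (C locale, byte-wise).
chr_order <- function(x) order(x, method = "radix")

chr_sort <- function(x) sort(x, method = "radix")

# Derive a per-stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(master, stage) {
  offsets <- c(simulate = 11L, lof = 23L, reads = 37L, phase = 53L,
               select = 71L, pipeline = 97L)
  off <- offsets[[stage]]
  as.integer((as.numeric(master) * 131L + off * 10007L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
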