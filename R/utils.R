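`%||%` <- function(x, y) if (is.null(x)) y else x

# Signal a classed error so callers can distinguish failure modes
# (e.g. "insufficient_data" vs "integrity_error") with tryCatch.
yt_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "yieldtrends_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

yt_warn <- function(msg) warning(msg, call. = FALSE)

# Composite series key used throughout for one (department, crop, season)
# annual series.
series_key <- function(department_id, crop, season_type) {
  paste(department_id, crop, season_type, sep = "|")
}

record_key <- function(df) {
  paste(df$department_id, df$crop, df$season_type, df$year, sep = "|")
}

# 32-bit FNV-1a over a character scalar; used to fingerprint run
# configurations in output manifests without external dependencies.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    # xor the byte into the low 8 bits (kept in doubles: h can exceed 2^31)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so every intermediate stays exactly representable in a double
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic integer sub-seed derived from a master seed and a label,
# kept below 2^31 so it is always a valid R seed.
derive_seed <- function(seed, label) {
  h <- strtoi(substr(fnv1a32(paste(seed, label)), 1, 7), base = 16L)
  h %% 2147483647L
}
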