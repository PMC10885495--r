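## Session cache for the constant configuration objects (schema,
## vocabularies, default rubric): building them involves many small
## data.frame allocations and they are pure functions of the source.
.pivas_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .pivas_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .pivas_cache)
  }
  get(key, envir = .pivas_cache, inherits = FALSE)
}

## Run `expr` under a temporary RNG state seeded with `seed` (NULL = use
## the current stream), restoring the caller's state afterwards.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Atomic writers: write to a sibling temp file, then rename into place.
write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE, na = "")
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits; used to
## stamp outputs with a config fingerprint without heavy dependencies.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    ## 32-bit modular multiply by the FNV prime 16777619 = 403 + 2^24,
    ## split so intermediate products stay exactly representable
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
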