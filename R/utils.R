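# run code under a fixed seed without disturbing the caller's RNG stream
with_seed_preserved <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

# small deterministic rolling hash of a character vector (config provenance)
config_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# derive module-level seeds from one master seed (kept < 2^31)
derive_seed <- function(master, offset) {
  (as.numeric(master) * 10007 + offset) %% 2147483647
}
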