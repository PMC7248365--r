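# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps generators deterministic without
# clobbering the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive reproducible child seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

db_to_amp <- function(db) 10^(db / 20)

# 10*log10(num/den) with a documented cap for vanishing denominators.
ratio_db <- function(num, den, cap_db = 200) {
  if (num <= 0) return(-cap_db)
  if (den <= 0) return(cap_db)
  min(max(10 * log10(num / den), -cap_db), cap_db)
}
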