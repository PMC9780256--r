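# Internal helpers: seeded substreams and misc.

# Deterministic 31-bit hash of a seed plus string components. Used to derive
# per-record random choices (e.g. which equivalent indel placement is kept)
# so that results do not depend on record order.
mix_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "\x1f")
  h <- 2166136261 %% 2147483647
  for (v in utf8ToInt(parts)) {
    h <- bitwXor(h, v)
    # FNV-style multiply, kept in double precision below 2^53 then reduced
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
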