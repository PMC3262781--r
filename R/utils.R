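# Run code with a private RNG stream: seeds explicitly, restores any
# pre-existing .Random.seed afterwards so fixtures never disturb user RNG state.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  force(code)
}

# numeric formatting used by NDF rendering: full-precision, locale-free
fmt_num <- function(x) sprintf("%.17g", x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
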