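# run expr with a local RNG state seeded at `seed`; global stream untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# format a p-value threshold at display precision (3 significant figures)
format_threshold <- function(x) signif(x, 3)

`%||%` <- function(a, b) if (is.null(a)) b else a
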