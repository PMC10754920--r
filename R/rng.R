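# Named random substreams.
#
# Every stochastic component draws from its own named substream so that
# adding one signal channel never perturbs another channel's samples. A
# substream is keyed by the master seed plus a path of string/integer
# labels, folded into a 31-bit seed with an FNV-1a style hash.

substream_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  # multiplier kept small so h * 65599 stays below 2^53 and the modular
  # arithmetic remains exact in doubles
  h <- as.numeric(master) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 65599 + code) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(master, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, ...))
  expr
}
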