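# internal helpers

# smooth positivity link: s * log(1 + exp(x / s)); ~identity for x >> s
softplus <- function(x, s = 0.05) {
  z <- x / s
  out <- ifelse(z > 30, x, s * log1p(exp(z)))
  out
}

# derive a sub-stream seed < 2^31 from a base seed and labels
derive_seed <- function(seed, ...) {
  labs <- paste(c(seed, ...), collapse = "/")
  # simple deterministic string hash (djb2), folded into [0, 2^31 - 1]
  h <- 5381
  for (ch in utf8ToInt(labs)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
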