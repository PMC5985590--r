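# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs on the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# derived-allele frequency per column of a 0/1 haplotype matrix
hap_freq <- function(alleles) colMeans(alleles)
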