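# shared helpers for the test suite

# seeded uniform DNA string
rand_dna <- function(n, seed = NULL) {
  f <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# substitute k positions of a sequence with a different base (seeded)
substitute_bases <- function(seq, k, seed) {
  withr::with_seed(seed, {
    ch <- strsplit(seq, "")[[1]]
    at <- sample(seq_along(ch), k)
    for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  })
}

# the default seeded dataset, generated once per test run
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_dataset(seed = 42)
    cache
  }
})
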