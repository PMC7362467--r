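## Run expr with a private RNG state seeded by `seed`, restoring the
## caller's stream afterwards. Keeps package functions reproducible from
## their own seed arguments without disturbing user code.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Stratified fold assignment: within each class, samples are dealt round-
## robin into k folds in a seeded random order.
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  withLocalSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}
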