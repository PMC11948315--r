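# shared fixtures, all generated in code

# scripted table in which every activation's loss worsens every epoch;
# activation k is always ranked k-th (offset by 0.1 * k)
uniformWorseTable <- function(nAF = 6L, epochs = 40L) {
  nm <- LETTERS[seq_len(nAF)]
  stats::setNames(lapply(seq_len(nAF), function(k) 1 + 0.1 * k + 0.05 * seq_len(epochs)), nm)
}

# nearest-prototype classifier accuracy on a blob dataset
nearestPrototypeAccuracy <- function(ds) {
  n <- dim(ds$images)[1]
  K <- dim(ds$prototypes)[1]
  pred <- vapply(seq_len(n), function(i) {
    d <- vapply(seq_len(K), function(k)
      sum((ds$images[i, , , ] - ds$prototypes[k, , , ])^2), numeric(1))
    which.min(d)
  }, integer(1))
  mean(pred == ds$labels)
}

# afcsConfig without the below-nominal-patience warning noise in tests
quietConfig <- function(...) suppressWarnings(afcsConfig(...))

# random scripted table: noisy decreasing-then-rising losses, seeded
randomScriptedTable <- function(seed, nAF = 4L, epochs = 60L) {
  withr::with_seed(seed, {
    nm <- LETTERS[seq_len(nAF)]
    stats::setNames(lapply(seq_len(nAF), function(k) {
      base <- 1.5 * exp(-0.15 * seq_len(epochs)) + 0.2 + 0.02 * k
      pmax(0.01, base + stats::rnorm(epochs, sd = 0.05))
    }), nm)
  })
}
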