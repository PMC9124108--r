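# Fixtures built in code; every generator is seeded so tests are
# deterministic.

# Dataset in which gene `sep_gene` separates the classes perfectly and the
# rest is standard normal noise.
separable_dataset <- function(n = 30, d = 20, sep_gene = 7, seed = 5) {
  anfisFS:::with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * d), n, d)
    x[, sep_gene] <- labels * 6 + rnorm(n, sd = 0.2)
    expression_set(x, labels)
  })
}

# Two well-separated Gaussian blobs in two dimensions, labelled 0/1.
blob_dataset <- function(n = 80, gap = 4, seed = 9) {
  anfisFS:::with_seed(seed, {
    labels <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(rnorm(n * 2), n, 2)
    x[labels == 1L, ] <- x[labels == 1L, ] + gap
    list(x = x, y = labels)
  })
}

# Tiny control for pipeline tests: exercises every stage at minimal cost.
tiny_control <- function(...) {
  anfis_fs_control(pack_size = 6, fs_iters = 5, abhc_inner = 5,
                   coa_pop = 6, coa_iters = 5, n_rules = 2, ...)
}

# A 1-input, 2-rule model whose forward pass is traced by hand in tests.
two_rule_model <- function() {
  anfis_model(centers = matrix(c(0, 2), 2, 1),
              widths = matrix(1, 2, 1),
              shapes = matrix(1, 2, 1),
              coefs = matrix(c(1, 1), 2, 1),
              bias = c(0, 1))
}

# Confusion matrices published for the four benchmark datasets (counts
# n00, n01, n10, n11).
benchmark_cms <- function() {
  list(leukemia = confusion2x2(8, 0, 2, 2),
       prostate = confusion2x2(16, 0, 6, 9),
       stanford = confusion2x2(2, 4, 0, 9),
       colon = confusion2x2(12, 1, 1, 5))
}
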