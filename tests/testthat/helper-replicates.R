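# Run a seeded fit over noisy replicates and collect estimates and standard
# errors for bias / coverage checks.
replicate_fits <- function(n_rep, base_seed, gen_fn, fit_fn, extract) {
  out <- lapply(seq_len(n_rep), function(i) {
    data <- gen_fn(base_seed + i)
    fit <- tryCatch(fit_fn(data), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    extract(fit)
  })
  ok <- !vapply(out, is.null, logical(1))
  do.call(rbind, out[ok])
}

# Fraction of replicates whose +-2 sigma interval covers the truth.
coverage2 <- function(est, se, truth) {
  mean(abs(est - truth) <= 2 * se)
}

expect_sigfig <- function(actual, expected, digits) {
  expect_equal(actual, expected,
               tolerance = 10^(-(digits - 1)) / 2)
}
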