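# shared fixtures, built once per test run
vor_p <- vor_calibrated_profile()
constrained_p <- constrained_profile()

# reference DoG used in small examples: 10 ms dip, 100 ms lobes
toy_dog <- make_dog_profile(-1, 0.010, 0.100)

# brute-force oracle: unwindowed double sum over all spike pairs
brute_force_dw <- function(v, c, profile, beta = 1) {
  if (length(v$times) == 0 || length(c$times) == 0) return(0)
  beta * sum(eval_profile(profile, outer(v$times, c$times, "-")))
}

random_train <- function(n, duration, seed) {
  with_seed_test(seed, spike_train(sort(stats::runif(n, 0, duration)), duration))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
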