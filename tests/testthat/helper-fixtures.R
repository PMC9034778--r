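# Shared fixtures: small, fast configurations used across test files.

# a reference parameter set used by many density tests
fix_params <- function() lba_params(v = c(2, 1), A = 0.5, k = 0.5, t0 = 0.15)

# a reduced sampler for tests that only need a working posterior, not
# the full-budget run (the full 1000/2000 budget is exercised in the
# acceptance suite)
fast_sampler <- function(seed = 1) {
  sampler_config(warmup = 400, iterations = 900, chains = 3, seed = seed)
}

# small cohort: 3 subjects keeps microstructure/photometry tests quick
small_cohort_config <- function(seed = 7, ...) {
  args <- list(...)
  if (is.null(args$n_subjects)) args$n_subjects <- 3
  if (is.null(args$n_trials)) args$n_trials <- 8
  args$seed <- seed
  do.call(cohort_config, args)
}

# deterministic sawtooth trace: runs and pauses with known structure,
# in track coordinates; returns trace plus the intended pause frames
make_sawtooth_trace <- function(fps = 30) {
  dt <- 1 / fps
  x <- c(seq(-5, 40, by = 0.7),          # run in
         rep(40, 6),                     # pause (6 frames, 200 ms)
         seq(40.7, 60, by = 0.7),        # approach
         rep(60, 10),                    # pause
         seq(59.3, 20, by = -0.7))       # avoid
  tracking_trace(seq_along(x) * dt, x)
}

# draw from a normal truncated below at 0 (rejection; fine for the
# means/SDs used here)
truncnorm_draw <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x > 0) { out[i] <- x; break }
    }
  }
  out
}
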