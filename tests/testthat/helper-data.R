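with_seed_for_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# Training problem where the only class-separating information is
# axis-specific (orientation wobble at constant vector magnitude), so a
# model that ignores axis identity cannot be fooled by test-time rotation
# while one trained without augmentation leans on the device frame.
orientation_windows <- function(n_walk, n_nonwalk, seed) {
  with_seed_for_test(seed, {
    t <- seq(0, 9.99, by = 0.01)
    wins <- c(
      lapply(seq_len(n_walk), function(i) {
        th <- 0.4 * sin(2 * pi * 1.5 * t + runif(1, 0, 2 * pi))
        cbind(sin(th) / sqrt(2), sin(th) / sqrt(2), cos(th)) +
          matrix(rnorm(3000, sd = 0.01), ncol = 3)
      }),
      lapply(seq_len(n_nonwalk), function(i)
        cbind(rnorm(1000, sd = 0.01), rnorm(1000, sd = 0.01),
              1 + rnorm(1000, sd = 0.01)))
    )
    list(windows = wins,
         labels = c(rep("walk", n_walk), rep("nonwalk", n_nonwalk)))
  })
}

shared_training_set <- function() {
  list(train = orientation_windows(24, 72, 101),
       val = orientation_windows(8, 24, 102))
}
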