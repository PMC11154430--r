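# shared fixtures, all generated in code

# exact damped-sinusoid sum: the analytic signal the DMD layer must invert
damped_sum <- function(alpha, freq, s0, n_frames = 100, dt = 0.02) {
  n <- 0:(n_frames - 1)
  s <- numeric(n_frames)
  for (k in seq_along(alpha)) {
    s <- s + 2 * Re(s0[k] * exp((alpha[k] + 2i * pi * freq[k]) * n * dt))
  }
  s
}

# three well-separated pairs inside the ranges used by the spectral
# recovery checks (alpha in [-6, -1] 1/s, f in [0.5, 8] Hz)
three_pair_params <- function() {
  list(alpha = c(-5.2, -2.7, -1.3),
       freq = c(0.8, 3.1, 7.4),
       s0 = complex(real = c(1.2, -0.7, 0.35),
                    imaginary = c(-0.5, 0.45, 0.2)))
}

# naive triple-loop reference for the identification cost: explicit sums
# over modes, probe steps and components, nothing vectorized
naive_cost <- function(probe_steps, baseline, standardized = FALSE) {
  cycles <- unique(probe_steps$cycle)
  total <- 0
  for (k in baseline$mode_rank) {
    brow <- baseline[baseline$mode_rank == k, ]
    cent <- c(brow$centroid_alpha, brow$centroid_freq, brow$centroid_s0)
    spread <- c(brow$spread_alpha, brow$spread_freq, brow$spread_s0)
    if (standardized) spread <- spread^2
    acc <- 0
    for (cc in cycles) {
      frow <- probe_steps[probe_steps$cycle == cc &
                            probe_steps$mode_rank == k, ]
      dev <- c(frow$alpha, frow$freq, frow$s0) - cent
      for (j in 1:3) acc <- acc + spread[j] * dev[j]^2
    }
    total <- total + acc / length(cycles)
  }
  total
}

# stack frame blocks along the time dimension
abind_frames <- function(blocks) {
  d <- dim(blocks[[1]])
  out <- array(0, c(sum(vapply(blocks, function(b) dim(b)[1], numeric(1))),
                    d[2], d[3]))
  at <- 0
  for (b in blocks) {
    out[at + seq_len(dim(b)[1]), , ] <- b
    at <- at + dim(b)[1]
  }
  out
}

# random feature tables for cost-oracle checks
random_features <- function(n_steps, K = 4, person = "X") {
  tidyr::expand_grid(person = person, cycle = seq_len(n_steps),
                     mode_rank = seq_len(K)) |>
    dplyr::mutate(alpha = stats::rnorm(dplyr::n(), -6, 1),
                  freq = stats::runif(dplyr::n(), 0.3, 8),
                  s0 = stats::rlnorm(dplyr::n(), 5, 0.5))
}
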