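# Shared simulation studies for the recovery and criterion-comparison tests.
# Each is computed once per test run and reused across test blocks.

study_recovery <- function() cached("study_recovery", {
  run_sim_study(
    shapes = c("gaussian", "skewed", "bimodal"), sample_sizes = 3000,
    replicates = 10, criteria = "HQ", seed = 101, keep_details = TRUE
  )
})

study_small_n <- function() cached("study_small_n", {
  run_sim_study(
    shapes = c("gaussian", "skewed", "bimodal"), sample_sizes = 1000,
    replicates = 6, criteria = "HQ", seed = 102
  )
})

study_large_n <- function() cached("study_large_n", {
  run_sim_study(
    shapes = "gaussian", sample_sizes = 10000,
    replicates = 6, criteria = c("HQ", "BIC"), seed = 103
  )
})

# Height of the left (minor) mode region of a standardized bimodal density:
# the density maximum left of the valley of the reference density.
minor_mode_height <- function(grid, reference) {
  d <- reference$density
  peaks <- which(diff(sign(diff(d))) < 0) + 1L
  stopifnot(length(peaks) >= 2)
  valley <- peaks[1] + which.min(d[peaks[1]:peaks[2]]) - 1L
  max(grid$density[seq_len(valley)])
}
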