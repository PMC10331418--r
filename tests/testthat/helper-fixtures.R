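# Shared helpers: small spectral utilities used across the test files.

# One-sided cosine-amplitude spectrum at 1/duration Hz resolution
# (rectangular window, full length). Returns amplitudes indexed by
# frequency bin; amp_at(f) picks the amplitude at an integer frequency.
amp_spectrum <- function(x) {
  n <- length(x)
  2 * Mod(fft(x)) / n
}

amp_at <- function(A, f, duration = 1) A[round(f * duration) + 1]

# Count spectral bins (positive frequencies) above a relative floor.
count_peaks <- function(x, floor_rel = 1e-6) {
  n <- length(x)
  X <- Mod(fft(x))[2:(n %/% 2 + 1)]
  sum(X > floor_rel * max(X))
}

# Dominant positive frequency of a series (rectangular full-length FFT).
dominant_freq <- function(x, rate) {
  n <- length(x)
  X <- Mod(fft(x - mean(x)))[2:(n %/% 2 + 1)]
  which.max(X) * rate / n
}

# A quiet unlocked parameter set with strong adaptation, for deterministic
# mechanism checks that should not be masked by 1:1 phase locking.
unlocked_params <- function(noise_d = 0) {
  punit_params(beta = 20, tau_m = 5, mu = 0, noise_d = noise_d, tau_a = 100,
               delta_a = 50, tau_d = 1, t_ref = 0)
}
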