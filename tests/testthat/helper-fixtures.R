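# Shared helpers: small gradient tables and independent brute-force oracles.

# Write a fraction TSV and return its path.
write_fraction_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Gaussian-band profile evaluated on an equal-width fraction grid, built
# directly from pnorm (independent of simulate_gradient's internals).
gaussian_profile <- function(centres, weights, sds = 0.003, n = 32,
                             dmin = 1.692, dmax = 1.765,
                             sample_id = "x", role = "treatment") {
  bounds <- seq(dmin, dmax, length.out = n + 1)
  lo <- bounds[-(n + 1)]; hi <- bounds[-1]
  mass <- rowSums(mapply(function(mu, w, s) {
    w * (pnorm(hi, mu, s) - pnorm(lo, mu, s))
  }, centres, weights, sds))
  gradient_profile(
    data.frame(fraction_id = seq_len(n),
               density = rev((lo + hi) / 2),
               dna_conc = rev(mass)),
    sample_id = sample_id, role = role)
}

# Brute-force GC skew recount with substring arithmetic (the oracle for
# gc_skew): linear mode only.
skew_oracle <- function(seq, window, step) {
  L <- nchar(seq)
  starts <- seq(1, L - window + 1, by = step)
  vapply(starts, function(st) {
    w <- strsplit(substr(seq, st, st + window - 1), "")[[1]]
    g <- sum(w == "G"); c_ <- sum(w == "C")
    if (g + c_ == 0) 0 else (g - c_) / (g + c_)
  }, numeric(1))
}

# Brute-force longest terminal prefix/suffix overlap (oracle for
# circularize).
overlap_oracle <- function(seq, min_overlap, max_mismatch_rate = 0,
                           max_overlap = NULL) {
  L <- nchar(seq)
  if (is.null(max_overlap)) max_overlap <- min(L %/% 2, 10000)
  ch <- strsplit(seq, "")[[1]]
  for (k in seq(max_overlap, min_overlap)) {
    mm <- sum(ch[1:k] != ch[(L - k + 1):L])
    if (mm <= k * max_mismatch_rate) return(k)
  }
  0L
}

random_dna <- function(n, seed, prob = rep(0.25, 4)) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = ""))
}
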