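# Shared fixtures and independent oracles used across the suite.

# quick culture-table builder (defaults give N = 1e9 per culture)
culture_table <- function(r, z = 1, nonselective_count = 100,
                          dilution_factor = 1e5, plated_volume_ml = 0.1,
                          culture_volume_ml = 10, strain = "wt") {
  n <- length(r)
  data.frame(strain = rep_len(strain, n), r = r, z = rep_len(z, n),
             nonselective_count = rep_len(nonselective_count, n),
             dilution_factor = rep_len(dilution_factor, n),
             plated_volume_ml = rep_len(plated_volume_ml, n),
             culture_volume_ml = rep_len(culture_volume_ml, n),
             stringsAsFactors = FALSE)
}

# exhaustive Mann-Whitney oracle: enumerate every labeling of the
# pooled sample and accumulate the exact two-sided tail probability
mw_enumeration_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# brute-force microhomology oracle: try every junction placement i and
# every homology window h, requiring the window to match both parents
mh_brute_force_oracle <- function(donor_end, acceptor_start, fused) {
  lf <- nchar(fused)
  ld <- nchar(donor_end)
  best <- NA_integer_
  for (i in 0:lf) {
    left_ok <- i == 0 ||
      (ld >= i && substring(donor_end, ld - i + 1) == substr(fused, 1, i))
    if (!left_ok) next
    for (h in 0:i) {
      rest_len <- lf - i
      acc_rest <- substr(acceptor_start, h + 1, h + rest_len)
      right_ok <- nchar(acc_rest) == rest_len &&
        acc_rest == substring(fused, i + 1)
      hom_ok <- h == 0 ||
        substr(acceptor_start, 1, h) == substr(fused, i - h + 1, i)
      if (right_ok && hom_ok && (is.na(best) || h > best)) best <- h
    }
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
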