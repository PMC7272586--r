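# Independent brute-force oracle for the rank-sum test: enumerate every
# assignment of the pooled sample into the two groups and read the exact
# two-sided p off the permutation distribution of U.
mw_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(length(pooled), n)
  us <- apply(splits, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}
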