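# Independent brute-force oracle for the exact rank-sum test: enumerates all
# C(n+m, n) assignments of the pooled midranks and reads the two-sided tail
# probability straight off the permutation distribution.
brute_ranksum_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  wobs <- sum(r[seq_len(na)])
  sets <- utils::combn(length(r), na)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  p_le <- mean(ws <= wobs + 1e-9)
  p_ge <- mean(ws >= wobs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
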