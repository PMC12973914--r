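# Independent oracles used by the unit and acceptance tests.  They compute
# the same quantities as the package by a different route (enumeration,
# inclusion-exclusion over level means, exhaustive pairwise scans) and must
# stay free of the implementation's code paths.

# Sum of squares for a factor subset by inclusion-exclusion over level
# means: each observation's estimated effect for the subset is
# sum_{T subset S} (-1)^{|S|-|T|} mean(y | levels of T), and the SS is the
# sum of squared effects over all observations (balanced layouts).
oracle_ss <- function(y, factors, subset) {
  n <- length(y)
  eff <- rep(0, n)
  m <- length(subset)
  for (mask in 0:(2^m - 1)) {
    keep <- subset[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    sign <- (-1)^(m - length(keep))
    if (length(keep) == 0) {
      term <- rep(mean(y), n)
    } else {
      g <- interaction(factors[keep], drop = TRUE)
      term <- stats::ave(y, g)
    }
    eff <- eff + sign * term
  }
  sum(eff^2)
}

# Exhaustive pairwise check of a letter display: TRUE when, for every pair,
# sharing at least one letter coincides with |difference| <= lsd.
letters_consistent <- function(means, letts, lsd) {
  k <- length(means)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      share <- length(intersect(strsplit(letts[i], "")[[1]],
                                strsplit(letts[j], "")[[1]])) > 0
      close_enough <- abs(means[i] - means[j]) <= lsd + 1e-12
      if (share != close_enough) return(FALSE)
    }
  }
  TRUE
}

# Brute-force dominance: a row is dominated when some other row has
# (tvc <, nb >=) or, for exact tvc ties, appears earlier with nb >=.
oracle_dominated <- function(tvc, nb) {
  n <- length(tvc)
  vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      if (j == i) return(FALSE)
      (tvc[j] < tvc[i] & nb[j] >= nb[i]) ||
        (tvc[j] == tvc[i] & nb[j] > nb[i]) ||
        (tvc[j] == tvc[i] & nb[j] == nb[i] & j < i)
    }, logical(1)))
  }, logical(1))
}
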