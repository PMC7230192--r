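# Independent brute-force oracles, deliberately hand-coded so they share no
# machinery with the package implementation.

# Hard-coded gamete tables as plain count vectors c(X1, X2, X3, Y); sperm
# classes are listed (X1-bearing, Y-bearing).
oracle_gametes <- function(karyomorph, regime, s = 0.5) {
  if (regime == "xy_female") {
    switch(karyomorph,
      KI   = list(list(g = c(1, 0, 1, 0), p = 0.5),
                  list(g = c(0, 0, 1, 1), p = 0.5)),
      KII  = list(list(g = c(1, 0, 1, 0), p = s),
                  list(g = c(0, 1, 0, 0), p = 1 - s)),
      KIII = list(list(g = c(0, 1, 0, 0), p = s),
                  list(g = c(0, 0, 1, 1), p = 1 - s)),
      KIV  = list(list(g = c(1, 0, 1, 0), p = 1)))
  } else {
    switch(karyomorph,
      KI   = list(list(g = c(1, 0, 0, 0), p = 0.5),
                  list(g = c(0, 0, 0, 1), p = 0.5)),
      KII  = list(list(g = c(1, 0, 0, 0), p = s),
                  list(g = c(0, 1, 0, 0), p = 1 - s)),
      KIII = list(list(g = c(0, 1, 0, 0), p = s),
                  list(g = c(0, 0, 0, 0), p = 1 - s)),
      KIV  = list(list(g = c(1, 0, 0, 0), p = 1)))
  }
}

# zygote probability table of a dam x KI cross by explicit enumeration of
# every (dam gamete, sire gamete) pair; returns a named vector keyed by the
# zygote count string "X1.X2.X3.Y" with raw probabilities.
oracle_cross_raw <- function(dam, regime, w = 1, s = 0.5) {
  dg <- oracle_gametes(dam, regime, s)
  sg <- oracle_gametes("KI", regime)
  # fertilization weight on the Y-bearing sperm class
  sp <- c(1, w); sp <- sp / sum(sp)
  out <- numeric(0)
  for (i in seq_along(dg)) for (j in 1:2) {
    z <- dg[[i]]$g + sg[[j]]$g
    key <- paste(z, collapse = ".")
    out[key] <- (if (key %in% names(out)) out[[key]] else 0) +
      dg[[i]]$p * sp[j]
  }
  out
}

# exact Fisher r x c p-value by brute enumeration over all cell layouts
# (expand.grid over free cells, margins filtered), probabilities from
# factorial ratios.  Only for small tables (n <= ~30).
oracle_fisher_rxc <- function(tab) {
  tab <- as.matrix(tab)
  r <- nrow(tab); cc <- ncol(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(m) {
    prod(factorial(rs)) * prod(factorial(cs)) /
      (factorial(n) * prod(factorial(m)))
  }
  free <- expand.grid(rep(list(0:max(tab, rs, cs)), (r - 1) * (cc - 1)))
  p_obs <- prob(tab)
  total <- 0
  for (k in seq_len(nrow(free))) {
    m <- matrix(0, r, cc)
    m[seq_len(r - 1), seq_len(cc - 1)] <- as.numeric(free[k, ])
    m[seq_len(r - 1), cc] <- rs[seq_len(r - 1)] - rowSums(m[, -cc, drop = FALSE])[seq_len(r - 1)]
    m[r, ] <- cs - colSums(m[-r, , drop = FALSE])
    if (any(m < 0)) next
    p <- prob(m)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

# exact two-sided binomial p by direct summation with choose()
oracle_binom_two_sided <- function(k, n, p0) {
  probs <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# random small count table with no zero margins
random_table <- function(r, cc, max_n = 12) {
  repeat {
    m <- matrix(rpois(r * cc, 1.5), r, cc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) && sum(m) <= max_n)
      return(m)
  }
}
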