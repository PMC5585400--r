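# Build a coverage track from a numeric vector anchored at a 0-based start.
make_track <- function(values, start = 0L, chrom = "chr1") {
  coverage_track(stats::setNames(
    list(S4Vectors::Rle(c(numeric(start), values))), chrom))
}

# One-row event table.
make_event <- function(distal, proximal, strand = "+", chrom = "chr1",
                       id = "ev1") {
  tandem_events(id, chrom, strand, distal, proximal)
}

# Independent fine-grid oracle for the posterior mean: plain numeric
# integration of p(psi)^n_prox (1-p)^n_dist at step 1e-5, no package code.
oracle_psi_mean <- function(n_distal, n_proximal, l_inc = 1, l_exc = 1,
                            h = 1e-5) {
  psi <- seq(h / 2, 1 - h / 2, by = h)
  p <- psi * l_inc / (psi * l_inc + (1 - psi) * l_exc)
  ll <- n_proximal * log(p) + n_distal * log(1 - p)
  f <- exp(ll - max(ll))
  sum(psi * f) / sum(f)
}

# Independent fine-grid oracle for the Bayes factor.
oracle_bf <- function(nd1, np1, nd2, np2, h = 1e-5) {
  psi <- seq(h / 2, 1 - h / 2, by = h)
  ll1 <- np1 * log(psi) + nd1 * log(1 - psi)
  ll2 <- np2 * log(psi) + nd2 * log(1 - psi)
  m <- max(ll1 + ll2)
  m1 <- h * sum(exp(ll1 - max(ll1)))
  m2 <- h * sum(exp(ll2 - max(ll2)))
  m0 <- h * sum(exp(ll1 + ll2 - m))
  exp(log(m1) + max(ll1) + log(m2) + max(ll2) - log(m0) - m)
}
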