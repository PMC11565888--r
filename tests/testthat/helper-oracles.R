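# Independent oracles used across the suite. Each is a deliberately naive
# computation (explicit summation / enumeration) kept separate from the
# package's implementation path.

# Poisson upper tail P(X >= n) by direct term summation (lgamma for k!).
oracle_poisson_tail <- function(n, mu, K = 200) {
  if (n == 0) return(1)
  k <- n:(n + K)
  sum(exp(-mu + k * log(mu) - lgamma(k + 1)))
}

# Binomial upper tail P(X >= k) via explicit choose() summation.
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Benjamini-Hochberg step-up q-values: m * p_(i) / i with cummin from the top.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q)[order(o)]
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of all table probabilities <= that of the observed table.
oracle_fisher2x2 <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  prob <- function(a) {
    b <- rs[1] - a; cc <- cs[1] - a; d <- n - a - b - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lgamma(rs[1] + 1) - lgamma(a + 1) - lgamma(b + 1) +
          lgamma(rs[2] + 1) - lgamma(cc + 1) - lgamma(d + 1) +
          lgamma(cs[1] + 1) + lgamma(cs[2] + 1) - lgamma(n + 1))
  }
  p_obs <- prob(m[1, 1])
  a_range <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  sum(vapply(a_range, prob, numeric(1))[vapply(a_range, prob, numeric(1)) <=
                                          p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p for small samples by full enumeration of
# rank assignments.
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(seq_len(nx + ny)[idx]) -
                nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tiny gene-model fixture with known CDS sequences for codon checks.
fixture_genes <- function() {
  tibble::tibble(
    gene = c("G1", "G2"),
    chrom = c("chrA", "chrA"),
    start = c(2001, 6001),
    end = c(2009, 6012),
    strand = c("+", "-"),
    cds_length = c(9, 12),
    N = cds_length + 1000
  )
}

fixture_cds <- function() {
  c(G1 = "ATGGCTTAA",     # M A *
    G2 = "ATGAAACCCTAA")  # M K P *  (coding strand; gene on minus strand)
}
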