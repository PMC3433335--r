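# Shared fixtures and independent oracles.

# Build a MatchedInput directly from vectors (bypasses file I/O).
mkMatched <- function(s, beta, sd = NA_real_, df = NA_real_, p = NA_real_,
                      fdr = NA_real_, treated = NA_real_,
                      control = NA_real_, nMissing = 0L) {
  n <- length(beta)
  fdr <- rep_len(fdr, n)
  new("MatchedInput",
      data = data.frame(gene = sprintf("g%03d", seq_len(n)),
                        s = as.integer(s), beta = beta,
                        sd = rep_len(sd, n), df = rep_len(df, n),
                        p = rep_len(p, n), fdr = fdr, fndr = 1 - fdr,
                        treated = rep_len(treated, n),
                        control = rep_len(control, n),
                        stringsAsFactors = FALSE),
      nUsed = as.integer(n), nMissing = as.integer(nMissing))
}

# Brute-force BH step-up: sort, multiply by m/rank, cumulative minimum from
# the largest p, clamp at 1, unsort. Independent of stats::p.adjust.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent EPI oracle: evaluates the density pointwise from its
# definition (direct summation over the correctly-signed values above phi)
# at midpoints between all breakpoints, then integrates the piecewise
# constant segments exactly; the [-eps, eps] interpolation strip is handled
# with its one-sided density limits.
epiOracle <- function(s, beta, M = 15, epsilon = M * 1e-12, sub = 7) {
  x <- pmax(pmin(s * beta, M), -M)
  n <- length(x)
  g <- function(phi) vapply(phi, function(ph) {
    if (ph > epsilon) sum(abs(x[x > ph])) / (n * M)
    else if (ph < -epsilon) sum(abs(x[x < ph])) / (n * M)
    else NA_real_
  }, numeric(1))
  gl <- sum(abs(x[x < -epsilon])) / (n * M)
  gr <- sum(abs(x[x > epsilon])) / (n * M)
  bp <- sort(unique(c(-M, -abs(x), -epsilon, epsilon, abs(x), M)))
  bp <- bp[bp >= -M & bp <= M]
  mass <- epsilon * (gl + gr)
  mom <- (gr - gl) * epsilon^2 / 3
  for (i in seq_len(length(bp) - 1L)) {
    lo <- bp[i]; hi <- bp[i + 1L]
    if (hi <= lo || (lo >= -epsilon && hi <= epsilon)) next
    grid <- seq(lo, hi, length.out = sub + 1L)
    mid <- (grid[-1L] + grid[-length(grid)]) / 2
    gv <- g(mid)
    w <- diff(grid)
    mass <- mass + sum(gv * w)
    mom <- mom + sum(gv * mid * w)
  }
  if (mass == 0) 0 else mom / mass
}

# Write a HYP statement table to a temp file.
writeHypTsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
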