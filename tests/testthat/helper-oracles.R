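# Independent oracles, kept deliberately naive so they share no code path
# with the package implementation.

# Birth size by direct enumeration: walk the bins of [x0, xd] and return the
# first whose inclusive cumulative count reaches q * (daughter-interval sum).
brute_birth_size <- function(bin_fl, counts, x0, xd, q) {
  in_d <- which(bin_fl >= x0 & bin_fl <= xd)
  total <- sum(counts[in_d])
  if (total <= 0) return(NA_real_)
  acc <- 0
  for (i in in_d) {
    acc <- acc + counts[i]
    if (acc >= q * total) return(bin_fl[i])
  }
  NA_real_
}

# Spearman as the Pearson correlation of midranks, from first principles.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# x0 rule by exhaustive candidate check (threshold alpha * raw mode count,
# k consecutive channels at or above it, counts strictly positive).
brute_x0 <- function(bin_fl, counts, alpha, k) {
  thr <- alpha * max(counts)
  n <- length(counts)
  for (b in seq_len(n - k + 1)) {
    window <- counts[b:(b + k - 1)]
    if (all(window >= thr & window > 0)) return(bin_fl[b])
  }
  NA_real_
}

# Random valid distribution on a random non-uniform grid. Counts are a
# noisy right-skewed bump plus occasional low-channel debris, the shape the
# extraction is built for; not guaranteed qc-pass (tests condition on qc).
random_distribution <- function() {
  n <- sample(15:60, 1)
  widths <- runif(n - 1, 0.3857, 1.2037)
  bins <- 10 + cumsum(c(0, widths))
  mu <- runif(1, log(18), log(35))
  sizes <- rlnorm(sample(c(200, 2000, 20000), 1), mu, runif(1, 0.15, 0.35))
  mids <- c(bins[1] - widths[1] / 2, bins[-n] + widths / 2,
            bins[n] + widths[n - 1] / 2)
  counts <- as.numeric(tabulate(findInterval(sizes, mids,
                                             rightmost.closed = TRUE),
                                nbins = n))
  counts[counts < 0] <- 0
  if (runif(1) < 0.5) {
    debris <- sample(seq_len(max(1, floor(n / 8))), 2, replace = TRUE)
    counts[debris] <- counts[debris] + rpois(2, 3)
  }
  if (sum(counts) <= 0) counts[ceiling(n / 2) + (-1:1)] <- c(3, 5, 2)
  size_distribution(bins, counts)
}

# Closed-form CDF and density of a generated strain's size mixture, from
# its ground-truth row: daughter log-size is N(meanlog_birth, sdlog_birth)
# plus an independent Unif(0, log_growth) growth term; mothers are
# lognormal.
mixture_cdf_fun <- function(truth_row) {
  mlb <- truth_row$meanlog_birth; sb <- truth_row$sdlog_birth
  L <- truth_row$log_growth
  mlm <- truth_row$meanlog_mother; sm <- truth_row$sdlog_mother
  w <- truth_row$weight_daughter
  H <- function(v) v * pnorm(v / sb) + sb * dnorm(v / sb)
  function(t) {
    c0 <- log(t) - mlb
    w * (H(c0) - H(c0 - L)) / L + (1 - w) * plnorm(t, mlm, sm)
  }
}

mixture_density_fun <- function(truth_row) {
  mlb <- truth_row$meanlog_birth; sb <- truth_row$sdlog_birth
  L <- truth_row$log_growth
  mlm <- truth_row$meanlog_mother; sm <- truth_row$sdlog_mother
  w <- truth_row$weight_daughter
  function(t) {
    w * (pnorm((log(t) - mlb) / sb) - pnorm((log(t) - mlb - L) / sb)) /
      (L * t) + (1 - w) * dlnorm(t, mlm, sm)
  }
}
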