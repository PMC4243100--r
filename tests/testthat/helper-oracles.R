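# Independent brute-force reference implementations and shared fixtures.
# These deliberately use naive loops and literal set counting so that the
# production (vectorised, cached) code paths are checked against a second,
# structurally different route.

# literal all-pairs-distance neighbourhood purity
oracle_purity <- function(x, labels, k) {
  n <- length(x)
  labels <- as.integer(factor(labels))
  out <- numeric(n)
  for (u in seq_len(n)) {
    others <- setdiff(seq_len(n), u)
    d <- abs(x[others] - x[u])
    # sort by (distance, index): ties towards the lower instance index
    nb <- others[order(d, others)][seq_len(k)]
    out[u] <- sum(labels[nb] == labels[u]) / k
  }
  out
}

# literal set-counting redundancy ratio
oracle_remi <- function(blur_p, blur_q) {
  p_set <- which(blur_p)
  q_set <- which(blur_q)
  if (length(p_set) == 0L) return(0)
  length(intersect(p_set, q_set)) / length(p_set)
}

# plug-in mutual information by explicit loops over level pairs (bits)
oracle_mi <- function(a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(a)
  total <- 0
  for (la in levels(a)) {
    for (lb in levels(b)) {
      pab <- sum(a == la & b == lb) / n
      if (pab > 0) {
        total <- total + pab * log2(pab / ((sum(a == la) / n) * (sum(b == lb) / n)))
      }
    }
  }
  total
}

# random small dataset of discrete codes
rand_discrete <- function(n, m, n_levels, seed) {
  set.seed(seed)
  matrix(sample.int(n_levels, n * m, replace = TRUE), n, m)
}

# Hand-built fixture: A is a strong separator that blurs exactly instance 8,
# B is an exact copy of A, and C is a weaker feature (|t_C| < |t_A|) that
# clear-discerns instance 8 while blurring instances 5 and 7.  With k = 3,
# mu = 0.66 the expected selection order is A, C, B.
fixture_abc <- function() {
  list(
    x = cbind(A = c(0, 1, 2, 3, 10, 11, 12, 3.5),
              B = c(0, 1, 2, 3, 10, 11, 12, 3.5),
              C = c(0, 1, 2, 3, 6, 13, 6.5, 15)),
    y = factor(c("t", "t", "t", "t", "n", "n", "n", "n"))
  )
}

# a tiny separable dataset: one perfectly separating feature plus noise
separable_dataset <- function(n = 12, m_noise = 4, seed = 42) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  signal <- ifelse(y == "a", 5, -5) + rnorm(n, sd = 0.1)
  x <- cbind(SIG = signal,
             matrix(rnorm(n * m_noise), n,
                    dimnames = list(NULL, paste0("N", seq_len(m_noise)))))
  expression_dataset(x, y)
}
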