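# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

oracle_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  s / abs(m)
}

# O(n^3) agglomerative average-linkage clustering on Euclidean distance;
# returns sorted merge heights.
oracle_average_linkage_heights <- function(mat) {
  clusters <- as.list(seq_len(nrow(mat)))
  d <- function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        pair_d <- outer(clusters[[a]], clusters[[b]],
                        Vectorize(function(i, j) d(i, j)))
        h <- mean(pair_d)
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

# product-limit estimator by direct product over event times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    deaths <- sum(time == ts[k] & event == 1)
    s <- s * (1 - deaths / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# two-group log-rank chi-square via the per-event-time 2x2 tables
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tk in ts) {
    n <- sum(time >= tk)
    n1 <- sum(time >= tk & group == g1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# consensus by naive membership counting over all genes
oracle_consensus <- function(sets, min_db) {
  genes <- unique(unlist(sets))
  genes[vapply(genes, function(g) {
    sum(vapply(sets, function(s) g %in% s, logical(1))) >= min_db
  }, logical(1))]
}

random_survival_table <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)),
    time = round(rexp(n, rate = 0.2), 2),
    event = rbinom(n, 1, 0.7)
  )
}
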