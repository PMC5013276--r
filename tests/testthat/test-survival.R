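test_that("gene z-scores use the population SD and satisfy the identities", {
  expr <- tibble::tibble(gene = "AKT2", s1 = 1, s2 = 3)
  z <- gene_zscores(expr, "AKT2")
  expect_equal(unlist(z[1, -1], use.names = FALSE), c(-1, 1))

  set.seed(51)
  expr2 <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%d", 1:4)),
    tibble::as_tibble(as.data.frame(matrix(rnorm(80, 8, 2), nrow = 4)) |>
                        stats::setNames(sprintf("s%02d", 1:20)))
  )
  z2 <- gene_zscores(expr2, expr2$gene)
  mat <- as.matrix(z2[, -1])
  expect_equal(rowMeans(mat), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowMeans(mat^2), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  # brute-force formula oracle
  raw <- as.matrix(expr2[, -1])
  for (i in 1:4) {
    mu <- sum(raw[i, ]) / 20
    sig <- sqrt(sum((raw[i, ] - mu)^2) / 20)
    expect_equal(mat[i, ], (raw[i, ] - mu) / sig, tolerance = 1e-12)
  }

  expect_error(gene_zscores(expr2, "nope"), "absent")
  const <- tibble::tibble(gene = "flat", s1 = 2, s2 = 2, s3 = 2)
  expect_error(gene_zscores(const, "flat"), "zero-variance")
})

test_that("multiple probes per gene are averaged before z-scoring", {
  expr <- tibble::tibble(gene = c("AKT2", "AKT2"),
                         s1 = c(1, 3), s2 = c(5, 7), s3 = c(0, 2))
  z <- gene_zscores(expr, "AKT2")
  # probe means are 2, 6, 1
  mu <- 3
  sig <- sqrt(mean((c(2, 6, 1) - mu)^2))
  expect_equal(unlist(z[1, -1], use.names = FALSE),
               (c(2, 6, 1) - mu) / sig)
})

test_that("network score sums z-scores per sample", {
  set.seed(52)
  z <- dplyr::bind_cols(
    tibble::tibble(gene = c("a", "b", "c")),
    tibble::as_tibble(as.data.frame(matrix(rnorm(30), nrow = 3)) |>
                        stats::setNames(sprintf("s%d", 1:10)))
  )
  sc <- network_score(z)
  mat <- as.matrix(z[, -1])
  for (j in 1:10) {
    acc <- 0
    for (i in 1:3) acc <- acc + mat[i, j]
    expect_equal(sc$score[j], unname(acc))
  }
  expect_equal(network_score(z, "a")$score, unname(mat[1, ]))
  expect_error(network_score(z, "zz"), "absent")
  expect_error(network_score(z[0, ]), "empty")

  # scores of standardized genes have cohort mean zero
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = c("a", "b")),
    tibble::as_tibble(as.data.frame(matrix(rnorm(20, 5), nrow = 2)) |>
                        stats::setNames(sprintf("s%d", 1:10)))
  )
  sc2 <- network_score(gene_zscores(expr, c("a", "b")))
  expect_equal(mean(sc2$score), 0, tolerance = 1e-12)
})

test_that("min-max normalization maps to [0,1] preserving order", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 0.3, 1)), c(0, 0.3, 1))
  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- minmax_normalize(x)
    expect_equal(range(y), c(0, 1))
    expect_equal(rank(y), rank(x))
  }
  expect_error(minmax_normalize(rep(3, 5)), "constant")
})

test_that("median split uses a strict-above rule with ties going low", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(2, 2, 2)), rep("low", 3))
  set.seed(54)
  for (i in 1:10) {
    x <- sample(1:5, 20, replace = TRUE)
    g <- median_split(x)
    ties <- sum(x == median(x))
    # ties-go-low: high never exceeds half the cohort, and any imbalance is
    # attributable to values sitting exactly at the median
    expect_lte(sum(g == "high"), length(x) / 2)
    if (ties == 0) {
      expect_lte(abs(sum(g == "high") - sum(g == "low")), 1)
    } else {
      expect_lte(sum(g == "low") - sum(g == "high"), 2 * ties)
    }
  }
})

test_that("follow-up truncation censors administratively", {
  surv <- tibble::tibble(time = c(3, 7, 5), event = c(1, 1, 1))
  tr <- truncate_followup(surv, 5)
  expect_equal(tr$time, c(3, 5, 5))
  expect_equal(tr$event, c(1, 0, 1))
  expect_lte(sum(tr$event), sum(surv$event))

  withna <- tibble::tibble(time = c(3, NA), event = c(1, 1))
  expect_message(tr2 <- truncate_followup(withna, 5), "dropping 1")
  expect_equal(nrow(tr2), 1L)
})

test_that("Kaplan-Meier estimates match hand values and a brute-force oracle", {
  none <- tibble::tibble(time = c(2, 5, 9), event = c(0, 0, 0))
  expect_true(all(km_estimate(none)$surv == 1))

  two <- tibble::tibble(time = c(1, 2), event = c(1, 1))
  km <- km_estimate(two)
  expect_equal(km$surv[km$time == 1], 0.5)
  expect_equal(km$surv[km$time == 2], 0)

  for (s in 1:20) {
    tab <- random_survival_table(12, seed = 500 + s)
    km <- km_estimate(tab)
    ref <- oracle_km(tab$time, tab$event)
    got <- km[km$n_event > 0, c("time", "surv")]
    expect_equal(got$time, ref$time)
    expect_equal(got$surv, ref$surv, tolerance = 1e-10)
  }

  expect_error(km_estimate(two[0, ]), "non-empty")
})

test_that("log-rank matches a hand-computed toy table and brute force", {
  # identical groups: duplicated table, chi-square 0
  tab <- random_survival_table(8, seed = 61)
  dup <- dplyr::bind_rows(tab, tab)
  lr0 <- logrank_test(dup, rep(c("a", "b"), each = 8))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # 6-subject toy example, statistic from the O/E/V tables by hand:
  # group A: events at 1, 3; censored 4. group B: events at 2, 5; censored 6.
  toy <- tibble::tibble(time = c(1, 3, 4, 2, 5, 6),
                        event = c(1, 1, 0, 1, 1, 0))
  grp <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(toy, grp)
  expect_equal(lr$chi_square, oracle_logrank_chisq(toy$time, toy$event, grp),
               tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(lr$chi_square, 1, lower.tail = FALSE))

  for (s in 1:20) {
    tab <- random_survival_table(16, seed = 700 + s)
    grp <- rep(c("x", "y"), 8)
    lr <- logrank_test(tab, grp)
    expect_equal(lr$chi_square,
                 oracle_logrank_chisq(tab$time, tab$event, grp),
                 tolerance = 1e-10)
  }

  expect_error(logrank_test(tab, rep("x", 16)), "2 groups")
})

test_that("score-readout correlation returns r and a two-sided p", {
  set.seed(62)
  sc <- rnorm(20)
  expect_equal(correlate_score_with_readout(sc, sc)$estimate, 1)
  expect_equal(correlate_score_with_readout(sc, -sc)$estimate, -1)
  y <- rnorm(20)
  res <- correlate_score_with_readout(sc, y)
  expect_equal(res$estimate, oracle_pearson(sc, y), tolerance = 1e-12)
  expect_equal(res$p_value, cor.test(sc, y)$p.value)
  expect_error(correlate_score_with_readout(sc, rep(1, 20)), "zero variance")
  sp <- correlate_score_with_readout(sc, y, method = "spearman")
  expect_equal(sp$estimate, cor(sc, y, method = "spearman"))
})

test_that("signature survival is invariant to per-gene affine rescaling", {
  co <- sim_cohort(n_samples = 60, n_genes = 10,
                   log_hazard_per_unit_score = 1.5, seed = 63)
  genes <- co$truth$signature_genes
  fit <- signature_survival(co$expr, co$surv, genes)

  expr2 <- co$expr
  set.seed(64)
  for (g in genes) {
    i <- which(expr2$gene == g)
    a <- runif(1, 0.5, 3)
    b <- rnorm(1, 0, 10)
    expr2[i, -1] <- a * expr2[i, -1] + b
  }
  fit2 <- signature_survival(expr2, co$surv, genes)
  expect_equal(fit2$scores$score, fit$scores$score, tolerance = 1e-10)
  expect_equal(fit2$scores$group, fit$scores$group)
  expect_equal(fit2$logrank$chi_square, fit$logrank$chi_square,
               tolerance = 1e-10)
})

test_that("signature survival objects tidy, glance and plot", {
  co <- sim_cohort(n_samples = 40, n_genes = 8, seed = 65)
  fit <- signature_survival(co$expr, co$surv, co$truth$signature_genes,
                            horizon = 5)
  td <- tidy(fit)
  expect_equal(nrow(td), 40L)
  expect_true(all(c("sample", "score", "score_norm", "group") %in% names(td)))
  expect_true(all(td$score_norm >= 0 & td$score_norm <= 1))

  gl <- glance(fit)
  expect_equal(gl$n_high + gl$n_low, 40L)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)

  expect_equal(tidy(fit$logrank)$statistic, fit$logrank$chi_square)
  expect_equal(sum(glance(fit$logrank)$observed), sum(fit$km$n_event))

  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$km), "ggplot")
})

test_that("KM curves start at one and never increase within a group", {
  co <- sim_cohort(n_samples = 80, n_genes = 8,
                   log_hazard_per_unit_score = 2, seed = 66)
  fit <- signature_survival(co$expr, co$surv, co$truth$signature_genes)
  for (g in unique(fit$km$group)) {
    s <- fit$km$surv[fit$km$group == g]
    expect_true(all(s <= 1))
    expect_true(all(diff(s) <= 1e-12))
  }
})
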