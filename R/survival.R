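#' Per-gene z-scores across a cohort
#'
#' Standardizes each signature gene across samples with the conventional
#' z-score using the population (divide-by-n) standard deviation. Multiple
#' probe rows mapping to the same gene are averaged per sample first.
#'
#' @param expr Expression tibble: first column gene/probe symbol, one
#'   numeric column per sample.
#' @param genes Genes to standardize; each must be present with nonzero
#'   variance.
#' @return A tibble: `gene` plus one z-score column per sample. Within each
#'   gene row the z-scores have mean 0 and population SD 1.
#' @export
#' @examples
#' expr <- tibble::tibble(gene = "AKT2", s1 = 1, s2 = 3)
#' gene_zscores(expr, "AKT2") # z = -1, +1
gene_zscores <- function(expr, genes) {
  stopifnot(length(genes) >= 1L, ncol(expr) >= 3L)
  missing <- setdiff(genes, expr[[1L]])
  if (length(missing)) {
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  id <- names(expr)[[1L]]
  avg <- expr |>
    dplyr::filter(.data[[id]] %in% genes) |>
    dplyr::group_by(gene = .data[[id]]) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
  mat <- as.matrix(avg[, -1L, drop = FALSE])
  n <- ncol(mat)
  mu <- rowMeans(mat)
  sigma <- sqrt(rowMeans((mat - mu)^2))
  if (any(sigma == 0)) {
    stop("zero-variance gene(s): ",
         paste(avg$gene[sigma == 0], collapse = ", "))
  }
  z <- (mat - mu) / sigma
  dplyr::bind_cols(tibble::tibble(gene = avg$gene),
                   tibble::as_tibble(as.data.frame(z, check.names = FALSE)))
}

#' Target-network score: per-sample sum of gene z-scores
#'
#' @param z z-score tibble from [gene_zscores()].
#' @param genes Optional subset of genes to sum (defaults to all rows).
#' @return A tibble with columns `sample` and `score`.
#' @export
network_score <- function(z, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, z$gene)
    if (length(missing)) {
      stop("gene(s) absent from z matrix: ", paste(missing, collapse = ", "))
    }
    z <- z[z$gene %in% genes, , drop = FALSE]
  }
  if (!nrow(z)) stop("empty gene set")
  mat <- as.matrix(z[, -1L, drop = FALSE])
  tibble::tibble(sample = colnames(mat), score = unname(colSums(mat)))
}

#' Min-max normalization to \[0, 1\]
#'
#' Subtracts the minimum and divides by the range, mapping the minimum to 0
#' and the maximum to 1.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[[1L]] == r[[2L]]) {
    stop("cannot min-max normalize a constant vector (zero range)")
  }
  (x - r[[1L]]) / (r[[2L]] - r[[1L]])
}

#' Median split into high/low groups
#'
#' Scores strictly above the median are `"high"`; scores at or below it are
#' `"low"` (a deterministic, inclusive tie rule).
#'
#' @param x Numeric scores, length >= 2.
#' @return Character vector of `"high"`/`"low"` labels along `x`.
#' @export
median_split <- function(x) {
  stopifnot(length(x) >= 2L, all(is.finite(x)))
  ifelse(x > stats::median(x), "high", "low")
}

#' Truncate follow-up at a horizon
#'
#' Administratively censors observations beyond `horizon`: times above it
#' are set to the horizon with `event = 0`. Records with missing time or
#' event status are dropped (with a message), mirroring the removal of
#' patients without survival information.
#'
#' @param surv Survival tibble with columns `time` and `event`.
#' @param horizon Positive follow-up horizon in the table's time units.
#' @return The truncated survival tibble.
#' @export
#' @examples
#' truncate_followup(tibble::tibble(time = c(3, 7), event = c(1, 1)), 5)
truncate_followup <- function(surv, horizon) {
  stopifnot(is.numeric(horizon), horizon > 0)
  drop <- is.na(surv$time) | is.na(surv$event)
  if (any(drop)) {
    message("dropping ", sum(drop), " record(s) without survival information")
    surv <- surv[!drop, , drop = FALSE]
  }
  over <- surv$time > horizon
  surv$event[over] <- 0L
  surv$time[over] <- horizon
  surv
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator (events precede censorings at tied times, the
#' standard convention) via [survival::survfit()], returned as a tidy
#' per-group step-function table.
#'
#' @param surv Survival tibble with columns `time` and `event`.
#' @param group Group labels along `surv` rows (a single group if omitted).
#' @return A tibble of class `km_fit`: `group`, `time`, `n_risk`, `n_event`,
#'   `surv` (estimate after `time`).
#' @export
km_estimate <- function(surv, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(surv))
  stopifnot(length(group) == nrow(surv))
  if (any(table(group) == 0L) || !nrow(surv)) stop("each group must be non-empty")
  dat <- data.frame(time = surv$time, event = surv$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) {
    rep(unique(dat$group), length(smry$time))
  } else {
    sub("^group=", "", as.character(smry$strata))
  }
  out <- tibble::tibble(group = grp, time = smry$time,
                        n_risk = smry$n.risk, n_event = smry$n.event,
                        surv = smry$surv)
  class(out) <- c("km_fit", class(out))
  out
}

#' Two-group log-rank test
#'
#' Unweighted Mantel-Haenszel log-rank chi-square (1 df) comparing two
#' survival curves, via [survival::survdiff()]. Identical groups give
#' chi-square 0 and p = 1.
#'
#' @param surv Survival tibble with columns `time` and `event`.
#' @param group Two-level group labels along `surv` rows.
#' @return A list of class `logrank_test`: `chi_square`, `p_value`, `df`,
#'   `n` (per-group sizes), `obs`, `exp` (per-group observed and expected
#'   events).
#' @export
logrank_test <- function(surv, group) {
  stopifnot(length(group) == nrow(surv))
  g <- unique(group)
  if (length(g) != 2L) stop("log-rank test requires exactly 2 groups, got ",
                            length(g))
  dat <- data.frame(time = surv$time, event = surv$event, group = group)
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chi <- unname(sd0$chisq)
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
                 df = 1L,
                 n = stats::setNames(as.integer(sd0$n),
                                     sub("^group=", "", names(sd0$n))),
                 obs = unname(sd0$obs), exp = unname(sd0$exp)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  n = %s; observed events = %s; expected = %s\n",
              paste(x$n, collapse = "/"), paste(x$obs, collapse = "/"),
              paste(round(x$exp, 2), collapse = "/")))
  cat(sprintf("  chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Correlate signature scores with a molecular readout
#'
#' Pearson (default) or Spearman correlation, with a two-sided p-value,
#' between per-sample signature scores and a matched readout such as a
#' protein or phospho-protein level.
#'
#' @param scores,readout Paired numeric vectors, n >= 3, finite, nonzero
#'   variance.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble with columns `estimate`, `p_value`, `n`, `method`.
#' @export
correlate_score_with_readout <- function(scores, readout,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(readout))
  ok <- is.finite(scores) & is.finite(readout)
  if (sum(ok) < 3L) stop("need at least 3 paired finite values")
  if (stats::sd(scores[ok]) == 0 || stats::sd(readout[ok]) == 0) {
    stop("zero variance in scores or readout")
  }
  ct <- suppressWarnings(
    stats::cor.test(scores[ok], readout[ok], method = method)
  )
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = sum(ok), method = method)
}

#' End-to-end signature survival analysis
#'
#' Computes the combined target-network score (sum of per-gene z-scores),
#' splits the cohort at the median score, truncates follow-up at an
#' optional horizon, and runs the Kaplan-Meier/log-rank comparison of the
#' high- and low-score groups.
#'
#' @param expr Expression tibble (first column gene, one column per sample).
#' @param surv Survival tibble with columns `sample`, `time`, `event`.
#' @param genes Signature gene set (e.g. `c("AKT2","GNA12","GYS1","SRF")`).
#' @param horizon Optional follow-up horizon for [truncate_followup()].
#' @return A list of class `signature_survival`: `scores` (per-sample tibble
#'   with `score`, `score_norm`, `group`), `km` (a `km_fit`), `logrank`
#'   (a `logrank_test`), `genes`, `horizon`.
#' @export
#' @examples
#' sim <- sim_cohort(n_samples = 60, seed = 7)
#' fit <- signature_survival(sim$expr, sim$surv, sim$truth$signature_genes)
#' glance(fit)
signature_survival <- function(expr, surv, genes, horizon = NULL) {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  z <- gene_zscores(expr, genes)
  scores <- network_score(z)
  scores <- scores[match(surv$sample, scores$sample), , drop = FALSE]
  if (anyNA(scores$sample)) {
    stop("survival table contains sample(s) absent from the expression matrix")
  }
  scores$score_norm <- minmax_normalize(scores$score)
  scores$group <- median_split(scores$score)
  st <- surv
  if (!is.null(horizon)) st <- truncate_followup(st, horizon)
  keep <- match(st$sample, scores$sample)
  structure(list(scores = scores,
                 km = km_estimate(st, scores$group[keep]),
                 logrank = logrank_test(st, scores$group[keep]),
                 genes = genes, horizon = horizon),
            class = "signature_survival")
}

#' @export
print.signature_survival <- function(x, ...) {
  cat("Target-network signature survival analysis\n")
  cat("  signature genes:", paste(x$genes, collapse = ", "), "\n")
  if (!is.null(x$horizon)) cat("  follow-up horizon:", x$horizon, "\n")
  print(x$logrank)
  invisible(x)
}
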