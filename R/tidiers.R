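#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a log-rank test
#'
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi_square, df = x$df, p_value = x$p_value)
}

#' Per-group summary of a log-rank test
#'
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @return Tibble with one row per group: `group`, `n`, `observed`,
#'   `expected`.
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(group = names(x$n), n = unname(x$n),
                 observed = x$obs, expected = x$exp)
}

#' Tidy per-sample scores of a signature survival fit
#'
#' @param x A `signature_survival` object.
#' @param ... Unused.
#' @return The per-sample score tibble (`sample`, `score`, `score_norm`,
#'   `group`).
#' @export
tidy.signature_survival <- function(x, ...) x$scores

#' One-row summary of a signature survival fit
#'
#' @param x A `signature_survival` object.
#' @param ... Unused.
#' @return One-row tibble: group sizes, log-rank statistic and p-value.
#' @export
glance.signature_survival <- function(x, ...) {
  tibble::tibble(n_high = sum(x$scores$group == "high"),
                 n_low = sum(x$scores$group == "low"),
                 statistic = x$logrank$chi_square,
                 p_value = x$logrank$p_value)
}

#' Classification summary of a screen
#'
#' @param x A `mirna_screen` tibble.
#' @param ... Unused.
#' @return One-row tibble with the cutoffs used and per-label counts.
#' @export
glance.mirna_screen <- function(x, ...) {
  co <- attr(x, "cutoffs")
  tibble::tibble(cv_cutoff = co[["cv"]], corr_cutoff = co[["corr"]],
                 n_tumor_suppressor = sum(x$label == "tumor_suppressor"),
                 n_oncomir = sum(x$label == "oncomiR"),
                 n_unclassified = sum(x$label == "unclassified"))
}
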