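#' Relative quantification by the delta-delta-Ct method
#'
#' Per record, delta-Ct = target Ct minus housekeeping Ct (several
#' housekeeping columns are averaged per record first).
#' Delta-delta-Ct is the mean treated delta-Ct minus the mean control
#' delta-Ct, and the fold change is \eqn{2^{-\Delta\Delta Ct}}, so the
#' control condition sits at fold 1.
#'
#' @param ct_table Tibble with columns `condition`
#'   (`"control"`/`"treated"`), `target_ct`, and one or more housekeeping
#'   Ct columns.
#' @param housekeeping Names of the housekeeping Ct columns.
#' @return A list with `delta_ct` (the input plus a `delta_ct` column),
#'   `ddct`, and `fold`.
#' @export
#' @examples
#' ct <- sim_ct_table(true_fold_change = 0.5, seed = 1)
#' ddct_fold_change(ct)$fold # 0.5
ddct_fold_change <- function(ct_table, housekeeping = "housekeeping_ct") {
  stopifnot(all(c("condition", "target_ct") %in% names(ct_table)),
            all(housekeeping %in% names(ct_table)))
  conds <- unique(ct_table$condition)
  if (!all(c("control", "treated") %in% conds)) {
    stop("ct_table must contain both 'control' and 'treated' records")
  }
  hk <- rowMeans(as.matrix(ct_table[, housekeeping, drop = FALSE]))
  ct_table$delta_ct <- ct_table$target_ct - hk
  dct_t <- mean(ct_table$delta_ct[ct_table$condition == "treated"])
  dct_c <- mean(ct_table$delta_ct[ct_table$condition == "control"])
  ddct <- dct_t - dct_c
  list(delta_ct = ct_table, ddct = ddct, fold = 2^(-ddct))
}

#' Normalize RTCA series to the transfection time point
#'
#' Divides each well's cell-index trace by its value at the transfection
#' time point, so every well equals 1 at transfection.
#'
#' @param series Tibble with a `time` column and one numeric column per
#'   well.
#' @param transfection_time A value of `time` present in the grid.
#' @return The normalized series tibble.
#' @export
#' @examples
#' rtca_normalize(tibble::tibble(time = 0:2, w1 = c(2, 4, 8)), 0)
rtca_normalize <- function(series, transfection_time) {
  stopifnot("time" %in% names(series))
  i0 <- which(series$time == transfection_time)
  if (length(i0) != 1L) {
    stop("transfection_time must match exactly one point of the time grid")
  }
  wells <- setdiff(names(series), "time")
  for (w in wells) {
    v0 <- series[[w]][[i0]]
    if (!is.finite(v0) || v0 == 0) {
      stop("well '", w, "' has zero or missing index at transfection time")
    }
    series[[w]] <- series[[w]] / v0
  }
  series
}

#' Two-group Student t-test
#'
#' Two-tailed Student t-test (equal-variance by default, Welch optional),
#' paired or unpaired. Degenerate zero-variance comparisons with equal
#' means return t = 0, p = 1 by convention.
#'
#' @param a,b Numeric vectors; equal lengths when `paired`.
#' @param paired Pair observations (test on differences)?
#' @param var_equal Pool variances (classical Student test)? Ignored when
#'   paired.
#' @return A tibble with columns `t`, `p_value`, `df`, `paired`.
#' @export
two_group_test <- function(a, b, paired = FALSE, var_equal = TRUE) {
  if (paired && length(a) != length(b)) {
    stop("paired test requires equal-length vectors")
  }
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  degenerate <- if (paired) stats::sd(a - b) == 0 else {
    stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)
  }
  if (degenerate) {
    df <- if (paired) length(a) - 1L else length(a) + length(b) - 2L
    return(tibble::tibble(t = 0, p_value = 1, df = df, paired = paired))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), paired = paired)
}
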