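#' Signed oncogene/tumor-suppressor class vector
#'
#' Encodes the protein panel's annotation as +1 for oncogenic and -1 for
#' tumor-suppressor proteins, in the column order of the screen matrix.
#' A miRNA whose readout profile correlates negatively with this vector
#' represses oncogenes and de-represses tumor suppressors — the operational
#' tumor-suppressor-miRNA pattern.
#'
#' @param annotation Tibble with columns `protein` and `cls`
#'   (`"oncogenic"` or `"tumor_suppressor"`).
#' @param proteins Character vector of protein ids in matrix column order.
#' @return Named numeric vector of +1/-1 along `proteins`.
#' @export
class_vector <- function(annotation, proteins) {
  idx <- match(proteins, annotation$protein)
  if (anyNA(idx)) {
    stop("unannotated protein(s): ",
         paste(proteins[is.na(idx)], collapse = ", "))
  }
  cls <- annotation$cls[idx]
  bad <- setdiff(unique(cls), c("oncogenic", "tumor_suppressor"))
  if (length(bad)) stop("unknown protein class: ", paste(bad, collapse = ", "))
  v <- ifelse(cls == "oncogenic", 1, -1)
  if (length(unique(v)) < 2L) {
    stop("degenerate class vector: both oncogenic and tumor_suppressor ",
         "proteins are required")
  }
  stats::setNames(v, proteins)
}

#' Coefficient of variation of a readout profile
#'
#' sd/|mean| with the sample SD, used as a flatness filter: a miRNA whose
#' readout barely varies across the protein panel carries no classifiable
#' signal. Missing values are dropped; a zero mean yields `Inf` (a maximally
#' variable profile, passing any finite cutoff).
#'
#' @param x Numeric readout vector.
#' @return A single non-negative number (possibly `Inf`).
#' @export
#' @examples
#' mirna_cv(c(1, 3)) # sqrt(2)/2
mirna_cv <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values to compute a CV")
  m <- mean(x)
  if (m == 0) return(Inf)
  stats::sd(x) / abs(m)
}

#' Correlation of a readout profile with the class vector
#'
#' Pearson (default) or Spearman correlation between a miRNA's readout
#' changes and the signed +1/-1 protein class vector; with Pearson this is
#' the point-biserial correlation. Pairs with a missing readout are dropped.
#' A zero-variance profile has no defined correlation and returns `NA`.
#'
#' @param x Numeric readout vector.
#' @param cvec Signed class vector from [class_vector()], same length.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
mirna_correlation <- function(x, cvec, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(cvec))
  ok <- is.finite(x) & is.finite(cvec)
  if (sum(ok) < 3L) stop("need at least 3 paired finite values")
  if (stats::sd(cvec[ok]) == 0) stop("class vector is constant on the paired values")
  if (stats::sd(x[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], cvec[ok], method = method)
}

#' Classify screen miRNAs as tumor suppressors or oncomiRs
#'
#' Scores every miRNA of a mimic-screen readout matrix by its coefficient of
#' variation and its correlation with the oncogene/tumor-suppressor class
#' vector, then labels it `tumor_suppressor` (cv >= `cv_cutoff` and
#' r <= -`corr_cutoff`), `oncomiR` (cv >= `cv_cutoff` and
#' r >= +`corr_cutoff`), or `unclassified`. Cutoffs are inclusive.
#'
#' @param readouts Tibble whose first column is the miRNA id and whose
#'   remaining numeric columns are per-protein readout changes.
#' @param annotation Protein annotation tibble (see [class_vector()]).
#' @param cv_cutoff,corr_cutoff Selection cutoffs; defaults 0.25 and 0.5.
#' @param method Correlation type passed to [mirna_correlation()].
#' @return A tibble of class `mirna_screen` with columns `mirna`, `cv`, `r`,
#'   `label`.
#' @export
#' @examples
#' sim <- sim_screen(n_mirnas = 50, seed = 1)
#' classify_mirnas(sim$readouts, sim$annotation) |> dplyr::count(label)
classify_mirnas <- function(readouts, annotation,
                            cv_cutoff = 0.25, corr_cutoff = 0.5,
                            method = "pearson") {
  mat <- screen_matrix(readouts)
  cvec <- class_vector(annotation, colnames(mat))
  cv <- apply(mat, 1L, mirna_cv)
  r <- apply(mat, 1L, mirna_correlation, cvec = cvec, method = method)
  label <- dplyr::case_when(
    is.na(r) ~ "unclassified",
    cv >= cv_cutoff & r <= -corr_cutoff ~ "tumor_suppressor",
    cv >= cv_cutoff & r >= corr_cutoff ~ "oncomiR",
    TRUE ~ "unclassified"
  )
  out <- tibble::tibble(mirna = readouts[[1L]], cv = unname(cv),
                        r = unname(r), label = label)
  class(out) <- c("mirna_screen", class(out))
  attr(out, "cutoffs") <- c(cv = cv_cutoff, corr = corr_cutoff)
  out
}

#' Per-pathway co-regulation flags
#'
#' For each classified miRNA and each pathway group, averages the signed
#' effect (readout change times the +1/-1 class sign) over the pathway's
#' proteins: a negative mean means the miRNA pushes that pathway's oncogenic
#' output down (`"down"`), positive means up, exactly zero is `"neutral"`.
#'
#' @param results `mirna_screen` tibble from [classify_mirnas()].
#' @param readouts The screen readout tibble used for classification.
#' @param annotation Protein annotation tibble with `pathway` column.
#' @return `results` with one `coreg_<pathway>` column per pathway group.
#' @export
pathway_coregulation <- function(results, readouts, annotation) {
  mat <- screen_matrix(readouts)
  stopifnot(identical(results$mirna, readouts[[1L]]))
  cvec <- class_vector(annotation, colnames(mat))
  pathways <- unique(annotation$pathway)
  signed <- sweep(mat, 2L, cvec, `*`)
  for (pw in pathways) {
    cols <- annotation$protein[annotation$pathway == pw]
    cols <- intersect(colnames(mat), cols)
    if (!length(cols)) stop("pathway '", pw, "' has no proteins in the matrix")
    m <- rowMeans(signed[, cols, drop = FALSE], na.rm = TRUE)
    results[[paste0("coreg_", pw)]] <-
      dplyr::case_when(m < 0 ~ "down", m > 0 ~ "up", TRUE ~ "neutral")
  }
  results
}

#' Select candidate tumor-suppressor miRNAs
#'
#' Returns the miRNAs labelled `tumor_suppressor` whose signed effect is
#' `"down"` in every pathway group, sorted by ascending correlation (most
#' negative, i.e. strongest tumor-suppressor pattern, first); ties break on
#' the miRNA id so the list is independent of input row order.
#'
#' @param results Output of [pathway_coregulation()].
#' @return Character vector of candidate miRNA ids.
#' @export
select_candidates <- function(results) {
  coreg_cols <- grep("^coreg_", names(results), value = TRUE)
  if (!length(coreg_cols)) {
    stop("results carry no pathway co-regulation flags; ",
         "run pathway_coregulation() first")
  }
  all_down <- Reduce(`&`, lapply(results[coreg_cols], `==`, "down"))
  keep <- results$label == "tumor_suppressor" & all_down
  cand <- results[keep, , drop = FALSE]
  cand$mirna[order(cand$r, cand$mirna)]
}

#' Hierarchically cluster classified miRNAs
#'
#' Agglomerative clustering of miRNA readout profiles (Euclidean distance,
#' average linkage by default) for heatmap row ordering. Missing readouts
#' are imputed to the row mean before clustering.
#'
#' @param readouts Screen readout tibble (first column miRNA id); typically
#'   restricted to classified miRNAs.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list with `order` (miRNA ids in leaf order), `heights` (merge
#'   heights), and the underlying `hclust` object.
#' @export
cluster_mirnas <- function(readouts, linkage = "average") {
  mat <- screen_matrix(readouts)
  if (nrow(mat) < 2L) stop("need at least 2 miRNAs to cluster")
  nimp <- sum(!is.finite(mat))
  if (nimp > 0L) {
    message("imputing ", nimp, " missing readout(s) to row means before clustering")
    for (i in seq_len(nrow(mat))) {
      bad <- !is.finite(mat[i, ])
      if (any(bad)) mat[i, bad] <- mean(mat[i, !bad])
    }
  }
  rownames(mat) <- readouts[[1L]]
  hc <- stats::hclust(stats::dist(mat), method = linkage)
  list(order = readouts[[1L]][hc$order], heights = hc$height, hclust = hc)
}

# first column = ids, remaining numeric columns -> matrix
screen_matrix <- function(readouts) {
  stopifnot(is.data.frame(readouts), ncol(readouts) >= 2L)
  ids <- readouts[[1L]]
  if (anyDuplicated(ids)) stop("duplicated row id(s) in readout table")
  mat <- as.matrix(readouts[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("readout columns must be numeric")
  mat
}
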