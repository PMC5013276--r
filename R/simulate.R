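#' Simulate an RPPA miRNA-mimic screen
#'
#' Generates a miRNA-by-protein readout matrix with the structure a
#' mimic-screen re-analysis assumes: a panel of proteins labelled oncogenic
#' or tumor-suppressor and grouped into PI3K, MAPK and cell-cycle pathways;
#' a set of planted tumor-suppressor miRNAs whose expected readout change is
#' `-effect_size` on oncogenic proteins and `+effect_size` on
#' tumor-suppressor proteins; planted oncomiRs with the mirrored pattern;
#' and Gaussian noise everywhere. Defaults match the screen scale the
#' pipeline is designed for: 733 miRNAs against 16 proteins.
#'
#' @param n_mirnas,n_proteins Matrix dimensions.
#' @param n_onco_proteins Number of proteins labelled oncogenic; the rest are
#'   tumor suppressors. Both classes must be represented.
#' @param n_planted_ts,n_planted_onco Numbers of planted tumor-suppressor
#'   miRNAs and oncomiRs.
#' @param effect_size Mean absolute readout change on targeted proteins for
#'   planted miRNAs.
#' @param noise_sd Standard deviation of the Gaussian readout noise (>= 0;
#'   0 gives the noiseless limit).
#' @param seed Integer seed; the same seed reproduces the same screen.
#' @return A list with `readouts` (tibble: `mirna` + one numeric column per
#'   protein), `annotation` (tibble: `protein`, `cls`, `pathway`), and
#'   `truth` (tibble: `mirna`, `planted` in
#'   `c("tumor_suppressor", "oncomiR", "none")`).
#' @export
#' @examples
#' sim <- sim_screen(n_mirnas = 20, n_proteins = 8, seed = 1)
#' sim$annotation
sim_screen <- function(n_mirnas = 733L, n_proteins = 16L,
                       n_onco_proteins = 10L,
                       n_planted_ts = 20L, n_planted_onco = 20L,
                       effect_size = 1, noise_sd = 0.3, seed = 1L) {
  stopifnot(n_mirnas >= 1L, n_proteins >= 2L,
            n_onco_proteins >= 1L, n_onco_proteins < n_proteins,
            n_planted_ts >= 0L, n_planted_onco >= 0L,
            effect_size >= 0, noise_sd >= 0)
  if (n_planted_ts + n_planted_onco > n_mirnas) {
    stop("n_planted_ts + n_planted_onco exceeds n_mirnas")
  }
  mirnas <- sprintf("miR-%04d", seq_len(n_mirnas))
  proteins <- sprintf("prot%02d", seq_len(n_proteins))
  cls <- rep(c("oncogenic", "tumor_suppressor"),
             c(n_onco_proteins, n_proteins - n_onco_proteins))
  pathway <- rep_len(c("PI3K", "MAPK", "cell_cycle"), n_proteins)
  annotation <- tibble::tibble(protein = proteins, cls = cls, pathway = pathway)
  csign <- ifelse(cls == "oncogenic", 1, -1)

  planted <- rep("none", n_mirnas)
  if (n_planted_ts > 0L) planted[seq_len(n_planted_ts)] <- "tumor_suppressor"
  if (n_planted_onco > 0L) {
    planted[n_planted_ts + seq_len(n_planted_onco)] <- "oncomiR"
  }

  withr::with_seed(seed, {
    vals <- matrix(stats::rnorm(n_mirnas * n_proteins, sd = noise_sd),
                   nrow = n_mirnas)
    # TS miRNA pushes oncogenic readouts down, tumor-suppressor readouts up
    mean_effect <- outer(
      ifelse(planted == "tumor_suppressor", -effect_size,
             ifelse(planted == "oncomiR", effect_size, 0)),
      csign
    )
    vals <- vals + mean_effect
    # randomize planted row positions so selection cannot rely on order
    perm <- sample.int(n_mirnas)
  })
  vals <- vals[perm, , drop = FALSE]
  planted <- planted[perm]
  colnames(vals) <- proteins

  readouts <- dplyr::bind_cols(
    tibble::tibble(mirna = mirnas),
    tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  )
  list(readouts = readouts,
       annotation = annotation,
       truth = tibble::tibble(mirna = mirnas, planted = planted))
}

#' Simulate per-database miRNA target prediction tables
#'
#' Emulates four prediction databases as independent detectors of a planted
#' target set: a TargetScan-like table with conservation flags, a DIANA-like
#' table with miTG scores, a PITA-like table with ddG accessibility scores,
#' and an unscored miRWalk-like table. Each true target is detected by each
#' database independently with probability `per_db_recall`, each decoy with
#' probability `per_db_fpr`; detected records receive scores that pass the
#' database's standard cutoff (miTG > 0.7, ddG < -10, conserved site).
#' Undetected genes may still appear as sub-threshold records, which the
#' filtering stage must remove.
#'
#' @param mirna miRNA identifier for all records.
#' @param true_targets,decoys Character vectors of gene symbols; must be
#'   non-empty and disjoint.
#' @param per_db_recall,per_db_fpr Per-database detection probabilities in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @return A list with `predictions` (tibble: `mirna`, `gene`, `db`,
#'   `score`, `conserved`) and `truth` (the planted target set).
#' @export
sim_prediction_tables <- function(mirna, true_targets, decoys,
                                  per_db_recall = 0.9, per_db_fpr = 0.05,
                                  seed = 1L) {
  if (!length(true_targets) || !length(decoys)) {
    stop("true_targets and decoys must both be non-empty")
  }
  if (length(intersect(true_targets, decoys))) {
    stop("true_targets and decoys must be disjoint")
  }
  stopifnot(per_db_recall >= 0, per_db_recall <= 1,
            per_db_fpr >= 0, per_db_fpr <= 1)
  genes <- c(true_targets, decoys)
  p_detect <- rep(c(per_db_recall, per_db_fpr),
                  c(length(true_targets), length(decoys)))
  dbs <- c("targetscan", "diana", "pita", "mirwalk")

  one_db <- function(db) {
    detected <- stats::runif(length(genes)) < p_detect
    # sub-threshold noise records for a third of the undetected genes
    noise <- !detected & stats::runif(length(genes)) < 1 / 3 & db != "mirwalk"
    n_d <- sum(detected); n_n <- sum(noise)
    rec <- tibble::tibble(
      mirna = mirna,
      gene = c(genes[detected], genes[noise]),
      db = db,
      score = NA_real_,
      conserved = NA
    )
    if (db == "diana") {
      rec$score <- c(stats::runif(n_d, 0.7, 1), stats::runif(n_n, 0, 0.7))
    } else if (db == "pita") {
      rec$score <- c(stats::runif(n_d, -30, -10), stats::runif(n_n, -10, 0))
    } else if (db == "targetscan") {
      rec$conserved <- rep(c(TRUE, FALSE), c(n_d, n_n))
    }
    rec
  }

  predictions <- withr::with_seed(seed, purrr::map_dfr(dbs, one_db))
  list(predictions = predictions,
       truth = tibble::tibble(gene = genes,
                              is_target = genes %in% true_targets))
}

#' Simulate a gene-expression cohort with survival outcomes
#'
#' Generates a microarray-style gene-by-sample expression matrix (per-gene
#' Gaussian with gene-specific mean and SD on a log2-like scale) and a
#' survival table whose hazard depends log-linearly on the cohort's
#' min-max-normalized target-network z-score: event times are exponential
#' with rate `baseline_hazard * exp(log_hazard_per_unit_score * s)` where
#' `s` in \[0, 1\] is the normalized sum of signature-gene z-scores.
#' Censoring is independent exponential, calibrated so that roughly
#' `censor_rate` of subjects are censored before their event under the
#' baseline hazard, plus administrative censoring at `followup_max`.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param signature_genes Gene symbols carrying the survival signal; they
#'   are included among the generated genes.
#' @param log_hazard_per_unit_score Log hazard ratio between the extremes of
#'   the normalized score (0 gives the null cohort).
#' @param baseline_hazard Events per time unit at score 0 (> 0).
#' @param censor_rate Target random-censoring fraction in \[0, 1).
#' @param followup_max Administrative follow-up horizon (time units).
#' @param seed Integer seed.
#' @return A list with `expr` (tibble: `gene` + one column per sample),
#'   `surv` (tibble: `sample`, `time`, `event`), and `truth` (generating
#'   parameters plus the true per-sample normalized score).
#' @export
sim_cohort <- function(n_samples = 216L, n_genes = 200L,
                       signature_genes = c("AKT2", "GNA12", "GYS1", "SRF"),
                       log_hazard_per_unit_score = 1,
                       baseline_hazard = 0.08, censor_rate = 0.2,
                       followup_max = 10, seed = 1L) {
  stopifnot(n_samples >= 4L, n_genes >= length(signature_genes),
            length(signature_genes) >= 1L, followup_max > 0)
  if (!is.finite(baseline_hazard) || baseline_hazard <= 0) {
    stop("baseline_hazard must be positive")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must be in [0, 1)")
  }
  n_extra <- n_genes - length(signature_genes)
  genes <- c(signature_genes,
             if (n_extra > 0L) sprintf("gene%04d", seq_len(n_extra)))
  samples <- sprintf("S%04d", seq_len(n_samples))

  withr::with_seed(seed, {
    gene_mean <- stats::runif(n_genes, 6, 10)
    gene_sd <- stats::runif(n_genes, 0.5, 1.5)
    vals <- matrix(stats::rnorm(n_genes * n_samples, mean = gene_mean,
                                sd = gene_sd),
                   nrow = n_genes)
    rownames(vals) <- genes
    z <- t(apply(vals[signature_genes, , drop = FALSE], 1L, function(x) {
      (x - mean(x)) / stats::sd(x) * sqrt((n_samples - 1) / n_samples)
    }))
    raw_score <- colSums(z)
    s <- (raw_score - min(raw_score)) / (max(raw_score) - min(raw_score))
    rate <- baseline_hazard * exp(log_hazard_per_unit_score * s)
    t_event <- stats::rexp(n_samples, rate = rate)
    t_cens <- if (censor_rate > 0) {
      stats::rexp(n_samples,
                  rate = baseline_hazard * censor_rate / (1 - censor_rate))
    } else {
      rep(Inf, n_samples)
    }
  })
  time <- pmin(t_event, t_cens, followup_max)
  event <- as.integer(t_event <= pmin(t_cens, followup_max))

  expr <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(as.data.frame(vals, check.names = FALSE) |>
                        stats::setNames(samples))
  )
  list(
    expr = expr,
    surv = tibble::tibble(sample = samples, time = time, event = event),
    truth = list(signature_genes = signature_genes,
                 log_hazard_per_unit_score = log_hazard_per_unit_score,
                 baseline_hazard = baseline_hazard,
                 score = tibble::tibble(sample = samples, score_true = s))
  )
}

#' Simulate a qPCR Ct table
#'
#' Generates paired control/treated Ct records whose expected
#' \eqn{2^{-\Delta\Delta Ct}} equals `true_fold_change`: treated target Ct
#' values are shifted by \eqn{-\log_2(\mathrm{fold})} relative to control,
#' with optional Gaussian noise on every Ct measurement.
#'
#' @param n_samples Replicates per condition.
#' @param true_fold_change True expression ratio treated/control (> 0).
#' @param ct_noise_sd SD of Gaussian noise added to each Ct (>= 0).
#' @param seed Integer seed.
#' @param housekeeping_ct,baseline_delta_ct Mean housekeeping Ct and mean
#'   control-condition delta-Ct, setting the (arbitrary) Ct scale.
#' @return A tibble with columns `sample`, `condition`, `target_ct`,
#'   `housekeeping_ct`, `replicate`.
#' @export
sim_ct_table <- function(n_samples = 6L, true_fold_change = 1,
                         ct_noise_sd = 0, seed = 1L,
                         housekeeping_ct = 18, baseline_delta_ct = 6) {
  if (!is.finite(true_fold_change) || true_fold_change <= 0) {
    stop("true_fold_change must be positive")
  }
  stopifnot(n_samples >= 1L, ct_noise_sd >= 0)
  shift <- -log2(true_fold_change)
  withr::with_seed(seed, {
    noise <- function(n) stats::rnorm(n, sd = ct_noise_sd)
    hk <- housekeeping_ct + noise(2L * n_samples)
    tgt <- c(housekeeping_ct + baseline_delta_ct + noise(n_samples),
             housekeeping_ct + baseline_delta_ct + shift + noise(n_samples))
  })
  tibble::tibble(
    sample = sprintf("%s_%02d", rep(c("ctrl", "trt"), each = n_samples),
                     rep(seq_len(n_samples), 2L)),
    condition = rep(c("control", "treated"), each = n_samples),
    target_ct = tgt,
    housekeeping_ct = hk,
    replicate = rep(seq_len(n_samples), 2L)
  )
}
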