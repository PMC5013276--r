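#' Default per-database prediction filtering rules
#'
#' The standard filtering rules for the four prediction databases: keep
#' TargetScan targets with conserved sites only, DIANA targets with an miTG
#' score strictly greater than 0.7, PITA targets with a ddG score strictly
#' less than -10, and all miRWalk targets (no cutoff).
#'
#' @return A tibble with columns `db`, `score_field`, `direction`,
#'   `threshold`, `require_conserved`.
#' @export
db_rules <- function() {
  tibble::tibble(
    db = c("targetscan", "diana", "pita", "mirwalk"),
    score_field = c("none", "miTG", "ddG", "none"),
    direction = c("none", "greater_than", "less_than", "none"),
    threshold = c(NA_real_, 0.7, -10, NA_real_),
    require_conserved = c(TRUE, FALSE, FALSE, FALSE)
  )
}

#' Filter prediction tables by database rules
#'
#' Applies each database's score rule to its records. Duplicate
#' (mirna, gene) records within a database collapse to the best score first
#' (maximum for a `greater_than` rule, minimum for `less_than`); thresholds
#' are strict inequalities. Unscored databases pass every record, subject to
#' the conservation flag where required.
#'
#' @param predictions Tibble with columns `mirna`, `gene`, `db`, `score`,
#'   `conserved` (scores/flags `NA` where a database has none).
#' @param rules Rule tibble as from [db_rules()].
#' @return Tibble of passing records: `mirna`, `gene`, `db`.
#' @export
#' @examples
#' preds <- tibble::tibble(
#'   mirna = "miR-x", gene = c("A", "B"), db = "diana",
#'   score = c(0.8, 0.7), conserved = NA
#' )
#' filter_predictions(preds, db_rules()) # keeps A only: 0.7 is not > 0.7
filter_predictions <- function(predictions, rules = db_rules()) {
  stopifnot(all(c("mirna", "gene", "db") %in% names(predictions)))
  unknown <- setdiff(unique(predictions$db), rules$db)
  if (length(unknown)) {
    stop("no filtering rule for database(s): ", paste(unknown, collapse = ", "))
  }
  purrr::map_dfr(unique(predictions$db), function(d) {
    rule <- rules[rules$db == d, ]
    rec <- predictions[predictions$db == d, , drop = FALSE]
    if (rule$direction != "none") {
      if (!"score" %in% names(rec) || all(is.na(rec$score))) {
        stop("database '", d, "' rule needs score field '", rule$score_field,
             "' but records carry no scores")
      }
      best <- if (rule$direction == "greater_than") max else min
      rec <- rec |>
        dplyr::group_by(.data$mirna, .data$gene) |>
        dplyr::summarise(score = best(.data$score, na.rm = TRUE),
                         conserved = any(.data$conserved %in% TRUE),
                         .groups = "drop") |>
        dplyr::mutate(db = d)
      keep <- if (rule$direction == "greater_than") {
        rec$score > rule$threshold
      } else {
        rec$score < rule$threshold
      }
      rec <- rec[keep & !is.na(keep), , drop = FALSE]
    } else {
      rec <- dplyr::distinct(rec, .data$mirna, .data$gene, .keep_all = TRUE)
    }
    if (isTRUE(rule$require_conserved)) {
      rec <- rec[rec$conserved %in% TRUE, , drop = FALSE]
    }
    rec[, c("mirna", "gene", "db")]
  })
}

#' Multi-database consensus target set
#'
#' Genes supported by at least `min_databases` of the filtered prediction
#' databases, with their supporting-database lists. The conventional rule keeps
#' targets common to two or more databases.
#'
#' @param filtered Filtered records from [filter_predictions()] (columns
#'   `mirna`, `gene`, `db`).
#' @param min_databases Minimum supporting databases (>= 1, at most the
#'   number of databases present).
#' @return A tibble of class `consensus_targets`: `mirna`, `gene`, `n_dbs`,
#'   `dbs` (list column), sorted by descending support.
#' @export
consensus_targets <- function(filtered, min_databases = 2L) {
  n_db <- dplyr::n_distinct(filtered$db)
  if (min_databases < 1L) stop("min_databases must be >= 1")
  if (nrow(filtered) && min_databases > n_db) {
    stop("min_databases (", min_databases, ") exceeds the ", n_db,
         " databases supplied")
  }
  out <- filtered |>
    dplyr::distinct(.data$mirna, .data$gene, .data$db) |>
    dplyr::group_by(.data$mirna, .data$gene) |>
    dplyr::summarise(n_dbs = dplyr::n_distinct(.data$db),
                     dbs = list(sort(unique(.data$db))), .groups = "drop") |>
    dplyr::filter(.data$n_dbs >= min_databases) |>
    dplyr::arrange(dplyr::desc(.data$n_dbs), .data$gene)
  class(out) <- c("consensus_targets", class(out))
  attr(out, "min_databases") <- as.integer(min_databases)
  out
}

#' Annotate consensus targets with pathway membership
#'
#' Looks each consensus target up in a gene-set collection (exact symbol
#' match) and records the sets containing it. This is membership lookup,
#' not an enrichment test.
#'
#' @param targets `consensus_targets` tibble.
#' @param gene_sets Gene-set tibble from [read_gmt()] (columns `set`,
#'   `gene`).
#' @param pathways Optional character vector: when given, an `in_pathway`
#'   flag marks targets belonging to at least one of the named sets.
#' @return `targets` with a `pathways` list column (and optionally
#'   `in_pathway`).
#' @export
annotate_pathways <- function(targets, gene_sets, pathways = NULL) {
  if (!nrow(gene_sets)) {
    warning("empty gene-set collection; all pathway annotations are empty")
  }
  targets$pathways <- lapply(targets$gene, function(g) {
    unique(gene_sets$set[gene_sets$gene == g])
  })
  if (!is.null(pathways)) {
    targets$in_pathway <- vapply(targets$pathways,
                                 function(p) any(p %in% pathways), logical(1))
  }
  targets
}

#' Venn region counts across filtered databases
#'
#' Counts the genes falling in every overlap region of the per-database
#' filtered sets (membership-pattern counts, as drawn in a Venn diagram).
#' Region counts sum to the size of the union.
#'
#' @param filtered Filtered records (columns `gene`, `db`) from
#'   [filter_predictions()].
#' @return A tibble with one row per non-empty membership pattern: one
#'   logical column per database, plus `n_genes`.
#' @export
venn_counts <- function(filtered) {
  dbs <- sort(unique(filtered$db))
  if (length(dbs) < 2L) stop("need at least 2 databases for Venn counts")
  member <- filtered |>
    dplyr::distinct(.data$gene, .data$db) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "db", values_from = "present",
                       values_fill = FALSE) |>
    dplyr::select(dplyr::all_of(c("gene", dbs)))
  member |>
    dplyr::count(dplyr::across(dplyr::all_of(dbs)), name = "n_genes") |>
    dplyr::arrange(dplyr::desc(rowSums(dplyr::pick(dplyr::all_of(dbs)))))
}
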