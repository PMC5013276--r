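#' Read a delimited matrix table
#'
#' Reads a tab-separated matrix with one header row and identifiers in the
#' first column, the layout used by GEO-style series matrices and screen
#' exports. Non-numeric cells become `NA` (with a warning); duplicated row or
#' column identifiers are rejected.
#'
#' @param path Path to a TSV file.
#' @param id_col Name to give the identifier column of the returned tibble.
#'   Defaults to the header of the first column, or `"id"` when that header
#'   is empty.
#' @return A tibble whose first column holds the row identifiers and whose
#'   remaining columns are numeric.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("mirna\tp1\tp2", "miR-1\t0.5\t-1.2", "miR-2\t0.1\t0.3"), tf)
#' read_matrix_tsv(tf)
read_matrix_tsv <- function(path, id_col = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("malformed matrix file '", path, "': need a header row and at least one data row")
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header at line 1 of '", path, "': fewer than two columns")
  }
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids)) {
    stop("duplicated column id(s) at line 1: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad)) {
    stop("line ", bad[[1L]] + 1L, " of '", path, "' has ",
         lengths(rows)[bad[[1L]]], " fields; expected ", length(header))
  }
  row_ids <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(row_ids)) {
    dup <- unique(row_ids[duplicated(row_ids)])
    stop("duplicated row id(s): ", paste(dup, collapse = ", "))
  }
  vals <- vapply(rows, function(r) {
    x <- r[-1L]
    x[x %in% c("NA", "")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }, numeric(length(col_ids)))
  vals <- matrix(vals, ncol = length(col_ids), byrow = TRUE,
                 dimnames = list(NULL, col_ids))
  raw <- do.call(rbind, lapply(rows, function(r) r[-1L]))
  n_coerced <- sum(is.na(vals) & !(raw %in% c("NA", "")))
  if (n_coerced > 0L) {
    warning(n_coerced, " non-numeric cell(s) set to NA in '", path, "'")
  }
  if (is.null(id_col)) id_col <- if (nzchar(header[[1L]])) header[[1L]] else "id"
  out <- tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := row_ids), out)
  out
}

#' Write a matrix table to TSV
#'
#' Inverse of [read_matrix_tsv()]: first column identifiers, remaining
#' columns numeric, `NA` written as the literal `NA`.
#'
#' @param x A tibble as returned by [read_matrix_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then gene symbols, all
#' tab-separated. Genes within a set are deduplicated; duplicated set names
#' are rejected.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description`, `gene` (one row per
#'   set-gene pair). Use [gene_set_list()] for the named-list view.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(set = character(), description = character(),
                          gene = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop("line ", short[[1L]], " of '", path,
         "' has fewer than 3 tab-separated fields")
  }
  sets <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(sets)) {
    stop("duplicated set name(s): ",
         paste(unique(sets[duplicated(sets)]), collapse = ", "))
  }
  purrr::map2_dfr(parts, sets, function(p, s) {
    tibble::tibble(set = s, description = p[[2L]], gene = unique(p[-(1:2)]))
  })
}

#' Write gene sets to GMT
#'
#' @param gmt A tibble with columns `set`, `description`, `gene`, as from
#'   [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gmt, path) {
  stopifnot(all(c("set", "description", "gene") %in% names(gmt)))
  lines <- gmt |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(
      line = paste(c(.data$set[[1L]], .data$description[[1L]], .data$gene),
                   collapse = "\t"),
      .groups = "drop"
    )
  # preserve input order of first appearance
  ord <- match(unique(gmt$set), lines$set)
  writeLines(lines$line[ord], path)
  invisible(path)
}

#' Named-list view of a gene-set tibble
#'
#' @param gmt A tibble from [read_gmt()].
#' @return A named list mapping set name to a character vector of genes.
#' @export
gene_set_list <- function(gmt) {
  split(gmt$gene, factor(gmt$set, levels = unique(gmt$set)))
}

#' Pipeline run configuration
#'
#' Bundles the analysis cutoffs with validation. Defaults are the pipeline's
#' reference constants: a coefficient-of-variation cutoff of 0.25, a
#' correlation cutoff of |0.5|, and a two-or-more-database consensus rule.
#'
#' @param cv_cutoff Minimum per-miRNA coefficient of variation (>= 0).
#' @param corr_cutoff Minimum |Pearson r| against the protein class vector,
#'   in (0, 1].
#' @param min_databases Minimum number of prediction databases supporting a
#'   consensus target (>= 1).
#' @param followup_years Follow-up horizon for administrative censoring, in
#'   years.
#' @param seed Integer seed recorded with the run.
#' @return A list of class `mirscreen_config`.
#' @export
#' @examples
#' run_config()
run_config <- function(cv_cutoff = 0.25, corr_cutoff = 0.5,
                       min_databases = 2L, followup_years = 5,
                       seed = 1L) {
  cfg <- list(cv_cutoff = as.numeric(cv_cutoff),
              corr_cutoff = as.numeric(corr_cutoff),
              min_databases = as.integer(min_databases),
              followup_years = as.numeric(followup_years),
              seed = as.integer(seed))
  problems <- character()
  if (!is.finite(cfg$cv_cutoff) || cfg$cv_cutoff < 0) {
    problems <- c(problems, "cv_cutoff must be >= 0")
  }
  if (!is.finite(cfg$corr_cutoff) || cfg$corr_cutoff <= 0 || cfg$corr_cutoff > 1) {
    problems <- c(problems, "corr_cutoff must be in (0, 1]")
  }
  if (is.na(cfg$min_databases) || cfg$min_databases < 1L) {
    problems <- c(problems, "min_databases must be >= 1")
  }
  if (!is.finite(cfg$followup_years) || cfg$followup_years <= 0) {
    problems <- c(problems, "followup_years must be > 0")
  }
  if (length(problems)) {
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "mirscreen_config")
}

#' @export
print.mirscreen_config <- function(x, ...) {
  cat("mirscreen run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Missing fields take the documented defaults of [run_config()];
#' out-of-range values raise a validation error naming the field.
#'
#' @param path Path to a YAML file (may be empty).
#' @return A `mirscreen_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param config A `mirscreen_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mirscreen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
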