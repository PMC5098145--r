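#' Cohort file readers and the risk report writer
#'
#' Canonical on-disk formats are tab-separated, UTF-8, decimal-point numbers
#' (comma-separated accepted on read by file extension). Patient order is
#' preserved from the input; nothing is sorted silently.
#'
#' @name cohort-io
NULL

file_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression/clinical variable matrix
#'
#' Expects variables in rows and patients in columns: the first column holds
#' variable ids, the header row holds patient ids.
#'
#' @param path TSV (or CSV) file path.
#' @return numeric matrix, variables x patients, with variable row names and
#'   patient column names.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = file_delim(path), header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) abort("expression matrix needs an id column and at least one patient")
  vars <- raw[[1]]
  if (anyDuplicated(vars)) {
    abort(sprintf("duplicated variable id: %s", vars[duplicated(vars)][1]))
  }
  pats <- names(raw)[-1]
  if (anyDuplicated(pats)) {
    abort(sprintf("duplicated patient id: %s", pats[duplicated(pats)][1]))
  }
  m <- matrix(NA_real_, length(vars), length(pats),
              dimnames = list(vars, pats))
  for (j in seq_along(pats)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !(is.na(col) | col %in% c("NA", "")))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at variable '%s', patient '%s'",
                    col[bad[1]], vars[bad[1]], pats[j]))
    }
    m[, j] <- num
  }
  m
}

#' Read a clinical survival table
#'
#' Expects columns `patient_id`, `time` (positive), `event` (0/1) and keeps
#' any additional covariate columns (e.g. `age`).
#'
#' @param path TSV (or CSV) file path.
#' @return tibble with validated `patient_id`, `time`, `event` plus extras.
#' @export
read_clinical_table <- function(path) {
  tbl <- readr::read_delim(path, delim = file_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  needed <- c("patient_id", "time", "event")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols)) {
    abort(paste("clinical table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  tbl$patient_id <- as.character(tbl$patient_id)
  check_survival(tbl$time, tbl$event, ids = tbl$patient_id)
  tbl
}

#' Assemble a cohort tibble from expression and clinical files
#'
#' Joins the two inputs on patient id, warning about (and dropping) patients
#' present in only one file. The result has one row per patient in clinical
#' order: `patient_id`, `time`, `event`, any clinical covariates, then one
#' column per expression variable.
#'
#' @param expression_path variables-x-patients matrix file
#'   (see [read_expression_matrix()]).
#' @param clinical_path clinical survival table (see [read_clinical_table()]).
#' @return a cohort tibble.
#' @export
cohort_from_files <- function(expression_path, clinical_path) {
  expr <- read_expression_matrix(expression_path)
  clin <- read_clinical_table(clinical_path)
  common <- intersect(clin$patient_id, colnames(expr))
  lost_clin <- setdiff(clin$patient_id, common)
  lost_expr <- setdiff(colnames(expr), common)
  if (length(lost_clin)) {
    warn(sprintf("%d patient(s) in clinical table but not expression matrix: excluded",
                 length(lost_clin)))
  }
  if (length(lost_expr)) {
    warn(sprintf("%d patient(s) in expression matrix but not clinical table: excluded",
                 length(lost_expr)))
  }
  if (length(common) == 0) abort("no patients shared between the two files")
  clin <- clin[clin$patient_id %in% common, , drop = FALSE]
  vals <- t(expr[, clin$patient_id, drop = FALSE])
  dplyr::bind_cols(clin, as_tibble(as.data.frame(vals)))
}

#' Write the per-patient risk report
#'
#' Writes `predictions.tsv` (the prediction table, full numeric precision),
#' `stats.json` (log-rank statistic/df/p and group sizes for each requested
#' grouping) and one Kaplan-Meier figure per grouping.
#'
#' @param predictions tibble with `patient_id`, `time`, `event` and at least
#'   one class column.
#' @param out_dir output directory (created if needed).
#' @param groupings character vector of class columns to stratify by;
#'   default `"risk_class"`.
#' @param plots write `km_<grouping>.png` figures (default TRUE).
#' @return invisibly, the paths written.
#' @export
write_risk_report <- function(predictions, out_dir, groupings = "risk_class",
                              plots = TRUE) {
  if (!all(c("patient_id", "time", "event") %in% names(predictions))) {
    abort("`predictions` needs patient_id, time and event columns")
  }
  missing_groups <- setdiff(groupings, names(predictions))
  if (length(missing_groups)) {
    abort(paste("grouping column(s) not present:", paste(missing_groups, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  tsv <- file.path(out_dir, "predictions.tsv")
  out <- as.data.frame(predictions)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tsv)

  stats <- list()
  for (g in groupings) {
    sub <- tibble(time = predictions$time, event = predictions$event,
                  group = predictions[[g]])
    lr <- logrank_test(sub, group = group)
    stats[[g]] <- list(
      statistic = lr$statistic, df = lr$df, p_value = lr$p_value,
      group_sizes = as.list(table(predictions[[g]]))
    )
    if (plots) {
      fig <- file.path(out_dir, paste0("km_", g, ".png"))
      p <- plot_km_by_group(sub, group = group) +
        ggplot2::labs(colour = g)
      ggplot2::ggsave(fig, p, width = 6, height = 4, dpi = 150)
      paths <- c(paths, fig)
    }
  }
  js <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, js, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, js)
  invisible(paths)
}
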