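survival_cols <- c("family_id", "dam_id", "sire_id", "block_id", "plant_id",
                   "replicate", "treatment", "n_nymphs", "n_dead_day10")

check_integerish <- function(df, col, table) {
  x <- df[[col]]
  bad <- which(!is.na(x) & (!is.numeric(x) | x != round(x) | x < 0))
  if (length(bad) > 0) {
    abort(sprintf("%s: column `%s` must hold non-negative integers (first bad row: %d)",
                  table, col, bad[1]))
  }
}

#' Validate a family survival table
#'
#' Checks the survival-table schema: required columns, non-negative integer
#' counts, and deaths never exceeding the nymphs counted before exposure.
#' Violations raise an error naming the offending column and row.
#'
#' @param df A data frame.
#' @return `df` invisibly, with count columns coerced to integer.
#' @export
validate_survival_table <- function(df) {
  miss <- setdiff(survival_cols, names(df))
  if (length(miss) > 0) {
    abort(paste0("survival table: missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_trt <- which(!df$treatment %in% c("control", "exposed"))
  if (length(bad_trt) > 0) {
    abort(sprintf("survival table: `treatment` must be 'control' or 'exposed' (first bad row: %d)",
                  bad_trt[1]))
  }
  for (col in c("replicate", "n_nymphs", "n_dead_day10")) {
    check_integerish(df, col, "survival table")
    df[[col]] <- as.integer(df[[col]])
  }
  bad <- which(!is.na(df$n_dead_day10) & df$n_dead_day10 > df$n_nymphs)
  if (length(bad) > 0) {
    abort(sprintf("survival table: n_dead_day10 > n_nymphs at row %d", bad[1]))
  }
  invisible(df)
}

#' Validate a life-history table
#'
#' Checks the life-history schema: required columns, at least one cumulative
#' `hatched_day<d>` column, non-negative integer counts, cumulative hatch
#' counts non-decreasing across days, and final hatched never exceeding eggs
#' laid. Violations raise an error naming the offending row.
#'
#' @param df A data frame.
#' @return `df` invisibly, with count columns coerced to integer.
#' @export
validate_life_history_table <- function(df) {
  core <- c("plant_id", "replicate_id", "treatment", "disk_day", "eggs_laid")
  miss <- setdiff(core, names(df))
  if (length(miss) > 0) {
    abort(paste0("life-history table: missing column(s): ", paste(miss, collapse = ", ")))
  }
  hcols <- grep("^hatched_day[0-9]+$", names(df), value = TRUE)
  if (length(hcols) == 0) {
    abort("life-history table: missing cumulative hatched_day<d> column(s)")
  }
  hcols <- hcols[order(as.integer(sub("hatched_day", "", hcols)))]
  for (col in c("disk_day", "eggs_laid", hcols)) {
    check_integerish(df, col, "life-history table")
    df[[col]] <- as.integer(df[[col]])
  }
  if (nrow(df) > 0) {
    hm <- as.matrix(df[hcols])
    if (length(hcols) > 1) {
      dec <- which(apply(hm, 1, function(r) any(diff(r) < 0)))
      if (length(dec) > 0) {
        abort(sprintf("life-history table: hatched counts decrease over days at row %d", dec[1]))
      }
    }
    over <- which(hm[, length(hcols)] > df$eggs_laid)
    if (length(over) > 0) {
      abort(sprintf("life-history table: hatched exceeds eggs_laid at row %d", over[1]))
    }
  }
  invisible(df)
}

#' Are all families present in both treatment arms?
#'
#' @param df A survival table.
#' @return `TRUE` if every `family_id` occurs in every treatment level.
#' @export
check_family_matching <- function(df) {
  tab <- table(df$family_id, df$treatment)
  all(tab > 0)
}

read_typed_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_guess()))
}

retype_counts <- function(df, cols) {
  for (col in intersect(cols, names(df))) df[[col]] <- as.integer(df[[col]])
  df
}

#' Read and write the experiment tables as CSV
#'
#' `write_tables()` writes a named list of tables (`survival` and/or
#' `life_history`) as UTF-8, header-row CSV files in `path`;
#' `read_tables()` reads whichever of the two files exist and validates
#' their schemas. Round-tripping a simulated table reproduces it exactly.
#'
#' @param tables Named list with elements `survival` and/or `life_history`.
#' @param path Directory for the CSV files.
#' @return `write_tables()` returns the file paths invisibly;
#'   `read_tables()` returns a named list of validated tibbles.
#' @export
write_tables <- function(tables, path) {
  stopifnot(is.list(tables))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  if (!is.null(tables$survival)) {
    validate_survival_table(tables$survival)
    f <- file.path(path, "survival.csv")
    readr::write_csv(tables$survival, f, progress = FALSE)
    out <- c(out, f)
  }
  if (!is.null(tables$life_history)) {
    validate_life_history_table(tables$life_history)
    f <- file.path(path, "life_history.csv")
    readr::write_csv(tables$life_history, f, progress = FALSE)
    out <- c(out, f)
  }
  invisible(out)
}

#' @rdname write_tables
#' @export
read_tables <- function(path) {
  out <- list()
  f_surv <- file.path(path, "survival.csv")
  if (file.exists(f_surv)) {
    df <- retype_counts(read_typed_csv(f_surv),
                        c("replicate", "n_nymphs", "n_dead_day10"))
    validate_survival_table(df)
    out$survival <- df
  }
  f_life <- file.path(path, "life_history.csv")
  if (file.exists(f_life)) {
    df <- read_typed_csv(f_life)
    df <- retype_counts(df, c("disk_day", "eggs_laid",
                              grep("^hatched_day", names(df), value = TRUE)))
    validate_life_history_table(df)
    out$life_history <- df
  }
  if (length(out) == 0) {
    abort(paste0("no survival.csv or life_history.csv found under ", path))
  }
  out
}
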