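#' Participant-by-variable cohort table
#'
#' A thin wrapper around `data.frame` used throughout the package: one row
#' per participant, categorical columns stored as factors (ordered factors
#' for ordinal variables) and missingness encoded as `NA`. A `provenance`
#' attribute records how the table was produced (generator, seed,
#' parameters) so any table can be regenerated from its metadata.
#'
#' @param data a data.frame; categorical columns should be factors.
#' @param provenance named list of generator metadata (free form).
#' @return an object of class `cohort_table` (inherits from `data.frame`).
#' @export
cohort_table <- function(data, provenance = list()) {
  stopifnot(is.data.frame(data))
  structure(
    as.data.frame(data, stringsAsFactors = FALSE),
    provenance = provenance,
    class = c("cohort_table", "data.frame")
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("cohort_table: %d participants x %d variables\n", nrow(x), ncol(x)))
  if (length(prov)) {
    src <- prov$generator %||% "unknown"
    cat(sprintf("  provenance: %s%s\n", src,
                if (!is.null(prov$seed)) sprintf(" (seed %s)", prov$seed) else ""))
  }
  miss <- vapply(x, function(col) sum(is.na(col)), integer(1))
  if (any(miss > 0)) {
    cat("  missing:", paste(sprintf("%s=%d", names(miss)[miss > 0], miss[miss > 0]),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Provenance metadata of a cohort table
#' @param x a `cohort_table`.
#' @export
provenance <- function(x) attr(x, "provenance")

#' Write a cohort table to CSV
#'
#' One header row; missing values are written as empty fields. Factor
#' columns are written as their labels.
#'
#' @param table a `cohort_table` (or plain data.frame).
#' @param path output file path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Empty fields become `NA`. An optional column map renames file columns
#' to the package's canonical names (`names(column_map)` are canonical,
#' values are the names in the file). Columns whose canonical name is a
#' known analysis or raw-item variable are validated and converted to the
#' appropriate factor or integer type; unknown columns are kept as read.
#'
#' @param path CSV file path.
#' @param column_map optional named character vector mapping canonical
#'   column names to file column names.
#' @return a `cohort_table`.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         check.names = FALSE)
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_cols)) {
      stop_input("mapped columns absent from file: ",
                 paste(missing_cols, collapse = ", "))
    }
    idx <- match(unname(column_map), names(raw))
    names(raw)[idx] <- names(column_map)
  }
  for (nm in names(raw)) raw[[nm]] <- coerce_known_column(raw[[nm]], nm)
  cohort_table(raw, provenance = list(generator = "csv", path = path))
}

# type the columns the package knows about; error with row indices for
# out-of-range codes so bad files are diagnosable
coerce_known_column <- function(col, name) {
  lv <- known_column_levels()[[name]]
  if (!is.null(lv)) {
    bad <- which(!is.na(col) & !(col %in% lv$levels))
    if (length(bad)) {
      stop_input(sprintf("column '%s': invalid codes in rows %s", name,
                         paste(utils::head(bad, 10), collapse = ", ")))
    }
    return(factor(col, levels = lv$levels, ordered = lv$ordered))
  }
  rng <- known_column_ranges()[[name]]
  if (!is.null(rng)) {
    col <- suppressWarnings(as.integer(col))
    bad <- which(!is.na(col) & (col < rng[1] | col > rng[2]))
    if (length(bad)) {
      stop_input(sprintf("column '%s': out-of-range values in rows %s", name,
                         paste(utils::head(bad, 10), collapse = ", ")))
    }
    return(col)
  }
  col
}

known_column_levels <- function() {
  item3 <- list(levels = c("no", "yes", "pns"), ordered = FALSE)
  bin <- list(levels = c("absent", "present"), ordered = FALSE)
  band4 <- list(levels = c("normal", "borderline", "high", "very_high"), ordered = TRUE)
  list(
    suicidality_item_a = item3, suicidality_item_b = item3, suicidality_item_c = item3,
    sdq_pain = list(levels = c("not_true", "somewhat_true", "certainly_true"),
                    ordered = TRUE),
    gender = list(levels = c("girl", "boy", "other_pns"), ordered = FALSE),
    suicidality = bin, pain = bin, pain_6m = bin, pain_today = bin,
    depression = list(levels = c("normal", "at_risk", "caseness"), ordered = TRUE),
    anxiety = list(levels = c("non_clinical", "borderline", "clinical"), ordered = TRUE),
    peers = band4, inhibition = band4
  )
}

known_column_ranges <- function() {
  list(chu_pain = c(0L, 4L), cesd_total = c(0L, 60L),
       anxiety_score = c(0L, 100L), peers_score = c(0L, 10L),
       inhibition_score = c(0L, 10L))
}
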