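#' Household table: one row per surveyed household/child
#'
#' The central container of the package.  A `household_table` is a
#' `data.frame` with one row per observation and an attached [codebook].
#' Reserved columns:
#' \describe{
#'   \item{`id`}{unique observation identifier (character).}
#'   \item{`weight`}{non-negative observation mass \eqn{w_s}; defaults to 1.}
#'   \item{`diet_class`}{binary; 1 = inadequate diet diversity (the treated
#'     state), 0 = adequate.}
#'   \item{`stunting`}{binary outcome; 1 = height-for-age more than 2 SD
#'     below the reference mean.}
#'   \item{`child_age_months`}{integer age of the child in months.}
#'   \item{`interview_day`}{integer day index within the fieldwork window.}
#' }
#' All codebook `covariate` variables are integer-coded columns; `item-flag`
#' variables (the 24-h recall food items) are optional binary columns.
#'
#' @param df A data.frame holding the columns above.
#' @param cb The [codebook] describing the coded variables.
#' @param missing_action What to do with rows carrying a missing covariate
#'   value: `"drop"` removes them with a logged count, `"category"` recodes
#'   them into an extra explicit "missing" category appended to the
#'   codebook.
#' @return An object of classes `household_table` and `data.frame`.
#' @export
household_table <- function(df, cb, missing_action = c("drop", "category")) {
  stopifnot(is.data.frame(df), inherits(cb, "codebook"))
  missing_action <- match.arg(missing_action)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("household table has no rows")

  if (is.null(df$id)) df$id <- as.character(seq_len(nrow(df)))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("household ids are not unique")

  if (is.null(df$weight)) {
    warning("no 'weight' column; all weights set to 1")
    df$weight <- 1
  }
  df$weight <- as.numeric(df$weight)
  if (anyNA(df$weight)) {
    warning(sum(is.na(df$weight)), " missing weights set to 1")
    df$weight[is.na(df$weight)] <- 1
  }
  if (any(df$weight < 0)) stop("negative weights are not allowed")

  for (col in c("diet_class", "stunting")) {
    if (!is.null(df[[col]])) {
      v <- as.integer(df[[col]])
      if (any(!v %in% c(0L, 1L, NA_integer_)))
        stop(sprintf("column '%s' must be binary 0/1", col))
      df[[col]] <- v
    }
  }

  covs <- codebook_vars(cb, "covariate")
  for (v in covs) {
    if (is.null(df[[v]])) stop("covariate column missing from table: ", v)
    df[[v]] <- decode_column(cb, v, df[[v]])
  }

  # missing covariate policy
  has_na <- Reduce(`|`, lapply(covs, function(v) is.na(df[[v]])), logical(nrow(df)))
  if (any(has_na)) {
    if (missing_action == "drop") {
      message(sum(has_na), " record(s) dropped for missing covariate values")
      df <- df[!has_na, , drop = FALSE]
      if (nrow(df) == 0L) stop("all records dropped for missing covariates")
    } else {
      plain <- lapply(cb, function(v) list(labels = v$labels, role = v$role))
      for (v in covs) {
        if (anyNA(df[[v]])) {
          plain[[v]]$labels <- c(plain[[v]]$labels, "missing")
          df[[v]][is.na(df[[v]])] <- length(plain[[v]]$labels) - 1L
        }
      }
      cb <- codebook(plain)
    }
  }

  if (sum(df$weight) <= 0) stop("total mass must be positive")
  structure(df, codebook = cb, class = c("household_table", "data.frame"))
}

# Map a raw CSV column (labels or integer codes) to validated integer codes.
decode_column <- function(cb, variable, x) {
  labs <- cb[[variable]]$labels
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    x[x == ""] <- NA_character_
    bad <- setdiff(unique(x[!is.na(x)]), labs)
    # labels may legitimately be numerals for pre-coded files
    if (length(bad) && all(grepl("^[0-9]+$", bad))) {
      v <- suppressWarnings(as.integer(x))
      bad2 <- invalid_codes(cb, variable, v)
      if (length(bad2))
        stop(sprintf("variable '%s': invalid code(s) %s", variable,
                     paste(bad2, collapse = ", ")))
      return(v)
    }
    if (length(bad))
      stop(sprintf("variable '%s': unknown label(s) %s", variable,
                   paste(sQuote(bad), collapse = ", ")))
    match(x, labs) - 1L
  } else {
    v <- as.integer(x)
    bad <- invalid_codes(cb, variable, v)
    if (length(bad))
      stop(sprintf("variable '%s': invalid code(s) %s", variable,
                   paste(bad, collapse = ", ")))
    v
  }
}

#' @export
print.household_table <- function(x, ...) {
  cat(sprintf("<household_table> %d records, total mass %.6g\n",
              nrow(x), total_mass(x)))
  cat(sprintf("  covariates: %s\n",
              paste(codebook_vars(attr(x, "codebook")), collapse = ", ")))
  NextMethod()
}

#' Total observation mass of a household table
#'
#' @param table A [household_table].
#' @return The sum of observation weights \eqn{\sum_s w_s}.
#' @export
total_mass <- function(table) {
  stopifnot(inherits(table, "household_table"))
  sum(table$weight)
}

#' Load a household table from CSV
#'
#' Reads a CSV with a header row, validates every column against the
#' codebook (category labels or integer codes are both accepted), and
#' applies the package's missing-data policy.  A missing `weight` column
#' defaults to unit mass with a warning.
#'
#' @param path CSV file path.
#' @param cb The [codebook] to validate against.
#' @inheritParams household_table
#' @return A [household_table].
#' @export
load_households <- function(path, cb, missing_action = c("drop", "category")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("empty household file: ", path)
  covs <- codebook_vars(cb, "covariate")
  absent <- setdiff(covs, names(df))
  if (length(absent))
    stop("header does not match codebook; missing column(s): ",
         paste(absent, collapse = ", "))
  household_table(df, cb, missing_action = missing_action)
}

#' Write a household table to CSV
#'
#' Writes integer codes as-is so that a round trip through
#' [load_households()] with the same codebook reproduces the table exactly.
#'
#' @param table A [household_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_households <- function(table, path) {
  stopifnot(inherits(table, "household_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Restrict a household table to an age window
#'
#' Children below six months are presumed breast- or bottle-fed and are
#' excluded from diet-diversity analysis; the survey's recall covers
#' children up to 25 months.  The default window is therefore 6--25 months
#' inclusive.
#'
#' @param table A [household_table] with a `child_age_months` column.
#' @param min_months,max_months Inclusive bounds in months.
#' @return The filtered [household_table]; surviving records are unchanged.
#' @export
filter_age_window <- function(table, min_months = 6L, max_months = 25L) {
  stopifnot(inherits(table, "household_table"))
  if (min_months > max_months) stop("min_months must not exceed max_months")
  if (is.null(table$child_age_months))
    stop("table has no 'child_age_months' column")
  keep <- table$child_age_months >= min_months &
    table$child_age_months <= max_months
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("no records in age window [", min_months, ", ", max_months,
         "] months; check the window")
  out <- table[keep, , drop = FALSE]
  structure(out, codebook = attr(table, "codebook"),
            class = c("household_table", "data.frame"))
}
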