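#' A categorical profile
#'
#' A profile fixes an ordered subset of coded covariates at specific
#' values; the households matching all of them form the profile's
#' subgroup.
#'
#' @param variables Character vector of covariate names (no repeats).
#' @param values Integer codes, one per variable.
#' @param cb Optional [codebook]; when supplied, each (variable, value)
#'   pair is validated.
#' @return An object of class `profile`.
#' @export
profile <- function(variables, values, cb = NULL) {
  variables <- as.character(variables)
  values <- as.integer(values)
  if (length(variables) != length(values))
    stop("variables and values must have equal length")
  if (anyDuplicated(variables)) stop("repeated variable in profile")
  if (!is.null(cb)) {
    for (i in seq_along(variables)) {
      v <- variables[i]
      if (is.null(cb[[v]])) stop("variable not in codebook: ", v)
      if (!values[i] %in% cb[[v]]$codes)
        stop(sprintf("invalid code %d for variable '%s'", values[i], v))
    }
  }
  structure(list(variables = variables, values = values), class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("<profile>", profile_key(x), "\n")
  invisible(x)
}

#' Canonical string key of a profile
#'
#' Variables sorted by name, rendered `var=code` and joined with `|`; used
#' for deterministic ordering, tie-breaking and joins between the polling
#' and impact metric tables.
#'
#' @param p A [profile].
#' @return A single string.
#' @export
profile_key <- function(p) {
  o <- order(p$variables)
  paste(sprintf("%s=%d", p$variables[o], p$values[o]), collapse = "|")
}

# Parse a profile key back into a profile object.
profile_from_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  profile(vapply(kv, `[`, "", 1L), as.integer(vapply(kv, `[`, "", 2L)))
}

#' Membership of households in a profile
#'
#' @param p A [profile].
#' @param table A [household_table].
#' @return Logical vector, TRUE for rows matching every fixed value.
#' @export
profile_members <- function(p, table) {
  stopifnot(inherits(p, "profile"), inherits(table, "household_table"))
  keep <- rep(TRUE, nrow(table))
  for (i in seq_along(p$variables)) {
    col <- table[[p$variables[i]]]
    if (is.null(col)) stop("profile variable not in table: ", p$variables[i])
    keep <- keep & (col == p$values[i])
  }
  keep & !is.na(keep)
}

#' Enumerate every profile over k-subsets of covariates
#'
#' Generates all value assignments of every size-`k` subset of the given
#' covariates, the exhaustive search space of the polling and impact
#' profiling analyses.  With 10 variables and `k = 5` there are
#' `choose(10, 5) = 252` variable subsets; the number of value profiles is
#' the sum over subsets of the product of category counts.
#'
#' @param variables Covariate names to combine.
#' @param k Profile size (number of variables fixed simultaneously).
#' @param cb The [codebook] supplying the category codes.
#' @return A list of [profile] objects with attributes `n_subsets` (the
#'   number of k-subsets) and `subset_id` (integer vector mapping each
#'   profile to its variable subset).
#' @export
enumerate_profiles <- function(variables, k, cb) {
  stopifnot(inherits(cb, "codebook"))
  if (k <= 0) stop("k must be positive")
  variables <- as.character(variables)
  if (k > length(variables)) stop("k exceeds the number of variables")
  missing <- setdiff(variables, names(cb))
  if (length(missing))
    stop("variable(s) not in codebook: ", paste(missing, collapse = ", "))
  subs <- utils::combn(variables, k, simplify = FALSE)
  out <- vector("list", 0L)
  subset_id <- integer(0L)
  for (si in seq_along(subs)) {
    vars <- subs[[si]]
    grid <- expand.grid(lapply(vars, function(v) cb[[v]]$codes),
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- vars
    profs <- lapply(seq_len(nrow(grid)), function(r) {
      profile(vars, as.integer(grid[r, ]))
    })
    out <- c(out, profs)
    subset_id <- c(subset_id, rep.int(si, length(profs)))
  }
  attr(out, "n_subsets") <- length(subs)
  attr(out, "subset_id") <- subset_id
  out
}
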