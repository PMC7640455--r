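#' Food-item to food-group mapping for the Child Dietary Diversity Score
#'
#' The 24-h recall instrument asks about 13 individual food items; the
#' CDDS counts distinct food *groups*.  The default mapping collapses the
#' 13 items into 7 groups (there is no recall item for foods cooked in oil
#' or fat, so the eighth standard group is unattainable and the score runs
#' 0--7):
#' grains/roots/tubers (1), vitamin-A rich foods (2), other fruits and
#' vegetables (3), meat/poultry/fish/seafood (4), eggs (5),
#' pulses/legumes/nuts (6), milk and milk products (7).
#'
#' @param mapping Named integer vector: item name -> group index in 1..7.
#'   Defaults to the 13-item instrument mapping.
#' @return An object of class `cdds_mapping`.
#' @export
cdds_mapping <- function(mapping = NULL) {
  if (is.null(mapping)) {
    path <- system.file("extdata", "cdds_items.yaml", package = "pollmatch")
    raw <- yaml::read_yaml(path)
    mapping <- vapply(raw$items, function(it) as.integer(it$group), integer(1))
    names(mapping) <- vapply(raw$items, function(it) it$item, character(1))
  }
  mapping <- vapply(mapping, as.integer, integer(1))
  if (is.null(names(mapping)) || any(names(mapping) == ""))
    stop("mapping must be a named vector of item -> group index")
  if (any(mapping < 1L | mapping > 7L))
    stop("group indices must lie in 1..7")
  structure(mapping, class = "cdds_mapping")
}

#' @export
print.cdds_mapping <- function(x, ...) {
  cat(sprintf("<cdds_mapping> %d items -> %d food groups\n",
              length(x), length(unique(unclass(x)))))
  print(unclass(x))
  invisible(x)
}

# Canonical group labels, index 1..7
cdds_group_labels <- function() {
  c("grains_roots_tubers", "vitamin_a_rich", "other_fruit_veg",
    "meat_poultry_fish", "eggs", "pulses_legumes_nuts", "milk_products")
}

#' Collapse item recall flags into food-group flags
#'
#' A group scores 1 whenever at least one of its items scores 1.
#'
#' @param item_flags Named binary vector (or single-row data.frame) of the
#'   13 recall items, names matching the mapping.
#' @param mapping A [cdds_mapping].
#' @return Integer vector of length 7, one flag per food group, named by
#'   group.
#' @export
map_items_to_groups <- function(item_flags, mapping = cdds_mapping()) {
  if (is.data.frame(item_flags)) item_flags <- unlist(item_flags[1, ])
  if (is.null(names(item_flags)))
    stop("item_flags must be named by item")
  unknown <- setdiff(names(item_flags), names(mapping))
  if (length(unknown))
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  flags <- as.integer(item_flags)
  if (any(!flags %in% c(0L, 1L))) stop("item flags must be binary")
  groups <- integer(7L)
  idx <- unclass(mapping)[names(item_flags)]
  for (g in 1:7) groups[g] <- as.integer(any(flags[idx == g] == 1L))
  names(groups) <- cdds_group_labels()
  groups
}

#' Child Dietary Diversity Score from food-group flags
#'
#' @param group_flags Binary vector of length 7 (one per food group).
#' @return Integer score 0--7: the number of distinct groups consumed.
#' @export
compute_cdds <- function(group_flags) {
  flags <- as.integer(group_flags)
  if (length(flags) != 7L) stop("expected 7 group flags")
  if (any(!flags %in% c(0L, 1L))) stop("group flags must be binary")
  sum(flags)
}

#' Classify diet-diversity adequacy
#'
#' Consumption of more than `threshold` food groups is classified as
#' adequately diverse; equal or below as inadequately diverse.  The
#' treatment indicator of the whole pipeline is the complement:
#' `diet_class = 1 - adequate`.
#'
#' @param cdds Integer score(s) in 0..7.
#' @param threshold Integer cutoff; adequacy requires `cdds > threshold`.
#'   Default 3 (the "more than 3 groups" convention).
#' @return Integer vector: 1 = adequate, 0 = inadequate.
#' @export
classify_adequacy <- function(cdds, threshold = 3L) {
  if (threshold < 0L || threshold > 7L) stop("threshold must lie in 0..7")
  cdds <- as.integer(cdds)
  if (any(cdds < 0L | cdds > 7L, na.rm = TRUE)) stop("cdds must lie in 0..7")
  as.integer(cdds > threshold)
}

#' Score a household table's recall items
#'
#' Adds `cdds`, `adequate` and `diet_class` columns computed from the
#' table's item-flag columns.
#'
#' @param table A [household_table] whose item-flag columns match the
#'   mapping's item names.
#' @param mapping A [cdds_mapping].
#' @param threshold Adequacy cutoff, see [classify_adequacy()].
#' @return The table with `cdds`, `adequate`, `diet_class` columns
#'   (re)computed.
#' @export
score_cdds <- function(table, mapping = cdds_mapping(), threshold = 3L) {
  stopifnot(inherits(table, "household_table"))
  items <- names(mapping)
  absent <- setdiff(items, names(table))
  if (length(absent))
    stop("item column(s) missing from table: ", paste(absent, collapse = ", "))
  m <- as.matrix(as.data.frame(table)[, items, drop = FALSE])
  storage.mode(m) <- "integer"
  idx <- unclass(mapping)[items]
  grp <- vapply(1:7, function(g) {
    as.integer(rowSums(m[, idx == g, drop = FALSE]) > 0L)
  }, integer(nrow(m)))
  table$cdds <- as.integer(rowSums(grp))
  table$adequate <- classify_adequacy(table$cdds, threshold)
  table$diet_class <- 1L - table$adequate
  table
}

#' Remove the interview-timing artifact from measured diet diversity
#'
#' Fieldwork spans several months, and measured diet diversity drifts with
#' the interview date (seasonality of food availability confounded with
#' the survey rollout).  With `method = "day-regression"` a linear
#' probability regression of the adequacy indicator on the interview-day
#' index estimates the artificial trend, and the indicator is then
#' adjusted by the minimal per-day reclassification that cancels it: on
#' days fitted above the overall adequacy rate the fitted excess
#' \eqn{n_d(\hat p_d - \bar p)} (rounded) of adequate records is
#' reclassified as inadequate, and conversely on days fitted below.  The
#' marginal records — those closest to the adequacy cutoff by CDDS score,
#' ties by record order — are flipped first, so the adjustment is
#' deterministic and touches as few records as the fitted trend requires
#' (none, asymptotically, when adequacy is day-independent).  With
#' `method = "none"` the table is returned untouched.
#'
#' A binary indicator cannot be detrended by residualizing the indicator
#' itself and re-thresholding the residual (that reproduces the input
#' whenever the fitted probabilities lie in (0, 1)), which is why the
#' correction reallocates records against the fitted trend instead.
#'
#' @param table A [household_table] with an `interview_day` column; a
#'   `cdds` column, when present, picks which records flip first.
#' @param method `"none"` or `"day-regression"`.
#' @return The table, with `adequate` and `diet_class` adjusted under
#'   `"day-regression"` and the flipped-record count attached as the
#'   `n_reclassified` attribute.
#' @export
detrend_interview_timing <- function(table,
                                     method = c("none", "day-regression")) {
  stopifnot(inherits(table, "household_table"))
  method <- match.arg(method)
  if (method == "none") return(table)
  if (is.null(table$interview_day))
    stop("table has no 'interview_day' column")
  if (is.null(table$adequate))
    stop("table has no 'adequate' column; score it first")
  day <- as.numeric(table$interview_day)
  if (length(unique(day)) < 2L) {
    warning("interview_day is constant; no timing adjustment possible")
    return(table)
  }
  adequate <- table$adequate
  fit <- stats::lm(adequate ~ day)
  phat <- stats::fitted(fit)
  pbar <- mean(adequate)
  score <- if (!is.null(table$cdds)) table$cdds else seq_along(adequate)
  n_flipped <- 0L
  for (d in unique(day)) {
    idx <- which(day == d)
    k <- round(sum(phat[idx] - pbar))
    if (k > 0) {        # fitted excess adequacy: demote marginal adequates
      cand <- idx[adequate[idx] == 1L]
      cand <- cand[order(score[cand], cand)]
      flip <- utils::head(cand, k)
      adequate[flip] <- 0L
      n_flipped <- n_flipped + length(flip)
    } else if (k < 0) { # fitted deficit: promote the highest inadequates
      cand <- idx[adequate[idx] == 0L]
      cand <- cand[order(-score[cand], cand)]
      flip <- utils::head(cand, -k)
      adequate[flip] <- 1L
      n_flipped <- n_flipped + length(flip)
    }
  }
  table$adequate <- adequate
  table$diet_class <- 1L - adequate
  attr(table, "n_reclassified") <- n_flipped
  table
}
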