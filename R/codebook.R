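#' Variable codebook for integer-coded household tables
#'
#' A codebook lists, for every variable in a household table, its ordered
#' category labels and its role.  Categories are coded as consecutive
#' integers starting at 0, in label order, so a profile can fix a variable
#' at a code and the code is meaningful across the whole pipeline.
#'
#' @param variables Named list.  Each element describes one variable and is
#'   either a character vector of ordered category labels (role defaults to
#'   `"covariate"`) or a list with elements `labels` (character) and `role`
#'   (one of `"covariate"`, `"item-flag"`, `"outcome"`, `"weight"`, `"meta"`).
#' @return An object of class `codebook`: a named list of
#'   `list(labels, codes, role)` entries, codes always `0:(K-1)`.
#' @examples
#' cb <- codebook(list(
#'   area = c("urban", "rural"),
#'   wealth = list(labels = c("poorest", "middle", "richest"),
#'                 role = "covariate")
#' ))
#' cb$area$codes
#' @export
codebook <- function(variables) {
  if (length(variables) == 0L || is.null(names(variables)) ||
      any(names(variables) == ""))
    stop("'variables' must be a non-empty named list")
  if (anyDuplicated(names(variables)))
    stop("duplicate variable names in codebook")
  roles <- c("covariate", "item-flag", "outcome", "weight", "meta")
  out <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    if (is.character(v)) v <- list(labels = v, role = "covariate")
    if (is.null(v$role)) v$role <- "covariate"
    if (!v$role %in% roles)
      stop(sprintf("variable '%s': unknown role '%s'", nm, v$role))
    labs <- as.character(v$labels)
    if (length(labs) < 1L) stop(sprintf("variable '%s': no labels", nm))
    if (anyDuplicated(labs))
      stop(sprintf("variable '%s': duplicate labels", nm))
    list(labels = labs, codes = seq_along(labs) - 1L, role = v$role)
  })
  names(out) <- names(variables)
  structure(out, class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d variables\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %-22s [%s] %s\n", nm, x[[nm]]$role,
                paste(x[[nm]]$labels, collapse = " | ")))
  invisible(x)
}

#' Variable names of a given role
#'
#' @param cb A [codebook].
#' @param role Role to select, e.g. `"covariate"`.
#' @return Character vector of variable names.
#' @export
codebook_vars <- function(cb, role = "covariate") {
  stopifnot(inherits(cb, "codebook"))
  names(cb)[vapply(cb, function(v) v$role == role, logical(1))]
}

#' Read or write a codebook as YAML or JSON
#'
#' The on-disk form maps each variable name to either a list of labels or a
#' mapping with `labels` and `role` keys; the format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @param cb A [codebook] (for writing).
#' @return `read_codebook` returns a [codebook]; `write_codebook` returns
#'   `path` invisibly.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  codebook(raw)
}

#' @rdname read_codebook
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  plain <- lapply(cb, function(v) list(labels = v$labels, role = v$role))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(plain, path, auto_unbox = FALSE, pretty = TRUE)
  else yaml::write_yaml(plain, path)
  invisible(path)
}

# Validate one column of integer codes against the codebook; returns the
# offending code values (empty if all valid).
invalid_codes <- function(cb, variable, codes) {
  ok <- codes %in% cb[[variable]]$codes
  unique(codes[!ok & !is.na(codes)])
}
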