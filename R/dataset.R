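#' Construct an observation dataset
#'
#' Bundles a records table (one row per respondent/observation, one
#' column per variable, `NA` = missing) with the variable specs in play
#' and a provenance tag.
#'
#' @param records data.frame; may contain a `unit_id` column plus one
#'   character column per variable.
#' @param specs named list of [variable_spec] objects covering every
#'   non-`unit_id` column.
#' @param provenance free-text tag, conventionally `"survey"` or
#'   `"synthetic"`.
#' @return object of class `park_dataset`.
#' @export
park_dataset <- function(records, specs, provenance = "survey") {
  stopifnot(is.data.frame(records))
  vars <- setdiff(names(records), "unit_id")
  unknown <- setdiff(vars, names(specs))
  if (length(unknown))
    stop("record columns without a variable spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  records[vars] <- lapply(records[vars], as.character)
  structure(list(records = records, specs = specs[names(specs) %in% c(vars)],
                 provenance = provenance),
            class = "park_dataset")
}

#' @export
print.park_dataset <- function(x, ...) {
  cat(sprintf("<park_dataset> %d records x %d variables (%s)\n",
              nrow(x$records), length(x$specs), x$provenance))
  invisible(x)
}

#' Validate a dataset against its variable specs and unit inventory
#'
#' A reporting operation: never throws for bad content, instead lists
#' every illegal state and unresolvable unit reference, and tabulates
#' per-variable missingness.
#'
#' @param ds a [park_dataset].
#' @param units optional unit inventory; when given, `unit_id` values
#'   are checked against it.
#' @return list with `errors` (character), `warnings` (character),
#'   `missingness` (named numeric in \[0,1\]), `n_records`.
#' @export
validate_dataset <- function(ds, units = NULL) {
  stopifnot(inherits(ds, "park_dataset"))
  rec <- ds$records
  errors <- character(0)
  warns <- character(0)
  vars <- intersect(names(rec), names(ds$specs))
  for (v in vars) {
    vals <- rec[[v]]
    bad <- !is.na(vals) & !vals %in% ds$specs[[v]]$states
    if (any(bad)) {
      rows <- which(bad)
      errors <- c(errors, sprintf(
        "record %d: illegal state '%s' for variable '%s'",
        rows, vals[rows], v))
    }
  }
  if (!is.null(units) && "unit_id" %in% names(rec)) {
    bad <- !rec$unit_id %in% units$unit_id
    if (any(bad))
      errors <- c(errors, sprintf("record %d: unknown unit_id %s",
                                  which(bad), rec$unit_id[bad]))
  }
  miss <- vapply(rec[vars], function(x) mean(is.na(x)), numeric(1))
  if (!nrow(rec)) warns <- c(warns, "dataset has no records")
  list(errors = errors, warnings = warns, missingness = miss,
       n_records = nrow(rec))
}

#' Write / read a dataset as CSV (empty cell = missing)
#'
#' @param ds a [park_dataset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "park_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param specs variable specs used to re-attach state systems on read.
#' @param provenance provenance tag for the reloaded dataset.
#' @export
read_dataset_csv <- function(path, specs, provenance = "survey") {
  rec <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  rec[rec == ""] <- NA
  if ("unit_id" %in% names(rec)) rec$unit_id <- as.integer(rec$unit_id)
  park_dataset(rec, specs, provenance)
}

#' Discretize the continuous columns of a measurement table
#'
#' Applies [discretize()] columnwise: every column of `measurements`
#' whose spec carries bin edges is mapped to state labels; columns that
#' are already categorical are passed through after a legality check.
#'
#' @param measurements data.frame of numeric measurements and/or state
#'   labels, one column per variable (plus optional `unit_id`).
#' @param specs named list of [variable_spec].
#' @param provenance provenance tag of the resulting dataset.
#' @return a [park_dataset] of state labels.
#' @export
discretize_dataset <- function(measurements, specs, provenance = "survey") {
  rec <- measurements
  for (v in setdiff(names(rec), "unit_id")) {
    sp <- specs[[v]]
    if (is.null(sp)) stop("no variable spec for column '", v, "'", call. = FALSE)
    if (is.numeric(rec[[v]])) {
      if (is.null(sp$bin_edges))
        stop("numeric column '", v, "' but spec has no bin edges", call. = FALSE)
      rec[[v]] <- discretize(rec[[v]], sp)
    } else {
      rec[[v]] <- as.character(rec[[v]])
    }
  }
  park_dataset(rec, specs, provenance)
}

# records as integer state-index matrix (NA = missing); used by the
# learning and inference code paths.
encode_records <- function(ds, nodes = names(ds$specs)) {
  rec <- ds$records
  out <- matrix(NA_integer_, nrow(rec), length(nodes),
                dimnames = list(NULL, nodes))
  for (v in nodes) {
    idx <- match(rec[[v]], ds$specs[[v]]$states)
    if (any(!is.na(rec[[v]]) & is.na(idx)))
      stop("illegal state in column '", v, "'", call. = FALSE)
    out[, v] <- idx
  }
  out
}
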