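#' Sentinel used for missing categorical cells
#'
#' Missing values are stored as `NA` in data frames and rendered as empty
#' cells in CSV; `MISSING` is never a modelled category.
#' @keywords internal
MISSING <- NA_character_

#' Construct a categorical variable specification
#'
#' A `variable_spec` names one study variable, its role in the analysis,
#' its ordered category system, and (optionally) the numeric cut points
#' that map a continuous measurement onto those categories.
#'
#' @param name variable name (single string).
#' @param role one of `"spatial"`, `"activity"`, `"individual"`,
#'   `"interaction"`.
#' @param states ordered character vector of category labels (>= 2).
#' @param bin_edges optional strictly increasing numeric vector of length
#'   `length(states) + 1`; bins are half-open `[lower, upper)` with the
#'   last bin closed.
#' @param unit optional measurement unit label.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, role, states, bin_edges = NULL, unit = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, c("spatial", "activity", "individual", "interaction"))
  states <- as.character(states)
  if (length(states) < 2L)
    stop("variable '", name, "': needs at least 2 states", call. = FALSE)
  if (anyDuplicated(states))
    stop("variable '", name, "': duplicate state labels", call. = FALSE)
  if (!is.null(bin_edges)) {
    bin_edges <- as.numeric(bin_edges)
    if (length(bin_edges) != length(states) + 1L)
      stop("variable '", name, "': bin_edges must have length(states)+1 entries",
           call. = FALSE)
    if (any(diff(bin_edges) <= 0))
      stop("variable '", name, "': bin_edges must be strictly increasing",
           call. = FALSE)
  }
  structure(list(name = name, role = role, states = states,
                 bin_edges = bin_edges, unit = unit),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s [%s]: %s\n", x$name, x$role,
              paste(x$states, collapse = " < ")))
  if (!is.null(x$bin_edges))
    cat("  edges:", paste(x$bin_edges, collapse = ", "),
        if (!is.null(x$unit)) paste0("(", x$unit, ")") else "", "\n")
  invisible(x)
}

#' Load the variable inventory from a JSON fixture
#'
#' Reads the packaged (or a user-supplied) variable inventory: 12 spatial,
#' 2 activity, 3 individual and 2 interaction variables, each with its
#' ordered state system and, where the variable is measured continuously,
#' its bin edges.
#'
#' @param path path to a JSON fixture; defaults to the packaged inventory.
#' @return named list of [variable_spec] objects.
#' @export
load_variable_specs <- function(path = system.file("extdata", "variable_specs.json",
                                                   package = "parkbbn")) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("variable spec fixture missing or empty: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse variable spec fixture: ",
                                           conditionMessage(e), call. = FALSE))
  vars <- raw$variables
  if (is.null(vars) || !length(vars))
    stop("variable spec fixture has no 'variables' entry: ", path, call. = FALSE)
  specs <- lapply(vars, function(v) {
    for (field in c("name", "role", "states"))
      if (is.null(v[[field]]))
        stop("malformed variable spec (missing '", field, "') near variable '",
             if (is.null(v$name)) "<unnamed>" else v$name, "'", call. = FALSE)
    variable_spec(v$name, v$role, unlist(v$states),
                  bin_edges = if (!is.null(v$bin_edges)) unlist(v$bin_edges),
                  unit = v$unit)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs)))
    stop("duplicate variable names in fixture: ",
         paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "),
         call. = FALSE)
  specs
}

#' Map a numeric measurement to its category
#'
#' Bins are half-open `[lower, upper)` with the last bin closed at the
#' upper edge, so every value in the declared domain maps to exactly one
#' state. Values outside the domain raise an error rather than being
#' clamped.
#'
#' @param value numeric vector of measurements.
#' @param spec a [variable_spec] with `bin_edges`.
#' @return character vector of state labels.
#' @export
discretize <- function(value, spec) {
  stopifnot(inherits(spec, "variable_spec"))
  if (is.null(spec$bin_edges))
    stop("variable '", spec$name, "' has no bin edges; it is not a ",
         "continuous-to-categorical variable", call. = FALSE)
  e <- spec$bin_edges
  out_of_range <- !is.na(value) & (value < e[1L] | value > e[length(e)])
  if (any(out_of_range))
    stop("variable '", spec$name, "': value(s) outside declared domain [",
         e[1L], ", ", e[length(e)], "]: ",
         paste(utils::head(value[out_of_range], 5L), collapse = ", "),
         call. = FALSE)
  idx <- findInterval(value, e, rightmost.closed = TRUE, left.open = FALSE)
  spec$states[idx]
}

#' Cut a continuous score into ordered levels by equal-frequency binning
#'
#' Used for the two interaction variables (crowds-congregate index: 5
#' levels; engagement score: 3 levels) whose level boundaries are not
#' fixed a priori. Edges are quantiles of the supplied training values;
#' freeze them once and reuse on held-out data via the returned spec.
#'
#' @param values numeric training values the quantile edges are computed from.
#' @param spec a [variable_spec] without fixed edges.
#' @param pad small relative widening of the outer edges so the observed
#'   min/max fall strictly inside the domain.
#' @return the spec with `bin_edges` filled in.
#' @export
quantile_bin_edges <- function(values, spec, pad = 1e-8) {
  stopifnot(inherits(spec, "variable_spec"))
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to compute quantile edges from", call. = FALSE)
  k <- length(spec$states)
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1L),
                        names = FALSE, type = 7)
  span <- max(diff(range(values)), 1)
  qs[1L] <- qs[1L] - pad * span
  qs[k + 1L] <- qs[k + 1L] + pad * span
  # equal values collapse quantiles; nudge duplicates apart deterministically
  for (i in seq_len(k)) if (qs[i + 1L] <= qs[i]) qs[i + 1L] <- qs[i] + pad * span
  spec$bin_edges <- qs
  spec
}
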