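#' Construct a directed acyclic network structure
#'
#' @param nodes character vector of variable names.
#' @param edges NULL, a 2-column matrix, or a data.frame with columns
#'   `from`, `to` (parent, child).
#' @return object of class `bn_structure` with fields `nodes` and
#'   `edges` (2-column character matrix).
#' @export
bn_structure <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(edges)
    colnames(edges) <- c("from", "to")
    edges <- matrix(as.character(edges), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  }
  bad <- !c(edges) %in% nodes
  if (any(bad))
    stop("edge endpoint(s) not in node set: ",
         paste(unique(c(edges)[bad]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(paste(edges[, 1], edges[, 2], sep = "\r")))
    stop("duplicate edges", call. = FALSE)
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edge", call. = FALSE)
  s <- structure(list(nodes = nodes, edges = edges), class = "bn_structure")
  topological_order(s)  # errors on a cycle
  s
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("<bn_structure> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Topological order of a structure's nodes
#'
#' Kahn's algorithm with deterministic (input-order) tie-breaking;
#' errors if the edge set contains a directed cycle.
#'
#' @param structure a [bn_structure].
#' @return character vector of node names, parents before children.
#' @export
topological_order <- function(structure) {
  nodes <- structure$nodes
  edges <- structure$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(edges[, 2])
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  avail <- nodes[indeg == 0L]
  indeg <- indeg[indeg > 0L]
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    if (nrow(edges)) {
      ch <- edges[edges[, 1] == v, 2]
      for (c_ in ch) {
        indeg[c_] <- indeg[c_] - 1L
        if (indeg[c_] == 0L) {
          avail <- c(avail, c_)
          indeg <- indeg[names(indeg) != c_]
        }
      }
    }
  }
  if (length(order) != length(nodes))
    stop("structure contains a directed cycle", call. = FALSE)
  order
}

# parents of a node, in deterministic (edge-insertion) order
bn_parents <- function(structure, node) {
  unname(structure$edges[structure$edges[, 2] == node, 1])
}

bn_children <- function(structure, node) {
  unname(structure$edges[structure$edges[, 1] == node, 2])
}

has_edge <- function(structure, from, to) {
  any(structure$edges[, 1] == from & structure$edges[, 2] == to)
}

# would adding from -> to create a directed cycle? (is `from` reachable
# from `to`?)
edge_creates_cycle <- function(structure, from, to) {
  if (from == to) return(TRUE)
  frontier <- to
  seen <- character(0)
  while (length(frontier)) {
    v <- frontier[1L]; frontier <- frontier[-1L]
    if (v == from) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    frontier <- c(frontier, bn_children(structure, v))
  }
  FALSE
}

add_edge <- function(structure, from, to) {
  bn_structure(structure$nodes, rbind(structure$edges, c(from, to)))
}

remove_edge <- function(structure, from, to) {
  keep <- !(structure$edges[, 1] == from & structure$edges[, 2] == to)
  bn_structure(structure$nodes, structure$edges[keep, , drop = FALSE])
}

#' Construct a conditional probability table
#'
#' The table is stored as a numeric array whose first dimension indexes
#' the child's states and whose remaining dimensions index the parents'
#' states in the given parent order. Every conditional distribution
#' (slice along the first dimension) must sum to 1.
#'
#' @param child child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param specs named list of [variable_spec] for child and parents.
#' @param values numeric array (or vector) of probabilities, child
#'   dimension first, parent dimensions in `parents` order.
#' @return object of class `bn_cpt`.
#' @export
bn_cpt <- function(child, parents, specs, values) {
  k <- length(specs[[child]]$states)
  pdims <- vapply(parents, function(p) length(specs[[p]]$states), integer(1))
  dims <- c(k, pdims)
  if (length(values) != prod(dims))
    stop("CPT for '", child, "': expected ", prod(dims), " values, got ",
         length(values), call. = FALSE)
  arr <- array(as.numeric(values), dim = dims)
  dimnames(arr) <- c(list(specs[[child]]$states),
                     lapply(parents, function(p) specs[[p]]$states))
  if (any(arr < -1e-12 | arr > 1 + 1e-12))
    stop("CPT for '", child, "': probabilities outside [0, 1]", call. = FALSE)
  sums <- if (length(parents) == 0L) sum(arr)
          else apply(arr, seq_along(dims)[-1L], sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("CPT for '", child, "': conditional distributions must sum to 1 ",
         "(max deviation ", format(max(abs(sums - 1))), ")", call. = FALSE)
  structure(list(child = child, parents = parents, values = arr),
            class = "bn_cpt")
}

#' Assemble a belief network
#'
#' @param structure a [bn_structure].
#' @param tables named list of [bn_cpt], one per node, parent lists
#'   matching the structure.
#' @param specs named list of [variable_spec] covering every node.
#' @return object of class `belief_network`.
#' @export
belief_network <- function(structure, tables, specs) {
  stopifnot(inherits(structure, "bn_structure"))
  missing_tab <- setdiff(structure$nodes, names(tables))
  if (length(missing_tab))
    stop("missing CPT for node(s): ", paste(missing_tab, collapse = ", "),
         call. = FALSE)
  missing_spec <- setdiff(structure$nodes, names(specs))
  if (length(missing_spec))
    stop("missing variable spec for node(s): ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  for (v in structure$nodes) {
    tab <- tables[[v]]
    pa <- bn_parents(structure, v)
    if (!identical(sort(tab$parents), sort(pa)))
      stop("CPT parents for '", v, "' do not match structure", call. = FALSE)
  }
  structure(list(structure = structure, tables = tables[structure$nodes],
                 specs = specs[structure$nodes]),
            class = "belief_network")
}

#' @export
print.belief_network <- function(x, ...) {
  cat(sprintf("<belief_network> %d nodes, %d edges\n",
              length(x$structure$nodes), nrow(x$structure$edges)))
  invisible(x)
}

#' Write / read a belief network as JSON interchange
#'
#' Nodes with their ordered states, edges, and CPT values in column-major
#' array order (child dimension fastest).
#'
#' @param net a [belief_network].
#' @param path output path.
#' @return `path` invisibly, or the reloaded [belief_network].
#' @export
bn_write_json <- function(net, path) {
  obj <- list(
    nodes = lapply(net$structure$nodes, function(v) {
      sp <- net$specs[[v]]
      list(name = v, role = sp$role, states = sp$states,
           bin_edges = sp$bin_edges, unit = sp$unit)
    }),
    edges = apply(net$structure$edges, 1, function(e) list(from = e[[1]], to = e[[2]])),
    cpts = lapply(net$structure$nodes, function(v) {
      tab <- net$tables[[v]]
      list(child = v, parents = as.list(tab$parents),
           values = as.numeric(tab$values))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname bn_write_json
#' @export
bn_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(obj$nodes, function(n)
    variable_spec(n$name, n$role, unlist(n$states),
                  bin_edges = if (!is.null(n$bin_edges)) unlist(n$bin_edges),
                  unit = n$unit))
  names(specs) <- vapply(specs, `[[`, "", "name")
  edges <- if (length(obj$edges)) {
    do.call(rbind, lapply(obj$edges, function(e) c(e$from, e$to)))
  } else NULL
  struct <- bn_structure(names(specs), edges)
  tables <- lapply(obj$cpts, function(ct)
    bn_cpt(ct$child, unlist2chr(ct$parents), specs, unlist(ct$values)))
  names(tables) <- vapply(tables, `[[`, "", "child")
  belief_network(struct, tables, specs)
}

# unlist that keeps character(0) for empty lists
unlist2chr <- function(x) if (length(x)) unlist(x) else character(0)
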