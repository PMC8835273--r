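# ---- factor algebra -------------------------------------------------------
# A factor is list(vars = character, states = named list of state labels,
# values = numeric array with dim = lengths(states) in vars order; a scalar
# factor has vars = character(0) and a length-1 values vector).

ve_factor <- function(vars, states, values) {
  if (length(vars)) {
    values <- array(values, dim = vapply(states, length, integer(1)))
  } else {
    values <- as.numeric(values)
  }
  list(vars = vars, states = states, values = values)
}

cpt_factor <- function(net, node) {
  tab <- net$tables[[node]]
  vars <- c(node, tab$parents)
  states <- lapply(vars, function(v) net$specs[[v]]$states)
  names(states) <- vars
  ve_factor(vars, states, tab$values)
}

factor_product <- function(f1, f2) {
  if (!length(f1$vars)) return(ve_factor(f2$vars, f2$states, f2$values * as.numeric(f1$values)))
  if (!length(f2$vars)) return(ve_factor(f1$vars, f1$states, f1$values * as.numeric(f2$values)))
  vars <- union(f1$vars, f2$vars)
  states <- c(f1$states, f2$states)[vars]
  grid <- do.call(expand.grid, c(lapply(states, seq_along),
                                 KEEP.OUT.ATTRS = FALSE))
  v1 <- f1$values[as.matrix(grid[f1$vars])]
  v2 <- f2$values[as.matrix(grid[f2$vars])]
  ve_factor(vars, states, v1 * v2)
}

factor_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (!var %in% f$vars) return(f)
  if (!length(keep))
    return(ve_factor(character(0), list(), sum(f$values)))
  perm <- c(match(keep, f$vars), match(var, f$vars))
  arr <- aperm(array(f$values, dim = vapply(f$states, length, integer(1))), perm)
  d <- dim(arr)
  nkeep <- prod(d[-length(d)])
  vals <- rowSums(matrix(arr, nrow = nkeep))
  ve_factor(keep, f$states[keep], vals)
}

factor_reduce <- function(f, var, state_index) {
  if (!var %in% f$vars) return(f)
  ix <- lapply(f$vars, function(v) if (v == var) state_index else
    seq_along(f$states[[v]]))
  vals <- do.call(`[`, c(list(f$values), ix, list(drop = FALSE)))
  keep <- setdiff(f$vars, var)
  if (!length(keep)) return(ve_factor(character(0), list(), as.numeric(vals)))
  ve_factor(keep, f$states[keep], as.numeric(vals))
}

# min-fill elimination order over the factor scopes; deterministic
# alphabetical tie-break.
elimination_order <- function(scopes, to_eliminate) {
  adj <- stats::setNames(vector("list", length(to_eliminate)), to_eliminate)
  all_vars <- unique(unlist(scopes))
  adj <- stats::setNames(lapply(all_vars, function(v) character(0)), all_vars)
  for (sc in scopes)
    for (v in sc)
      adj[[v]] <- union(adj[[v]], setdiff(sc, v))
  order <- character(0)
  remaining <- sort(to_eliminate)
  while (length(remaining)) {
    fill <- vapply(remaining, function(v) {
      nb <- intersect(adj[[v]], names(adj))
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1L))
        for (j in seq(i + 1L, length(nb)))
          if (!nb[j] %in% adj[[nb[i]]]) cnt <- cnt + 1L
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]  # ties: first in sorted order
    nb <- intersect(adj[[v]], names(adj))
    for (a in nb) adj[[a]] <- union(setdiff(adj[[a]], v), setdiff(nb, a))
    adj[[v]] <- NULL
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

# eliminate vars from a factor list by sum-product; returns a single factor
# over the surviving vars (possibly scalar).
run_elimination <- function(factors, eliminate) {
  ord <- elimination_order(lapply(factors, `[[`, "vars"), eliminate)
  for (v in ord) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
  }
  Reduce(factor_product, factors)
}

# evidence: named list/vector variable -> state label
reduce_all <- function(net, factors, evidence) {
  for (v in names(evidence)) {
    st <- match(evidence[[v]], net$specs[[v]]$states)
    if (is.na(st))
      stop("illegal evidence state '", evidence[[v]], "' for variable '", v,
           "'", call. = FALSE)
    factors <- lapply(factors, factor_reduce, var = v, state_index = st)
  }
  factors
}

# ---- user-facing inference -------------------------------------------------

#' Joint probability of a complete assignment
#'
#' Product of the per-node conditional probabilities under the network's
#' DAG/CPT factorization.
#'
#' @param net a [belief_network].
#' @param assignment named character vector/list mapping every node to a
#'   state label.
#' @return probability in \[0, 1\].
#' @export
joint_probability <- function(net, assignment) {
  nodes <- net$structure$nodes
  miss <- setdiff(nodes, names(assignment))
  if (length(miss))
    stop("assignment misses node(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  p <- 1
  for (v in nodes) {
    tab <- net$tables[[v]]
    ix <- vapply(c(v, tab$parents), function(u) {
      m <- match(assignment[[u]], net$specs[[u]]$states)
      if (is.na(m)) stop("illegal state '", assignment[[u]], "' for '", u,
                         "'", call. = FALSE)
      m
    }, integer(1))
    p <- p * net$tables[[v]]$values[matrix(ix, 1)]
  }
  as.numeric(p)
}

#' Posterior distribution of a query variable
#'
#' Exact inference by variable elimination (min-fill order,
#' deterministic tie-break). Returns the normalized conditional
#' distribution of `query` given the evidence.
#'
#' @param net a [belief_network].
#' @param query query variable name (not in the evidence).
#' @param evidence named character vector/list of observed states
#'   (possibly empty).
#' @return named probability vector over the query's states.
#' @export
posterior <- function(net, query, evidence = NULL) {
  if (query %in% names(evidence))
    stop("query variable is part of the evidence", call. = FALSE)
  jp <- joint_posterior(net, query, evidence)
  stats::setNames(as.numeric(jp), net$specs[[query]]$states)
}

#' Joint posterior over a small set of variables
#'
#' @param net a [belief_network].
#' @param vars character vector of query variables.
#' @param evidence named character vector/list of observed states.
#' @return numeric array over the query variables' states (in `vars`
#'   order), normalized given the evidence.
#' @export
joint_posterior <- function(net, vars, evidence = NULL) {
  stopifnot(all(vars %in% net$structure$nodes))
  factors <- lapply(net$structure$nodes, cpt_factor, net = net)
  factors <- reduce_all(net, factors, evidence)
  eliminate <- setdiff(net$structure$nodes, c(vars, names(evidence)))
  res <- run_elimination(factors, eliminate)
  z <- sum(res$values)
  if (z <= 0)
    stop("impossible evidence: zero marginal probability", call. = FALSE)
  if (!length(res$vars)) return(res$values / z)
  perm <- match(vars, res$vars)
  arr <- res$values / z
  if (length(vars) > 1L) arr <- aperm(arr, perm)
  dimnames(arr) <- lapply(vars, function(v) net$specs[[v]]$states)
  arr
}

#' Probability of partial evidence
#'
#' Marginal probability of an arbitrary partial assignment, obtained by
#' eliminating all unobserved variables.
#'
#' @inheritParams posterior
#' @return probability in \[0, 1\].
#' @export
prob_evidence <- function(net, evidence) {
  factors <- lapply(net$structure$nodes, cpt_factor, net = net)
  factors <- reduce_all(net, factors, evidence)
  res <- run_elimination(factors, setdiff(net$structure$nodes, names(evidence)))
  sum(res$values)
}

#' Log-likelihood of a dataset under a network
#'
#' Sum over records of the log (marginal) record probability; missing
#' cells are marginalized exactly. A record of probability zero yields
#' `-Inf` with a diagnostic attribute listing the offending rows.
#'
#' @param net a [belief_network].
#' @param ds a [park_dataset] whose columns cover the network's nodes.
#' @return log-likelihood (<= 0), possibly `-Inf` with attribute
#'   `zero_records`.
#' @export
log_likelihood <- function(net, ds) {
  nodes <- net$structure$nodes
  X <- encode_records(ds, nodes)
  ll_rows <- record_log_probs(net, X)
  ll <- sum(ll_rows)
  if (any(is.infinite(ll_rows)))
    attr(ll, "zero_records") <- which(is.infinite(ll_rows))
  ll
}

# per-record log marginal probabilities for an integer state matrix
# (NA = missing). Complete rows use the fast factored product; rows with
# missing cells fall back to exact elimination.
record_log_probs <- function(net, X) {
  nodes <- net$structure$nodes
  n <- nrow(X)
  out <- numeric(n)
  complete <- !apply(is.na(X), 1L, any)
  if (any(complete)) {
    lp <- numeric(sum(complete))
    Xc <- X[complete, , drop = FALSE]
    for (v in nodes) {
      tab <- net$tables[[v]]
      ix <- Xc[, c(v, tab$parents), drop = FALSE]
      lp <- lp + log(tab$values[ix])
    }
    out[complete] <- lp
  }
  for (r in which(!complete)) {
    obs <- which(!is.na(X[r, ]))
    ev <- stats::setNames(
      lapply(obs, function(j) net$specs[[nodes[j]]]$states[X[r, j]]),
      nodes[obs])
    out[r] <- log(prob_evidence(net, ev))
  }
  out
}

#' Most probable state of a target variable
#'
#' Argmax of the posterior; ties are broken by the lowest state index,
#' so prediction is deterministic.
#'
#' @inheritParams posterior
#' @param target target variable name.
#' @return list with `state` (label) and `probability`.
#' @export
predict_state <- function(net, target, evidence = NULL) {
  post <- posterior(net, target, evidence)
  ix <- which.max(post)  # which.max returns the first maximum
  list(state = names(post)[ix], probability = as.numeric(post[ix]))
}

# posterior of `target` for every row of an integer state matrix whose
# other columns are fully observed: P(t | rest) is proportional to the
# product over the target's family factors (its own CPT and its
# children's), which is exact. Rows with missing cells besides the
# target fall back to variable elimination. Returns an n x k matrix.
posterior_matrix <- function(net, target, X) {
  nodes <- net$structure$nodes
  k <- length(net$specs[[target]]$states)
  n <- nrow(X)
  fam <- c(target, bn_children(net$structure, target))
  fam_vars <- unique(unlist(lapply(fam, function(v) c(v, net$tables[[v]]$parents))))
  other <- setdiff(nodes, target)
  ok <- !apply(is.na(X[, intersect(fam_vars, other), drop = FALSE]), 1L, any)
  post <- matrix(NA_real_, n, k)
  if (any(ok)) {
    lp <- matrix(0, sum(ok), k)
    Xo <- X[ok, , drop = FALSE]
    for (s in seq_len(k)) {
      Xs <- Xo
      Xs[, target] <- s
      for (v in fam) {
        tab <- net$tables[[v]]
        ix <- Xs[, c(v, tab$parents), drop = FALSE]
        lp[, s] <- lp[, s] + log(tab$values[ix])
      }
    }
    m <- apply(lp, 1L, max)
    w <- exp(lp - m)
    post[ok, ] <- w / rowSums(w)
  }
  for (r in which(!ok)) {
    obs <- which(!is.na(X[r, ]) & nodes != target)
    ev <- stats::setNames(
      lapply(obs, function(j) net$specs[[nodes[j]]]$states[X[r, j]]),
      nodes[obs])
    post[r, ] <- posterior(net, target, ev)
  }
  post
}
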