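# ---- EM parameter learning ------------------------------------------------

# flat family-config index for an integer state matrix: child state index
# varies fastest, then parents in CPT order (matches array linear order).
family_flat_index <- function(X, vars, dims) {
  idx <- X[, vars[1L]]
  mult <- dims[1L]
  if (length(vars) > 1L) {
    for (j in 2:length(vars)) {
      idx <- idx + (X[, vars[j]] - 1L) * mult
      mult <- mult * dims[j]
    }
  }
  idx
}

# counts array per node family from a complete integer state matrix
family_counts <- function(X, child, parents, dims, weights = NULL) {
  vars <- c(child, parents)
  flat <- family_flat_index(X, vars, dims)
  total <- prod(dims)
  if (is.null(weights)) {
    cnt <- tabulate(flat, nbins = total)
  } else {
    cnt <- numeric(total)
    rs <- rowsum(weights, flat)
    cnt[as.integer(rownames(rs))] <- rs[, 1L]
  }
  array(cnt, dim = dims)
}

# normalize a counts array (child dimension first) into a CPT, adding
# pseudo_count to every cell; all-zero rows (with pseudo_count = 0)
# become uniform.
counts_to_cpt <- function(counts, pseudo_count) {
  counts <- counts + pseudo_count
  k <- dim(counts)[1L]
  m <- matrix(counts, nrow = k)
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    m[, zero] <- 1 / k
    cs[zero] <- 1
  }
  array(sweep(m, 2L, cs, `/`), dim = dim(counts))
}

random_cpt_values <- function(dims) {
  k <- dims[1L]
  m <- matrix(stats::rgamma(prod(dims), shape = 1), nrow = k)
  array(sweep(m, 2L, colSums(m), `/`), dim = dims)
}

# enumerate completions of one incomplete record; returns list(grid =
# integer matrix over all nodes (one row per completion), logp = NULL)
complete_record_grid <- function(x, miss_idx, state_counts) {
  grids <- lapply(miss_idx, function(j) seq_len(state_counts[j]))
  G <- as.matrix(do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE)))
  n_comp <- nrow(G)
  M <- matrix(rep(x, each = n_comp), nrow = n_comp,
              dimnames = list(NULL, names(x)))
  M[, miss_idx] <- G
  M
}

#' Fit CPT parameters by expectation-maximization
#'
#' Learns the conditional probability tables of a fixed structure from
#' records that may contain missing cells. On fully complete data a
#' single M-step reproduces the (pseudo-count smoothed) relative
#' conditional frequencies exactly; with missing cells the E-step
#' distributes each record over its completions in exact posterior
#' proportion, and the observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' With `pseudo_count > 0` the M-step maximizes the Dirichlet-smoothed
#' (MAP) objective; the observed-data log-likelihood then converges but
#' may fluctuate within the prior's pull. Strict per-iteration
#' likelihood monotonicity is guaranteed for `pseudo_count = 0`
#' (maximum-likelihood EM).
#'
#' @param structure a [bn_structure].
#' @param ds a [park_dataset] covering the structure's nodes.
#' @param pseudo_count nonnegative Dirichlet smoothing pseudo-count added
#'   to every CPT cell at the M-step (default 1; prevents zero rows).
#' @param tol relative log-likelihood improvement below which EM stops.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE`
#'   with a warning.
#' @param seed integer seed for the random CPT initialization; `NULL`
#'   initializes every table uniform.
#' @param max_completions guard on the number of per-record missing-cell
#'   completions enumerated in the E-step.
#' @return list with `net` (the fitted [belief_network]), `loglik`
#'   (final observed-data log-likelihood), `trace` (per-iteration
#'   log-likelihoods), `iterations`, `converged`.
#' @export
em_fit <- function(structure, ds, pseudo_count = 1, tol = 1e-6,
                   max_iter = 500L, seed = NULL, max_completions = 1e5) {
  stopifnot(inherits(structure, "bn_structure"), inherits(ds, "park_dataset"))
  nodes <- structure$nodes
  if (!nrow(ds$records)) stop("empty dataset", call. = FALSE)
  specs <- ds$specs[nodes]
  if (any(vapply(specs, is.null, logical(1))))
    stop("dataset lacks spec for some structure node", call. = FALSE)
  X <- encode_records(ds, nodes)
  state_counts <- vapply(specs, function(s) length(s$states), integer(1))

  fam <- lapply(nodes, function(v) {
    pa <- bn_parents(structure, v)
    list(child = v, parents = pa, dims = state_counts[c(v, pa)])
  })
  names(fam) <- nodes

  complete <- !apply(is.na(X), 1L, any)
  Xc <- X[complete, , drop = FALSE]
  base_counts <- lapply(fam, function(f)
    if (nrow(Xc)) family_counts(Xc, f$child, f$parents, f$dims)
    else array(0, dim = f$dims))

  build_net <- function(params) {
    tables <- lapply(nodes, function(v)
      bn_cpt(v, fam[[v]]$parents, specs, params[[v]]))
    names(tables) <- nodes
    belief_network(structure, tables, specs)
  }

  # fast path: complete data has a closed-form maximum
  if (all(complete)) {
    params <- lapply(nodes, function(v) counts_to_cpt(base_counts[[v]], pseudo_count))
    names(params) <- nodes
    net <- build_net(params)
    ll <- sum(record_log_probs(net, X))
    return(list(net = net, loglik = ll, trace = ll, iterations = 1L,
                converged = TRUE))
  }

  incomplete_rows <- which(!complete)
  comp_grids <- lapply(incomplete_rows, function(r) {
    miss <- which(is.na(X[r, ]))
    n_comp <- prod(state_counts[miss])
    if (n_comp > max_completions)
      stop("record ", r, " has too many missing-cell completions (",
           n_comp, "); reduce missingness or raise max_completions",
           call. = FALSE)
    complete_record_grid(X[r, ], miss, state_counts)
  })

  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    params <- lapply(nodes, function(v) random_cpt_values(fam[[v]]$dims))
  } else {
    params <- lapply(nodes, function(v)
      array(1 / state_counts[v], dim = fam[[v]]$dims))
  }
  names(params) <- nodes

  trace <- numeric(0)
  converged <- FALSE
  net <- build_net(params)
  for (iter in seq_len(max_iter)) {
    # E-step under current params; also yields the current log-likelihood
    counts <- base_counts
    ll <- if (nrow(Xc)) sum(record_log_probs(net, Xc)) else 0
    for (i in seq_along(incomplete_rows)) {
      M <- comp_grids[[i]]
      lp <- numeric(nrow(M))
      for (v in nodes) {
        tab <- net$tables[[v]]
        lp <- lp + log(tab$values[M[, c(v, tab$parents), drop = FALSE]])
      }
      mx <- max(lp)
      if (!is.finite(mx)) {
        w <- rep(1 / nrow(M), nrow(M))
        ll <- -Inf
      } else {
        w <- exp(lp - mx)
        z <- sum(w)
        ll <- ll + mx + log(z)
        w <- w / z
      }
      for (v in nodes) {
        f <- fam[[v]]
        flat <- family_flat_index(M, c(f$child, f$parents), f$dims)
        rs <- rowsum(w, flat)
        counts[[v]][as.integer(rownames(rs))] <-
          counts[[v]][as.integer(rownames(rs))] + rs[, 1L]
      }
    }
    trace <- c(trace, ll)
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (is.finite(ll) && abs(ll - prev) <= tol * (abs(prev) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
    # M-step
    params <- lapply(nodes, function(v) counts_to_cpt(counts[[v]], pseudo_count))
    names(params) <- nodes
    net <- build_net(params)
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations",
            call. = FALSE)
  list(net = net, loglik = trace[length(trace)], trace = trace,
       iterations = length(trace), converged = converged)
}
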