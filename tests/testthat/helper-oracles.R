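# Independent brute-force oracles. These re-derive quantities from first
# principles (full-joint enumeration, scalar loops) and deliberately share
# no code with the package's inference/learning paths.

# full joint table: one row per complete assignment (integer state
# indices), with its probability = product of CPT lookups
oracle_joint_table <- function(net) {
  nodes <- net$structure$nodes
  grid <- do.call(expand.grid, c(stats::setNames(
    lapply(nodes, function(v) seq_along(net$specs[[v]]$states)), nodes),
    KEEP.OUT.ATTRS = FALSE))
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    tab <- net$tables[[v]]
    ix <- as.matrix(grid[, c(v, tab$parents), drop = FALSE])
    p <- p * tab$values[ix]
  }
  grid$p <- p
  grid
}

# posterior of `query` given evidence (named list var -> state label),
# by filtering and summing the full joint
oracle_posterior <- function(net, query, evidence = NULL) {
  jt <- oracle_joint_table(net)
  keep <- rep(TRUE, nrow(jt))
  for (v in names(evidence))
    keep <- keep & jt[[v]] == match(evidence[[v]], net$specs[[v]]$states)
  k <- length(net$specs[[query]]$states)
  out <- numeric(k)
  for (s in seq_len(k)) out[s] <- sum(jt$p[keep & jt[[query]] == s])
  out / sum(out)
}

# marginal probability of a partial assignment
oracle_prob_evidence <- function(net, evidence) {
  jt <- oracle_joint_table(net)
  keep <- rep(TRUE, nrow(jt))
  for (v in names(evidence))
    keep <- keep & jt[[v]] == match(evidence[[v]], net$specs[[v]]$states)
  sum(jt$p[keep])
}

# mutual information (bits) between two variables by joint enumeration
oracle_mutual_information <- function(net, a, b) {
  jt <- oracle_joint_table(net)
  ka <- length(net$specs[[a]]$states)
  kb <- length(net$specs[[b]]$states)
  j <- matrix(0, ka, kb)
  for (i in seq_len(ka)) for (l in seq_len(kb))
    j[i, l] <- sum(jt$p[jt[[a]] == i & jt[[b]] == l])
  j <- j / sum(j)
  pa_ <- rowSums(j); pb_ <- colSums(j)
  mi <- 0
  for (i in seq_len(ka)) for (l in seq_len(kb))
    if (j[i, l] > 0) mi <- mi + j[i, l] * log2(j[i, l] / (pa_[i] * pb_[l]))
  mi
}

# observed-data log-likelihood of an integer state matrix (NA = missing)
# under a net, by summing the joint over each record's completions
oracle_loglik <- function(net, X) {
  jt <- oracle_joint_table(net)
  nodes <- net$structure$nodes
  total <- 0
  for (r in seq_len(nrow(X))) {
    keep <- rep(TRUE, nrow(jt))
    for (j in seq_along(nodes))
      if (!is.na(X[r, j])) keep <- keep & jt[[nodes[j]]] == X[r, j]
    total <- total + log(sum(jt$p[keep]))
  }
  total
}

# scalar-loop evaluation of the congregate index from raw primitives
oracle_congregate <- function(S, A_start, A_end, B, T) {
  A <- (A_start + A_end) / 2
  N <- length(B)
  acc <- 0
  for (i in seq_len(N)) acc <- acc + (B[i] / A) * log(T[i])
  acc / (N * log10(S))
}

# ---- random fixtures -------------------------------------------------------

rand_cpt_vals <- function(dims) {
  m <- matrix(stats::rgamma(prod(dims), shape = 1), nrow = dims[1L])
  array(sweep(m, 2L, colSums(m), `/`), dim = dims)
}

# random net over n_nodes nodes with 2..max_states states each; random
# DAG respecting a random topological order
random_net <- function(n_nodes, max_states = 4L, edge_prob = 0.4,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("V", seq_len(n_nodes))
  specs <- lapply(nodes, function(v) {
    k <- sample(2:max_states, 1L)
    variable_spec(v, "spatial", paste0(v, "_s", seq_len(k)))
  })
  names(specs) <- nodes
  ord <- sample(nodes)
  edges <- NULL
  for (i in seq_len(n_nodes - 1L))
    for (j in seq(i + 1L, n_nodes))
      if (stats::runif(1) < edge_prob)
        edges <- rbind(edges, c(ord[i], ord[j]))
  struct <- bn_structure(nodes, edges)
  tables <- lapply(nodes, function(v) {
    pa <- struct$edges[struct$edges[, 2] == v, 1]
    pa <- unname(pa)
    dims <- vapply(c(v, pa), function(u) length(specs[[u]]$states), integer(1))
    bn_cpt(v, pa, specs, rand_cpt_vals(dims))
  })
  names(tables) <- nodes
  belief_network(struct, tables, specs)
}

# random congregate session with valid primitives
random_session <- function(unit_id = 1L) {
  S <- stats::runif(1, 20, 900)
  N <- sample(2:12, 1L)
  sizes <- integer(0)
  left <- N
  while (left > 0) {
    b <- sample.int(min(left, 5L), 1L)
    sizes <- c(sizes, b)
    left <- left - b
  }
  Tg <- stats::runif(length(sizes), 1.5, 60)
  persons <- data.frame(B = rep(sizes, sizes), T = rep(Tg, sizes))
  A_start <- sample(1:(N + 3L), 1L)
  A_end <- sample(0:(N + 3L), 1L)
  congregate_session(unit_id, S, A_start, A_end, persons, N)
}

# small hand-set chain net A -> B used across tests
toy_chain_net <- function() {
  specs <- list(
    A = variable_spec("A", "spatial", c("a1", "a2")),
    B = variable_spec("B", "interaction", c("b1", "b2")))
  st <- bn_structure(c("A", "B"), rbind(c("A", "B")))
  tabs <- list(
    A = bn_cpt("A", character(0), specs, c(0.3, 0.7)),
    B = bn_cpt("B", "A", specs, c(0.9, 0.1, 0.2, 0.8)))
  belief_network(st, tabs, specs)
}
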