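# ---- prior constraints ----------------------------------------------------

#' Edge constraints for structure search
#'
#' Encodes the prior knowledge used to initialize and restrict the
#' network search: edges that must be present, edges that may never be
#' present, and an optional tier order (e.g. spatial variables before
#' activity variables before interaction variables) that forbids edges
#' pointing against the tier direction. Edges within a tier are allowed.
#'
#' @param required,forbidden NULL, 2-column matrix, or data.frame of
#'   (parent, child) pairs.
#' @param tier_order NULL or ordered list of character vectors; an edge
#'   from a later tier into an earlier tier is forbidden.
#' @return object of class `edge_constraints`.
#' @export
edge_constraints <- function(required = NULL, forbidden = NULL,
                             tier_order = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0)
      return(matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to"))))
    x <- as.matrix(x)
    matrix(as.character(x), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  required <- norm(required)
  forbidden <- norm(forbidden)
  key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
  if (length(intersect(key(required), key(forbidden))))
    stop("an edge cannot be both required and forbidden", call. = FALSE)
  structure(list(required = required, forbidden = forbidden,
                 tier_order = tier_order),
            class = "edge_constraints")
}

# tier index of each variable; NA for variables outside the tiers
tier_of <- function(constraints, nodes) {
  tiers <- constraints$tier_order
  out <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  for (i in seq_along(tiers)) out[intersect(tiers[[i]], nodes)] <- i
  out
}

edge_allowed <- function(constraints, from, to, nodes) {
  if (any(constraints$forbidden[, 1] == from & constraints$forbidden[, 2] == to))
    return(FALSE)
  if (!is.null(constraints$tier_order)) {
    tr <- tier_of(constraints, nodes)
    if (!is.na(tr[from]) && !is.na(tr[to]) && tr[from] > tr[to]) return(FALSE)
  }
  TRUE
}

edge_required <- function(constraints, from, to) {
  any(constraints$required[, 1] == from & constraints$required[, 2] == to)
}

#' Read edge constraints from a YAML file
#'
#' Expected keys: `required` and `forbidden` (lists of `[from, to]`
#' pairs) and `tiers` (ordered list of variable-name lists).
#'
#' @param path YAML file path.
#' @return an [edge_constraints] object.
#' @export
read_constraints_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pairs <- function(x) if (length(x)) do.call(rbind, lapply(x, unlist)) else NULL
  edge_constraints(required = pairs(y$required), forbidden = pairs(y$forbidden),
                   tier_order = lapply(y$tiers, unlist))
}

#' Default structure-search constraints for a space type
#'
#' Encodes the a-priori mechanism "spatial factors -> activity type ->
#' social interaction": spatial and individual variables form the first
#' tier, activity variables the second, the two interaction variables
#' the last, and the draft contains the mediation prior edges (physical
#' activity -> crowds congregate where physical activity is modelled,
#' leisure activity -> engagement where leisure activity is modelled).
#'
#' @param specs named list of [variable_spec] for the variables in play.
#' @param required_mediation include the mediation prior edges as
#'   required (default TRUE); set FALSE for an uninformed search that
#'   keeps only the tier order.
#' @return an [edge_constraints] object.
#' @export
default_constraints <- function(specs, required_mediation = TRUE) {
  roles <- vapply(specs, `[[`, "", "role")
  tiers <- list(names(roles)[roles %in% c("spatial", "individual")],
                names(roles)[roles == "activity"],
                names(roles)[roles == "interaction"])
  req <- NULL
  if (required_mediation) {
    req <- rbind(
      if (all(c("physical_activity", "crowds_congregate") %in% names(specs)))
        c("physical_activity", "crowds_congregate"),
      if (all(c("leisure_activity", "engagement") %in% names(specs)))
        c("leisure_activity", "engagement"))
  }
  edge_constraints(required = req, tier_order = tiers)
}

# ---- draft and candidates -------------------------------------------------

#' Initial (draft) network from prior constraints
#'
#' The draft DAG contains exactly the required edges; required sets
#' that are cyclic or that violate the tier order are an error.
#'
#' @param constraints an [edge_constraints].
#' @param specs named list of [variable_spec] giving the node set.
#' @return a [bn_structure].
#' @export
draft_network <- function(constraints, specs) {
  nodes <- names(specs)
  req <- constraints$required
  for (i in seq_len(nrow(req)))
    if (!edge_allowed(constraints, req[i, 1], req[i, 2], nodes))
      stop("required edge ", req[i, 1], " -> ", req[i, 2],
           " violates the forbidden set or tier order", call. = FALSE)
  bn_structure(nodes, req)  # errors if the required set is cyclic
}

#' Propose candidate structures by random edge mutations
#'
#' Starting from the draft, each candidate is produced by a random walk
#' of single-edge moves (add / remove / reverse), of geometric length,
#' honoring the forbidden set, tier order, required edges, acyclicity,
#' and the parent cap. The draft itself is always the first candidate;
#' candidates are deduplicated. Deterministic under a fixed seed.
#'
#' @param draft a [bn_structure].
#' @param constraints an [edge_constraints].
#' @param n_candidates number of distinct candidates wanted.
#' @param max_parents cap on the number of parents per node.
#' @param seed integer seed.
#' @param walk_mean mean number of mutation moves per candidate (0
#'   yields copies of the draft only).
#' @return list of distinct [bn_structure] objects (the draft first).
#' @export
propose_candidates <- function(draft, constraints, n_candidates,
                               max_parents = 4L, seed = 1L, walk_mean = 8) {
  stopifnot(n_candidates >= 1)
  nodes <- draft$nodes
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  canon <- function(s) paste(sort(paste(s$edges[, 1], s$edges[, 2], sep = ">")),
                             collapse = "|")
  out <- list(draft)
  seen <- canon(draft)
  attempts <- 0L
  max_attempts <- 60L * n_candidates
  while (length(out) < n_candidates && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- draft
    n_moves <- if (walk_mean <= 0) 0L else 1L + stats::rgeom(1L, 1 / walk_mean)
    for (m in seq_len(n_moves)) cand <- mutate_structure(cand, constraints, max_parents)
    key <- canon(cand)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out <- c(out, list(cand))
    }
  }
  if (length(out) < min(2L, n_candidates) && walk_mean > 0)
    stop("constraint set admits no candidate beyond the draft", call. = FALSE)
  out
}

# fast internal edge ops: callers guarantee validity, so skip the full
# bn_structure() revalidation done by add_edge/remove_edge
fast_add <- function(s, from, to) {
  s$edges <- rbind(s$edges, c(from, to))
  s
}
fast_remove <- function(s, from, to) {
  keep <- !(s$edges[, 1] == from & s$edges[, 2] == to)
  s$edges <- s$edges[keep, , drop = FALSE]
  s
}

# one random feasible add/remove/reverse move, by rejection sampling
# (identity if no feasible move is found within the attempt budget)
mutate_structure <- function(s, constraints, max_parents) {
  nodes <- s$nodes
  n_par <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(s$edges)) {
    tb <- table(s$edges[, 2])
    n_par[names(tb)] <- as.integer(tb)
  }
  non_required <- if (nrow(s$edges)) {
    which(!vapply(seq_len(nrow(s$edges)), function(i)
      edge_required(constraints, s$edges[i, 1], s$edges[i, 2]), logical(1)))
  } else integer(0)

  for (mv in sample(c("add", "remove", "reverse"))) {
    if (mv == "add") {
      for (try in 1:20) {
        ft <- sample(nodes, 2L)
        if (has_edge(s, ft[1], ft[2])) next
        if (n_par[ft[2]] >= max_parents) next
        if (!edge_allowed(constraints, ft[1], ft[2], nodes)) next
        if (edge_creates_cycle(s, ft[1], ft[2])) next
        return(fast_add(s, ft[1], ft[2]))
      }
    } else if (mv == "remove" && length(non_required)) {
      i <- non_required[sample.int(length(non_required), 1L)]
      return(fast_remove(s, s$edges[i, 1], s$edges[i, 2]))
    } else if (mv == "reverse" && length(non_required)) {
      for (try in 1:10) {
        i <- non_required[sample.int(length(non_required), 1L)]
        f <- s$edges[i, 1]; t <- s$edges[i, 2]
        if (!edge_allowed(constraints, t, f, nodes)) next
        if (n_par[f] >= max_parents) next
        s2 <- fast_remove(s, f, t)
        if (edge_creates_cycle(s2, t, f)) next
        return(fast_add(s2, t, f))
      }
    }
  }
  s
}

# ---- split, evaluation, selection -----------------------------------------

#' Split a dataset into non-overlapping training and test sets
#'
#' @param ds a [park_dataset].
#' @param test_fraction fraction of records held out, in (0, 1).
#' @param seed integer seed.
#' @param stratify_by optional variable name; the split then preserves
#'   per-state proportions of that variable.
#' @return list with `train` and `test` [park_dataset]s.
#' @export
split_dataset <- function(ds, test_fraction = 0.3, seed = 1L,
                          stratify_by = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- nrow(ds$records)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (is.null(stratify_by)) {
    test_ix <- sort(sample.int(n, max(1L, round(test_fraction * n))))
  } else {
    g <- ds$records[[stratify_by]]
    g[is.na(g)] <- "<missing>"
    test_ix <- sort(unlist(lapply(split(seq_len(n), g), function(ix) {
      if (length(ix) < 2L) return(integer(0))
      sample(ix, max(1L, round(test_fraction * length(ix))))
    }), use.names = FALSE))
  }
  list(train = park_dataset(ds$records[-test_ix, , drop = FALSE], ds$specs,
                            ds$provenance),
       test = park_dataset(ds$records[test_ix, , drop = FALSE], ds$specs,
                           ds$provenance))
}

#' Fit and score one candidate structure
#'
#' Fits the candidate's CPTs on the training set with [em_fit()], then,
#' for every test record and target variable, computes the posterior of
#' the target given all other observed variables and scores the
#' logarithmic loss (mean negative log probability of the observed
#' state, zero is perfect) and the accuracy (fraction of records where
#' the argmax state matches). Predicted probabilities are floored at
#' 1e-9 before taking logs so sparse test sets keep a finite loss.
#'
#' @param structure a [bn_structure].
#' @param train,test [park_dataset]s from a non-overlapping split.
#' @param targets character vector of target variables.
#' @param em_args list of extra arguments passed to [em_fit()].
#' @return object of class `candidate_result`: list with `structure`,
#'   `fitted`, `train_loglik`, and `metrics` (data.frame of per-target
#'   `log_loss` and `accuracy`).
#' @export
evaluate_candidate <- function(structure, train, test, targets,
                               em_args = list()) {
  fit <- do.call(em_fit, c(list(structure = structure, ds = train), em_args))
  net <- fit$net
  Xt <- encode_records(test, structure$nodes)
  metrics <- do.call(rbind, lapply(targets, function(tg) {
    obs <- Xt[, tg]
    keep <- !is.na(obs)
    if (!any(keep))
      stop("target '", tg, "' entirely missing in the test set", call. = FALSE)
    post <- posterior_matrix(net, tg, Xt[keep, , drop = FALSE])
    p_obs <- post[cbind(seq_len(sum(keep)), obs[keep])]
    pred <- max.col(post, ties.method = "first")
    data.frame(target = tg,
               log_loss = mean(-log(pmax(p_obs, 1e-9))),
               accuracy = mean(pred == obs[keep]),
               n_test = sum(keep))
  }))
  structure(list(structure = structure, fitted = net,
                 train_loglik = fit$loglik, metrics = metrics),
            class = "candidate_result")
}

#' Select the best candidate
#'
#' Default rule: highest mean target accuracy; ties broken by lower
#' mean log loss, then by fewer edges, then by candidate order.
#'
#' @param candidates list of `candidate_result` objects.
#' @param selection_rule `"accuracy"` (default) or `"log_loss"` (lowest
#'   mean log loss first, accuracy as tie-break).
#' @return the winning `candidate_result`.
#' @export
select_best <- function(candidates, selection_rule = c("accuracy", "log_loss")) {
  stopifnot(length(candidates) >= 1)
  selection_rule <- match.arg(selection_rule)
  acc <- vapply(candidates, function(cr) mean(cr$metrics$accuracy), numeric(1))
  ll <- vapply(candidates, function(cr) mean(cr$metrics$log_loss), numeric(1))
  ne <- vapply(candidates, function(cr) nrow(cr$structure$edges), numeric(1))
  ord <- if (selection_rule == "accuracy") {
    order(-acc, ll, ne, seq_along(candidates))
  } else {
    order(ll, -acc, ne, seq_along(candidates))
  }
  candidates[[ord[1L]]]
}

#' Prior-constrained structure search
#'
#' End-to-end search: build the draft from the constraints, propose
#' random candidates, fit and score each on the train/test split, and
#' select the winner.
#'
#' @param train,test [park_dataset]s from a non-overlapping split.
#' @param constraints an [edge_constraints].
#' @param targets target variables scored on the test set.
#' @param n_candidates number of candidate structures.
#' @param max_parents parent cap per node.
#' @param seed integer seed driving candidate proposal.
#' @param em_args list of extra arguments for [em_fit()].
#' @param walk_mean mean mutation-walk length (see
#'   [propose_candidates()]).
#' @return list with `best` (`candidate_result`) and `ledger`
#'   (data.frame of per-candidate metrics).
#' @export
search_structures <- function(train, test, constraints, targets,
                              n_candidates = 200L, max_parents = 4L,
                              seed = 1L, em_args = list(), walk_mean = 8) {
  specs <- train$specs
  draft <- draft_network(constraints, specs)
  cands <- propose_candidates(draft, constraints, n_candidates,
                              max_parents = max_parents, seed = seed,
                              walk_mean = walk_mean)
  results <- lapply(cands, evaluate_candidate, train = train, test = test,
                    targets = targets, em_args = em_args)
  ledger <- do.call(rbind, lapply(seq_along(results), function(i) {
    m <- results[[i]]$metrics
    data.frame(candidate = i, n_edges = nrow(results[[i]]$structure$edges),
               train_loglik = results[[i]]$train_loglik,
               mean_accuracy = mean(m$accuracy),
               mean_log_loss = mean(m$log_loss))
  }))
  list(best = select_best(results), ledger = ledger, candidates = results)
}
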