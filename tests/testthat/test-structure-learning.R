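test_that("draft networks honor required edges and tier order", {
  specs <- load_variable_specs()
  net <- ground_truth_network("fitness_equipment")
  cons <- default_constraints(net$specs)
  draft <- draft_network(cons, net$specs)
  expect_true(any(draft$edges[, 1] == "physical_activity" &
                  draft$edges[, 2] == "crowds_congregate"))
  expect_true(any(draft$edges[, 1] == "leisure_activity" &
                  draft$edges[, 2] == "engagement"))
  # empty constraints give an edgeless DAG
  e0 <- draft_network(edge_constraints(), net$specs)
  expect_identical(nrow(e0$edges), 0L)
  # a required edge violating the tier order is rejected
  bad <- edge_constraints(required = rbind(c("engagement", "accessibility")),
                          tier_order = cons$tier_order)
  expect_error(draft_network(bad, net$specs), "tier")
  # a cyclic required set is rejected
  cyc <- edge_constraints(required = rbind(c("accessibility", "gender"),
                                           c("gender", "accessibility")))
  expect_error(draft_network(cyc, net$specs), "cycle")
  expect_error(edge_constraints(required = rbind(c("a", "b")),
                                forbidden = rbind(c("a", "b"))),
               "both required and forbidden")
})

test_that("candidate proposal respects constraints and is deterministic", {
  net <- ground_truth_network("path")
  cons <- default_constraints(net$specs)
  draft <- draft_network(cons, net$specs)
  # zero mutation moves: the draft itself
  only <- propose_candidates(draft, cons, 1, seed = 1, walk_mean = 0)
  expect_length(only, 1L)
  expect_identical(only[[1]]$edges, draft$edges)

  forb <- edge_constraints(
    required = cons$required,
    forbidden = rbind(c("visual_obstacles", "crowds_congregate")),
    tier_order = cons$tier_order)
  cands <- propose_candidates(draft, forb, 200, seed = 7)
  keys1 <- vapply(cands, function(s)
    paste(sort(paste(s$edges[, 1], s$edges[, 2])), collapse = "|"), "")
  expect_false(any(duplicated(keys1)))
  tiers <- forb$tier_order
  for (s in cands) {
    expect_silent(topological_order(s))  # acyclic
    expect_false(any(s$edges[, 1] == "visual_obstacles" &
                     s$edges[, 2] == "crowds_congregate"))
    # required edges always kept
    expect_true(any(s$edges[, 1] == "leisure_activity" &
                    s$edges[, 2] == "engagement"))
    # parent cap
    if (nrow(s$edges)) expect_lte(max(table(s$edges[, 2])), 4L)
    # tier order: no edge from interaction back into spatial/individual
    expect_false(any(s$edges[, 1] %in% tiers[[3]] & s$edges[, 2] %in% tiers[[1]]))
  }
  cands2 <- propose_candidates(draft, forb, 200, seed = 7)
  keys2 <- vapply(cands2, function(s)
    paste(sort(paste(s$edges[, 1], s$edges[, 2])), collapse = "|"), "")
  expect_identical(keys1, keys2)
})

test_that("train/test splits are disjoint, exhaustive, and stratifiable", {
  ds <- sample_records(scenario_config("path", n_records = 200, seed = 3))
  sp <- split_dataset(ds, 0.3, seed = 9)
  expect_identical(nrow(sp$train$records) + nrow(sp$test$records), 200L)
  key <- function(d) do.call(paste, c(d$records, sep = "\r"))
  # no record index appears twice: reconstruct via row multiset equality
  all_keys <- sort(c(key(sp$train), key(sp$test)))
  expect_identical(all_keys, sort(key(ds)))
  sp2 <- split_dataset(ds, 0.25, seed = 1, stratify_by = "crowds_congregate")
  frac <- function(d) mean(d$records$crowds_congregate == "very_low")
  expect_equal(frac(sp2$test), frac(ds), tolerance = 0.06)
})

test_that("candidate evaluation scores log loss and accuracy on held-out data", {
  # deterministic parent -> child copy learned with no smoothing:
  # perfect prediction, log loss 0, accuracy 100%
  specs <- list(A = variable_spec("A", "spatial", c("a1", "a2")),
                B = variable_spec("B", "interaction", c("b1", "b2")))
  st <- bn_structure(c("A", "B"), rbind(c("A", "B")))
  rec <- data.frame(A = rep(c("a1", "a2"), 30),
                    B = rep(c("b1", "b2"), 30))
  train <- park_dataset(rec, specs)
  test <- park_dataset(rec[1:20, ], specs)
  res <- evaluate_candidate(st, train, test, "B",
                            em_args = list(pseudo_count = 0))
  expect_equal(res$metrics$log_loss, 0, tolerance = 1e-9)
  expect_equal(res$metrics$accuracy, 1)

  # uniform 5-state predictor: log loss ln 5, accuracy 20% on balanced data
  specs5 <- list(T5 = variable_spec("T5", "interaction", paste0("s", 1:5)),
                 Z = variable_spec("Z", "spatial", c("z1", "z2")))
  st5 <- bn_structure(c("T5", "Z"))
  rec5 <- data.frame(T5 = rep(paste0("s", 1:5), 20), Z = "z1")
  train5 <- park_dataset(rec5, specs5)
  res5 <- evaluate_candidate(st5, train5, train5, "T5",
                             em_args = list(pseudo_count = 0))
  expect_equal(res5$metrics$log_loss, log(5), tolerance = 1e-9)
  expect_equal(res5$metrics$accuracy, 0.2)

  # a target entirely missing from the test set is an error
  test_na <- park_dataset(transform(rec[1:5, ], B = NA_character_), specs)
  expect_error(evaluate_candidate(st, train, test_na, "B"),
               "entirely missing")
})

test_that("stored metrics equal a from-scratch recomputation (no leakage)", {
  ds <- sample_records(scenario_config("path", n_records = 600, seed = 21,
                                       effect = "strong"))
  sp <- split_dataset(ds, 0.3, seed = 2)
  gen <- ground_truth_network("path", effect = "strong")
  res <- evaluate_candidate(gen$structure, sp$train, sp$test,
                            c("crowds_congregate", "engagement"))
  net <- res$fitted
  Xt <- parkbbn:::encode_records(sp$test, gen$structure$nodes)
  for (tg in c("crowds_congregate", "engagement")) {
    obs <- Xt[, tg]
    ll <- acc <- numeric(0)
    for (r in seq_len(nrow(Xt))) {
      ev_vars <- setdiff(gen$structure$nodes, tg)
      ev <- lapply(ev_vars, function(v)
        net$specs[[v]]$states[Xt[r, v]])
      names(ev) <- ev_vars
      post <- posterior(net, tg, ev)
      ll <- c(ll, -log(max(post[obs[r]], 1e-9)))
      acc <- c(acc, which.max(post) == obs[r])
    }
    m <- res$metrics[res$metrics$target == tg, ]
    expect_equal(m$log_loss, mean(ll), tolerance = 1e-9)
    expect_equal(m$accuracy, mean(acc), tolerance = 1e-12)
  }
})

test_that("the generating structure beats an edgeless one on held-out loss", {
  ds <- sample_records(scenario_config("fitness_equipment", n_records = 1500,
                                       seed = 5, effect = "strong"))
  sp <- split_dataset(ds, 0.3, seed = 5)
  gen <- ground_truth_network("fitness_equipment", effect = "strong")
  empty <- bn_structure(gen$structure$nodes)
  targets <- c("crowds_congregate", "engagement")
  r_true <- evaluate_candidate(gen$structure, sp$train, sp$test, targets)
  r_null <- evaluate_candidate(empty, sp$train, sp$test, targets)
  expect_lte(mean(r_true$metrics$log_loss), mean(r_null$metrics$log_loss))
  expect_gte(mean(r_true$metrics$accuracy), mean(r_null$metrics$accuracy))
})

test_that("selection prefers accuracy, then log loss, then sparsity", {
  mk <- function(acc, ll, n_edges) {
    edges <- if (n_edges) rbind(c("A", "B")) else NULL
    structure(list(structure = bn_structure(c("A", "B"), edges),
                   fitted = NULL, train_loglik = 0,
                   metrics = data.frame(target = "B", log_loss = ll,
                                        accuracy = acc)),
              class = "candidate_result")
  }
  a <- mk(0.7, 0.9, 1); b <- mk(0.7, 0.5, 1); c_ <- mk(0.6, 0.1, 0)
  expect_identical(select_best(list(a, b, c_)), b)
  expect_identical(select_best(list(a)), a)
  d <- mk(0.7, 0.5, 0)
  expect_identical(select_best(list(a, b, d)), d)  # tie on acc+ll: fewer edges
  expect_identical(select_best(list(a, c_), "log_loss"), c_)
})

test_that("more training data does not hurt selected-model test loss", {
  # scaled down (30 candidates, 5 replicates) to keep the suite fast;
  # asserts the mean over replicates, as a distributional property
  loss_at <- function(n, i) {
    ds <- sample_records(scenario_config("path", n_records = n,
                                         seed = 700 + i, effect = "strong"))
    sp <- split_dataset(ds, 0.3, seed = 800 + i)
    cons <- default_constraints(ds$specs)
    res <- search_structures(sp$train, sp$test, cons,
                             c("crowds_congregate", "engagement"),
                             n_candidates = 30, seed = 900 + i)
    mean(res$best$metrics$log_loss)
  }
  small <- vapply(1:5, function(i) loss_at(200, i), numeric(1))
  large <- vapply(1:5, function(i) loss_at(2000, i), numeric(1))
  expect_lte(mean(large), mean(small))
})
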