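test_that("structure construction enforces DAG invariants", {
  expect_error(bn_structure(c("A", "B"), rbind(c("A", "B"), c("B", "A"))),
               "cycle")
  expect_error(bn_structure(c("A", "B"), rbind(c("A", "B"), c("A", "B"))),
               "duplicate")
  expect_error(bn_structure("A", rbind(c("A", "A"))), "self-loop")
  expect_error(bn_structure(c("A"), rbind(c("A", "Z"))), "not in node set")
  s <- bn_structure(c("C", "A", "B"), rbind(c("A", "B"), c("B", "C")))
  ord <- topological_order(s)
  expect_lt(match("A", ord), match("B", ord))
  expect_lt(match("B", ord), match("C", ord))
})

test_that("CPT rows must be normalized distributions", {
  specs <- list(A = variable_spec("A", "spatial", c("a1", "a2")))
  expect_error(bn_cpt("A", character(0), specs, c(0.5, 0.6)), "sum to 1")
  expect_error(bn_cpt("A", character(0), specs, c(1.2, -0.2)), "outside")
  expect_error(bn_cpt("A", character(0), specs, c(0.5, 0.2, 0.3)), "expected 2")
})

test_that("joint probability is the CPT product and sums to one", {
  specs <- list(A = variable_spec("A", "spatial", c("a1", "a2")))
  st <- bn_structure("A")
  net1 <- belief_network(st, list(A = bn_cpt("A", character(0), specs,
                                             c(0.5, 0.5))), specs)
  expect_equal(joint_probability(net1, list(A = "a1")), 0.5)

  net <- toy_chain_net()
  expect_equal(joint_probability(net, list(A = "a1", B = "b1")), 0.27)
  expect_error(joint_probability(net, list(A = "a1")), "misses node")

  withr::local_seed(21)
  net5 <- random_net(5)
  jt <- oracle_joint_table(net5)
  expect_equal(sum(jt$p), 1, tolerance = 1e-12)
  # package joint_probability agrees with the oracle row by row (spot check)
  nodes <- net5$structure$nodes
  for (r in sample(nrow(jt), 20)) {
    asn <- lapply(nodes, function(v) net5$specs[[v]]$states[jt[r, v]])
    names(asn) <- nodes
    expect_equal(joint_probability(net5, asn), jt$p[r], tolerance = 1e-12)
  }
})

test_that("variable elimination matches enumeration and Bayes by hand", {
  net <- toy_chain_net()
  # empty evidence: prior marginal
  expect_equal(unname(posterior(net, "B")),
               c(0.3 * 0.9 + 0.7 * 0.2, 0.3 * 0.1 + 0.7 * 0.8),
               tolerance = 1e-12)
  # hand Bayes: P(A = a1 | B = b1) = .27 / (.27 + .14)
  expect_equal(unname(posterior(net, "A", list(B = "b1"))[1]),
               0.27 / 0.41, tolerance = 1e-12)
  # evidence on the only parent returns the CPT row
  expect_equal(unname(posterior(net, "B", list(A = "a2"))), c(0.2, 0.8),
               tolerance = 1e-12)
  expect_error(posterior(net, "B", list(B = "b1")), "part of the evidence")

  withr::local_seed(31)
  for (i in 1:20) {
    netr <- random_net(sample(3:6, 1))
    nodes <- netr$structure$nodes
    q <- sample(nodes, 1)
    ev_vars <- setdiff(nodes, q)
    ev_vars <- ev_vars[stats::runif(length(ev_vars)) < 0.4]
    ev <- lapply(ev_vars, function(v) sample(netr$specs[[v]]$states, 1))
    names(ev) <- ev_vars
    expect_equal(unname(posterior(netr, q, ev)), oracle_posterior(netr, q, ev),
                 tolerance = 1e-10)
    expect_equal(sum(posterior(netr, q, ev)), 1, tolerance = 1e-9)
  }
})

test_that("impossible evidence is rejected", {
  specs <- list(A = variable_spec("A", "spatial", c("a1", "a2")),
                B = variable_spec("B", "spatial", c("b1", "b2")))
  st <- bn_structure(c("A", "B"), rbind(c("A", "B")))
  tabs <- list(A = bn_cpt("A", character(0), specs, c(1, 0)),
               B = bn_cpt("B", "A", specs, c(1, 0, 0, 1)))
  net <- belief_network(st, tabs, specs)
  expect_error(posterior(net, "B", list(A = "a2")), "impossible evidence")
})

test_that("log-likelihood sums record log-probabilities, marginalizing gaps", {
  specs <- list(A = variable_spec("A", "spatial", c("a1", "a2")))
  st <- bn_structure("A")
  net_sure <- belief_network(st, list(A = bn_cpt("A", character(0), specs,
                                                 c(1, 0))), specs)
  ds1 <- park_dataset(data.frame(A = "a1"), specs)
  expect_equal(log_likelihood(net_sure, ds1), 0)
  ds0 <- park_dataset(data.frame(A = "a2"), specs)
  ll0 <- log_likelihood(net_sure, ds0)
  expect_identical(unclass(ll0)[1], -Inf)
  expect_identical(attr(ll0, "zero_records"), 1L)

  # two independent fair coins, one complete record -> ln(1/4)
  specs2 <- list(A = variable_spec("A", "spatial", c("h", "t")),
                 B = variable_spec("B", "spatial", c("h", "t")))
  st2 <- bn_structure(c("A", "B"))
  net2 <- belief_network(st2, list(
    A = bn_cpt("A", character(0), specs2, c(0.5, 0.5)),
    B = bn_cpt("B", character(0), specs2, c(0.5, 0.5))), specs2)
  expect_equal(log_likelihood(net2, park_dataset(data.frame(A = "h", B = "t"),
                                                 specs2)),
               log(0.25), tolerance = 1e-12)

  # missing cell equals the enumeration over completions
  withr::local_seed(41)
  netr <- random_net(4)
  nodes <- netr$structure$nodes
  X <- matrix(NA_integer_, 6, 4, dimnames = list(NULL, nodes))
  for (r in 1:6)
    for (j in 1:4)
      X[r, j] <- sample(seq_along(netr$specs[[nodes[j]]]$states), 1)
  X[cbind(1:6, sample(1:4, 6, replace = TRUE))] <- NA
  rec <- as.data.frame(lapply(nodes, function(v)
    ifelse(is.na(X[, v]), NA, netr$specs[[v]]$states[X[, v]])),
    col.names = nodes)
  ds <- park_dataset(rec, netr$specs)
  expect_equal(log_likelihood(netr, ds), oracle_loglik(netr, X),
               tolerance = 1e-10)
})

test_that("EM on complete data reproduces smoothed frequencies exactly", {
  net <- toy_chain_net()
  ds <- sample_records(scenario_config(ground_truth = net, n_records = 200,
                                       seed = 6))
  ds$records$unit_id <- NULL
  fit0 <- em_fit(net$structure, ds, pseudo_count = 0)
  # independent frequency computation via table()
  tabAB <- table(factor(ds$records$A, c("a1", "a2")),
                 factor(ds$records$B, c("b1", "b2")))
  expect_equal(unname(as.numeric(fit0$net$tables$A$values)),
               unname(as.numeric(rowSums(tabAB) / sum(tabAB))),
               tolerance = 1e-12)
  expect_equal(unname(fit0$net$tables$B$values["b1", "a1"]),
               unname(tabAB["a1", "b1"] / sum(tabAB["a1", ])),
               tolerance = 1e-12)
  # Laplace smoothing with pseudo-count 1
  fit1 <- em_fit(net$structure, ds, pseudo_count = 1)
  expect_equal(unname(fit1$net$tables$B$values["b1", "a1"]),
               unname((tabAB["a1", "b1"] + 1) / (sum(tabAB["a1", ]) + 2)),
               tolerance = 1e-12)
  expect_true(fit1$converged)
  expect_error(em_fit(net$structure, park_dataset(ds$records[0, ], ds$specs)),
               "empty dataset")
})

test_that("EM with missing cells beats a random-parameter grid", {
  net <- toy_chain_net()
  specs3 <- c(net$specs,
              list(C = variable_spec("C", "spatial", c("c1", "c2"))))
  st3 <- bn_structure(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C")))
  tabs3 <- list(A = net$tables$A,
                B = bn_cpt("B", "A", specs3, c(0.9, 0.1, 0.2, 0.8)),
                C = bn_cpt("C", "A", specs3, c(0.7, 0.3, 0.4, 0.6)))
  gen <- belief_network(st3, tabs3, specs3)
  ds <- sample_records(scenario_config(ground_truth = gen, n_records = 80,
                                       missing_rate = 0.2, seed = 13))
  ds$records$unit_id <- NULL
  fit <- em_fit(st3, ds, pseudo_count = 0.1, seed = 2)
  X <- matrix(NA_integer_, nrow(ds$records), 3,
              dimnames = list(NULL, c("A", "B", "C")))
  for (v in c("A", "B", "C"))
    X[, v] <- match(ds$records[[v]], specs3[[v]]$states)
  expect_equal(fit$trace[length(fit$trace)], oracle_loglik(fit$net, X),
               tolerance = 1e-8)
  # brute-force random parameterizations never beat the EM optimum
  withr::local_seed(99)
  best_grid <- -Inf
  for (g in 1:1000) {
    cand <- belief_network(st3, list(
      A = bn_cpt("A", character(0), specs3, rand_cpt_vals(2)),
      B = bn_cpt("B", "A", specs3, rand_cpt_vals(c(2, 2))),
      C = bn_cpt("C", "A", specs3, rand_cpt_vals(c(2, 2)))), specs3)
    best_grid <- max(best_grid, oracle_loglik(cand, X))
  }
  expect_gte(fit$trace[length(fit$trace)], best_grid)
})

test_that("EM log-likelihood trace is non-decreasing", {
  withr::local_seed(55)
  for (i in 1:10) {
    gen <- random_net(3, max_states = 3)
    ds <- sample_records(scenario_config(ground_truth = gen, n_records = 60,
                                         missing_rate = 0.25, seed = 100 + i))
    ds$records$unit_id <- NULL
    fit <- em_fit(gen$structure, ds, pseudo_count = 0, seed = i,
                  max_iter = 60)
    expect_true(all(diff(fit$trace) >= -1e-9))
  }
})

test_that("argmax prediction is deterministic with tie-breaking by state order", {
  specs <- list(A = variable_spec("A", "spatial", c("a1", "a2", "a3")))
  st <- bn_structure("A")
  sure <- belief_network(st, list(A = bn_cpt("A", character(0), specs,
                                             c(0, 1, 0))), specs)
  expect_identical(predict_state(sure, "A")$state, "a2")
  expect_equal(predict_state(sure, "A")$probability, 1)
  unif <- belief_network(st, list(A = bn_cpt("A", character(0), specs,
                                             rep(1 / 3, 3))), specs)
  expect_identical(predict_state(unif, "A")$state, "a1")
  net <- toy_chain_net()
  expect_identical(predict_state(net, "A", list(B = "b1"))$state, "a1")
})

test_that("networks round-trip through JSON interchange", {
  withr::local_seed(61)
  net <- random_net(5)
  path <- withr::local_tempfile(fileext = ".json")
  bn_write_json(net, path)
  back <- bn_read_json(path)
  expect_identical(back$structure$nodes, net$structure$nodes)
  expect_identical(back$structure$edges, net$structure$edges)
  for (v in net$structure$nodes) {
    expect_identical(back$tables[[v]]$parents, net$tables[[v]]$parents)
    expect_equal(as.numeric(back$tables[[v]]$values),
                 as.numeric(net$tables[[v]]$values), tolerance = 1e-12)
  }
})
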