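# Unit tests for the auditors: the recurrence score, degree features,
# node-balanced subsampling (against exhaustive search), and the verdict
# plumbing of every audit on a small synthetic dataset.

test_that("recurrence_score matches hand-computed examples", {
  expect_equal(recurrence_score(3, 1, 1, 3), 0.5)
  expect_equal(recurrence_score(0, 2, 0, 1), 0)
  expect_equal(recurrence_score(5, 1, 2, 0), 0.875)
  expect_equal(recurrence_score(0, 0, 0, 0), 0.5)     # unseen proteins
  expect_error(recurrence_score(-1, 0, 0, 0), "non-negative")
})

test_that("recurrence_score is in [0,1], 0.5 at equal degrees, swap-invariant", {
  withr::with_seed(4, {
    d <- matrix(rpois(400, 3), ncol = 4)
    s <- recurrence_score(d[, 1], d[, 2], d[, 3], d[, 4])
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(s, recurrence_score(d[, 3], d[, 4], d[, 1], d[, 2]))
    expect_equal(recurrence_score(d[, 1], d[, 1], d[, 3], d[, 3]),
                 rep(0.5, 100))
  })
})

test_that("degree_pair_features has four entries in canonical order, zeros for strangers", {
  train <- tibble::tibble(a = c("A", "A", "B"), b = c("B", "C", "C"),
                          label = c(1L, 1L, 0L))
  deg <- compute_degree_table(train)
  x <- degree_pair_features(deg, tibble::tibble(a = c("C", "Z"),
                                                b = c("A", "A"),
                                                label = c(1L, 0L)))
  expect_equal(colnames(x), c("a_pos", "a_neg", "b_pos", "b_neg"))
  expect_equal(ncol(x), 4)
  expect_equal(unname(x[1, ]), c(2, 0, 1, 1))   # canonicalized to (A, C)
  expect_equal(unname(x[2, ]), c(2, 0, 0, 0))   # Z unseen -> zeros
})

test_that("node_balanced_subsample solves the four-protein worked example", {
  positives <- tibble::tibble(a = c("A", "C"), b = c("B", "D"),
                              label = c(1L, 1L))
  candidates <- tibble::tibble(a = c("A", "B", "A", "B"),
                               b = c("C", "D", "D", "C"))
  out <- node_balanced_subsample(positives, candidates, seed = 1)
  expect_equal(nrow(out$residual), 0)
  d <- compute_degree_table(out$pairs)
  expect_equal(d$d_pos, d$d_neg)
  expect_equal(nrow(out$selected), 2)
  # the two selected negatives must be a perfect matching of {A,B,C,D}
  expect_setequal(c(out$selected$a, out$selected$b), c("A", "B", "C", "D"))
})

test_that("greedy balance matches exhaustive subset search on random instances", {
  perfectly_balanceable <- function(positives, candidates) {
    # exhaustive search over all candidate subsets for a perfect balance
    n <- nrow(candidates)
    for (size in 0:n) {
      for (rows in utils::combn(n, size, simplify = FALSE)) {
        sel <- candidates[rows, ]
        sel$label <- 0L
        d <- compute_degree_table(dplyr::bind_rows(positives, sel))
        if (all(d$d_pos == d$d_neg)) return(TRUE)
      }
    }
    FALSE
  }
  withr::with_seed(31, {
    n_feasible <- 0
    for (trial in 1:6) {
      ids <- LETTERS[1:5]
      all_p <- t(utils::combn(ids, 2))
      take <- sample.int(nrow(all_p), 7)
      positives <- tibble::tibble(a = all_p[take[1:3], 1],
                                  b = all_p[take[1:3], 2], label = 1L)
      candidates <- tibble::tibble(a = all_p[take[4:7], 1],
                                   b = all_p[take[4:7], 2])
      out <- node_balanced_subsample(positives, candidates, seed = trial)
      # soundness: an empty residual must be a genuine perfect balance,
      # and the greedy may never claim success where none exists
      d <- compute_degree_table(out$pairs)
      if (nrow(out$residual) == 0) {
        expect_equal(d$d_pos, d$d_neg)
        expect_true(perfectly_balanceable(positives, candidates))
      } else {
        expect_true(any(d$d_pos != d$d_neg))
      }
      expect_lte(nrow(out$selected), nrow(positives))
      if (perfectly_balanceable(positives, candidates)) {
        n_feasible <- n_feasible + 1
      }
    }
    expect_gt(n_feasible, 0)   # the success branch was actually exercised
  })
})

test_that("infeasible star positives report the residual imbalance", {
  positives <- tibble::tibble(a = rep("H", 5),
                              b = paste0("X", 1:5), label = 1L)
  candidates <- tibble::tibble(a = c("H", "H", "X1", "X2"),
                               b = c("X6", "X7", "X3", "X4"))
  out <- node_balanced_subsample(positives, candidates, seed = 2)
  expect_equal(out$residual$imbalance[out$residual$id == "H"], 3)
  expect_error(node_balanced_subsample(positives, candidates[0, ]), "empty")
  expect_error(
    node_balanced_subsample(positives,
                            tibble::tibble(a = "H", b = "X1")),
    "disjoint"
  )
})

test_that("pairs of exactly balanced proteins always score 0.5 after balancing", {
  ds <- small_dataset(bias_beta = 0.6, seed = 21)
  train <- split_in_network(ds$pairs, rounds = 1, seed = 3)$train[[1]]
  pos <- train[train$label == 1L, ]
  cand <- pairaudit:::all_candidate_pairs(unique(c(train$a, train$b)),
                                          pairaudit:::pair_key(pos$a, pos$b))
  out <- node_balanced_subsample(pos, cand, seed = 4)
  deg <- compute_degree_table(out$pairs)
  balanced <- deg$id[deg$d_pos == deg$d_neg]
  # the balancing must succeed for the bulk of the proteins
  expect_gt(length(balanced), 0.7 * nrow(deg))
  both <- out$pairs$a %in% balanced & out$pairs$b %in% balanced
  expect_gt(sum(both), 0)
  x <- degree_pair_features(deg, out$pairs[both, ])
  expect_equal(recurrence_score(x[, 1], x[, 2], x[, 3], x[, 4]),
               rep(0.5, sum(both)))
})

test_that("audits return coherent audit_result objects on a biased dataset", {
  ds <- small_dataset(bias_beta = 1, seed = 13)
  sp <- split_in_network(ds$pairs, rounds = 2, seed = 1)
  fm <- extract_features(ds$proteins, "conjoint_triad")
  grid <- list(list(num_trees = 40L))

  bench <- benchmark_audit(sp, fm, adapter_forest, grid, seed = 1)
  expect_s3_class(bench, "audit_result")
  expect_equal(bench$auditor, "benchmark")
  expect_length(bench$per_round_auc, 2)
  expect_equal(bench$mean_auc, mean(bench$per_round_auc))
  expect_equal(bench$reference_auc, 0.5)
  expect_equal(bench$verdict, "inconclusive")
  expect_length(bench$details$adapters, 2)

  fa <- feature_audit(sp, ds$proteins, "conjoint_triad", adapter_forest,
                      grid, seed = 1)
  expect_equal(fa$auditor, "feature_masked")
  expect_equal(fa$verdict,
               if (fa$mean_auc > 0.55) "bias_indicated" else
                 "no_bias_indicated")

  nd <- node_degree_audit(sp, reference_auc = bench$mean_auc, seed = 1)
  expect_equal(nd$auditor, "node_degree")
  expect_equal(nd$delta, nd$mean_auc - bench$mean_auc)
  expect_equal(nd$verdict,
               if (abs(nd$delta) <= 0.05) "bias_indicated" else
                 "no_bias_indicated")

  rec <- recurrence_audit(sp, reference_auc = bench$mean_auc)
  expect_equal(rec$auditor, "recurrence")
  expect_true(all(rec$per_round_auc >= 0 & rec$per_round_auc <= 1))

  db <- debias_audit(sp, ds$proteins, "conjoint_triad", grid = grid,
                     seed = 1)
  expect_equal(db$auditor, "debias_masked_balanced")
  expect_true(db$details$masked)
  expect_length(db$details$residual_imbalance, 2)
  expect_equal(db$verdict,
               if (abs(db$mean_auc - 0.5) <= 0.05) "no_bias_indicated" else
                 "bias_indicated")
  db2 <- debias_audit(sp, ds$proteins, "conjoint_triad", grid = grid,
                      mask = FALSE, seed = 1)
  expect_equal(db2$auditor, "debias_balanced")
})

test_that("generalizability audit filters foreign pairs per round membership", {
  ds <- small_dataset(bias_beta = 1, seed = 13)
  sp <- split_in_network(ds$pairs, rounds = 2, seed = 1)
  fm <- extract_features(ds$proteins, "conjoint_triad")
  grid <- list(list(num_trees = 40L))
  bench <- benchmark_audit(sp, fm, adapter_forest, grid, seed = 1)

  # an independent interaction draw over the same proteome
  cfg2 <- synthetic_config(n_proteins = 60L, n_pos = 150L, bias_beta = 0,
                           seed = 99)
  foreign <- generate_interactions(ds$proteins, cfg2)
  ga <- generalizability_audit(bench, sp, foreign, fm, NULL, seed = 1)
  expect_equal(ga$auditor, "generalizability")
  expect_length(ga$per_round_auc, 2)
  expect_equal(ga$reference_auc, bench$mean_auc)
  expect_equal(ga$details$gap, -ga$delta)
  stub <- structure(list(details = list(), mean_auc = 0.5),
                    class = "audit_result")
  expect_error(generalizability_audit(stub, sp, foreign, fm, NULL),
               "adapter")
})
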