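test_that("evaluate_pair reproduces hand-enumerated shared/distinct sums", {
  # A-B 0.9, A-C 0.8, B-C 0.7, A-D 0.5
  w <- matrix(0, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  w["A", "B"] <- w["B", "A"] <- 0.9
  w["A", "C"] <- w["C", "A"] <- 0.8
  w["B", "C"] <- w["C", "B"] <- 0.7
  w["A", "D"] <- w["D", "A"] <- 0.5
  d <- evaluate_pair(w, 1, 2)
  expect_equal(d$shared, 1.5)
  expect_equal(d$distinct, 0.5)
  expect_true(d$merge)
  # star: center A, leaves B..E -> skip
  s <- matrix(0, 5, 5)
  s[1, 2:5] <- s[2:5, 1] <- c(0.9, 0.8, 0.7, 0.6)
  ds <- evaluate_pair(s, 1, 2)
  expect_equal(ds$shared, 0)
  expect_equal(ds$distinct, 0.8 + 0.7 + 0.6)
  expect_false(ds$merge)
  # identical neighborhoods, no private links -> merge
  t3 <- matrix(0, 3, 3)
  t3[1, 2] <- t3[2, 1] <- 0.5
  t3[1, 3] <- t3[3, 1] <- 0.4
  t3[2, 3] <- t3[3, 2] <- 0.3
  expect_true(evaluate_pair(t3, 1, 2)$merge)
  expect_error(evaluate_pair(t3, 1, 1), "differ")
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- 1
  expect_error(evaluate_pair(w2, 1, 3), "adjacent")
})

test_that("run_merging handles degenerate graphs and conserves mass", {
  expect_equal(run_merging(matrix(0, 4, 4))$K, 0)
  for (seed in 1:10) {
    set.seed(seed)
    w <- random_connected_graph(sample(5:10, 1))
    tr <- run_merging(w)
    if (tr$K > 0) {
      # growth curves are non-decreasing
      expect_true(all(apply(tr$growth, 1, function(g) all(diff(g) >= 0))))
      # live member sets partition the nodes after every event
      expect_equal(sort(unlist(tr$members)), seq_len(nrow(w)))
      expect_equal(sum(lengths(tr$members)), nrow(w))
    }
  }
})

test_that("merging events equal the brute-force reference on random graphs", {
  set.seed(42)
  for (i in 1:40) {
    w <- random_connected_graph(sample(4:10, 1))
    got <- run_merging(w)$events
    ref <- ref_merging(w)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) expect_equal(unname(as.matrix(got)),
                                unname(as.matrix(ref)))
  }
})

test_that("trajectory fits recover exact log and exp curves", {
  K <- 20
  t <- (1:K) / K
  # single-node trajectory object carrying an arbitrary growth curve
  traj_of <- function(y) structure(list(growth = matrix(y, 1, K,
                                          dimnames = list("v", NULL)),
                                        nodes = "v", n_nodes = 1L, K = K),
                                   class = "merge_trajectory")
  ylog <- 0.1 + 0.2 * log(t + 0.2)
  cl <- fit_trajectory_models(traj_of(ylog))
  expect_equal(cl$r2_log, 1, tolerance = 1e-10)
  expect_identical(cl$label, "segregator")
  expect_equal(cl$a_log, 0.1, tolerance = 1e-8)
  expect_equal(cl$b_log, 0.2, tolerance = 1e-8)
  yexp <- 0.05 * exp(1.5 * t)
  cle <- fit_trajectory_models(traj_of(yexp))
  expect_equal(cle$r2_exp, 1, tolerance = 1e-10)
  expect_identical(cle$label, "integrator")
  expect_equal(cle$a_exp, 0.05, tolerance = 1e-8)
  expect_equal(cle$b_exp, 1.5, tolerance = 1e-8)
  # a never-merging node is flagged unclassified
  ycon <- rep(0.4, K)
  expect_identical(fit_trajectory_models(traj_of(ycon))$label,
                   "unclassified")
})

test_that("group maps normalize per subject and average across subjects", {
  cl1 <- data.frame(node = c("a", "b", "c"),
                    r2_log = c(0.2, 0.6, 1.0), r2_exp = c(0.5, 0.5, 0.5),
                    score = c(-0.3, 0.1, 0.5), label = "x")
  gm1 <- group_maps(list(cl1))
  expect_equal(unname(gm1$S), c(0, 0.5, 1))
  expect_equal(unname(gm1$I), c(0, 0, 0))    # constant map -> zeros
  # identical S and I give a zero difference map
  cl2 <- cl1; cl2$r2_exp <- cl1$r2_log
  expect_equal(unname(group_maps(list(cl2))$S_minus_I), rep(0, 3))
  # subject order does not matter
  cl3 <- cl1; cl3$r2_log <- rev(cl1$r2_log)
  expect_equal(group_maps(list(cl1, cl3))$S,
               group_maps(list(cl3, cl1))$S)
})

test_that("random baseline merges everything and is seed-deterministic", {
  set.seed(7)
  w <- random_connected_graph(8)
  b1 <- random_rule_baseline(w, seed = 11)
  b2 <- random_rule_baseline(w, seed = 11)
  expect_identical(b1$events, b2$events)
  expect_equal(b1$K, 7)   # connected: merges down to one super-node
  expect_equal(random_rule_baseline(matrix(0, 3, 3), 1)$K, 0)
})

test_that("relabeling nodes permutes but preserves the event sequence", {
  set.seed(13)
  w <- random_connected_graph(8)
  tr <- run_merging(w)
  perm <- sample(8)
  wp <- w[perm, perm]
  trp <- run_merging(wp)
  expect_equal(trp$K, tr$K)
  # merged member sets correspond under the relabeling
  orig_sets <- lapply(tr$members, sort)
  perm_sets <- lapply(trp$members, function(s) sort(perm[s]))
  expect_setequal(sapply(orig_sets, paste, collapse = ","),
                  sapply(perm_sets, paste, collapse = ","))
})
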