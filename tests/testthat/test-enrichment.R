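test_that("Fisher overrepresentation matches hypergeometric enumeration", {
  uni <- paste0("g", 1:20)
  sel <- uni[1:5]
  term <- c(uni[1:3], uni[10])
  f <- fisher_overrepresentation(sel, term, uni)
  expect_equal(f$p, 496 / 15504, tolerance = 1e-12)
  expect_equal(f$overlap, 3)
  expect_equal(f$fold, (3 / 5) / (4 / 20))
  # degenerate: term = selection = universe
  f1 <- fisher_overrepresentation(uni, uni, uni)
  expect_equal(f1$p, 1)
  expect_equal(f1$fold, 1)
  expect_error(fisher_overrepresentation(character(0), term, uni), "empty")
  # agreement with stats::fisher.test (independent route)
  ft <- fisher.test(matrix(c(3, 2, 1, 14), 2), alternative = "greater")
  expect_equal(f$p, ft$p.value, tolerance = 1e-10)
})

test_that("hypergeometric p equals brute-force enumeration over small tables", {
  for (N in c(5, 12, 20, 30)) {
    uni <- paste0("g", seq_len(N))
    for (K in c(1, floor(N / 3), N - 1)) {
      for (s in c(1, floor(N / 2), N)) {
        term <- uni[seq_len(K)]
        sel <- uni[seq_len(s)]
        ov <- length(intersect(term, sel))
        got <- fisher_overrepresentation(sel, term, uni)$p
        expect_equal(got, ref_hyper_upper(ov, K, N, s), tolerance = 1e-12)
      }
    }
  }
})

test_that("term filters apply the size and prefilter rules at their boundaries", {
  uni <- paste0("g", 1:3000)
  sets <- list(tiny = uni[1:4], five = uni[1:5],
               big = uni[1:2000], toobig = uni[1:2001])
  coll <- list(sets = sets, universe = uni)
  f <- filter_terms(coll)
  expect_setequal(names(f$sets), c("five", "big"))
  expect_setequal(attr(f, "removed"), c("tiny", "toobig"))
  expect_error(filter_terms(list(sets = sets, universe = character(0))),
               "universe")
  # overlap < 3 is flagged for discard even when p is small
  uni2 <- paste0("g", 1:100)
  coll2 <- list(sets = list(t1 = uni2[1:5]), universe = uni2)
  res <- enrich_terms(uni2[c(1, 2, 50:60)], coll2,
                      list(uni2[70:80]), min_overlap = 3)
  expect_false(res$prefilter_pass[res$term == "t1"])
})

test_that("surrogate-calibrated p behaves at rank extremes and ties", {
  expect_equal(surrogate_calibrated_p(1e-10, runif(999, 0.01, 1),
                                      tie_break = "conservative"),
               1 / 1000)
  sp <- seq(0.001, 0.999, length.out = 999)
  expect_equal(surrogate_calibrated_p(median(sp), sp,
                                      tie_break = "conservative"),
               0.5, tolerance = 0.01)
  expect_error(surrogate_calibrated_p(0.5, numeric(0)), "surrogate")
  # randomized tie split stays within the tie range
  set.seed(1)
  p <- replicate(50, surrogate_calibrated_p(0.5, rep(0.5, 99)))
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_gt(var(p), 0)
})

test_that("kappa matrix matches hand computation", {
  uni <- paste0("g", 1:100)
  sets <- list(t1 = uni[1:20], t2 = uni[c(1:15, 21:25)],
               t3 = uni[1:20], t4 = uni[30:34])
  k <- kappa_matrix(sets, uni)
  expect_equal(k["t1", "t3"], 1)
  # |T1|=|T2|=20, overlap 15: p_o=0.90, p_e=0.68, kappa=0.6875
  expect_equal(k["t1", "t2"], 0.6875, tolerance = 1e-12)
  expect_lt(k["t1", "t4"], 0)     # disjoint small terms: slightly negative
  expect_equal(k, t(k))
  expect_true(all(diag(k) == 1))
})

test_that("kappa clustering cuts at the threshold and picks min-p representatives", {
  uni <- paste0("g", 1:200)
  a <- uni[1:30]
  sets <- list(a1 = a, a2 = c(a[1:28], uni[31:32]),
               b1 = uni[100:130], b2 = c(uni[100:127], uni[140:141]))
  k <- kappa_matrix(sets, uni)
  p <- c(a1 = 0.04, a2 = 0.001, b1 = 0.02, b2 = 0.3)
  cl <- cluster_terms(k, p, 0.3)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_identical(cl$term[cl$representative], c("a2", "b1"))
  # identical terms fall into one cluster; input order irrelevant
  cl2 <- cluster_terms(k[c(3, 4, 1, 2), c(3, 4, 1, 2)], p, 0.3)
  m1 <- split(cl$term, cl$cluster)
  m2 <- split(cl2$term, cl2$cluster)
  expect_setequal(unname(sapply(m1, paste, collapse = "+")),
                  unname(sapply(m2, paste, collapse = "+")))
  single <- cluster_terms(k[1, 1, drop = FALSE], p[1])
  expect_true(single$representative)
})

test_that("planted enrichment is detected and flagged through the full path", {
  geo <- gen_region_geometry(40, 120, 3)
  map <- sa_map(geo, 30, 21)
  ex <- gen_expression_matrix(map, geo,
                              expression_spec(600, 30, 0, 0.8, seed = 12))
  r <- spatial_correlation(map, ex$expr)
  sel <- select_genes_sd(r)
  planted <- names(ex$labels)[ex$labels == "planted_pos"]
  gs <- gen_gene_sets(rownames(ex$expr), 40, c(10, 80),
                      planted[1:25], seed = 13)
  sur <- make_surrogates(map, geo, 100, seed = 14)
  sig <- surrogate_significance(sur, ex$expr)
  ssel <- surrogate_selections(sig$null_r, sel$upper_cutoff, "upper")
  res <- enrich_terms(sel$upper, gs, ssel, seed = 15)
  i <- match(gs$planted_term, res$term)
  expect_true(res$fdr_pass[i])
  expect_equal(res$empirical_p[i], min(res$empirical_p))
  expect_true(all(res$empirical_p > 0 & res$empirical_p <= 1))
})
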