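test_that("panel generator is deterministic and honours the factor model", {
  sp <- panel_spec(12, 50, list(1:6, 7:12), 1, 0, noise_sd = 0, seed = 3)
  pp <- gen_timeseries_panel(sp)
  # coupling 1, no noise: module members carry identical signals
  x <- pp$panels[[1]]
  expect_equal(cor(x[1, ], x[2, ]), 1)
  expect_equal(cor(x[7, ], x[12, ]), 1)
  # same seed, bit-identical output
  pp2 <- gen_timeseries_panel(sp)
  expect_identical(pp$panels, pp2$panels)
  expect_identical(unname(pp$labels),
                   c(rep("segregator", 12)))
})

test_that("within-module correlations exceed between-module ones", {
  for (seed in 1:20) {
    sp <- panel_spec(12, 300, list(1:6, 7:12), 0.8, 0,
                     noise_sd = 0.5, seed = seed)
    x <- gen_timeseries_panel(sp)$panels[[1]]
    r <- cor(t(x))
    within <- c(r[1:6, 1:6][upper.tri(diag(6))],
                r[7:12, 7:12][upper.tri(diag(6))])
    between <- as.vector(r[1:6, 7:12])
    expect_gt(mean(within), mean(between))
  }
})

test_that("panel spec validation rejects bad structure", {
  expect_error(panel_spec(10, 50, list(1:4, 3:6)), "disjoint")
  expect_error(panel_spec(10, 50, list(1:4), integrator_nodes = 4),
               "integrator")
  expect_error(panel_spec(10, 50, list(1:4), module_coupling = 1.2),
               "couplings|loadings")
})

test_that("region geometry is a valid metric layout", {
  g <- gen_region_geometry(2, 10, 1)
  g$coords[1, ] <- c(0, 0, 0); g$coords[2, ] <- c(3, 0, 0)
  d <- as.matrix(dist(g$coords))
  expect_equal(unname(d[1, 2]), 3)
  g68 <- gen_region_geometry(68, 140, 5)
  expect_equal(g68$dist, t(g68$dist))
  expect_true(all(diag(g68$dist) == 0))
  expect_lte(max(g68$dist), 140 * sqrt(3))
  # deterministic under seed
  expect_identical(g68$coords, gen_region_geometry(68, 140, 5)$coords)
})

test_that("expression generator plants exact correlations", {
  geo <- gen_region_geometry(30, 100, 2)
  map <- sa_map(geo, 25, 7)
  es <- expression_spec(200, 20, 20, 0.8, 25, seed = 3)
  ex <- gen_expression_matrix(map, geo, es)
  r <- sapply(seq_len(nrow(ex$expr)), function(i) cor(ex$expr[i, ], map))
  expect_equal(unname(r[ex$labels == "planted_pos"]), rep(0.8, 20),
               tolerance = 1e-10)
  expect_equal(unname(r[ex$labels == "planted_neg"]), rep(-0.8, 20),
               tolerance = 1e-10)
  expect_lt(abs(mean(r[ex$labels == "background"])), 0.15)
  expect_error(gen_expression_matrix(rep(1, 30), geo, es), "constant")
})

test_that("planted correlation window holds across seeds", {
  geo <- gen_region_geometry(40, 120, 4)
  for (seed in 1:5) {
    map <- sa_map(geo, 30, seed + 100)
    ex <- gen_expression_matrix(map, geo,
                                expression_spec(300, 30, 0, 0.8,
                                                seed = seed))
    r <- sapply(seq_len(300), function(i) cor(ex$expr[i, ], map))
    expect_true(all(abs(abs(r[1:30]) - 0.8) < 0.1))
  }
})

test_that("gene-set generator plants one exact term deterministically", {
  uni <- paste0("g", 1:500)
  planted <- sample(uni, 40)
  gs <- gen_gene_sets(uni, 30, c(10, 60), planted, seed = 9)
  expect_identical(gs$sets[[gs$planted_term]], sort(unique(planted)))
  gs2 <- gen_gene_sets(uni, 30, c(10, 60), planted, seed = 9)
  expect_identical(gs$sets, gs2$sets)
  expect_error(gen_gene_sets(uni, 10, c(0, 50)), "size_range")
  expect_error(gen_gene_sets(uni, 10, c(5, 50), c("nope")), "subset")
  # expected overlap of a random term with a random selection is ks/N
  set.seed(1)
  ovs <- replicate(400, {
    term <- sample(uni, 50); sel <- sample(uni, 30)
    length(intersect(term, sel))
  })
  expect_equal(mean(ovs), 50 * 30 / 500, tolerance = 0.1)
})

test_that("dN/dS generator reproduces the curve family exactly at zero noise", {
  sp <- dnds_spec("linear", c(0.1, 0.002), times = c(sp1 = 10, sp2 = 20),
                  noise_sd = 0, seed = 1)
  uni <- paste0("g", 1:50)
  dn <- gen_dnds_table(sp, uni[1:20], uni)
  ratios <- dnds_ratios(dn$table)
  mo <- annotation_species_means(ratios, uni[1:20])
  expect_equal(unname(mo["sp1"]), 0.12)
  expect_equal(unname(mo["sp2"]), 0.14)
  # ratio read-back
  row <- dn$table[1, ]
  expect_equal(row$dN / row$dS, ratios$omega[1])
  expect_true(all(dn$table$dN > 0 & dn$table$dS > 0))
})

test_that("noiseless generated data recovers its family with R2 = 1", {
  for (fam in c("linear", "logarithmic", "quadratic", "exponential")) {
    sp <- dnds_spec(fam, default_dnds_coefficients(fam), noise_sd = 0,
                    seed = 2)
    uni <- paste0("g", 1:40)
    dn <- gen_dnds_table(sp, uni[1:15], uni)
    mo <- annotation_species_means(dnds_ratios(dn$table), uni[1:15])
    times <- setNames(dn$species$divergence_time_my, dn$species$species)
    ft <- fit_curve_families(times, mo)
    expect_identical(ft$best, fam)
    expect_equal(ft$fits$r2[match(fam, ft$fits$family)], 1,
                 tolerance = 1e-10)
  }
})
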