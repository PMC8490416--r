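def_times <- c(chimpanzee = 6.6, gorilla = 8.8, orangutan = 15.8,
               macaque = 29.4, olive_baboon = 29.4, vervet_AGM = 29.4,
               marmoset = 43.2)

test_that("dN/dS ratios divide correctly and exclude undefined rows", {
  tab <- data.frame(gene = c("a", "a", "b", "b"),
                    species = c("s1", "s2", "s1", "s2"),
                    dN = c(0.02, 0.03, 0.01, 0.05),
                    dS = c(0.04, 0.03, 0, 0.04))
  expect_message(rr <- dnds_ratios(tab), "excluded")
  expect_equal(nrow(rr), 3)
  expect_equal(rr$omega[1], 0.5)
  expect_equal(rr$omega[rr$gene == "a" & rr$species == "s2"], 1)
  expect_equal(attr(rr, "n_excluded"), 1)
  expect_error(dnds_ratios(rbind(tab, tab[1, ])), "duplicate")
})

test_that("species means average valid ratios and name missing species", {
  tab <- data.frame(gene = rep(c("a", "b"), each = 2),
                    species = rep(c("s1", "s2"), 2),
                    dN = c(0.02, 0.02, 0.04, 0.08),
                    dS = c(0.1, 0.1, 0.1, 0.1))
  rr <- dnds_ratios(tab)
  mo <- annotation_species_means(rr, c("a", "b"))
  expect_equal(unname(mo["s1"]), mean(c(0.2, 0.4)))
  expect_equal(unname(annotation_species_means(rr, "a")["s2"]), 0.2)
  expect_error(annotation_species_means(rr, character(0)), "empty")
  rr2 <- rr[!(rr$species == "s2" & rr$gene == "a"), ]
  expect_error(annotation_species_means(rr2, "a"), "s2")
})

test_that("noiseless data from each family is recovered to 1e-8 and selected", {
  specs <- list(linear = c(0.02, 0.006), logarithmic = c(0.05, 0.03),
                quadratic = c(0.3, -0.015, 4e-4),
                exponential = c(2, -0.05))
  for (fam in names(specs)) {
    y <- connevo:::curve_family_value(fam, specs[[fam]], def_times)
    ft <- fit_curve_families(def_times, y)
    expect_identical(ft$best, fam)
    i <- match(fam, ft$fits$family)
    expect_equal(ft$fits$r2[i], 1, tolerance = 1e-10)
    got <- c(ft$fits$b0[i], ft$fits$b1[i], ft$fits$b2[i])
    expect_equal(got[seq_along(specs[[fam]])], specs[[fam]],
                 tolerance = 1e-8)
  }
  # exponential spec example: y = 2 exp(-0.05 t)
  y <- 2 * exp(-0.05 * def_times)
  ft <- fit_curve_families(def_times, y)
  expect_identical(ft$best, "exponential")
  # noiseless linear beats quadratic by parsimony (both fit perfectly)
  ylin <- 0.1 + 0.002 * def_times
  expect_identical(fit_curve_families(def_times, ylin)$best, "linear")
})

test_that("R2, F and p are mutually consistent for all families", {
  set.seed(4)
  y <- 0.1 + 0.003 * def_times + rnorm(7, sd = 0.01)
  ft <- fit_curve_families(def_times, y)
  for (i in seq_len(4)) {
    r2 <- ft$fits$r2[i]; k <- ft$fits$k[i]; n <- ft$fits$n[i]
    f_expected <- (r2 / k) / ((1 - r2) / (n - k - 1))
    expect_equal(ft$fits$fstat[i], f_expected, tolerance = 1e-10)
    expect_equal(ft$fits$p[i],
                 pf(f_expected, k, n - k - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    # independent R2 check: 1 - SSres/SStot on the original scale
    fam <- ft$fits$family[i]
    pred <- switch(fam,
      linear = ft$fits$b0[i] + ft$fits$b1[i] * def_times,
      logarithmic = ft$fits$b0[i] + ft$fits$b1[i] * log(def_times),
      quadratic = ft$fits$b0[i] + ft$fits$b1[i] * def_times +
        ft$fits$b2[i] * def_times^2,
      exponential = ft$fits$b0[i] * exp(ft$fits$b1[i] * def_times))
    r2_ind <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    expect_equal(r2, max(0, min(1, r2_ind)), tolerance = 1e-10)
  }
  expect_error(fit_curve_families(rep(5, 7), y), "variance")
  expect_error(fit_curve_families(def_times[1:3], y[1:3]), "4 species")
})

test_that("permutation null excludes original genes and is deterministic", {
  uni <- paste0("g", 1:300)
  sp <- dnds_spec("linear", c(0.02, 0.006), noise_sd = 0.03, seed = 6)
  dn <- gen_dnds_table(sp, uni[1:30], uni)
  rr <- dnds_ratios(dn$table)
  times <- setNames(dn$species$divergence_time_my, dn$species$species)
  mo <- annotation_species_means(rr, uni[1:30])
  ft <- fit_curve_families(times, mo)
  p1 <- permutation_corrected_p(ft, rr, uni[1:30], uni, 50, seed = 3)
  p2 <- permutation_corrected_p(ft, rr, uni[1:30], uni, 50, seed = 3)
  expect_identical(p1$null_r2, p2$null_r2)
  expect_equal(p1$p, 1 - pnorm(p1$z))
  # z = 0 maps to exactly 0.5
  expect_equal(1 - pnorm(0), 0.5)
  # the drawing pool excludes every original gene: verify directly
  set.seed(3)
  draws <- replicate(50, sample(setdiff(uni, uni[1:30]), 30))
  expect_false(any(draws %in% uni[1:30]))
  # z three SD above the null mean
  expect_equal(1 - pnorm(3), 0.00135, tolerance = 1e-4)
  expect_error(permutation_corrected_p(ft, rr, uni[1:10], uni[1:15], 10, 1),
               "fewer")
})
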