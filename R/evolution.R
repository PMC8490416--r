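#' Per-row dN/dS ratios with exclusion of undefined rows
#'
#' Computes `omega = dN/dS` for every (gene, species) row. Rows with
#' `dS = 0` or missing dN/dS are excluded (not set to infinity) and
#' counted in the `n_excluded` attribute; a message reports the count.
#' Ratios above 1 indicate positive (adaptive, diversifying) selection,
#' below 1 purifying selection.
#'
#' @param table data.frame with columns `gene`, `species`, `dN`, `dS`.
#' @return the table with an `omega` column, invalid rows dropped;
#'   attribute `n_excluded`.
#' @export
dnds_ratios <- function(table) {
  stopifnot(all(c("gene", "species", "dN", "dS") %in% names(table)))
  if (anyDuplicated(table[c("gene", "species")]))
    stop("duplicate (gene, species) rows")
  bad <- is.na(table$dN) | is.na(table$dS) | table$dS == 0
  if (any(bad))
    message(sum(bad), " row(s) with dS = 0 or missing values excluded")
  out <- table[!bad, , drop = FALSE]
  out$omega <- out$dN / out$dS
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Mean dN/dS per species over an annotation's gene set
#'
#' Arithmetic mean of the valid ratios of the gene set's members, one
#' value per species. Errors if any species has no valid ratio in the
#' set.
#'
#' @param ratios data.frame from [dnds_ratios()] (must have `omega`).
#' @param gene_set character vector of gene ids (nonempty).
#' @return named numeric vector of per-species mean ratios.
#' @export
annotation_species_means <- function(ratios, gene_set) {
  if (!length(gene_set)) stop("empty gene set")
  if (is.null(ratios$omega)) ratios <- dnds_ratios(ratios)
  sub <- ratios[ratios$gene %in% gene_set, , drop = FALSE]
  sp <- unique(ratios$species)
  miss <- setdiff(sp, unique(sub$species))
  if (length(miss))
    stop("no valid dN/dS ratio for species: ", paste(miss, collapse = ", "))
  means <- tapply(sub$omega, sub$species, mean)
  out <- as.vector(means[sp])
  names(out) <- sp
  out
}

# R-squared on the original y scale plus the F statistic and p-value of
# the overall regression, computed from the R-squared identity with k
# predictor parameters.
r2_f_p <- function(y, pred, k) {
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - pred)^2) / sst
  r2c <- max(0, min(1, r2))
  df2 <- length(y) - k - 1
  f <- (r2c / k) / ((1 - r2c) / df2)
  p <- stats::pf(f, k, df2, lower.tail = FALSE)
  list(r2 = r2c, f = f, p = p)
}

#' Fit the four curve families to mean dN/dS against divergence time
#'
#' Ordinary least squares fits of linear (`y = b0 + b1*t`), logarithmic
#' (`y = b0 + b1*log(t)`), quadratic (`y = b0 + b1*t + b2*t^2`) and
#' exponential (`y = b0*exp(b1*t)`, fitted by OLS on `log y` with fit
#' quality re-expressed on the original y scale). For each family, R^2,
#' the overall F statistic and its p-value are reported; the best model
#' minimizes the p-value, with near-perfect fits (R^2 within 1e-8 of 1)
#' treated as tied and resolved by parsimony (fewer parameters), then by
#' the family order above.
#'
#' @param times numeric vector of divergence times (> 0, million years);
#'   at least 4 distinct values.
#' @param y numeric vector of mean dN/dS per species (same length).
#' @return object of class `"curve_fit"`: list with `fits` (data.frame:
#'   family, b0, b1, b2, r2, fstat, p, k, n) and `best` (family name).
#' @export
fit_curve_families <- function(times, y) {
  stopifnot(length(times) == length(y), all(times > 0))
  n <- length(y)
  if (n < 4) stop("need at least 4 species")
  if (stats::sd(times) == 0) stop("zero variance in divergence times")
  fams <- c("linear", "logarithmic", "quadratic", "exponential")
  fits <- data.frame(family = fams, b0 = NA_real_, b1 = NA_real_,
                     b2 = NA_real_, r2 = NA_real_, fstat = NA_real_,
                     p = NA_real_, k = c(1L, 1L, 2L, 1L), n = n,
                     stringsAsFactors = FALSE)
  design <- list(linear = cbind(1, times),
                 logarithmic = cbind(1, log(times)),
                 quadratic = cbind(1, times, times^2))
  for (fam in names(design)) {
    ft <- stats::lm.fit(design[[fam]], y)
    i <- match(fam, fams)
    cf <- ft$coefficients
    fits$b0[i] <- cf[1]; fits$b1[i] <- cf[2]
    if (fam == "quadratic") fits$b2[i] <- cf[3]
    m <- r2_f_p(y, ft$fitted.values, fits$k[i])
    fits$r2[i] <- m$r2; fits$fstat[i] <- m$f; fits$p[i] <- m$p
  }
  if (all(y > 0)) {
    ft <- stats::lm.fit(cbind(1, times), log(y))
    i <- match("exponential", fams)
    fits$b0[i] <- exp(ft$coefficients[1]); fits$b1[i] <- ft$coefficients[2]
    pred <- fits$b0[i] * exp(fits$b1[i] * times)
    m <- r2_f_p(y, pred, 1L)
    fits$r2[i] <- m$r2; fits$fstat[i] <- m$f; fits$p[i] <- m$p
  }
  cand <- which(!is.na(fits$p))
  perfect <- cand[fits$r2[cand] >= 1 - 1e-8]
  best <- if (length(perfect)) {
    perfect[order(fits$k[perfect], perfect)][1]
  } else {
    cand[order(fits$p[cand], fits$k[cand], cand)][1]
  }
  structure(list(fits = fits, best = fits$family[best],
                 times = times, y = y), class = "curve_fit")
}

#' Gene-list permutation null for a best-family fit
#'
#' Draws `n_iter` random gene lists of the original size from the
#' universe with the original genes excluded, refits the original's best
#' curve family to each list's per-species mean ratios, z-scores the
#' original R^2 against the null R^2 distribution and converts it to a
#' corrected p-value through the standard normal CDF:
#' `p = 1 - pnorm(z)`.
#'
#' @param fit a `"curve_fit"` for the original gene list.
#' @param ratios data.frame from [dnds_ratios()].
#' @param gene_set the original annotation gene list.
#' @param universe_genes all candidate genes.
#' @param n_iter number of permutation lists (default 100).
#' @param seed integer seed.
#' @return list with `z`, `p`, `null_r2`, `null_mean`, `null_sd`,
#'   `n_iter`, `family`.
#' @export
permutation_corrected_p <- function(fit, ratios, gene_set, universe_genes,
                                    n_iter = 100, seed = 1L) {
  stopifnot(inherits(fit, "curve_fit"))
  pool <- setdiff(universe_genes, gene_set)
  nset <- length(gene_set)
  if (length(pool) < nset)
    stop("universe minus the original set has fewer genes than the set")
  fam <- fit$best
  i <- match(fam, fit$fits$family)
  r2_orig <- fit$fits$r2[i]
  set.seed(seed)
  null_r2 <- numeric(n_iter)
  for (b in seq_len(n_iter)) {
    rl <- sample(pool, nset)
    mo <- annotation_species_means(ratios, rl)
    ftb <- refit_family(fam, fit$times, mo)
    null_r2[b] <- ftb
  }
  mu <- mean(null_r2)
  sdv <- stats::sd(null_r2)
  if (sdv == 0) stop("degenerate permutation null (zero SD)")
  z <- (r2_orig - mu) / sdv
  list(z = z, p = 1 - stats::pnorm(z), null_r2 = null_r2,
       null_mean = mu, null_sd = sdv, n_iter = n_iter, family = fam)
}

# R-squared (original y scale, clamped to [0,1]) of one family's OLS fit.
refit_family <- function(family, times, y) {
  if (family == "exponential") {
    if (any(y <= 0)) return(NA_real_)
    ft <- stats::lm.fit(cbind(1, times), log(y))
    pred <- exp(ft$coefficients[1] + ft$coefficients[2] * times)
  } else {
    x <- switch(family,
                linear = cbind(1, times),
                logarithmic = cbind(1, log(times)),
                quadratic = cbind(1, times, times^2))
    ft <- stats::lm.fit(x, y)
    pred <- ft$fitted.values
  }
  sst <- sum((y - mean(y))^2)
  max(0, min(1, 1 - sum((y - pred)^2) / sst))
}
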