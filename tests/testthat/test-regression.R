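test_that("pearson_r behaves as a product-moment correlation must", {
  set.seed(3)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(x, x), 1.0)
  # invariance under positive affine maps, antisymmetry under negation
  expect_equal(pearson_r(3 * x + 7, y), r)
  expect_equal(pearson_r(x, 0.5 * y - 2), r)
  expect_equal(pearson_r(-x, y), -r)
  expect_error(pearson_r(rep(1, 5), y[1:5]), class = "insula_degenerate_error")
  expect_error(pearson_r(x[1:2], y[1:2]), class = "insula_validation_error")
})

test_that("the species-area power law recovers exact data and errors on degenerate input", {
  S <- c(20, 30, 50, 80, 120)
  A <- (S / 10)^(1 / 0.3)  # chosen so S = 10 * A^0.3 holds exactly
  tab <- make_island_table(5, Area = A, Spp = S)
  fit <- fit_species_area_power_law(tab)
  expect_equal(fit$c, 10, tolerance = 1e-8)
  expect_equal(fit$z, 0.3, tolerance = 1e-8)
  expect_equal(fit$r_loglog, 1)

  const <- make_island_table(5, Area = rep(1000, 5), Spp = S)
  expect_error(fit_species_area_power_law(const),
               class = "insula_degenerate_error")
})

test_that("AICc arithmetic and limits hold", {
  expect_equal(aic(-50, 4), 108)
  expect_equal(aicc(-50, 4, 8), 108 + 40 / 3)
  expect_equal(aicc(-50, 0, 8), aic(-50, 0))
  expect_equal(aicc(-50, 4, 1e9), aic(-50, 4), tolerance = 1e-6)
  expect_error(aicc(-50, 4, 5), class = "insula_domain_error")
  # strictly decreasing in the log-likelihood at fixed k, n
  lls <- seq(-60, -40, by = 2.5)
  expect_true(all(diff(sapply(lls, aicc, k = 3, n = 10)) < 0))
})

test_that("intercept-only NB fit has the arithmetic mean as fitted value", {
  y <- c(12, 45, 230, 80, 51, 9, 140, 33)
  tab <- make_island_table(8, Spp = y)
  fit <- fit_negative_binomial(tab, character())
  expect_equal(unname(exp(fit$coefficients[1])), mean(y), tolerance = 1e-6)
  expect_equal(fit$explained_deviance, 0)
  expect_identical(fit$k, 2L)
})

test_that("NB ML estimates match the dense grid-search oracle on tiny data", {
  set.seed(42)
  for (i in 1:3) {
    n <- 8
    x <- stats::runif(n, -1, 1)
    mu <- exp(stats::runif(1, 4.5, 5.5) + stats::runif(1, 0.5, 1) * x)
    y <- stats::rnbinom(n, mu = mu, size = stats::runif(1, 1, 2))
    y[y == 0] <- 1
    tab <- make_island_table(n, Spp = y); tab$X <- x
    fit <- suppressWarnings(fit_negative_binomial(tab, "X"))
    orc <- oracle_nb_grid_fit(y, x)
    expect_true(all(agrees_sig(unname(fit$coefficients), c(orc$b0, orc$b1))))
    expect_true(agrees_sig(fit$theta, orc$theta))
    expect_true(agrees_sig(fit$loglik, orc$loglik))
  }
})

test_that("beta ML estimates match the dense grid-search oracle on tiny data", {
  set.seed(43)
  for (i in 1:3) {
    n <- 6
    x <- stats::runif(n, -1, 1)
    mu <- stats::plogis(stats::runif(1, -2, -1) + stats::runif(1, 0.5, 1) * x)
    y <- stats::rbeta(n, mu * 40, (1 - mu) * 40)
    tab <- make_island_table(n, Spp = rep(1000, n)); tab$X <- x; tab$Y <- y
    fit <- fit_beta_regression(tab, "X", response = "Y")
    orc <- oracle_beta_grid_fit(y, x)
    expect_true(all(agrees_sig(unname(fit$coefficients), c(orc$g0, orc$g1))))
    expect_true(agrees_sig(fit$phi, orc$phi))
  }
})

test_that("NB2 approaches the Poisson GLM as dispersion becomes large", {
  set.seed(8)
  n <- 200
  x <- stats::runif(n, -1, 1)
  y <- stats::rpois(n, exp(3 + 0.8 * x))
  tab <- make_island_table(n, Spp = y); tab$X <- x
  nb <- suppressWarnings(fit_negative_binomial(tab, "X"))
  pois <- stats::glm(y ~ x, family = stats::poisson())
  expect_equal(unname(nb$coefficients), unname(stats::coef(pois)),
               tolerance = 1e-3)
  expect_gt(nb$theta, 100)
})

test_that("adding a predictor never increases residual deviance at fixed theta", {
  tab <- load_island_fixture()
  subsets <- list(character(), "Area", c("Area", "Topography"),
                  c("Area", "Topography", "Isolation"),
                  c("Area", "Topography", "Isolation", "Population"))
  devs <- sapply(subsets, function(pr)
    fit_negative_binomial(tab, pr, theta = 100)$residual_deviance)
  expect_true(all(diff(devs) <= 1e-8))
  for (pr in subsets[-1]) {
    f <- fit_negative_binomial(tab, pr, theta = 100)
    expect_gte(f$explained_deviance, 0)
    expect_lte(f$explained_deviance, 1)
  }
})

test_that("near-noiseless beta data recovers the linear predictor", {
  set.seed(12)
  n <- 40
  x <- stats::runif(n, -1, 1)
  mu <- stats::plogis(-1 + 2 * x)
  y <- stats::rbeta(n, mu * 5000, (1 - mu) * 5000)
  tab <- make_island_table(n, Spp = rep(1000, n)); tab$X <- x; tab$Y <- y
  fit <- fit_beta_regression(tab, "X", response = "Y")
  expect_equal(unname(fit$coefficients), c(-1, 2), tolerance = 0.05)
  expect_gt(fit$pseudo_r2, 0.99)
})

test_that("the beta fitter agrees with an independent ML implementation", {
  skip_if_not_installed("glmmTMB")
  tab <- load_island_fixture()
  fit <- fit_beta_regression(tab, c("Topography", "Isolation"))
  ref <- glmmTMB::glmmTMB(Prop ~ Topography + Isolation,
                          data = as.data.frame(tab),
                          family = glmmTMB::beta_family())
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-4)
  expect_equal(fit$phi, stats::sigma(ref), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("beta boundary responses error by default and shrink on request", {
  y <- c(0.1, 0.2, 0, 0.3, 0.25, 0.15, 0.4, 0.2) * 1000
  tab <- make_island_table(8, Spp = rep(1000, 8), Endemics = y)
  expect_error(fit_beta_regression(tab, "Topography"),
               class = "insula_domain_error")
  fit <- fit_beta_regression(tab, character(), boundary = "shrink")
  expect_s3_class(fit, "beta_fit")
})

test_that("best_subsets ranks every subset and flags failed fits", {
  cfg <- synthetic_config(seed = 99, table = list(n = 40))
  tab <- generate_island_table(cfg)
  mt <- suppressWarnings(best_subsets(tab, "count"))
  expect_identical(nrow(mt$summary), 15L)  # all non-empty subsets of 4
  expect_true(!is.unsorted(mt$summary$aicc))
  expect_identical(mt$summary$rank, seq_len(15L))

  single <- suppressWarnings(best_subsets(tab, "count", candidates = "Area"))
  expect_identical(nrow(single$summary), 1L)

  # a subset that cannot be fitted is flagged, the others still ranked
  tab2 <- tab; tab2$Bad <- rep(1, nrow(tab))  # constant column
  class(tab2) <- class(tab); attr(tab2, "provenance") <- "test"
  mt2 <- suppressWarnings(
    best_subsets(tab2, "proportion",
                 specs = list(ok = "Topography", bad = "Bad")))
  expect_identical(names(mt2$failures), "bad")
  expect_identical(mt2$summary$label, "ok")
})

test_that("exact AICc ties break by parameter count then label", {
  summ <- data.frame(label = c("b", "a", "c"),
                     predictors = c("x", "x+y", "x"),
                     k = c(4L, 3L, 4L),
                     loglik = 0, aic = 0,
                     aicc = c(100, 100, 100))
  ranked <- summ[order(summ$aicc, summ$k, summ$label), ]
  expect_identical(ranked$label, c("a", "b", "c"))

  # identical predictor sets under two labels: same aicc and k, label decides
  tab <- load_island_fixture()
  mt <- best_subsets(tab, "count",
                     specs = list(Z1 = c("Area", "Topography"),
                                  A1 = c("Topography", "Area")))
  expect_equal(mt$summary$aicc[1], mt$summary$aicc[2])
  expect_identical(mt$summary$label, c("A1", "Z1"))
})

test_that("model reports render p-values, deviances and round-trip as CSV", {
  tab <- load_island_fixture()
  mt <- best_subsets(tab, "count", specs = count_model_specs())
  rep1 <- model_report(mt)
  expect_identical(names(rep1)[1:2], c("Model", "Predictors"))
  c1 <- rep1[rep1$Model == "C1", ]
  expect_match(c1$Predictors, "Area, <0.001\\*")
  expect_match(c1$ExplainedDeviance, "^96.3%$")
  expect_false(any(grepl("Intercept", rep1$Predictors)))

  p <- withr::local_tempfile(fileext = ".csv")
  model_report(mt, p)
  back <- utils::read.csv(p, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  expect_equal(as.data.frame(back), rep1)

  bt <- best_subsets(tab, "proportion", specs = proportion_model_specs())
  rep2 <- model_report(bt)
  expect_true("PseudoR2" %in% names(rep2))
  d2 <- rep2[rep2$Model == "D2", ]
  expect_match(d2$Predictors, "Topography, 0\\.0[0-9]+\\*")
})

test_that("prediction surfaces are consistent with fitted values and monotone", {
  tab <- load_island_fixture()
  fit <- fit_negative_binomial(tab, c("Area", "Topography"))
  # at an observed island's coordinates the surface equals its fitted mean
  surf1 <- predict_surface(fit, "Area", "Topography",
                           x_range = rep(tab$Area[1], 2),
                           y_range = rep(tab$Topography[1], 2), n_grid = 2)
  expect_equal(surf1$mu[1], unname(stats::fitted(fit$model)[1]),
               tolerance = 1e-8)
  # monotone in each predictor with a positive coefficient
  surf <- predict_surface(fit, "Area", "Topography", n_grid = 10)
  expect_true(all(fit$coefficients[c("Area", "Topography")] > 0))
  by_topo <- surf$mu[surf$Area == min(surf$Area)]
  expect_true(all(diff(by_topo) > 0))
  expect_error(predict_surface(fit, "Area", "Isolation"),
               class = "insula_validation_error")
})
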