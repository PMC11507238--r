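test_that("intercept-only fit recovers the marginal log-odds", {
  y <- c(rep("blue", 100), rep("intermediate", 50), rep("brown", 50))
  g <- tibble::tibble(sample_id = sprintf("s%d", seq_along(y)))
  fit <- fit_mlr(g, y, "eye", predictors = character(0), ref = "blue")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[, "(Intercept)"]),
               c(log(50 / 100), log(50 / 100)), tolerance = 1e-5)
  # predicted probabilities = observed marginals
  pr <- predict(fit, g[1, ])
  expect_equal(unlist(pr[1, c("blue", "intermediate", "brown")]),
               c(blue = 0.5, intermediate = 0.25, brown = 0.25),
               tolerance = 1e-5)
})

test_that("phenotype independent of genotype drives slopes to zero", {
  n <- 20000
  cohort <- withr::with_seed(3, {
    g <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                        snp1 = rbinom(n, 2, 0.4),
                        snp2 = rbinom(n, 2, 0.2))
    y <- sample(c("blue", "brown"), n, replace = TRUE, prob = c(0.3, 0.7))
    list(g = g, y = y)
  })
  g2 <- cohort$g
  names(g2)[2:3] <- c("rs12913832", "rs1800407")
  fit <- fit_mlr(g2, cohort$y, "eye", predictors = c("rs12913832", "rs1800407"))
  expect_lt(max(abs(fit$coefficients[, -1])), 0.1)
  expect_equal(unname(fit$coefficients[1, 1]), log(0.7 / 0.3), tolerance = 0.1)
})

test_that("binary fit matches a brute-force likelihood grid on a toy set", {
  g <- tibble::tibble(sample_id = sprintf("s%d", 1:10),
                      rs12913832 = c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L, 1L))
  y <- c("blue", "blue", "brown", "blue", "brown", "brown",
         "brown", "brown", "blue", "brown")
  fit <- fit_mlr(g, y, "eye", predictors = "rs12913832", ref = "blue")
  # grid-search oracle over (intercept, slope)
  ll <- function(a, b) {
    eta <- a + b * g$rs12913832
    p <- 1 / (1 + exp(-eta))
    sum(ifelse(y == "brown", log(p), log(1 - p)))
  }
  grid <- expand.grid(a = seq(-3, 3, by = 0.01), b = seq(-3, 3, by = 0.01))
  best <- grid[which.max(mapply(ll, grid$a, grid$b)), ]
  expect_equal(unname(fit$coefficients["brown", "(Intercept)"]), best$a,
               tolerance = 0.02)
  expect_equal(unname(fit$coefficients["brown", "rs12913832"]), best$b,
               tolerance = 0.02)
  expect_equal(fit$log_lik, ll(best$a, best$b), tolerance = 1e-3)
})

test_that("fit agrees with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  cohort <- generate_cohort(clean_spec(1500, seed = 21))
  preds <- pigment_panel("eye")$rsid
  fit <- fit_mlr(cohort$genotypes, cohort$phenotypes, "eye",
                 predictors = preds, ref = "blue")
  df <- data.frame(y = factor(cohort$phenotypes$eye,
                              c("blue", "intermediate", "brown")),
                   as.data.frame(cohort$genotypes[, preds]))
  ref_fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 500)
  expect_equal(unname(as.matrix(coef(ref_fit))),
               unname(fit$coefficients), tolerance = 1e-3)
  expect_equal(as.numeric(logLik(ref_fit)), fit$log_lik, tolerance = 1e-4)
})

test_that("predicted probabilities are normalised and handle missing dosages", {
  cohort <- generate_cohort(clean_spec(400, seed = 8))
  fit <- fit_mlr(cohort$genotypes, cohort$phenotypes, "eye",
                 predictors = pigment_panel("eye")$rsid)
  g <- cohort$genotypes
  g$rs12913832[1] <- NA_integer_   # required marker: never imputed
  g$rs1393350[2] <- NA_integer_    # imputable
  pr_none <- predict(fit, g, impute = "none")
  expect_true(all(is.na(pr_none$blue[1:2])))
  pr <- predict(fit, g, impute = "mean")
  expect_true(is.na(pr$blue[1]))   # NA-call signal, not a number
  expect_false(is.na(pr$blue[2]))
  expect_true(pr$.imputed[2])
  sums <- rowSums(as.matrix(pr[, c("blue", "intermediate", "brown")]))
  expect_equal(sums[-1], rep(1, nrow(g) - 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("AIC follows 2k - 2logLik and nested-model bookkeeping", {
  cohort <- generate_cohort(clean_spec(800, seed = 12))
  f1 <- fit_mlr(cohort$genotypes, cohort$phenotypes, "eye",
                predictors = "rs12913832")
  expect_equal(AIC(f1), 2 * f1$n_params - 2 * f1$log_lik)
  expect_equal(f1$n_params, 2 * 2)  # (K-1)(1+P), K=3, P=1
  # adding a predictor adds K-1 parameters and cannot reduce the likelihood
  f2 <- fit_mlr(cohort$genotypes, cohort$phenotypes, "eye",
                predictors = c("rs12913832", "rs1393350"))
  expect_equal(f2$n_params - f1$n_params, 2)
  expect_gte(f2$log_lik, f1$log_lik - 1e-6)
  expect_equal(AIC(f2) - AIC(f1),
               2 * 2 - 2 * (f2$log_lik - f1$log_lik), tolerance = 1e-9)
})

test_that("complete separation is capped and flagged, zero-category errors", {
  g <- tibble::tibble(sample_id = sprintf("s%d", 1:20),
                      rs12913832 = rep(c(0L, 2L), each = 10))
  y <- rep(c("blue", "brown"), each = 10)
  expect_warning(fit <- fit_mlr(g, y, "eye", predictors = "rs12913832"),
                 "separation")
  expect_false(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_lte(max(abs(fit$coefficients)), 15)

  expect_error(fit_mlr(g, rep("blue", 20), "eye", predictors = "rs12913832"),
               "2 observed categories")
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- tiny_eye_data()
  fit <- suppressWarnings(
    fit_mlr(d$genotypes, d$phenotypes, "eye", predictors = "rs12913832"))
  td <- tidy(fit)
  expect_named(td, c("y.level", "term", "estimate"))
  expect_equal(nrow(td), 2 * 2)
  gl <- glance(fit)
  expect_named(gl, c("logLik", "AIC", "df", "nobs", "n_dropped", "converged"))
  expect_equal(gl$nobs, 6)
})
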