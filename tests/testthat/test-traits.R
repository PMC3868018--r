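test_that("optimal scaling standardizes to mean 0 and SD 10", {
  set.seed(1)
  x <- rnorm(37, 50, 9)
  z <- optimal_scale(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 10, tolerance = 1e-12)
  # affine invariance
  expect_equal(optimal_scale(3.2 * x + 11), z, tolerance = 1e-9)
  # idempotence
  expect_equal(optimal_scale(z), z, tolerance = 1e-9)
  # hand-computed three-point column under the population-SD convention
  expect_equal(optimal_scale(c(1, 2, 3)),
               c(-1, 0, 1) / sqrt(2 / 3) * 10, tolerance = 1e-12)
  # sample-SD convention is available and gives the simpler values
  expect_equal(optimal_scale(c(1, 2, 3), sd_denom = "sample"),
               c(-10, 0, 10), tolerance = 1e-12)
  expect_error(optimal_scale(data.frame(a = rep(1, 5))), "'a'")
})

test_that("lasso path endpoints are the null model and the OLS solution", {
  set.seed(7)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8)
  X <- sweep(X, 2, colMeans(X))
  beta <- c(3, -2, 0, 0, 1, 0, 0, 0)
  y <- drop(X %*% beta) + rnorm(n)
  y <- y - mean(y)
  path <- lasso_path(X, y)
  expect_equal(length(path$fractions), 51)
  expect_true(all(path$coefficients[1, ] == 0))
  expect_lt(max(abs(path$coefficients[51, ] - oracle_ols(X, y))), 1e-6)
  # L1 norm is nondecreasing along the shrinkage axis
  l1 <- rowSums(abs(path$coefficients))
  expect_true(all(diff(l1) > -1e-10))
  # each constrained solution honors its L1 budget
  expect_true(all(l1 <= path$fractions * sum(abs(path$beta_ols)) + 1e-8))
})

test_that("homotopy knots agree with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(13)
  n <- 50
  X <- sweep(matrix(rnorm(n * 6), n, 6), 2, colMeans(matrix(0, 1, 6)))
  X <- sweep(X, 2, colMeans(X))
  y <- drop(X %*% c(2, -1, 0.5, 0, 0, 0)) + rnorm(n)
  y <- y - mean(y)
  hom <- infoweight:::lasso_homotopy(X, y)
  # mid-path knots (exclude the endpoints)
  ks <- seq(2, length(hom$lambda) - 1)
  for (kk in ks) {
    lam <- hom$lambda[kk]
    if (lam <= 0) next
    g <- glmnet::glmnet(X, y, lambda = lam / n, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(as.numeric(g$beta) - hom$beta[kk, ])), 1e-5)
  }
})

test_that("a dominant predictor enters the path first", {
  set.seed(17)
  n <- 200
  true_x <- rnorm(n)
  y <- 0.9 * true_x + rnorm(n, sd = sqrt(1 - 0.81))
  X <- cbind(true_x, matrix(rnorm(n * 7), n, 7))
  colnames(X) <- paste0("x", 1:8)
  X <- sweep(X, 2, colMeans(X))
  y <- y - mean(y)
  path <- lasso_path(X, y)
  first_nonzero <- apply(path$coefficients, 2,
                         function(co) which(abs(co) > 1e-10)[1])
  expect_equal(unname(which.min(first_nonzero)), 1)
})

test_that(".632 selection is seed-deterministic and error-consistent", {
  set.seed(19)
  n <- 36
  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- paste0("t", 1:8)
  y <- drop(X %*% c(-0.5, -0.5, 0, 0, 0, 0, 0, 0)) + rnorm(n)
  Xs <- as.matrix(optimal_scale(as.data.frame(X)))
  ys <- optimal_scale(y)
  a <- select_optimal(Xs, ys, B = 50, seed = 42)
  b <- select_optimal(Xs, ys, B = 50, seed = 42)
  expect_identical(a$fraction, b$fraction)
  expect_identical(a$coefficients, b$coefficients)
  expect_equal(a$errors$err632,
               0.368 * a$errors$apparent + 0.632 * a$errors$oob)
  # expected prediction error at the chosen level is the minimum
  expect_equal(min(a$errors$err632), a$errors$err632[
    match(a$fraction, a$errors$fraction)])
})

test_that("bootstrap correlation reproduces the closed-form Pearson r", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(0.9, 2.8, 2.6, 4.9, 3.1)
  bc <- bootstrap_corr(x, y, B = 500, seed = 3)
  expect_equal(bc$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(bc$r, cor(x, y), tolerance = 1e-12)
})

test_that("a perfect correlation is significant with a degenerate-free CI", {
  x <- seq(1, 4, length.out = 20)
  bc <- bootstrap_corr(x, x, B = 1000, seed = 5)
  expect_equal(bc$r, 1)
  expect_true(bc$significant)
  expect_gt(bc$ci[1], 0)
})

test_that("bootstrap CI flags match the exclusion-of-zero rule", {
  set.seed(23)
  x <- rnorm(40)
  y_null <- rnorm(40)
  bc <- bootstrap_corr(x, y_null, B = 2000, seed = 7)
  expect_identical(bc$significant, bc$ci[1] > 0 || bc$ci[2] < 0)
  expect_error(bootstrap_corr(1:2, 1:2), ">= 3")
})

test_that("normality check is valid, bounded, and powered", {
  set.seed(29)
  ks <- ks_normality(rnorm(200))
  expect_gte(ks$statistic, 0)
  expect_lte(ks$statistic, 1)
  expect_gt(ks$p, 0.001)
  ks_u <- ks_normality(runif(500))
  expect_lt(ks_u$p, 0.01)
  expect_error(ks_normality(rep(2, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "n >= 5")
  asy <- ks_normality(runif(500), method = "asymptotic")
  expect_true(is.finite(asy$p))
})

test_that("the association stage recovers a strong planted signal", {
  set.seed(31)
  n <- 36
  stats <- ppi_subscale_stats()
  traits <- as.data.frame(lapply(seq_len(8), function(j)
    rnorm(n, stats$mean[j], stats$sd[j])))
  names(traits) <- stats$trait
  z <- (traits[["Stress Immunity"]] - mean(traits[["Stress Immunity"]])) /
    sd(traits[["Stress Immunity"]])
  param <- exp(log(1.1) - 0.8 * z + rnorm(n, sd = 0.25))
  res <- associate_traits(traits, param, target = "gamma_reward",
                          B_select = 100, B_corr = 2000, seed = 11)
  expect_true("Stress Immunity" %in% res$selection$predictors)
  sel_row <- res$correlations[res$correlations$trait == "Stress Immunity", ]
  expect_lt(sel_row$r, 0)
  expect_true(sel_row$significant)
  expect_equal(nrow(res$normality), 9)
})
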