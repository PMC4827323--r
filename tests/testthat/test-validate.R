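test_that("nrmse matches closed forms and is scale-consistent", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(0.5, 0.5), c(0, 1)), 0.5)
  # on a [0, 1]-spanning target NRMSE equals RMSE
  y <- c(0, 1, 0.5, 1, 0)
  yh <- y + 0.1
  expect_equal(nrmse(yh, y), sqrt(mean(0.1^2)))
  # scaling y, y_hat and range together changes nothing
  expect_equal(nrmse(3 * yh, 3 * y, range = 3), nrmse(yh, y, range = 1))
  # constant target falls back to range 1
  expect_equal(nrmse(c(1, 1), c(0, 0)), 1)
  expect_error(nrmse(numeric(0), numeric(0)), "empty")
})

test_that("the hyperparameter grids are ten log-spaced values each", {
  g <- grid_spec()
  expect_equal(g$lambda, 10^seq(-6, 0, length.out = 10))
  expect_equal(g$sigma, 10^seq(-3, 3, length.out = 10))
  expect_equal(length(g$lambda) * length(g$sigma), 100)
})

expect_partition <- function(folds, universe) {
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_union, sort(universe))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
  }
  sizes <- lengths(lapply(folds, `[[`, "test"))
  expect_lte(max(sizes) - min(sizes), 1)
}

test_that("schemes 1-2 build shuffled partitions of their index sets", {
  for (seed in 0:2) {
    p1 <- make_split_plan(1, 100, seed = seed)
    expect_length(p1$folds, 10)
    expect_partition(p1$folds, 1:100)
    for (f in p1$folds) expect_equal(sort(union(f$train, f$test)), 1:100)

    plateau <- rep(c(TRUE, FALSE), 50)
    p2 <- make_split_plan(2, 100, plateau, seed = seed)
    expect_partition(p2$folds, which(plateau))
    for (f in p2$folds) {
      expect_true(all(plateau[f$train]) && all(plateau[f$test]))
    }
  }
})

test_that("scheme 3 is a single plateau-train / intermediate-test split", {
  plateau <- c(rep(TRUE, 30), rep(FALSE, 20))
  p <- make_split_plan(3, 50, plateau)
  expect_length(p$folds, 1)
  expect_equal(p$folds[[1]]$train, 1:30)
  expect_equal(p$folds[[1]]$test, 31:50)
  expect_equal(sort(union(p$folds[[1]]$train, p$folds[[1]]$test)), 1:50)
})

test_that("schemes 4-5 use contiguous, ordered folds", {
  p4 <- make_split_plan(4, 10)
  tests <- lapply(p4$folds, `[[`, "test")
  expect_equal(tests, list(1:2, 3:4, 5:6, 7:8, 9:10))
  expect_partition(p4$folds, 1:10)

  plateau <- rep(c(TRUE, TRUE, FALSE, FALSE, TRUE), 20)
  p5 <- make_split_plan(5, 100, plateau)
  expect_partition(p5$folds, 1:100)
  for (f in p5$folds) {
    expect_true(all(plateau[f$train]))            # train only on plateaus
    expect_true(all(diff(f$test) == 1))           # contiguous test block
    expect_length(intersect(f$train, f$test), 0)
  }
  # contiguity for scheme 4 with a size not divisible by 5
  p4b <- make_split_plan(4, 23)
  for (f in p4b$folds) expect_true(all(diff(f$test) == 1))
  expect_partition(p4b$folds, 1:23)
})

test_that("degenerate split requests are rejected", {
  expect_error(make_split_plan(6, 100), "1:5")
  expect_error(make_split_plan(2, 100), "plateau")
  expect_error(make_split_plan(3, 10, rep(TRUE, 10)), "intermediate")
  expect_error(make_split_plan(1, 5), "10 frames")
})

test_that("grid-search fit counts follow the evaluation arithmetic", {
  set.seed(10)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- runif(100)
  plateau <- rep(c(TRUE, FALSE), 50)
  grid <- grid_spec()

  cases <- list(
    list(plan = make_split_plan(1, 100), method = "rr", fits = 100),
    list(plan = make_split_plan(4, 100), method = "rr", fits = 50),
    list(plan = make_split_plan(3, 100, plateau), method = "rr", fits = 10),
    list(plan = make_split_plan(3, 100, plateau), method = "rrff", fits = 100)
  )
  for (case in cases) {
    reset_fit_count()
    gs <- grid_search(X, y, case$plan, method = case$method, grid = grid,
                      D = 20, seed = 1L)
    expect_equal(fit_count(), case$fits)
    expect_equal(gs$n_fits, case$fits)
  }
})

test_that("a single-point grid returns that point with its CV error", {
  set.seed(11)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.numeric(X %*% rnorm(4))
  g1 <- grid_spec(lambda_exponents = c(-2, -2), n_lambda = 1)
  gs <- grid_search(X, y, make_split_plan(1, 50), method = "rr", grid = g1)
  expect_equal(gs$best$lambda, 1e-2)
  expect_equal(gs$best$nrmse, mean(gs$fold_nrmse))
  expect_equal(nrow(gs$results), 10)
})

test_that("the selected grid point minimizes the fold-mean error", {
  set.seed(12)
  X <- matrix(rnorm(300), 75, 4)
  y <- as.numeric(X %*% rnorm(4) + rnorm(75, sd = 0.2))
  gs <- grid_search(X, y, make_split_plan(1, 75), method = "rr")
  means <- dplyr::summarise(dplyr::group_by(gs$results, lambda),
                            m = mean(nrmse), .groups = "drop")
  expect_equal(gs$best$nrmse, min(means$m))
  expect_equal(gs$best$lambda, means$lambda[which.min(means$m)])
})

test_that("the t-test matches the pooled-variance textbook formula", {
  a <- c(0.1, 0.2, 0.3)
  b <- c(0.15, 0.25, 0.35)
  res <- ttest_two_tailed(a, b)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 4)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-8)
  expect_equal(res$p.value, p_oracle, tolerance = 1e-8)
  expect_equal(res$parameter, 4)
})

test_that("t-test conventions: identical, separated and constant samples", {
  x <- c(1, 2, 3)
  same <- ttest_two_tailed(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  far <- ttest_two_tailed(x, x + 10)
  expect_lt(far$p.value, 0.01)
  const <- ttest_two_tailed(c(1, 1), c(1, 1))
  expect_equal(const$p.value, 1)
  expect_equal(ttest_two_tailed(c(1, 1), c(2, 2))$p.value, 0)
  expect_error(ttest_two_tailed(1, c(1, 2)), ">= 2")
  # Welch and paired variants delegate to the standard machinery
  w <- ttest_two_tailed(x, x + c(0.1, 0.3, 0.2), welch = TRUE)
  expect_equal(w$p.value,
               stats::t.test(x, x + c(0.1, 0.3, 0.2))$p.value)
})

test_that("aggregation computes mean, SD and SEM over subjects", {
  rep1 <- tibble::tibble(subject = 1, scheme = 1, method = "rr",
                         dof = "a", fold = 1:2, nrmse = c(0.1, 0.1))
  rep2 <- dplyr::mutate(rep1, subject = 2, nrmse = 0.3)
  agg <- aggregate_report(dplyr::bind_rows(rep1, rep2))
  expect_equal(agg$mean_nrmse, 0.2)
  expect_equal(agg$sd_nrmse, stats::sd(c(0.1, 0.3)))  # n - 1 denominator
  expect_equal(agg$sem_nrmse, agg$sd_nrmse / sqrt(2))

  same <- dplyr::bind_rows(rep1, dplyr::mutate(rep1, subject = 2))
  agg2 <- aggregate_report(same)
  expect_equal(agg2$sd_nrmse, 0)
  expect_equal(agg2$sem_nrmse, 0)

  ten <- dplyr::bind_rows(lapply(1:10, function(s) {
    dplyr::mutate(rep1, subject = s, nrmse = 0.1 + 0.01 * s)
  }))
  agg3 <- aggregate_report(ten)
  expect_equal(agg3$sem_nrmse, agg3$sd_nrmse / sqrt(10))
  expect_error(aggregate_report(rep1[, -1]), "subject")
})
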