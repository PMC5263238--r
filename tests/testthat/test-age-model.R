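test_that("a strong planted gene is selected first with faithful R2", {
  set.seed(31)
  n <- 120
  expr <- matrix(rnorm(100 * n), 100,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
  ages <- 50 + 10 * expr["g007", ] + rnorm(n, sd = 1)
  gen_r2 <- 100 / 101
  fit <- fitStepwiseAgeModel(expr, ages,
                             ageModelSpec(rownames(expr),
                                          covariates = character(0)))
  expect_equal(fit@trace$term[fit@trace$action == "add"][1], "g007")
  expect_lt(abs(modelR2(fit) - gen_r2), 0.05)
  expect_gte(modelR2(fit), fit@covariateR2)
})

test_that("pure-noise candidates select nothing at a strict entry threshold",
{
  set.seed(32)
  n <- 80
  expr <- matrix(rnorm(50 * n), 50,
                 dimnames = list(sprintf("g%03d", 1:50), NULL))
  ages <- runif(n, 20, 100)
  covars <- data.frame(bank = sample(c("A", "B"), n, TRUE),
                       cause_of_death = sample(c("x", "y"), n, TRUE))
  fit <- fitStepwiseAgeModel(expr, ages,
                             ageModelSpec(rownames(expr),
                                          entry_p = 0.001,
                                          removal_p = 0.002),
                             covariate_data = covars)
  expect_length(selectedTerms(fit), 0)
  expect_equal(modelR2(fit), fit@covariateR2, tolerance = 1e-12)
})

test_that("an interaction with null main effects is found when enabled", {
  set.seed(33)
  n <- 200
  expr <- matrix(rnorm(20 * n), 20,
                 dimnames = list(sprintf("g%03d", 1:20), NULL))
  # main effects present so the genes can enter, product dominant
  ages <- 60 + 5 * expr["g001", ] + 5 * expr["g002", ] +
    12 * expr["g001", ] * expr["g002", ] + rnorm(n, sd = 2)
  fit <- fitStepwiseAgeModel(
    expr, ages,
    ageModelSpec(rownames(expr), covariates = character(0),
                 allow_interactions = TRUE, max_terms = 6))
  expect_true("g001:g002" %in% selectedTerms(fit))
})

test_that("prediction is the linear predictor and names missing genes", {
  set.seed(34)
  n <- 100
  expr <- matrix(rnorm(30 * n), 30,
                 dimnames = list(sprintf("g%03d", 1:30), NULL))
  ages <- 40 + 8 * expr["g003", ] + rnorm(n)
  train <- 1:70
  fit <- fitStepwiseAgeModel(expr[, train], ages[train],
                             ageModelSpec(rownames(expr),
                                          covariates = character(0)))
  # training residuals orthogonal to the selected design (OLS)
  res <- ages[train] - fit@fitted
  for (tm in selectedTerms(fit))
    expect_lt(abs(sum(res * expr[tm, train])), 1e-6)
  # held-out correlation
  pred <- predictAge(fit, expr[, -train])
  expect_gt(cor(pred, ages[-train]), 0.7)
  expect_error(
    predictAge(fit, expr[setdiff(rownames(expr), "g003"), -train,
                         drop = FALSE]),
    "g003")
})

test_that("an intercept-only fit predicts the mean age", {
  set.seed(35)
  n <- 40
  expr <- matrix(rnorm(5 * n), 5,
                 dimnames = list(sprintf("g%03d", 1:5), NULL))
  ages <- rnorm(n, 60, 10)
  fit <- fitStepwiseAgeModel(expr, ages,
                             ageModelSpec(rownames(expr),
                                          covariates = character(0),
                                          entry_p = 1e-9, removal_p = 2e-9))
  if (length(selectedTerms(fit)) == 0)
    expect_equal(unique(round(fit@fitted, 9)), round(mean(ages), 9))
  pred <- predictAge(fit, expr)
  expect_equal(pred, fit@fitted, tolerance = 1e-9)
})

test_that("forced covariates stay in and redundant dummies are dropped", {
  set.seed(36)
  n <- 60
  expr <- matrix(rnorm(10 * n), 10,
                 dimnames = list(sprintf("g%03d", 1:10), NULL))
  bank <- sample(c("A", "B"), n, TRUE)
  covars <- data.frame(bank = bank, dup = bank)  # perfectly collinear
  ages <- 50 + 5 * (bank == "B") + rnorm(n)
  expect_warning(
    fit <- fitStepwiseAgeModel(expr, ages,
                               ageModelSpec(rownames(expr),
                                            covariates = c("bank", "dup")),
                               covariate_data = covars),
    "redundant")
  expect_gt(fit@covariateR2, 0.5)
})

test_that("cell-type model ranking orders by R2 with term-count tie-break", {
  set.seed(37)
  n <- 90
  expr <- matrix(rnorm(40 * n), 40,
                 dimnames = list(sprintf("g%03d", 1:40), NULL))
  ages <- 50 + 9 * expr["g001", ] + rnorm(n)
  fits <- list(
    microglia = fitStepwiseAgeModel(
      expr, ages, ageModelSpec(sprintf("g%03d", 1:10),
                               covariates = character(0))),
    neuron = fitStepwiseAgeModel(
      expr, ages, ageModelSpec(sprintf("g%03d", 21:30),
                               covariates = character(0))))
  rk <- compareCelltypeModels(fits)
  expect_equal(rk$cell_type[1], "microglia")
  expect_equal(compareCelltypeModels(fits["neuron"])$cell_type, "neuron")
  # explicit tie on r2 -> fewer terms wins
  tie <- data.frame()
  f1 <- fits$microglia; f2 <- fits$microglia
  f2@terms <- c(f2@terms, "g002")
  rk2 <- compareCelltypeModels(list(a = f2, b = f1))
  expect_equal(rk2$cell_type[1], "b")
})

test_that("model specs validate their thresholds", {
  expect_error(ageModelSpec("g1", entry_p = 0.1, removal_p = 0.05),
               "smaller")
  expect_error(ageModelSpec(character(0)), "candidate")
  expect_error(ageModelSpec("g1", max_terms = 0), "max_terms")
})
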