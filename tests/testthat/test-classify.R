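# Reduced problem sizes throughout: few proteins, short chains, small
# Monte-Carlo budgets, and a small property pool where template discovery is
# not itself under test.
small_pool <- c("Arg", "Lys", "Gly", "Leu", "Positive")

strong_dataset <- function(n_per_class = 8, seed = 11) {
  generate_dataset(n_per_class, n_per_class, n_residues = 100,
                   cluster_radius = 12, enrichment = 10, seed = seed)
}

test_that("rank-based AUC equals the trapezoidal ROC integral", {
  cases <- list(
    list(score = c(0.9, 0.8, 0.3, 0.2),
         label = c("binding", "binding", "nonbinding", "nonbinding")),
    list(score = c(0.9, 0.4, 0.6, 0.2),
         label = c("binding", "binding", "nonbinding", "nonbinding")),
    list(score = c(0.5, 0.5, 0.5, 0.1),   # ties across classes
         label = c("binding", "nonbinding", "binding", "nonbinding")),
    list(score = c(0.1, 0.2, 0.8, 0.9),   # perfectly wrong
         label = c("binding", "binding", "nonbinding", "nonbinding"))
  )
  for (cs in cases) {
    expect_equal(auc_rank(cs$score, cs$label),
                 trapezoid_auc(cs$score, cs$label), tolerance = 1e-12)
  }
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2),
                        c("binding", "binding", "nonbinding", "nonbinding")), 1)
  expect_error(auc_rank(c(0.1, 0.9), c("binding", "binding")),
               class = "bh_error_config")
})

test_that("training interpolates separable data and is seed-deterministic", {
  ds <- strong_dataset()
  model <- bh_train(ds, radius = 8, n_templates = 2, n_samples = 1500,
                    seed = 5, pool = small_pool, max_length = 2, ntree = 300)
  # model stores exactly the templates its features use
  expect_equal(length(model$templates), 2L)
  used <- unique(vapply(model$space$template, paste, character(1),
                        collapse = ","))
  expect_setequal(used, vapply(model$templates, paste, character(1),
                               collapse = ","))
  # training-set predictions reproduce the labels on strongly separable data
  pred <- predict(model, ds)
  expect_equal(as.character(pred$label), as.character(ds$label))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  # identical seed -> identical model behaviour on a fixed probe
  model2 <- bh_train(ds, radius = 8, n_templates = 2, n_samples = 1500,
                     seed = 5, pool = small_pool, max_length = 2, ntree = 300)
  probe <- generate_structure(100, label = "binding", seed = 999)
  expect_identical(predict(model, probe), predict(model2, probe))
})

test_that("the trained model never sees non-training structures", {
  ds <- strong_dataset(6, seed = 21)
  train <- ds[1:8, ]
  probe <- generate_structure(100, label = "binding", seed = 500)
  m1 <- bh_train(train, radius = 8, n_templates = 1, n_samples = 1000,
                 seed = 3, pool = small_pool, max_length = 2, ntree = 200)
  # mutate every non-training structure; the model must be unaffected
  ds2 <- ds
  for (i in 9:12) {
    ds2$structure[[i]] <- generate_structure(50, seed = 1000 + i)
  }
  m2 <- bh_train(ds2[1:8, ], radius = 8, n_templates = 1, n_samples = 1000,
                 seed = 3, pool = small_pool, max_length = 2, ntree = 200)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("hyperparameter selection respects the grid", {
  ds <- strong_dataset(6, seed = 31)
  # a single-cell grid is returned as-is
  hp <- select_hyperparameters(ds, radii = 8, n_templates_grid = 3L,
                               n_samples = 500, pool = small_pool,
                               max_length = 2)
  expect_equal(hp$radius, 8)
  expect_equal(hp$n_templates, 3L)
  # chosen values always come from the grid
  hp2 <- select_hyperparameters(ds, radii = c(6, 10),
                                n_templates_grid = c(1L, 2L),
                                k_internal = 3L, n_samples = 400,
                                pool = small_pool, max_length = 2,
                                ntree = 100, seed = 7)
  expect_true(hp2$radius %in% c(6, 10))
  expect_true(hp2$n_templates %in% c(1L, 2L))
  expect_equal(nrow(hp2$grid), 4L)
  # stratification failure is reported
  tiny <- ds[c(1:2, 7:8), ]
  expect_error(
    select_hyperparameters(tiny, radii = c(6, 10), n_templates_grid = 1L,
                           k_internal = 5L, n_samples = 300,
                           pool = small_pool, max_length = 2),
    class = "bh_error_config"
  )
})

test_that("cross-validation reports per-fold metrics without leakage", {
  ds <- strong_dataset(6, seed = 41)
  cv <- cross_validate(ds, k = 3, radii = 8, n_templates_grid = 1L,
                       n_samples = 800, seed = 2, pool = small_pool,
                       max_length = 2, ntree = 200)
  expect_equal(nrow(cv$folds), 3L)
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  expect_true(all(cv$folds$radius == 8))
  # every protein predicted exactly once
  expect_setequal(cv$predictions$id, ds$id)
  g <- glance(cv)
  expect_equal(g$mean_auc, mean(cv$folds$auc))
  t <- tidy(cv)
  expect_identical(t, cv$folds)
  expect_error(cross_validate(ds[1:4, ], k = 3, radii = 8,
                              n_templates_grid = 1L, n_samples = 300),
               class = "bh_error_config")
})

test_that("models persist to a versioned archive", {
  ds <- strong_dataset(4, seed = 51)
  model <- bh_train(ds, radius = 8, n_templates = 1, n_samples = 500,
                    seed = 1, pool = small_pool, max_length = 2, ntree = 100)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  back <- read_model(path)
  probe <- generate_structure(80, seed = 123)
  expect_identical(predict(back, probe), predict(model, probe))
  expect_error(read_model(withr::local_tempfile()), class = "bh_error_parse")
})

test_that("model tidiers expose attributes and fit summaries", {
  ds <- strong_dataset(4, seed = 61)
  model <- bh_train(ds, radius = 8, n_templates = 1, n_samples = 500,
                    seed = 1, pool = small_pool, max_length = 2, ntree = 100)
  td <- tidy(model)
  expect_equal(nrow(td), nrow(model$space))
  expect_true(all(diff(td$importance) <= 0))
  g <- glance(model)
  expect_equal(g$radius, 8)
  expect_equal(g$ntree, 100L)
})
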