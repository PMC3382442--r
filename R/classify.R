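.label_levels <- c("nonbinding", "binding")

#' Labeled structure datasets
#'
#' A `bh_dataset` is a tibble with one row per protein: columns `id`,
#' `label` (factor with levels `"nonbinding"`, `"binding"`) and `structure`
#' (list of [protein_structure()]s). `read_dataset()` builds one from a
#' manifest CSV with columns `id`, `path`, `label`, reading each structure
#' file.
#'
#' @param x A data frame with columns `id`, `label`, `structure`.
#' @return A tibble of class `bh_dataset`.
#' @export
as_bh_dataset <- function(x) {
  x <- as_tibble(x)
  if (!all(c("id", "label", "structure") %in% names(x))) {
    abort("dataset needs columns id, label, structure", class = "bh_error_config")
  }
  lab <- as.character(x$label)
  if (!all(lab %in% .label_levels)) {
    abort("labels must be 'binding' or 'nonbinding'", class = "bh_error_config")
  }
  x$id <- as.character(x$id)
  x$label <- factor(lab, levels = .label_levels)
  if (anyDuplicated(x$id)) {
    abort("duplicated protein ids", class = "bh_error_config")
  }
  structure(x, class = c("bh_dataset", class(x)))
}

#' @rdname as_bh_dataset
#' @param manifest Path to a manifest CSV (`id`, `path`, `label`); relative
#'   structure paths are resolved against the manifest's directory.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) {
    abort(paste0("manifest not found: ", manifest), class = "bh_error_parse")
  }
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("id", "path", "label") %in% names(man))) {
    abort("manifest needs columns id, path, label", class = "bh_error_parse")
  }
  paths <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(manifest), man$path))
  structures <- purrr::map2(paths, man$id, function(p, i) {
    read_structure(p, id = i)
  })
  as_bh_dataset(tibble(id = man$id, label = man$label, structure = structures))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the rank statistic (equivalent to
#' the Wilcoxon form, with average ranks for tied scores).
#'
#' @param score Numeric scores, higher meaning more binding-like.
#' @param label True labels (`"binding"` / `"nonbinding"` or a factor).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(score, label) {
  pos <- as.character(label) == "binding"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes needed for AUC", class = "bh_error_config")
  }
  r <- rank(score)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Full-pool master histograms for every protein and radius; the expensive,
# label-independent part of the pipeline, computed once and reused.
compute_masters <- function(dataset, radii, n_samples, seed,
                            pool, table) {
  grid <- tidyr::expand_grid(row = seq_len(nrow(dataset)), radius = radii)
  masters <- purrr::map2(grid$row, grid$radius, function(i, r) {
    master_histogram(dataset$structure[[i]], pool = pool, R = r,
                     n_samples = n_samples, seed = seed, table = table)
  })
  tibble(id = dataset$id[grid$row], radius = grid$radius, master = masters)
}

# Per-protein histograms for the given templates, from cached masters.
hist_tbl_from_masters <- function(masters, templates, labels = NULL) {
  grid <- tidyr::expand_grid(row = seq_len(nrow(masters)),
                             ti = seq_along(templates))
  out <- tibble(
    id = masters$id[grid$row],
    histogram = purrr::map2(grid$row, grid$ti, function(i, t) {
      marginalize(masters$master[[i]], templates[[t]])
    })
  )
  if (!is.null(labels)) out$label <- labels[match(out$id, names(labels))]
  out
}

feature_matrix <- function(features, space) {
  x <- as.matrix(features[, space$attr_id, drop = FALSE])
  colnames(x) <- paste0("a", seq_len(ncol(x)))
  x
}

fit_core <- function(masters_r, labels, search_cfg, n_templates,
                     forest_seed, ntree) {
  templates_all <- discover_templates(
    masters_r$master[labels[masters_r$id] == "binding"],
    masters_r$master[labels[masters_r$id] == "nonbinding"],
    search_cfg
  )
  fit_with_templates(masters_r, labels,
                     templates_all$template[seq_len(min(n_templates, nrow(templates_all)))],
                     templates_all, forest_seed, ntree)
}

fit_with_templates <- function(masters_r, labels, templates, templates_tbl,
                               forest_seed, ntree) {
  hist_tbl <- hist_tbl_from_masters(masters_r, templates, labels)
  space <- collect_attributes(hist_tbl)
  features <- featurize_dataset(hist_tbl, space)
  x <- feature_matrix(features, space)
  if (all(x == 0)) {
    abort("degenerate feature matrix: all values zero",
          class = "bh_error_degenerate")
  }
  y <- factor(as.character(features$label), levels = .label_levels)
  forest <- with_seed(forest_seed,
                      randomForest::randomForest(x = x, y = y, ntree = ntree))
  list(forest = forest, space = space, templates = templates,
       templates_tbl = templates_tbl)
}

predict_from_masters <- function(fit, masters_r) {
  hist_tbl <- hist_tbl_from_masters(masters_r, fit$templates)
  ids <- unique(hist_tbl$id)
  scores <- vapply(ids, function(i) {
    v <- vectorize(hist_tbl$histogram[hist_tbl$id == i], fit$space)
    x <- matrix(v, nrow = 1)
    colnames(x) <- paste0("a", seq_along(v))
    unname(stats::predict(fit$forest, x, type = "prob")[, "binding"])
  }, numeric(1))
  tibble(id = ids, score = unname(scores),
         label = factor(ifelse(scores >= 0.5, "binding", "nonbinding"),
                        levels = .label_levels))
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

check_stratification <- function(labels, k) {
  counts <- table(labels)
  if (any(counts < k)) {
    abort(sprintf("each class needs at least %d members for %d-fold stratification",
                  k, k),
          class = "bh_error_config")
  }
}

#' Select sampling-ball radius and number of templates by internal CV
#'
#' Evaluates every cell of the (radius x number-of-templates) grid by
#' stratified internal cross-validation on the training set only: templates
#' are discovered on each internal training portion, a forest is fitted and
#' scored by AUC on the internal validation portion. The cell with the
#' highest mean internal AUC wins; ties prefer the smaller radius, then
#' fewer templates. With a single grid cell no internal CV is run.
#'
#' @param dataset A [as_bh_dataset()] tibble (the training set).
#' @param radii Numeric vector of candidate sampling-ball radii in
#'   Angstroms; default `c(4, 8, 12)`.
#' @param n_templates_grid Integer vector of candidate template counts;
#'   default `c(1, 3, 5, 7)`.
#' @param k_internal Internal fold count (default 5, stratified).
#' @param n_samples,seed Monte-Carlo settings passed to histogram
#'   construction.
#' @param lambda,max_length,pool,table Template-search settings (see
#'   [search_config()]).
#' @param ntree Forest size (default 500).
#' @param masters Optional precomputed master-histogram table (internal
#'   reuse).
#' @return A list with `radius`, `n_templates` and `grid` (per-cell mean
#'   internal AUC).
#' @export
select_hyperparameters <- function(dataset, radii = c(4, 8, 12),
                                   n_templates_grid = c(1L, 3L, 5L, 7L),
                                   k_internal = 5L, n_samples = 10000L,
                                   seed = 1L, lambda = 0.5, max_length = 3L,
                                   pool = default_pool(table),
                                   table = default_property_table(),
                                   ntree = 500L, masters = NULL) {
  dataset <- as_bh_dataset(dataset)
  if (length(radii) == 1L && length(n_templates_grid) == 1L) {
    return(list(radius = radii, n_templates = n_templates_grid[[1]],
                grid = tibble(radius = radii,
                              n_templates = n_templates_grid[[1]],
                              mean_auc = NA_real_)))
  }
  check_stratification(dataset$label, k_internal)
  if (is.null(masters)) {
    masters <- compute_masters(dataset, radii, n_samples, seed, pool, table)
  }
  labels <- stats::setNames(dataset$label, dataset$id)
  fold <- stratified_folds(dataset$label, k_internal,
                           derive_seed(seed, "internal-folds"))
  max_nt <- max(n_templates_grid)
  search_cfg <- search_config(pool = pool, max_length = max_length,
                              lambda = lambda, n_templates = max_nt,
                              table = table)
  cells <- tidyr::expand_grid(radius = radii, n_templates = n_templates_grid)
  aucs <- matrix(NA_real_, nrow = nrow(cells), ncol = k_internal)
  for (f in seq_len(k_internal)) {
    train_ids <- dataset$id[fold != f]
    val_ids <- dataset$id[fold == f]
    for (r in radii) {
      m_train <- masters[masters$radius == r & masters$id %in% train_ids, ]
      m_val <- masters[masters$radius == r & masters$id %in% val_ids, ]
      templates_all <- discover_templates(
        m_train$master[labels[m_train$id] == "binding"],
        m_train$master[labels[m_train$id] == "nonbinding"],
        search_cfg
      )
      for (ci in which(cells$radius == r)) {
        nt <- min(cells$n_templates[ci], nrow(templates_all))
        fit <- fit_with_templates(m_train, labels,
                                  templates_all$template[seq_len(nt)],
                                  templates_all,
                                  derive_seed(seed, paste0("if", f, "r", r, "t", nt)),
                                  ntree)
        pred <- predict_from_masters(fit, m_val)
        truth <- labels[pred$id]
        aucs[ci, f] <- auc_rank(pred$score, truth)
      }
    }
  }
  cells$mean_auc <- rowMeans(aucs)
  best <- cells[order(-cells$mean_auc, cells$radius, cells$n_templates), ][1, ]
  list(radius = best$radius, n_templates = best$n_templates, grid = cells)
}

#' Train a ball-histogram random-forest model
#'
#' Discovers templates on the full training set, builds the attribute space
#' and per-protein feature vectors, and fits a seeded random forest.
#'
#' @inheritParams select_hyperparameters
#' @param radius Sampling-ball radius in Angstroms.
#' @param n_templates Number of templates to discover.
#' @return A `bh_model`: the fitted forest together with the attribute
#'   space, discovered templates and training metadata.
#' @export
bh_train <- function(dataset, radius = 8, n_templates = 3L,
                     n_samples = 10000L, seed = 1L, lambda = 0.5,
                     max_length = 3L, pool = default_pool(table),
                     table = default_property_table(), ntree = 500L,
                     masters = NULL) {
  dataset <- as_bh_dataset(dataset)
  if (nlevels(droplevels(dataset$label)) < 2L) {
    abort("both classes must be present for training", class = "bh_error_config")
  }
  if (is.null(masters)) {
    masters <- compute_masters(dataset, radius, n_samples, seed, pool, table)
  }
  masters_r <- masters[masters$radius == radius & masters$id %in% dataset$id, ]
  labels <- stats::setNames(dataset$label, dataset$id)
  search_cfg <- search_config(pool = pool, max_length = max_length,
                              lambda = lambda, n_templates = n_templates,
                              table = table)
  fit <- fit_core(masters_r, labels, search_cfg, n_templates,
                  derive_seed(seed, "forest"), ntree)
  structure(
    list(forest = fit$forest, space = fit$space, templates = fit$templates,
         templates_tbl = fit$templates_tbl, radius = radius,
         n_templates = n_templates, n_samples = as.integer(n_samples),
         seed = as.integer(seed), pool = pool, table = table,
         lambda = lambda, max_length = max_length, ntree = as.integer(ntree)),
    class = "bh_model"
  )
}

#' @export
print.bh_model <- function(x, ...) {
  cat("Ball-histogram random-forest model\n")
  cat("  radius:", x$radius, "A;", length(x$templates), "templates;",
      nrow(x$space), "attributes;", x$ntree, "trees\n")
  for (t in x$templates) cat("  template: (", paste(t, collapse = ", "), ")\n")
  invisible(x)
}

#' Predict DNA-binding propensity for new structures
#'
#' Builds the model's histograms for each structure (same sampling radius,
#' sample count and seed derivation as in training), vectorizes them against
#' the stored attribute space and returns the forest's binding vote
#' fraction; labels threshold the score at 0.5.
#'
#' @param object A `bh_model`.
#' @param newdata A [protein_structure()] or a [as_bh_dataset()] tibble
#'   (its `label` column, if any, is ignored).
#' @param ... Unused.
#' @return A tibble with columns `id`, `score` and `label`.
#' @export
predict.bh_model <- function(object, newdata, ...) {
  if (inherits(newdata, "protein_structure")) {
    structures <- list(newdata)
    ids <- structure_id(newdata)
  } else {
    structures <- newdata$structure
    ids <- newdata$id
  }
  masters <- tibble(
    id = ids, radius = object$radius,
    master = purrr::map(structures, function(s) {
      master_histogram(s, pool = object$pool, R = object$radius,
                       n_samples = object$n_samples, seed = object$seed,
                       table = object$table)
    })
  )
  predict_from_masters(object, masters)
}

#' Persist and restore trained models
#'
#' The model (forest, attribute space, templates, training metadata) is
#' stored in a single versioned archive file.
#'
#' @param model A `bh_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bh_model"))
  saveRDS(list(format = "ballhist-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("model file not found: ", path), class = "bh_error_parse")
  }
  arch <- readRDS(path)
  if (!identical(arch$format, "ballhist-model")) {
    abort("not a ballhist model archive", class = "bh_error_parse")
  }
  arch$model
}

#' Cross-validated evaluation of the ball-histogram pipeline
#'
#' Stratified k-fold outer cross-validation. Within each fold the
#' sampling-ball radius and number of templates are chosen by internal
#' cross-validation on the training portion only
#' ([select_hyperparameters()]), templates are re-discovered on the training
#' portion, a forest is fitted, and AUC (rank-based) and accuracy (0.5
#' threshold) are measured on the held-out portion. Nothing from a held-out
#' fold influences template discovery, attribute collection or
#' hyperparameter selection for that fold.
#'
#' @inheritParams select_hyperparameters
#' @param k Number of outer folds (default 10).
#' @return A `bh_cv` object: list with `folds` (per-fold metrics and chosen
#'   hyperparameters), `summary` (mean and sd of AUC and accuracy) and
#'   `predictions`.
#' @export
cross_validate <- function(dataset, k = 10L, radii = c(4, 8, 12),
                           n_templates_grid = c(1L, 3L, 5L, 7L),
                           k_internal = 5L, n_samples = 10000L, seed = 1L,
                           lambda = 0.5, max_length = 3L,
                           pool = default_pool(table),
                           table = default_property_table(), ntree = 500L) {
  dataset <- as_bh_dataset(dataset)
  if (k < 2L) abort("k must be >= 2", class = "bh_error_config")
  check_stratification(dataset$label, k)
  masters <- compute_masters(dataset, radii, n_samples, seed, pool, table)
  labels <- stats::setNames(dataset$label, dataset$id)
  fold <- stratified_folds(dataset$label, k, derive_seed(seed, "outer-folds"))
  fold_rows <- list()
  pred_rows <- list()
  for (f in seq_len(k)) {
    train <- dataset[fold != f, ]
    test_ids <- dataset$id[fold == f]
    hp <- select_hyperparameters(
      train, radii = radii, n_templates_grid = n_templates_grid,
      k_internal = k_internal, n_samples = n_samples, seed = seed,
      lambda = lambda, max_length = max_length, pool = pool, table = table,
      ntree = ntree,
      masters = masters[masters$id %in% train$id, ]
    )
    m_train <- masters[masters$radius == hp$radius & masters$id %in% train$id, ]
    m_test <- masters[masters$radius == hp$radius & masters$id %in% test_ids, ]
    search_cfg <- search_config(pool = pool, max_length = max_length,
                                lambda = lambda, n_templates = hp$n_templates,
                                table = table)
    fit <- fit_core(m_train, labels, search_cfg, hp$n_templates,
                    derive_seed(seed, paste0("fold", f)), ntree)
    pred <- predict_from_masters(fit, m_test)
    truth <- labels[pred$id]
    fold_rows[[f]] <- tibble(
      fold = f, auc = auc_rank(pred$score, truth),
      accuracy = mean(as.character(pred$label) == as.character(truth)),
      radius = hp$radius, n_templates = hp$n_templates
    )
    pred_rows[[f]] <- dplyr::mutate(pred, fold = f,
                                    truth = as.character(truth))
  }
  folds <- dplyr::bind_rows(fold_rows)
  out <- list(
    folds = folds,
    summary = tibble(
      metric = c("auc", "accuracy"),
      mean = c(mean(folds$auc), mean(folds$accuracy)),
      sd = c(stats::sd(folds$auc), stats::sd(folds$accuracy))
    ),
    predictions = dplyr::bind_rows(pred_rows),
    k = k, seed = as.integer(seed)
  )
  structure(out, class = "bh_cv")
}

#' @export
print.bh_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("  AUC      %.3f +/- %.3f\n", x$summary$mean[1], x$summary$sd[1]))
  cat(sprintf("  Accuracy %.3f +/- %.3f\n", x$summary$mean[2], x$summary$sd[2]))
  print(x$folds)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param cv A `bh_cv` object.
#' @param path Output path.
#' @param config Optional list echoed into the report.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(cv, path, config = NULL) {
  report <- list(k = cv$k, seed = cv$seed,
                 summary = cv$summary, folds = cv$folds)
  if (!is.null(config)) report$config <- config
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
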