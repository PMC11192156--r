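# Random-forest species classifier: configuration, training on a feature
# table (categorical Site one-hot expanded behind a fixed vocabulary),
# prediction by majority vote, ntree/mtry tuning, and the
# importance-threshold refit. The tree ensemble itself is grown in C++
# (bootstrap bagging, Gini splits, mtry feature subsampling).

#' Random-forest configuration
#'
#' @param ntree Number of trees (default 500).
#' @param mtry Predictors tried per split; default `floor(sqrt(p))` of the
#'   number of logical predictors (Site counts as one), resolved at training
#'   time when `NULL`. With the default 26 predictors this is 5.
#' @param min_node_size Smallest node that may still be split (default 1:
#'   trees are grown to purity).
#' @param seed Integer seed; training is fully reproducible given the seed.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(ntree = 500L, mtry = NULL, min_node_size = 1L,
                          seed = 1L) {
  if (ntree < 1L) stop("`ntree` must be >= 1")
  if (!is.null(mtry) && mtry < 1L) stop("`mtry` must be >= 1")
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Default mtry for p logical predictors
#' @param p Number of predictors.
#' @return `floor(sqrt(p))`, at least 1.
#' @export
default_mtry <- function(p) max(1L, as.integer(floor(sqrt(p))))

# Build the numeric design matrix for a feature table under a schema:
# numeric predictors as-is, Site one-hot against the stored vocabulary.
build_design <- function(table, schema) {
  missing_cols <- setdiff(schema$predictors, names(table))
  if (length(missing_cols) > 0L)
    stop("table is missing predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  num <- setdiff(schema$predictors, "Site")
  X <- as.matrix(as.data.frame(lapply(table[num], as.numeric)))
  if ("Site" %in% schema$predictors) {
    unseen <- setdiff(unique(table$Site), schema$site_levels)
    if (length(unseen) > 0L)
      stop("unseen Site level(s): ", paste(unseen, collapse = ", "),
           "; the model was trained on sites ",
           paste(schema$site_levels, collapse = ", "))
    oh <- vapply(schema$site_levels,
                 function(l) as.numeric(table$Site == l), numeric(nrow(table)))
    if (nrow(table) == 1L) oh <- matrix(oh, nrow = 1L,
                                        dimnames = list(NULL, schema$site_levels))
    colnames(oh) <- paste0("Site=", schema$site_levels)
    X <- cbind(X, oh)
  }
  X
}

#' Train the random-forest species classifier
#'
#' Each tree is grown on a bootstrap sample of the training rows; at every
#' node `mtry` predictors are drawn without replacement and the split with
#' the largest decrease in Gini impurity is taken. Out-of-bag (OOB) votes
#' give the OOB error estimate, and each predictor's importance is its mean
#' decrease in Gini (count-scaled impurity reduction summed over its splits,
#' averaged over trees). Site's one-hot columns are aggregated into a single
#' logical `Site` importance.
#'
#' @param train A `feature_table` with species labels (at least 2 classes).
#' @param config A [forest_config()].
#' @return An object of class `trained_forest` with the ensemble, the
#'   resolved configuration, the predictor schema (names and Site
#'   vocabulary), class labels, per-predictor importance, and `oob_error`.
#' @export
train_forest <- function(train, config = forest_config()) {
  if (!("species" %in% names(train)) || anyNA(train$species))
    stop("training table must have a species label on every row")
  predictors <- ft_predictors(train)
  if (is.null(predictors)) stop("not a feature_table: use assemble_table()")
  class_labels <- sort(unique(as.character(train$species)))
  if (length(class_labels) < 2L)
    stop("training requires at least 2 species; got only: ", class_labels)
  schema <- list(predictors = predictors,
                 site_levels = if ("Site" %in% predictors)
                   sort(unique(as.character(train$Site))) else character(0))
  X <- build_design(train, schema)
  y <- match(as.character(train$species), class_labels) - 1L
  p_logical <- length(predictors)
  mtry <- if (is.null(config$mtry)) default_mtry(p_logical) else config$mtry
  if (mtry > ncol(X)) stop("`mtry` (", mtry, ") exceeds the ", ncol(X),
                           " design columns")
  fit <- .rf_train(X, y, nclass = length(class_labels), ntree = config$ntree,
                   mtry = mtry, min_node = config$min_node_size,
                   seed = config$seed)
  imp <- setNames(as.numeric(fit$importance), colnames(X))
  oob <- fit$oob_votes
  voted <- rowSums(oob) > 0
  oob_pred <- max.col(oob[voted, , drop = FALSE], ties.method = "first")
  oob_error <- if (any(voted)) mean(oob_pred != (y[voted] + 1L)) else NA_real_
  structure(list(trees = fit$trees,
                 config = forest_config(config$ntree, mtry,
                                        config$min_node_size, config$seed),
                 schema = schema, class_labels = class_labels,
                 importance = imp, oob_error = oob_error,
                 n_train = nrow(X), version = 1L),
            class = "trained_forest")
}

#' @export
print.trained_forest <- function(x, ...) {
  cat(sprintf("trained_forest: %d trees, mtry %d, %d classes (%s)\n",
              x$config$ntree, x$config$mtry, length(x$class_labels),
              paste(x$class_labels, collapse = ", ")))
  cat(sprintf("  trained on %d rows; OOB error %.4f\n", x$n_train, x$oob_error))
  invisible(x)
}

#' Predictor importance (mean decrease in Gini)
#'
#' @param model A `trained_forest`.
#' @param aggregate_site Sum the Site one-hot columns into a single `Site`
#'   entry (default `TRUE`, matching the logical-predictor accounting)?
#' @return Named numeric vector, decreasing.
#' @export
forest_importance <- function(model, aggregate_site = TRUE) {
  imp <- model$importance
  if (aggregate_site && length(model$schema$site_levels) > 0L) {
    is_site <- startsWith(names(imp), "Site=")
    imp <- c(imp[!is_site], Site = sum(imp[is_site]))
  }
  sort(imp, decreasing = TRUE)
}

#' Predict species for new particles
#'
#' Each seed is run through every tree; the species predicted by the most
#' trees wins (ties break to the first label in the model's class order).
#'
#' @param model A `trained_forest`.
#' @param table A `feature_table` (or data frame) with the model's predictor
#'   columns. Unseen Site levels are an error, not a silent recode.
#' @return `data.frame` with a `species` column and one `vote_<class>`
#'   fraction column per class (fractions sum to 1 per row).
#' @export
predict_species <- function(model, table) {
  K <- length(model$class_labels)
  if (nrow(table) == 0L) {
    out <- data.frame(species = character(0))
    for (l in model$class_labels) out[[paste0("vote_", l)]] <- numeric(0)
    return(out)
  }
  X <- build_design(table, model$schema)
  votes <- .rf_votes(model$trees, X, K)
  frac <- votes / rowSums(votes)
  lab <- model$class_labels[max.col(votes, ties.method = "first")]
  out <- data.frame(species = lab, stringsAsFactors = FALSE)
  for (k in seq_len(K)) out[[paste0("vote_", model$class_labels[k])]] <- frac[, k]
  out
}

#' Tune ntree and mtry by OOB error
#'
#' Trains one forest per grid point on the same table with the same seed and
#' ranks them by OOB error; ties prefer the smaller `ntree`, then the
#' smaller `mtry`.
#'
#' @param table Labeled `feature_table`.
#' @param ntree_grid,mtry_grid Non-empty integer vectors.
#' @param seed Seed shared by every grid point.
#' @return List with `grid` (a `data.frame` of `ntree`, `mtry`, `oob_error`)
#'   and `best` (the winning [forest_config()]).
#' @export
tune_forest <- function(table, ntree_grid = c(100L, 250L, 500L),
                        mtry_grid = c(3L, 5L, 8L), seed = 1L) {
  if (length(ntree_grid) == 0L || length(mtry_grid) == 0L)
    stop("tuning grids must be non-empty")
  grid <- expand.grid(ntree = as.integer(ntree_grid),
                      mtry = as.integer(mtry_grid))
  grid$oob_error <- vapply(seq_len(nrow(grid)), function(i) {
    train_forest(table, forest_config(grid$ntree[i], grid$mtry[i],
                                      seed = seed))$oob_error
  }, 0)
  ord <- order(grid$oob_error, grid$ntree, grid$mtry)
  best <- grid[ord[1], ]
  list(grid = grid,
       best = forest_config(best$ntree, best$mtry, seed = seed))
}

#' Refit on high-importance predictors only
#'
#' Retains the logical predictors whose mean decrease in Gini exceeds
#' `threshold`, retrains with the same configuration and seed on the same
#' training rows, and reports the new test accuracy. Note the threshold is
#' on count-scaled Gini units, which grow with training-set size; prefer
#' `quantile` to name a fraction of predictors instead.
#'
#' @param train,test Labeled `feature_table`s (the original split).
#' @param model The unfiltered `trained_forest` fitted on `train`.
#' @param threshold Keep predictors with importance strictly above this
#'   value (ignored when `quantile` is given).
#' @param quantile If non-`NULL`, keep predictors at or above this
#'   importance quantile (e.g. 0.5 keeps the top half).
#' @return List with `retained` (predictor names), `model` (the refit
#'   forest), `accuracy` (refit test accuracy) and `baseline_accuracy`.
#' @export
importance_filter_refit <- function(train, test, model, threshold = 0,
                                    quantile = NULL) {
  if (threshold < 0) stop("`threshold` must be >= 0")
  imp <- forest_importance(model)
  if (!is.null(quantile)) threshold <- stats::quantile(imp, quantile)[[1]] - 1e-12
  retained <- names(imp)[imp > threshold]
  if (length(retained) == 0L)
    stop("no predictor has importance above ", format(threshold),
         "; lower the threshold (max importance is ", format(max(imp)), ")")
  retained <- intersect(ft_predictors(train), retained)  # stable order
  sub <- function(ft) structure(ft, predictors = retained,
                                class = c("feature_table", "data.frame"))
  refit <- train_forest(sub(train), model$config)
  base_pred <- predict_species(model, test)$species
  refit_pred <- predict_species(refit, sub(test))$species
  list(retained = retained, model = refit,
       accuracy = mean(refit_pred == test$species),
       baseline_accuracy = mean(base_pred == test$species))
}

#' Save / load a trained forest
#'
#' The model is serialized to a single versioned JSON archive (schema,
#' configuration, class labels, importance, trees), portable across
#' platforms.
#'
#' @param model A `trained_forest`.
#' @param path File path (conventionally `.json`).
#' @return `save_forest` returns `path` invisibly; `load_forest` the model.
#' @export
save_forest <- function(model, path) {
  payload <- unclass(model)
  payload$config <- unclass(payload$config)
  payload$importance <- as.list(payload$importance)  # keep names in JSON
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(m$version) || m$version != 1L)
    stop("unsupported model archive version: ", m$version)
  m$trees <- lapply(m$trees, function(t) list(
    feature = as.integer(t$feature), thresh = as.numeric(t$thresh),
    left = as.integer(t$left), right = as.integer(t$right),
    pred = as.integer(t$pred)))
  m$schema$predictors <- as.character(m$schema$predictors)
  m$schema$site_levels <- as.character(unlist(m$schema$site_levels))
  m$class_labels <- as.character(m$class_labels)
  m$importance <- unlist(m$importance)
  m$config <- forest_config(m$config$ntree, m$config$mtry,
                            m$config$min_node_size, m$config$seed)
  structure(m, class = "trained_forest")
}
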