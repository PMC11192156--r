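# Feature assembly: join measurements with tag metadata into the table the
# classifier consumes, and split it into training and test sets.

#' Assemble the classifier feature table
#'
#' Joins per-particle measurements with the collection metadata parsed from
#' their tags: drops `Skew`/`Kurt` (frequently missing on binary scans),
#' adds the categorical `Site` predictor, and drops (with a warning) any row
#' still missing a predictor value.
#'
#' @param records `data.frame` of [measure_particle()] rows (must have a
#'   `tag` column).
#' @param metadata Optional `data.frame` from [parse_tags()]; by default the
#'   tags in `records` are parsed directly.
#' @param tag_mode Tag grammar mode passed to [parse_tag()].
#' @param include_positional Keep the positional predictors (X, Y, XM, YM,
#'   BX, BY, FeretX, FeretY)? Default `TRUE`, using all available traits; set
#'   `FALSE` for a position-free variant model.
#' @return A `feature_table`: a `data.frame` with the predictor columns, a
#'   `species` column (`NA` where the tag carries no species), and the
#'   bookkeeping columns `tag`, `trap_id`, `replicate_index`, `fill_status`,
#'   `batch_id` (never used for prediction). The predictor names are stored
#'   in `attr(, "predictors")`.
#' @export
assemble_table <- function(records, metadata = NULL,
                           tag_mode = c("strict", "site_only"),
                           include_positional = TRUE) {
  tag_mode <- match.arg(tag_mode)
  if (nrow(records) == 0L) stop("no measurement records to assemble")
  if (is.null(metadata)) metadata <- parse_tags(unique(records$tag), mode = tag_mode)
  miss <- setdiff(unique(records$tag), metadata$source_tag)
  if (length(miss) > 0L)
    stop("no metadata for tag(s): ", paste(miss, collapse = ", "))
  m <- metadata[match(records$tag, metadata$source_tag), ]
  predictors <- if (include_positional) PREDICTORS_DEFAULT
                else setdiff(PREDICTORS_DEFAULT, POSITIONAL_PREDICTORS)
  out <- records[, setdiff(predictors, "Site"), drop = FALSE]
  out$Site <- m$site
  out$species <- m$species_label
  out$tag <- records$tag
  out$trap_id <- m$trap_id
  out$replicate_index <- m$replicate_index
  out$fill_status <- m$fill_status
  out$batch_id <- m$batch_id
  if ("label_id" %in% names(records)) out$label_id <- records$label_id
  complete <- stats::complete.cases(out[, predictors, drop = FALSE])
  if (!all(complete)) {
    warning(sum(!complete), " row(s) dropped for missing predictor values")
    out <- out[complete, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("all rows dropped: no complete predictor vectors")
  rownames(out) <- NULL
  structure(out, predictors = predictors, class = c("feature_table", "data.frame"))
}

#' Coerce a plain data frame to a feature table
#'
#' @param df A `data.frame` containing the predictor columns (and optionally
#'   `species` and bookkeeping columns).
#' @param predictors Character vector of predictor column names.
#' @return A `feature_table`.
#' @export
as_feature_table <- function(df, predictors = PREDICTORS_DEFAULT) {
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols) > 0L)
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  structure(as.data.frame(df), predictors = predictors,
            class = c("feature_table", "data.frame"))
}

ft_predictors <- function(ft) attr(ft, "predictors", exact = TRUE)

# subsetting keeps the class and predictor attribute
#' @export
`[.feature_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out))
    out <- structure(out, predictors = ft_predictors(x),
                     class = c("feature_table", "data.frame"))
  out
}

#' Stratified train/test split
#'
#' For each species, `round(train_fraction * n)` rows (half-up, clamped so
#' both sides stay non-empty) are allocated to the training set and the rest
#' to the test set. With `group_by_batch = TRUE`, whole batches (the two
#' replicate scans of the same physical seeds) are kept on one side, which
#' avoids leakage between replicates at the cost of only approximate
#' stratification.
#'
#' @param table A `feature_table` with species labels.
#' @param train_fraction Proportion of rows used for training (default 0.8).
#' @param seed Integer seed; the same seed always reproduces the same split.
#' @param group_by_batch Keep replicate scans of one batch together?
#' @return List with elements `train` and `test` (both `feature_table`s).
#' @export
split_train_test <- function(table, train_fraction = 0.8, seed = 1L,
                             group_by_batch = FALSE) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must be strictly between 0 and 1")
  if (!("species" %in% names(table)) || anyNA(table$species))
    stop("the table must carry species labels for every row")
  counts <- table(table$species)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L)
    stop("species with fewer than 2 rows cannot be split: ",
         paste(small, collapse = ", "))
  train_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(table$species)), function(sp) {
      rows <- which(table$species == sp)
      n <- length(rows)
      if (group_by_batch) {
        batches <- split(rows, table$batch_id[rows])
        ord <- sample(length(batches))
        target <- floor(train_fraction * n + 0.5)
        got <- 0L; chosen <- integer(0)
        for (b in ord) {
          if (got >= target) break
          chosen <- c(chosen, batches[[b]])
          got <- got + length(batches[[b]])
        }
        if (length(chosen) == n)  # keep at least one batch for testing
          chosen <- setdiff(chosen, batches[[ord[length(ord)]]])
        if (length(chosen) == 0L) chosen <- batches[[ord[1]]]
        chosen
      } else {
        k <- floor(train_fraction * n + 0.5)
        k <- min(max(k, 1L), n - 1L)
        rows[sample(n, k)]
      }
    }))
  })
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}
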