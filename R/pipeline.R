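#' Coefficient of determination and RMSE helpers
#'
#' `r_squared()` defaults to the squared Pearson correlation between observed
#' and predicted values (the convention of RRegrs-style pipelines); `mode =
#' "ssr"` instead returns 1 - SSE/SST. `rmse()` is the root-mean-square
#' error.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param mode `"corr"` (default) or `"ssr"`.
#' @return A single number.
#' @export
r_squared <- function(observed, predicted, mode = c("corr", "ssr")) {
  mode <- match.arg(mode)
  stopifnot(length(observed) == length(predicted))
  if (mode == "corr") {
    if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) return(0)
    stats::cor(observed, predicted)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' @rdname r_squared
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((observed - predicted)^2))
}

#' Normalize the feature columns of a feature table
#'
#' Centers and scales every feature column (z-score) over the whole dataset;
#' the target column is left untouched. Zero-variance columns are dropped
#' with a warning. The returned scaler can be replayed on new data with
#' [apply_scaler()] (stored parameters, no refit).
#'
#' @param table feature table (numeric columns only).
#' @param target name of the target column to exclude from scaling (default
#'   `"flux"`; use `NULL` if there is none).
#' @return List with `table` (normalized), `center`, `scale` (named numeric)
#'   and `dropped` (names of removed zero-variance columns).
#' @export
normalize_features <- function(table, target = "flux") {
  feats <- setdiff(names(table), target)
  x <- table[feats]
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  sds <- vapply(x, stats::sd, numeric(1))
  dropped <- names(sds)[sds == 0]
  if (length(dropped) == length(feats)) stop("all feature columns have zero variance")
  if (length(dropped) > 0L) {
    warning("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
    x <- x[setdiff(feats, dropped)]
  }
  center <- vapply(x, mean, numeric(1))
  scale <- vapply(x, stats::sd, numeric(1))
  scaled <- as.data.frame(mapply(function(col, m, s) (col - m) / s, x, center, scale,
                                 SIMPLIFY = FALSE))
  if (!is.null(target) && target %in% names(table)) scaled[[target]] <- table[[target]]
  list(table = scaled, center = center, scale = scale, dropped = dropped)
}

#' @rdname normalize_features
#' @param scaler list returned by [normalize_features()].
#' @param newdata data.frame holding at least the scaler's columns.
#' @export
apply_scaler <- function(scaler, newdata) {
  cols <- names(scaler$center)
  missing <- setdiff(cols, names(newdata))
  if (length(missing) > 0L) stop("newdata lacks column(s): ", paste(missing, collapse = ", "))
  out <- newdata
  for (nm in cols) out[[nm]] <- (newdata[[nm]] - scaler$center[[nm]]) / scaler$scale[[nm]]
  out
}

#' Remove highly correlated feature columns
#'
#' Iterative pairwise Pearson filter in the style of caret's
#' `findCorrelation` (the behaviour RRegrs inherits): while any absolute
#' pairwise correlation reaches the cutoff, the member of the worst pair with
#' the larger mean absolute correlation to all other features is removed. The
#' target column is never removed.
#'
#' @param table feature table.
#' @param cutoff absolute-correlation cutoff in (0, 1]; default 0.9.
#' @param target target column name, exempt from filtering (default `"flux"`).
#' @return List with `table` (reduced) and `removed` (column names).
#' @export
remove_correlated <- function(table, cutoff = 0.9, target = "flux") {
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  feats <- setdiff(names(table), target)
  if (length(feats) < 2L) stop("need at least two feature columns")
  cm <- stats::cor(table[feats])
  removed <- caret::findCorrelation(cm, cutoff = cutoff, names = TRUE, exact = TRUE)
  list(table = table[setdiff(names(table), removed)], removed = removed)
}

#' Random train/test splits
#'
#' Draws `n_splits` independent random partitions of `1:n_cases` into a
#' training part of size `round(train_fraction * n_cases)` and its test
#' complement; deterministic under a fixed seed.
#'
#' @param n_cases number of cases (>= 4).
#' @param n_splits number of splits (default 10).
#' @param train_fraction training fraction (default 0.75).
#' @param seed integer seed.
#' @return List of `n_splits` lists with integer vectors `train` and `test`.
#' @export
make_splits <- function(n_cases, n_splits = 10L, train_fraction = 0.75, seed = 1L) {
  stopifnot(n_cases >= 4L)
  if (n_splits < 1L) stop("n_splits must be >= 1")
  if (!(train_fraction > 0 && train_fraction < 1)) stop("train_fraction must be in (0, 1)")
  n_train <- round(train_fraction * n_cases)
  set.seed(seed)
  lapply(seq_len(n_splits), function(s) {
    train <- sort(sample.int(n_cases, n_train))
    list(train = train, test = setdiff(seq_len(n_cases), train))
  })
}

#' Default hyperparameter grids
#'
#' The neural-network grid covers hidden-layer sizes 200/300/400 plus the
#' additionally screened 1/5/10/15, with weight decays 0, 0.001, 0.005, 0.01,
#' 0.1 and 0.2; the random-forest grid covers 1500 trees plus the
#' additionally screened 5..500.
#'
#' @return List with data.frames `NN` (`size`, `decay`) and `RF` (`ntree`).
#' @export
default_grids <- function() {
  list(
    NN = expand.grid(size = c(1, 5, 10, 15, 200, 300, 400),
                     decay = c(0, 0.001, 0.005, 0.01, 0.1, 0.2)),
    RF = data.frame(ntree = c(5, 10, 20, 30, 40, 50, 100, 500, 1500))
  )
}

.fit_one <- function(method, x_tr, y_tr, params, nn_maxit, seed) {
  set.seed(seed)
  switch(method,
    LM = {
      d <- cbind(x_tr, .y = y_tr)
      stats::lm(.y ~ ., data = d)
    },
    NN = nnet::nnet(as.matrix(x_tr), y_tr, size = params$size, decay = params$decay,
                    linout = TRUE, trace = FALSE, maxit = nn_maxit,
                    MaxNWts = 10L * (params$size * (ncol(x_tr) + 2L) + 1L) + 100L),
    RF = randomForest::randomForest(x_tr, y_tr, ntree = params$ntree,
                                    mtry = max(1L, floor(ncol(x_tr) / 3))),
    stop("unknown method '", method, "' (expected LM, NN or RF)")
  )
}

.predict_one <- function(method, model, x) {
  if (method == "LM") {
    as.numeric(stats::predict(model, newdata = x))
  } else {
    as.numeric(stats::predict(model, as.matrix(x)))
  }
}

# Repeated k-fold CV mean RMSE over a grid; returns index of the best row.
.cv_tune <- function(method, x, y, grid, folds, repeats, nn_maxit, seed) {
  if (nrow(grid) == 1L) return(1L)
  set.seed(seed)
  n <- nrow(x)
  score <- numeric(nrow(grid))
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      tr <- fold != f
      for (g in seq_len(nrow(grid))) {
        fit <- .fit_one(method, x[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE],
                        nn_maxit, seed + 1000L * r + f)
        pred <- .predict_one(method, fit, x[!tr, , drop = FALSE])
        score[g] <- score[g] + rmse(y[!tr], pred)
      }
    }
  }
  which.min(score)
}

#' Fit regression models over random splits
#'
#' For each split and method, hyperparameters are chosen by repeated k-fold
#' cross-validation on the training part (skipped when the grid has a single
#' row), the model is refit on the full training part, and R-squared and RMSE
#' are computed on both parts. Methods: `"LM"` ordinary least squares, `"NN"`
#' single-hidden-layer network (logistic hidden units, linear output, L2
#' weight decay, fixed iteration cap — no early stopping), `"RF"` random
#' forest with `mtry = floor(p/3)`.
#'
#' @param table normalized, filtered feature table including the target.
#' @param splits list from [make_splits()].
#' @param methods subset of `c("LM", "NN", "RF")`.
#' @param target target column name (default `"flux"`).
#' @param grids named list of hyperparameter grids (see [default_grids()]).
#' @param cv_folds,cv_repeats cross-validation folds (default 10) and repeats
#'   (default 1).
#' @param nn_maxit iteration cap for the network optimizer (default 500).
#' @param rsq R-squared convention passed to [r_squared()].
#' @param seed integer seed; every (method, split) fit derives its own
#'   sub-seed from it.
#' @return data.frame with one row per (method, split): hyperparameters and
#'   `R2_tr`, `RMSE_tr`, `R2_ts`, `RMSE_ts`; the fitted models are attached
#'   as attribute `"models"` (named `"<method>.<split>"`).
#' @export
fit_models <- function(table, splits, methods = c("LM", "NN", "RF"),
                       target = "flux", grids = default_grids(),
                       cv_folds = 10L, cv_repeats = 1L, nn_maxit = 500L,
                       rsq = c("corr", "ssr"), seed = 1L) {
  rsq <- match.arg(rsq)
  bad <- setdiff(methods, c("LM", "NN", "RF"))
  if (length(bad) > 0L) stop("unknown method(s): ", paste(bad, collapse = ", "))
  stopifnot(target %in% names(table))
  x <- table[setdiff(names(table), target)]
  y <- table[[target]]
  rows <- list()
  models <- list()
  for (method in methods) {
    grid <- if (method == "LM") data.frame(.dummy = 0) else grids[[method]]
    if (is.null(grid)) stop("no grid supplied for method ", method)
    for (s in seq_along(splits)) {
      idx_tr <- splits[[s]]$train
      idx_ts <- splits[[s]]$test
      sub_seed <- seed + 7919L * match(method, c("LM", "NN", "RF")) + s
      best <- .cv_tune(method, x[idx_tr, , drop = FALSE], y[idx_tr], grid,
                       cv_folds, cv_repeats, nn_maxit, sub_seed)
      params <- grid[best, , drop = FALSE]
      fit <- .fit_one(method, x[idx_tr, , drop = FALSE], y[idx_tr], params,
                      nn_maxit, sub_seed)
      pred_tr <- .predict_one(method, fit, x[idx_tr, , drop = FALSE])
      pred_ts <- .predict_one(method, fit, x[idx_ts, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, split = s,
        size = if (method == "NN") params$size else NA_real_,
        decay = if (method == "NN") params$decay else NA_real_,
        ntree = if (method == "RF") params$ntree else NA_real_,
        R2_tr = r_squared(y[idx_tr], pred_tr, rsq),
        RMSE_tr = rmse(y[idx_tr], pred_tr),
        R2_ts = r_squared(y[idx_ts], pred_ts, rsq),
        RMSE_ts = rmse(y[idx_ts], pred_ts),
        seed = sub_seed
      )
      models[[paste0(method, ".", s)]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

#' Summary statistics per regression method
#'
#' Aggregates per-split results into the mean, minimum and maximum of
#' R-squared and RMSE on the training and test parts, per method — the shape
#' of the study's headline statistics table.
#'
#' @param results data.frame from [fit_models()].
#' @return data.frame with columns `method`, `statistic` (Mean/Min/Max) and
#'   the four metrics.
#' @export
aggregate_statistics <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("empty results")
  metrics <- c("R2_tr", "RMSE_tr", "R2_ts", "RMSE_ts")
  out <- do.call(rbind, lapply(split(results, results$method), function(d) {
    vals <- rbind(Mean = colMeans(d[metrics]),
                  Min = vapply(d[metrics], min, numeric(1)),
                  Max = vapply(d[metrics], max, numeric(1)))
    cbind(data.frame(method = d$method[1L], statistic = rownames(vals)),
          as.data.frame(vals))
  }))
  rownames(out) <- NULL
  out[order(match(out$method, c("LM", "NN", "RF"))), ]
}

#' Select the best model across methods and splits
#'
#' Primary criterion: maximum test R-squared; ties broken by minimum test
#' RMSE. For random forests, among tree counts whose test RMSE is within 1%
#' of the best RF test RMSE, the fewest trees wins (parsimony rule).
#'
#' @param results data.frame from [fit_models()].
#' @param models optional model list (defaults to `attr(results, "models")`).
#' @param rf_rmse_tolerance relative RMSE tolerance of the parsimony rule
#'   (default 0.01).
#' @return List with `result` (the chosen row) and `model` (the fitted object,
#'   `NULL` when no model list is available).
#' @export
select_best_model <- function(results, models = attr(results, "models"),
                              rf_rmse_tolerance = 0.01) {
  if (is.null(results) || nrow(results) == 0L) stop("empty results")
  best_i <- order(-results$R2_ts, results$RMSE_ts)[1L]
  if (identical(results$method[best_i], "RF")) {
    rf <- results[results$method == "RF", , drop = FALSE]
    ok <- rf[rf$RMSE_ts <= min(rf$RMSE_ts) * (1 + rf_rmse_tolerance), , drop = FALSE]
    pick <- ok[order(ok$ntree, -ok$R2_ts, ok$RMSE_ts)[1L], , drop = FALSE]
    best_i <- which(results$method == "RF" & results$split == pick$split &
                      results$ntree == pick$ntree)[1L]
  }
  row <- results[best_i, , drop = FALSE]
  key <- paste0(row$method, ".", row$split)
  list(result = row, model = if (!is.null(models)) models[[key]] else NULL)
}

#' Persist a selected model with a JSON sidecar
#'
#' Writes the fitted model as an RDS file and a human-readable JSON sidecar
#' holding its method, hyperparameters, statistics and seed.
#'
#' @param selection list from [select_best_model()].
#' @param path output path for the model (`.rds`); the sidecar gets the same
#'   path with extension `.json`.
#' @return Invisibly, the sidecar path.
#' @export
save_model <- function(selection, path) {
  saveRDS(selection$model, path)
  sidecar <- sub("\\.rds$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(as.list(selection$result), sidecar,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(sidecar)
}

#' Regression ROC curve
#'
#' For each shift s (a constant added to the predictions — the regression
#' analogue of a classification threshold), the curve point is the total
#' over-estimation `OVER(s) = sum(max(e_i, 0))` against the total
#' under-estimation `UNDER(s) = sum(min(e_i, 0))` of the shifted residuals
#' `e_i = (pred_i + s) - obs_i`. The default shift grid spans plus/minus the
#' residual range in 201 steps.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param shifts optional numeric vector of shifts.
#' @return Object of class `rroc_curve`: data.frame with columns `shift`,
#'   `over` (>= 0, non-decreasing) and `under` (<= 0, non-decreasing).
#' @examples
#' rroc_curve(c(1, 2), c(2, 0), shifts = c(-1, 0, 2))
#' @export
rroc_curve <- function(observed, predicted, shifts = NULL) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1L) stop("need at least one observation")
  resid <- predicted - observed
  if (is.null(shifts)) {
    r <- diff(range(resid))
    shifts <- if (r == 0) 0 else seq(-r, r, length.out = 201L)
  }
  shifts <- sort(shifts)
  pts <- vapply(shifts, function(s) {
    e <- resid + s
    c(over = sum(pmax(e, 0)), under = sum(pmin(e, 0)))
  }, numeric(2))
  structure(data.frame(shift = shifts, over = pts["over", ], under = pts["under", ]),
            class = c("rroc_curve", "data.frame"))
}

#' @export
plot.rroc_curve <- function(x, ...) {
  graphics::plot(x$over, x$under, type = "l", xlab = "OVER", ylab = "UNDER",
                 main = "Regression ROC", ...)
  zero <- which.min(abs(x$shift))
  graphics::points(x$over[zero], x$under[zero], pch = 19)
  invisible(x)
}
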