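#' Control parameters for the stacked ensemble
#'
#' Hyperparameter search spaces and budgets. Defaults follow common practice
#' for the three base learners; every budget scales down for small runs.
#'
#' @param n_iter Random-search iterations per learner.
#' @param inner_k Inner CV folds for hyperparameter evaluation.
#' @param n_perm Permutations per predictor for permutation importance.
#' @param num_trees Random-forest trees (fixed, not searched).
#' @param min_node_size Candidate minimum node sizes for the forest.
#' @param gbt_rounds Range of boosting rounds.
#' @param gbt_depth Range of tree depths.
#' @param gbt_lr_log10 log10 range of the boosting learning rate.
#' @param gbt_subsample Range of the boosting row subsample fraction.
#' @param svr_cost_log10 log10 range of the SVR cost.
#' @param svr_gamma_log10 log10 range of the RBF gamma.
#' @param svr_eps_frac Range of SVR epsilon as a fraction of the target SD.
#' @return An `ensemble_control` list.
#' @export
ensemble_control <- function(n_iter = 30, inner_k = 5, n_perm = 5,
                             num_trees = 500, min_node_size = c(1, 5, 10),
                             gbt_rounds = c(100, 2000), gbt_depth = c(1, 6),
                             gbt_lr_log10 = c(-3, -0.5),
                             gbt_subsample = c(0.5, 1),
                             svr_cost_log10 = c(-1, 3),
                             svr_gamma_log10 = c(-4, 0),
                             svr_eps_frac = c(0.01, 1)) {
  stopifnot(n_iter >= 1, inner_k >= 2, n_perm >= 1)
  structure(as.list(environment()), class = "ensemble_control")
}

.learners <- c("rf", "gbt", "svr")

sample_hp <- function(learner, n_iter, p, sdy, control) {
  lapply(seq_len(n_iter), function(i) {
    switch(learner,
      rf = list(mtry = sample(seq(max(1, ceiling(p / 5)), p), 1),
                min_node_size = sample(control$min_node_size, 1),
                num_trees = control$num_trees),
      gbt = list(nrounds = sample(seq(control$gbt_rounds[1],
                                      control$gbt_rounds[2]), 1),
                 max_depth = sample(seq(control$gbt_depth[1],
                                        control$gbt_depth[2]), 1),
                 eta = 10^runif(1, control$gbt_lr_log10[1],
                                control$gbt_lr_log10[2]),
                 subsample = runif(1, control$gbt_subsample[1],
                                   control$gbt_subsample[2])),
      svr = list(cost = 10^runif(1, control$svr_cost_log10[1],
                                 control$svr_cost_log10[2]),
                 gamma = 10^runif(1, control$svr_gamma_log10[1],
                                  control$svr_gamma_log10[2]),
                 # log-uniform over the epsilon-fraction range: small tubes
                 # are as likely as wide ones
                 epsilon = max(10^runif(1, log10(control$svr_eps_frac[1]),
                                        log10(control$svr_eps_frac[2])) * sdy,
                               1e-6))
    )
  })
}

fit_base_learner <- function(learner, X, y, hp, seed) {
  if (var(y) == 0) {
    return(structure(list(mean = y[1]), class = "mean_learner"))
  }
  switch(learner,
    rf = ranger::ranger(y = y, x = as.data.frame(X),
                        num.trees = hp$num_trees,
                        mtry = min(hp$mtry, ncol(X)),
                        min.node.size = hp$min_node_size,
                        seed = seed, num.threads = 1,
                        verbose = FALSE),
    gbt = {
      set.seed(seed)
      xgboost::xgb.train(
        params = xgboost::xgb.params(max_depth = hp$max_depth,
                                     learning_rate = hp$eta,
                                     subsample = hp$subsample, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = hp$nrounds, verbose = 0)
    },
    svr = {
      ctr <- colMeans(X)
      scl <- apply(X, 2, sd); scl[scl == 0] <- 1
      Xs <- scale(X, ctr, scl)
      m <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                      kernel = "radial", cost = hp$cost, gamma = hp$gamma,
                      epsilon = hp$epsilon, scale = FALSE)
      structure(list(svm = m, center = ctr, scale = scl), class = "scaled_svr")
    }
  )
}

predict_base_learner <- function(model, X) {
  if (inherits(model, "mean_learner")) return(rep(model$mean, nrow(X)))
  if (inherits(model, "ranger")) {
    return(predict(model, data = as.data.frame(X),
                   num.threads = 1, verbose = FALSE)$predictions)
  }
  if (inherits(model, "scaled_svr")) {
    return(as.numeric(predict(model$svm, scale(X, model$center, model$scale))))
  }
  predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Mean absolute error and root-mean-square error
#'
#' @param predicted,observed Aligned numeric vectors.
#' @return Named vector `c(mae, rmse)`.
#' @export
prediction_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("prediction_metrics: length mismatch", call. = FALSE)
  }
  r <- predicted - observed
  c(mae = mean(abs(r)), rmse = sqrt(mean(r^2)))
}

# balanced block partition used for inner folds; falls back to plain random
# row folds when the training subset holds fewer blocks than k
partition_blocks <- function(block, k, seed) {
  ub <- sort(unique(block))
  set.seed(seed)
  if (length(ub) < k) {
    return(sample(rep_len(seq_len(k), length(block))))
  }
  sizes <- table(block)[ub]
  ord <- sample.int(length(ub))
  fold_of_block <- integer(length(ub))
  load <- numeric(k)
  for (b in ord) {
    f <- which.min(load)
    fold_of_block[b] <- f
    load[f] <- load[f] + sizes[b]
  }
  fold_of_block[match(block, ub)]
}

#' Random hyperparameter search for one base learner
#'
#' Draws `n_iter` configurations from the learner's space and returns the one
#' minimising mean inner-fold RMSE; ties are broken by draw order.
#'
#' @param learner `"rf"`, `"gbt"` or `"svr"`.
#' @param X Encoded feature matrix (training rows).
#' @param y Target.
#' @param inner_fold Inner-fold id per row.
#' @param control An [ensemble_control()].
#' @param seed RNG seed (governs both the draws and the fits).
#' @return List `hp` (chosen configuration) and `rmse` (its mean inner RMSE).
#' @export
random_search <- function(learner, X, y, inner_fold, control, seed) {
  set.seed(seed)
  configs <- sample_hp(learner, control$n_iter, ncol(X), sd(y), control)
  fit_seeds <- sample.int(.Machine$integer.max - 1, control$n_iter)
  scores <- vapply(seq_along(configs), function(i) {
    errs <- vapply(sort(unique(inner_fold)), function(f) {
      tr <- inner_fold != f
      if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
      m <- fit_base_learner(learner, X[tr, , drop = FALSE], y[tr],
                            configs[[i]], fit_seeds[i])
      prediction_metrics(predict_base_learner(m, X[!tr, , drop = FALSE]),
                         y[!tr])[["rmse"]]
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  list(hp = configs[[which.min(scores)]], rmse = min(scores))
}

#' Fit the stacked ensemble under repeated nested spatial cross-validation
#'
#' The engine of the reciprocal-modelling pipeline: a simple-mean stack of a
#' random forest, gradient-boosted regression trees and RBF support-vector
#' regression. For every repeat of the spatially blocked outer 5-fold plan,
#' each outer training set is split into inner folds (again by block) on which
#' a random search tunes each learner; the tuned learners are refit on the
#' full outer training set and predict the held-out fold, so out-of-fold
#' predictions cover every site exactly once per repeat. MAE/RMSE are computed
#' per repeat on the out-of-fold predictions, and permutation importance is
#' measured out-of-fold as the mean RMSE increase when a predictor's column is
#' shuffled.
#'
#' Categorical predictors are one-hot encoded against training-fold levels
#' (unseen levels at prediction encode to zero), missing numerics take the
#' training-fold median, and SVR inputs are standardised with training-fold
#' statistics. The whole fit is reproducible given `(data, seed)`.
#'
#' @param data Model frame with the predictor columns and the target.
#' @param spec A [predictor_spec()].
#' @param plan A [assign_spatial_folds()] plan over the rows of `data`.
#' @param target Name of the target column.
#' @param control An [ensemble_control()].
#' @param seed Master RNG seed.
#' @return A `soc_ensemble` object with `oof` (n x repeats out-of-fold
#'   predictions), `metrics` (per-repeat MAE/RMSE), `importance` (raw and
#'   max-normalised permutation importance) and the fitted per-fold learners.
#' @export
soc_ensemble <- function(data, spec, plan, target = "target",
                         control = ensemble_control(), seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"), nrow(data) == nrow(plan$folds))
  # canonical internal row order: resampling learners (bootstrap, subsample,
  # row permutation) draw by row index, so a stable order makes the whole fit
  # invariant to how the caller happened to sort the table
  ord <- if ("site_id" %in% names(data)) order(data$site_id) else
    seq_len(nrow(data))
  data <- data[ord, , drop = FALSE]
  plan <- within_plan_reorder(plan, ord)
  inv_ord <- order(ord)
  y_all <- as.numeric(data[[target]])
  if (anyNA(y_all)) stop("soc_ensemble: target has missing values", call. = FALSE)
  if (var(y_all) == 0) {
    warning("soc_ensemble: constant target; model degenerates to the mean",
            call. = FALSE)
  }
  set.seed(seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max - 1,
                                plan$repeats * plan$k * 4),
                     nrow = plan$repeats * plan$k)
  models <- vector("list", plan$repeats)
  oof <- matrix(NA_real_, nrow(data), plan$repeats)
  metr <- matrix(NA_real_, plan$repeats, 2,
                 dimnames = list(NULL, c("mae", "rmse")))
  preds <- c(spec$numeric, spec$categorical)
  imp_acc <- setNames(numeric(length(preds)), preds)
  imp_n <- 0
  for (r in seq_len(plan$repeats)) {
    models[[r]] <- vector("list", plan$k)
    for (f in seq_len(plan$k)) {
      srow <- (r - 1) * plan$k + f
      te <- plan$folds[, r] == f
      tr <- !te
      if (!any(te)) { models[[r]][[f]] <- NULL; next }
      dtr <- data[tr, , drop = FALSE]
      enc <- make_encoder(dtr, spec)
      Xtr <- encode_features(dtr, enc)
      ytr <- y_all[tr]
      inner <- partition_blocks(plan$block[tr], control$inner_k, seed_mat[srow, 1])
      fitted <- list()
      for (li in seq_along(.learners)) {
        L <- .learners[li]
        hp <- if (var(ytr) == 0) list() else
          random_search(L, Xtr, ytr, inner, control,
                        seed_mat[srow, 1 + li])$hp
        fitted[[L]] <- list(
          model = fit_base_learner(L, Xtr, ytr, hp, seed_mat[srow, 1 + li]),
          hp = hp)
      }
      Xte <- encode_features(data[te, , drop = FALSE], enc)
      base_pred <- vapply(.learners, function(L)
        predict_base_learner(fitted[[L]]$model, Xte), numeric(sum(te)))
      oof[te, r] <- rowMeans(base_pred)
      models[[r]][[f]] <- list(enc = enc, learners = fitted)
      # out-of-fold permutation importance on this fold's test rows
      set.seed(seed_mat[srow, 4])
      base_rmse <- prediction_metrics(oof[te, r], y_all[te])[["rmse"]]
      nte <- sum(te)
      if (nte >= 2) {
        dte <- data[te, , drop = FALSE]
        for (p in preds) {
          dd <- 0
          for (b in seq_len(control$n_perm)) {
            dp <- dte
            dp[[p]] <- dp[[p]][sample.int(nte)]
            Xp <- encode_features(dp, enc)
            pp <- rowMeans(vapply(.learners, function(L)
              predict_base_learner(fitted[[L]]$model, Xp), numeric(nte)))
            dd <- dd + prediction_metrics(pp, y_all[te])[["rmse"]] - base_rmse
          }
          imp_acc[p] <- imp_acc[p] + dd / control$n_perm
        }
        imp_n <- imp_n + 1
      }
    }
    ok <- !is.na(oof[, r])
    metr[r, ] <- prediction_metrics(oof[ok, r], y_all[ok])
  }
  raw <- pmax(imp_acc / max(imp_n, 1), 0)
  normalized <- if (max(raw) > 0) raw / max(raw) else raw
  oof <- oof[inv_ord, , drop = FALSE]           # back to caller row order
  structure(list(
    models = models, oof = oof, metrics = as.data.frame(metr),
    importance = list(raw = raw, normalized = normalized),
    spec = spec, plan = plan, target = target, control = control,
    seed = seed, n = nrow(data), y = y_all
  ), class = "soc_ensemble")
}

#' @export
print.soc_ensemble <- function(x, ...) {
  cat("Stacked SOC ensemble (rf + gbt + svr, simple-mean stack)\n",
      "  n = ", x$n, ", ", x$plan$repeats, " repeat(s) x ", x$plan$k,
      " spatial folds\n",
      "  out-of-fold MAE  = ", round(mean(x$metrics$mae), 3),
      "  RMSE = ", round(mean(x$metrics$rmse), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.soc_ensemble <- function(object, ...) {
  imp <- sort(object$importance$normalized, decreasing = TRUE)
  out <- list(metrics = object$metrics, importance = imp,
              repeats = object$plan$repeats, k = object$plan$k, n = object$n)
  class(out) <- "summary.soc_ensemble"
  out
}

#' @export
print.summary.soc_ensemble <- function(x, ...) {
  cat("Per-repeat out-of-fold metrics:\n")
  print(round(x$metrics, 3))
  cat("\nPermutation importance (max-normalised):\n")
  print(round(x$importance, 3))
  invisible(x)
}

#' Predict from a stacked ensemble with repeat-spread uncertainty
#'
#' Each repeat's prediction for a site is the mean over that repeat's outer-
#' fold models (each itself the simple mean of the three base learners); the
#' final prediction averages the repeats and the uncertainty is the
#' interquartile range (type-7 quantiles) of the per-repeat predictions.
#'
#' @param object A `soc_ensemble`.
#' @param newdata data.frame carrying all predictor columns.
#' @param details If `TRUE`, attach per-learner and per-repeat prediction
#'   arrays as attributes.
#' @param ... Unused.
#' @return data.frame with `pred` (mean prediction) and `pred_iqr`.
#' @export
predict.soc_ensemble <- function(object, newdata, details = FALSE, ...) {
  n <- nrow(newdata)
  reps <- length(object$models)
  per_repeat <- matrix(NA_real_, n, reps)
  per_learner <- if (details)
    array(NA_real_, c(n, reps, length(.learners)),
          dimnames = list(NULL, NULL, .learners))
  for (r in seq_len(reps)) {
    fold_preds <- list()
    learner_sum <- matrix(0, n, length(.learners))
    nf <- 0
    for (f in seq_along(object$models[[r]])) {
      mod <- object$models[[r]][[f]]
      if (is.null(mod)) next
      X <- encode_features(newdata, mod$enc, warn_unseen = r == 1L && nf == 0L)
      bp <- vapply(.learners, function(L)
        predict_base_learner(mod$learners[[L]]$model, X), numeric(n))
      fold_preds[[length(fold_preds) + 1L]] <- rowMeans(bp)
      learner_sum <- learner_sum + bp
      nf <- nf + 1
    }
    per_repeat[, r] <- Reduce(`+`, fold_preds) / length(fold_preds)
    if (details) per_learner[, r, ] <- learner_sum / nf
  }
  out <- data.frame(
    pred = rowMeans(per_repeat),
    pred_iqr = apply(per_repeat, 1, function(v) IQR(v, type = 7))
  )
  if (details) {
    attr(out, "per_repeat") <- per_repeat
    attr(out, "per_learner") <- per_learner
  }
  out
}

#' Permutation importance of the predictors
#'
#' Without new data, returns the importance stored at fit time (mean
#' out-of-fold RMSE increase over shuffles of each predictor, negatives
#' clipped to zero). With `newdata`/`target`, recomputes it against the full
#' ensemble prediction on that data.
#'
#' @param object A `soc_ensemble`.
#' @param newdata Optional data to measure on.
#' @param target Target column name in `newdata`.
#' @param n_perm Permutations per predictor.
#' @param seed RNG seed.
#' @return List with `raw` and `normalized` named importance vectors.
#' @export
permutation_importance <- function(object, newdata = NULL, target = object$target,
                                   n_perm = object$control$n_perm, seed = 1L) {
  if (is.null(newdata)) return(object$importance)
  y <- as.numeric(newdata[[target]])
  base <- prediction_metrics(predict(object, newdata)$pred, y)[["rmse"]]
  preds <- c(object$spec$numeric, object$spec$categorical)
  set.seed(seed)
  raw <- vapply(preds, function(p) {
    mean(vapply(seq_len(n_perm), function(b) {
      dp <- newdata
      dp[[p]] <- dp[[p]][sample.int(nrow(dp))]
      prediction_metrics(predict(object, dp)$pred, y)[["rmse"]] - base
    }, numeric(1)))
  }, numeric(1))
  raw <- pmax(raw, 0)
  list(raw = raw, normalized = if (max(raw) > 0) raw / max(raw) else raw)
}
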