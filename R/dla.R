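# Detection analysis (data labeling analysis): train a fixed roster of six
# standard classifier families to tell real rows (label 0) from synthetic
# rows (label 1); near-chance discrimination means high fidelity. The best
# classifier per fold is chosen by F1 on the synthetic class — the most
# restrictive case.

dla_roster <- c("logistic", "tree", "random_forest", "gboost",
                "nearest_neighbor", "naive_bayes")

# Numeric design matrix: z-scored continuous columns (train statistics) and
# one-hot categoricals.
dla_features <- function(tab, schema, center, scale_) {
  cc <- continuous_cols(schema)
  X <- as.matrix(tab[cc])
  X <- sweep(sweep(X, 2, center, "-"), 2, pmax(scale_, 1e-9), "/")
  for (cs in schema$columns) {
    if (cs$kind != "categorical") next
    L <- length(cs$levels)
    M <- matrix(0, nrow(tab), L)
    M[cbind(seq_len(nrow(tab)), tab[[cs$name]])] <- 1
    colnames(M) <- paste0(cs$name, "_", seq_len(L))
    X <- cbind(X, M)
  }
  X
}

dla_scores <- function(clf, Xtr, ytr, Xte, dftr, dfte) {
  switch(clf,
    logistic = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Xtr), ytr,
                                             family = stats::binomial()))
      eta <- cbind(1, Xte) %*% ifelse(is.na(fit$coefficients), 0,
                                      fit$coefficients)
      1 / (1 + exp(-eta))
    },
    tree = {
      fit <- rpart::rpart(y ~ ., data = cbind(dftr, y = factor(ytr)),
                          method = "class")
      stats::predict(fit, dfte, type = "prob")[, "1"]
    },
    random_forest = {
      fit <- randomForest::randomForest(Xtr, factor(ytr), ntree = 100)
      stats::predict(fit, Xte, type = "prob")[, "1"]
    },
    gboost = {
      dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = 4, eta = 0.3,
                                              nthread = 1,
                                              tree_method = "hist"),
                                data = dtr, nrounds = 40, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(Xte))
    },
    nearest_neighbor = {
      pr <- class::knn(Xtr, Xte, factor(ytr), k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(dftr, factor(ytr))
      stats::predict(fit, dfte, type = "raw")[, "1"]
    },
    stop("unknown classifier: ", clf))
}

#' Detection analysis of synthetic against real rows
#'
#' @param real,syn `clinical_table`s over the same schema.
#' @param test_frac stratified test fraction (default 0.3).
#' @param seed integer seed for the split and any stochastic learners.
#' @param roster classifier subset (default all six families).
#' @param max_per_class cap on rows per class fed to the classifiers (a
#'   seeded subsample keeps the battery affordable on large tables without
#'   changing its null behaviour).
#' @return a `dla_result`: per-classifier AUC / F1 / recall on the test
#'   split (synthetic = positive class), plus the best classifier by F1 and
#'   its scores.
#' @export
dla <- function(real, syn, test_frac = 0.3, seed = 1, roster = dla_roster,
                max_per_class = 1000) {
  if (nrow(real$data) > max_per_class)
    real <- ct_subset(real, with_seed(derive_seed(seed, "dla-real"),
                                      sample.int(nrow(real$data), max_per_class)))
  if (nrow(syn$data) > max_per_class)
    syn <- ct_subset(syn, with_seed(derive_seed(seed, "dla-syn"),
                                    sample.int(nrow(syn$data), max_per_class)))
  nr <- nrow(real$data); ns <- nrow(syn$data)
  if (min(nr, ns) < 4) stop("each class needs at least 4 rows")
  schema <- real$schema
  tab <- rbind(real$data, syn$data)
  y <- c(rep(0L, nr), rep(1L, ns))
  cc <- continuous_cols(schema)
  res <- with_seed(seed, {
    te <- c(sample.int(nr, round(test_frac * nr)),
            nr + sample.int(ns, round(test_frac * ns)))
    trn <- setdiff(seq_len(nr + ns), te)
    center <- colMeans(as.matrix(tab[trn, cc]))
    scale_ <- apply(as.matrix(tab[trn, cc]), 2, stats::sd)
    Xtr <- dla_features(tab[trn, , drop = FALSE], schema, center, scale_)
    Xte <- dla_features(tab[te, , drop = FALSE], schema, center, scale_)
    dftr <- as.data.frame(Xtr); dfte <- as.data.frame(Xte)
    ytr <- y[trn]; yte <- y[te]
    rows <- lapply(roster, function(clf) {
      sc <- as.numeric(dla_scores(clf, Xtr, ytr, Xte, dftr, dfte))
      auc <- as.numeric(pROC::auc(yte, sc, quiet = TRUE,
                                  direction = "<", levels = c(0, 1)))
      pred <- as.integer(sc >= 0.5)
      tp <- sum(pred == 1 & yte == 1)
      fp <- sum(pred == 1 & yte == 0)
      fn <- sum(pred == 0 & yte == 1)
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      data.frame(classifier = clf, auc = auc, f1 = f1, recall = rec)
    })
    do.call(rbind, rows)
  })
  best <- which.max(res$f1)
  structure(list(per_classifier = res,
                 best = res$classifier[best],
                 auc = res$auc[best], f1 = res$f1[best],
                 recall = res$recall[best],
                 chosen_by = "f1"),
            class = "dla_result")
}

#' @export
print.dla_result <- function(x, ...) {
  print(x$per_classifier, row.names = FALSE)
  cat("best by F1:", x$best, sprintf("(auc %.3f, f1 %.3f, recall %.3f)\n",
                                     x$auc, x$f1, x$recall))
  invisible(x)
}
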