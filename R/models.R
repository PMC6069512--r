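## Supervised-learning harness: five classifier families over any feature
## spec, with stratified 10-fold cross-validated hyperparameter selection
## on the training split only.
##
## Families map onto established fitters: decision tree = rpart, random
## forest = ranger, maximum entropy = glmnet multinomial ridge (an L2
## regularized multinomial logistic model), SVM = e1071 linear-kernel
## C-SVC. Multinomial naive Bayes is implemented here (additive-smoothed
## count model), the standard text-classification variant.

ALGORITHMS <- c("decision-tree", "random-forest", "naive-bayes",
                "maximum-entropy", "svm")

#' Default hyperparameter grid for a classifier family
#'
#' Small conventional grids, ordered simplest model first so that
#' cross-validation ties resolve to the lower-complexity point:
#' tree depth 5/10/30 (30 = effectively unlimited), forest size 100/300,
#' naive-Bayes additive smoothing 1.0/0.1, maximum-entropy L2 penalty
#' 10/1/0.1/0.01, SVM cost 0.1/1/10.
#'
#' @param algorithm one of `r paste(ALGORITHMS, collapse = ", ")`
#' @return named list with `param` (name) and `values`
#' @export
default_grid <- function(algorithm) {
  switch(match.arg(algorithm, ALGORITHMS),
         "decision-tree" = list(param = "maxdepth", values = c(5, 10, 30)),
         "random-forest" = list(param = "num_trees", values = c(100, 300)),
         "naive-bayes" = list(param = "alpha", values = c(1.0, 0.1)),
         "maximum-entropy" = list(param = "lambda", values = c(10, 1, 0.1, 0.01)),
         "svm" = list(param = "cost", values = c(0.1, 1, 10)))
}

#' Training configuration
#'
#' @param algorithm classifier family
#' @param feature_spec a [feature_spec()]
#' @param folds cross-validation folds (default 10, stratified by class)
#' @param seed integer seed recorded in all outputs
#' @param grid optional hyperparameter grid as returned by
#'   [default_grid()]
#' @return a `train_config` object
#' @export
train_config <- function(algorithm, feature_spec = supstatus::feature_spec(8),
                         folds = 10L, seed = 1L, grid = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stopifnot(inherits(feature_spec, "feature_spec"), folds >= 2)
  grid <- grid %||% default_grid(algorithm)
  if (!length(grid$values)) stop("hyperparameter grid must be non-empty", call. = FALSE)
  structure(list(algorithm = algorithm, feature_spec = feature_spec,
                 folds = as.integer(folds), seed = as.integer(seed),
                 grid = grid),
            class = "train_config")
}

## Stratified fold assignment: within each class, a seeded shuffle then
## round-robin fold labels. Errors when a class has fewer members than
## folds, since stratification would leave empty cells.
make_folds <- function(y, k, seed) {
  tab <- table(y)
  short <- names(tab)[tab < k]
  if (length(short)) {
    stop(sprintf("stratification error: class(es) %s have fewer than %d members",
                 paste(short, collapse = ", "), k), call. = FALSE)
  }
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

## ---- per-family fit / predict ------------------------------------------

## Degenerate feature spaces (an indicator feature set on a corpus with
## no indicators) can yield fewer than two columns; the fitters need at
## least two, so constant zero columns are padded on deterministically.
## The same padding is applied at prediction time via the vectorizer.
pad_features <- function(X, min_cols = 2L) {
  k <- min_cols - ncol(X)
  if (k <= 0L) return(X)
  pad <- Matrix::Matrix(0, nrow = nrow(X), ncol = k, sparse = TRUE,
                        dimnames = list(rownames(X), paste0(".pad", seq_len(k))))
  methods::as(cbind(X, pad), "CsparseMatrix")
}

## rpart needs a data.frame with syntactic column names; the positional
## names f1..fp are used and restored at prediction time.
tree_frame <- function(X) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("f", seq_len(ncol(df)))
  df
}

fit_multinomial_nb <- function(X, y, alpha) {
  classes <- levels(y)
  V <- ncol(X)
  counts <- t(vapply(classes, function(cl) {
    Matrix::colSums(X[y == cl, , drop = FALSE])
  }, numeric(V)))
  log_cond <- log(counts + alpha) - log(rowSums(counts) + alpha * V)
  log_prior <- log(as.numeric(table(y)[classes]) / length(y))
  structure(list(classes = classes, log_prior = log_prior,
                 log_cond = log_cond, alpha = alpha),
            class = "multinomial_nb")
}

predict_multinomial_nb <- function(fit, X) {
  scores <- as.matrix(X %*% t(fit$log_cond))
  scores <- sweep(scores, 2, fit$log_prior, "+")
  colnames(scores) <- fit$classes
  prob <- exp(scores - apply(scores, 1, max))
  prob <- prob / rowSums(prob)
  list(class = fit$classes[max.col(scores, ties.method = "first")], prob = prob)
}

## Majority-prior fallback for an entirely empty feature space (all-zero
## matrix): predicts class priors; keeps degenerate cells well defined.
fit_prior <- function(y) {
  structure(list(priors = prop.table(table(y)), classes = levels(y)),
            class = "prior_model")
}

## rpart's minimum-child-size constraint (minbucket = 7) makes features
## occurring in fewer than 7 training documents unusable for any split:
## the nonzero side of such a split is always below minbucket. Dropping
## them before fitting is therefore prediction-exact and shrinks the
## dense frame the tree scans by an order of magnitude on n-gram spaces.
TREE_MINBUCKET <- 7L

tree_keep_cols <- function(X) {
  keep <- which(Matrix::colSums(X != 0) >= TREE_MINBUCKET)
  if (!length(keep)) keep <- 1L
  keep
}

fit_one <- function(algorithm, X, y, value, seed) {
  if (algorithm %in% c("maximum-entropy", "svm") && Matrix::nnzero(X) == 0) {
    return(fit_prior(y))
  }
  switch(algorithm,
    "decision-tree" = {
      keep <- tree_keep_cols(X)
      df <- tree_frame(X[, keep, drop = FALSE]); df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(maxdepth = value,
                                                         cp = 1e-4,
                                                         minbucket = TREE_MINBUCKET,
                                                         xval = 0))
      attr(fit, "keep_cols") <- keep
      fit
    },
    "random-forest" =
      ranger::ranger(x = X, y = y, num.trees = value, probability = TRUE,
                     seed = seed, num.threads = 1),
    "naive-bayes" = fit_multinomial_nb(X, y, value),
    "maximum-entropy" =
      glmnet::glmnet(x = X, y = y, family = "multinomial", alpha = 0,
                     lambda = sort(unique(c(value, value * 2)), decreasing = TRUE),
                     standardize = FALSE),
    "svm" = e1071::svm(x = X, y = y, kernel = "linear", cost = value,
                       scale = FALSE))
}

predict_one <- function(algorithm, fit, X, value = NULL, classes = NULL) {
  if (inherits(fit, "prior_model")) {
    prob <- matrix(rep(as.numeric(fit$priors), each = nrow(X)), nrow = nrow(X),
                   dimnames = list(rownames(X), fit$classes))
    cl <- fit$classes[which.max(fit$priors)]
    return(list(class = rep(cl, nrow(X)), prob = prob))
  }
  switch(algorithm,
    "decision-tree" = {
      keep <- attr(fit, "keep_cols") %||% seq_len(ncol(X))
      prob <- predict(fit, newdata = tree_frame(X[, keep, drop = FALSE]),
                      type = "prob")
      list(class = colnames(prob)[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    "random-forest" = {
      prob <- predict(fit, data = X, num.threads = 1)$predictions
      list(class = colnames(prob)[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    "naive-bayes" = predict_multinomial_nb(fit, X),
    "maximum-entropy" = {
      prob <- predict(fit, newx = X, s = value, type = "response")[, , 1]
      if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1,
                                             dimnames = list(NULL, names(prob)))
      list(class = colnames(prob)[max.col(prob, ties.method = "first")],
           prob = prob)
    },
    "svm" = list(class = as.character(predict(fit, newdata = X)), prob = NULL))
}

## Snip a deep rpart tree back to a depth limit. Greedy top-down growth
## means the depth-d tree is exactly the top of the deep tree, so one
## deep fit per fold covers the whole depth grid.
snip_depth <- function(fit, depth) {
  nodes <- as.numeric(rownames(fit$frame))
  node_depth <- floor(log2(nodes))
  internal <- fit$frame$var != "<leaf>"
  toss <- nodes[internal & node_depth == depth]
  if (!length(toss)) return(fit)
  rpart::snip.rpart(fit, toss = toss)
}

## Cross-validated grid selection and final refit on a prebuilt feature
## matrix. Nested grids share fits across grid points: maximum entropy
## uses one glmnet path per fold for all lambdas, the decision tree grows
## one deep tree per fold and snips it to each depth, and the random
## forest grows the largest forest once per fold and predicts with the
## first `num_trees` trees for the smaller points.
train_on_matrix <- function(X, y, algorithm, grid, folds, seed) {
  fold_id <- make_folds(y, folds, derive_seed(seed, "folds"))
  values <- grid$values
  cv_f <- matrix(NA_real_, nrow = length(values), ncol = folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k; va <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    Xva <- X[va, , drop = FALSE]; yva <- y[va]
    fold_seed <- derive_seed(seed, paste0("fold", k))
    sc <- function(pred_class) {
      score(as.character(yva), pred_class)$weighted["f_measure"]
    }
    if (algorithm == "maximum-entropy") {
      fit <- if (Matrix::nnzero(Xtr) == 0) fit_prior(ytr)
        else glmnet::glmnet(x = Xtr, y = ytr, family = "multinomial",
                            alpha = 0, lambda = sort(values, decreasing = TRUE),
                            standardize = FALSE)
      for (v in seq_along(values)) {
        cv_f[v, k] <- sc(predict_one(algorithm, fit, Xva, value = values[v])$class)
      }
    } else if (algorithm == "decision-tree") {
      deep <- fit_one(algorithm, Xtr, ytr, max(values), fold_seed)
      keep <- attr(deep, "keep_cols")
      va_frame <- tree_frame(Xva[, keep, drop = FALSE])
      for (v in seq_along(values)) {
        snipped <- snip_depth(deep, values[v])
        prob <- predict(snipped, newdata = va_frame, type = "prob")
        cv_f[v, k] <- sc(colnames(prob)[max.col(prob, ties.method = "first")])
      }
    } else if (algorithm == "random-forest") {
      ## classification forest in CV (faster than a probability forest;
      ## only class votes are needed for the weighted-F criterion)
      big <- ranger::ranger(x = Xtr, y = ytr, num.trees = max(values),
                            probability = FALSE, seed = fold_seed,
                            num.threads = 1)
      for (v in seq_along(values)) {
        pred <- predict(big, data = Xva, num.trees = values[v],
                        num.threads = 1)$predictions
        cv_f[v, k] <- sc(as.character(pred))
      }
    } else {
      for (v in seq_along(values)) {
        fit <- fit_one(algorithm, Xtr, ytr, values[v], fold_seed)
        cv_f[v, k] <- sc(predict_one(algorithm, fit, Xva, value = values[v])$class)
      }
    }
  }
  mean_f <- rowMeans(cv_f)
  best <- which.max(round(mean_f, 12))   # ties -> first = simplest
  final <- fit_one(algorithm, X, y, values[best], derive_seed(seed, "final"))
  list(fit = final, value = values[best],
       cv_table = data.frame(param = grid$param, value = values,
                             mean_cv_weighted_f = mean_f))
}

#' Train a use-status classifier
#'
#' Fits the configured family over the configured feature set: the
#' vectorizer vocabulary, document frequencies and every fitted parameter
#' come from the training corpus only; hyperparameters are chosen by
#' stratified k-fold cross-validated weighted F-measure, ties going to
#' the simplest grid point, and the final model is refit on the full
#' training split.
#'
#' @param prep a [prepare_corpus()] result for the labeled training split
#' @param cfg a [train_config()]
#' @param lexicons lexicon bundle
#' @return a `sup_model`
#' @export
train_model <- function(prep, cfg, lexicons = default_lexicons()) {
  stopifnot(inherits(cfg, "train_config"))
  if (inherits(prep, "sup_corpus")) prep <- prepare_corpus(prep, lexicons)
  if (any(is.na(prep$corpus$label))) {
    stop("training corpus must be fully labeled", call. = FALSE)
  }
  y <- as_status(prep$corpus$label)
  vectorizer <- fit_vectorizer(prep, cfg$feature_spec, lexicons)
  X <- pad_features(transform_features(vectorizer, prep, lexicons))
  fitted <- train_on_matrix(X, y, cfg$algorithm, cfg$grid, cfg$folds, cfg$seed)
  structure(
    list(algorithm = cfg$algorithm, vectorizer = vectorizer,
         fit = fitted$fit, selected = stats::setNames(fitted$value, cfg$grid$param),
         cv_table = fitted$cv_table, classes = STATUS_CLASSES,
         class_priors = prop.table(table(y)), folds = cfg$folds,
         seed = cfg$seed),
    class = "sup_model")
}

#' @export
print.sup_model <- function(x, ...) {
  cat(sprintf("<sup_model> %s, feature type %d, %s = %g (CV weighted F %.3f), seed %d\n",
              x$algorithm, x$vectorizer$spec$type_id, names(x$selected),
              x$selected,
              max(x$cv_table$mean_cv_weighted_f), x$seed))
  invisible(x)
}

#' Predict use status for new sentences
#'
#' @param object a `sup_model`
#' @param prep a `sup_corpus` or [prepare_corpus()] result
#' @param lexicons lexicon bundle
#' @param type `"class"` for labels, `"prob"` for class-probability
#'   vectors (not available for the SVM, which is left uncalibrated)
#' @param ... unused
#' @return for `"class"`, a character vector of labels named by sentence
#'   id (empty input gives an empty vector); for `"prob"`, a matrix with
#'   one row per sentence whose rows sum to 1
#' @export
predict.sup_model <- function(object, prep, lexicons = default_lexicons(),
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(prep, "sup_corpus")) prep <- prepare_corpus(prep, lexicons)
  if (!nrow(prep$corpus)) {
    return(if (type == "class") stats::setNames(character(0), character(0))
           else matrix(numeric(0), 0, 4, dimnames = list(NULL, STATUS_CLASSES)))
  }
  if (type == "prob" && object$algorithm == "svm") {
    stop("the SVM predicts labels only (decision values are not calibrated)",
         call. = FALSE)
  }
  X <- pad_features(transform_features(object$vectorizer, prep, lexicons))
  pred <- predict_one(object$algorithm, object$fit, X,
                      value = unname(object$selected))
  if (type == "class") stats::setNames(pred$class, prep$corpus$id)
  else {
    rownames(pred$prob) <- prep$corpus$id
    pred$prob[, STATUS_CLASSES[STATUS_CLASSES %in% colnames(pred$prob)],
              drop = FALSE]
  }
}

#' Train and evaluate the full algorithm-by-feature-type grid
#'
#' One cell per classifier family and feature type: each cell is trained
#' on the training split (with cross-validated hyperparameter selection)
#' and scored on the test split with support-weighted precision, recall
#' and F-measure. The cell with the highest weighted F is flagged.
#'
#' @param prep_train,prep_test prepared labeled splits
#' @param lexicons lexicon bundle
#' @param algorithms classifier families to include
#' @param types feature type ids to include
#' @param folds,seed cross-validation setup
#' @param indicator_window window for feature types 8 and 9
#' @return data frame with one row per cell: `type`, `features`,
#'   `algorithm`, `precision`, `recall`, `f_measure`, `best`
#' @export
grid_report <- function(prep_train, prep_test, lexicons = default_lexicons(),
                        algorithms = ALGORITHMS, types = 1:9,
                        folds = 10L, seed = 1L, indicator_window = 6L) {
  type_labels <- c("raw uni", "uni", "tf-idf", "bi", "uni+bi", "uni+bi+tri",
                   "indi only", "uni+bi+indi", "uni+bi+tri+indi")
  y_train <- as_status(prep_train$corpus$label)
  gold_test <- prep_test$corpus$label
  rows <- list()
  for (tp in types) {
    spec <- feature_spec(tp, indicator_window = indicator_window)
    fs_tr <- corpus_features(prep_train, spec, lexicons)
    fs_te <- corpus_features(prep_test, spec, lexicons)
    vec <- fit_vectorizer(prep_train, spec, lexicons, featsets = fs_tr)
    Xtr <- pad_features(transform_features(vec, prep_train, lexicons,
                                           featsets = fs_tr))
    Xte <- pad_features(transform_features(vec, prep_test, lexicons,
                                           featsets = fs_te))
    for (algo in algorithms) {
      fitted <- train_on_matrix(Xtr, y_train, algo, default_grid(algo),
                                folds, derive_seed(seed, paste0(algo, tp)))
      pred <- predict_one(algo, fitted$fit, Xte, value = fitted$value)
      w <- score(gold_test, pred$class)$weighted
      rows[[length(rows) + 1L]] <-
        data.frame(type = tp, features = type_labels[tp], algorithm = algo,
                   precision = w["precision"], recall = w["recall"],
                   f_measure = w["f_measure"], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$best <- seq_len(nrow(out)) == which.max(out$f_measure)
  out
}
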