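#' Classifier specification
#'
#' Families and hyperparameter ranges follow the model zoo used for
#' pre-FOG recognition: SVM (kernel linear/quadratic/gaussian, kernel
#' scale 0.001--100, box constraint 0.01--100), kNN (1--50 neighbours,
#' euclidean/manhattan metric, equal/inverse/squared-inverse distance
#' weight), regularized LDA (gamma 0.01--1 covariance shrinkage, delta
#' 0.01--100 coefficient threshold), regularized logistic regression
#' (ridge lambda 0.01--100) and the fixed decision tree (Gini split,
#' minimum leaf size 1, at most 15 splits).
#'
#' @param family One of `"svm"`, `"knn"`, `"lda"`, `"logistic"`,
#'   `"decision_tree"`.
#' @param kernel,kernel_scale,box_constraint SVM hyperparameters.
#' @param k,metric,weight kNN hyperparameters.
#' @param gamma,delta Regularized-LDA hyperparameters.
#' @param lambda Ridge penalty for logistic regression.
#' @param fn_cost False-negative cost: misclassification-cost multiplier
#'   on the positive class (>= 1; a zero cost would never predict
#'   positive and is treated as 1).
#' @return An object of class `fog_model_spec`.
#' @export
fog_model_spec <- function(family = c("svm", "knn", "lda", "logistic",
                                      "decision_tree"),
                           kernel = c("linear", "quadratic", "gaussian"),
                           kernel_scale = 1, box_constraint = 1,
                           k = 5, metric = c("euclidean", "manhattan"),
                           weight = c("equal", "inverse",
                                      "squared_inverse"),
                           gamma = 0.01, delta = 0.01, lambda = 0.01,
                           fn_cost = 1) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  metric <- match.arg(metric)
  weight <- match.arg(weight)
  fn_cost <- max(1, fn_cost)
  stopifnot(kernel_scale >= 0.001, kernel_scale <= 100,
            box_constraint >= 0.01, box_constraint <= 100,
            k >= 1, k <= 50, gamma >= 0.01, gamma <= 1,
            delta >= 0.01, delta <= 100, lambda >= 0.01, lambda <= 100)
  structure(list(family = family, kernel = kernel,
                 kernel_scale = kernel_scale,
                 box_constraint = box_constraint, k = as.integer(k),
                 metric = metric, weight = weight, gamma = gamma,
                 delta = delta, lambda = lambda, fn_cost = fn_cost),
            class = "fog_model_spec")
}

# Prune an rpart fit to at most `max_splits` splits using its cp table.
prune_to_splits <- function(fit, max_splits = 15) {
  ct <- fit$cptable
  ok <- which(ct[, "nsplit"] <= max_splits)
  if (length(ok) == 0 || max(ct[, "nsplit"]) <= max_splits) return(fit)
  rpart::prune(fit, cp = ct[max(ok), "CP"])
}

fit_rpart_gini <- function(x, y, fn_cost = 1) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  loss <- matrix(c(0, fn_cost, 1, 0), 2, 2)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini", loss = loss),
                      control = rpart::rpart.control(
                        minbucket = 1, minsplit = 2, cp = 0, xval = 0,
                        maxdepth = 30, maxcompete = 0, maxsurrogate = 0,
                        usesurrogate = 0))
  prune_to_splits(fit, 15)
}

#' Fit a cost-sensitive binary classifier
#'
#' The false-negative cost is realized as the standard cost-sensitive
#' mechanism of each family: class weights for the SVM, a loss matrix for
#' the tree, a positive-prior multiplier for LDA, observation weights for
#' logistic regression and vote weighting for kNN.
#'
#' @param x Numeric matrix or data frame of features (training rows).
#' @param y Integer labels, 0 (negative/gait) and 1 (positive class).
#' @param spec A [fog_model_spec()].
#' @return A `fog_model` with a [predict.fog_model()] method returning
#'   both hard labels and continuous scores.
#' @export
fit_fog_model <- function(x, y, spec) {
  stopifnot(inherits(spec, "fog_model_spec"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  fit <- switch(
    spec$family,
    svm = {
      kern <- switch(spec$kernel, linear = "linear",
                     quadratic = "polynomial", gaussian = "radial")
      args <- list(x = x, y = factor(y, levels = c(0, 1)), kernel = kern,
                   cost = spec$box_constraint, scale = TRUE,
                   class.weights = c("0" = 1, "1" = spec$fn_cost))
      if (kern == "radial") args$gamma <- 1 / spec$kernel_scale^2
      if (kern == "polynomial") {
        args$degree <- 2; args$coef0 <- 1
        args$gamma <- 1 / spec$kernel_scale^2
      }
      do.call(e1071::svm, args)
    },
    knn = {
      mu <- colMeans(x)
      sd <- apply(x, 2, stats::sd)
      sd[sd == 0] <- 1
      list(x = scale(x, mu, sd), y = y, mu = mu, sd = sd)
    },
    lda = {
      m0 <- colMeans(x[y == 0, , drop = FALSE])
      m1 <- colMeans(x[y == 1, , drop = FALSE])
      s0 <- stats::cov(x[y == 0, , drop = FALSE])
      s1 <- stats::cov(x[y == 1, , drop = FALSE])
      n0 <- sum(y == 0); n1 <- sum(y == 1)
      S <- ((n0 - 1) * s0 + (n1 - 1) * s1) / (n0 + n1 - 2)
      Sg <- (1 - spec$gamma) * S + spec$gamma * diag(diag(S),
                                                     nrow = ncol(x))
      w <- tryCatch(solve(Sg, m1 - m0),
                    error = function(e) MASS_ginv(Sg) %*% (m1 - m0))
      w <- as.numeric(w)
      w[abs(w) <= spec$delta] <- 0       # delta: coefficient threshold
      b <- -sum(w * (m0 + m1) / 2) +
        log((n1 / (n0 + n1)) * spec$fn_cost / (n0 / (n0 + n1)))
      list(w = w, b = b)
    },
    logistic = {
      glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = spec$lambda,
                     weights = ifelse(y == 1, spec$fn_cost, 1))
    },
    decision_tree = fit_rpart_gini(x, y, spec$fn_cost)
  )
  structure(list(spec = spec, fit = fit, features = colnames(x),
                 class_prior = c(`0` = mean(y == 0), `1` = mean(y == 1))),
            class = "fog_model")
}

# Moore-Penrose fallback for a singular shrunken covariance.
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Predict labels and scores from a fitted classifier
#'
#' @param object A `fog_model`.
#' @param newdata Feature matrix/data frame with the training schema.
#' @param ... Unused.
#' @return List with `label` (integer 0/1) and `score` (continuous;
#'   larger = more positive-class evidence).
#' @export
predict.fog_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (!all(object$features %in% colnames(x))) {
      stop("feature schema mismatch between model and new data")
    }
    x <- x[, object$features, drop = FALSE]
  }
  spec <- object$spec
  switch(
    spec$family,
    svm = {
      pr <- stats::predict(object$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      score <- as.numeric(dv[, 1])
      if (grepl("^0/1", colnames(dv)[1])) score <- -score
      list(label = as.integer(as.character(pr)), score = score)
    },
    knn = {
      tr <- object$fit
      xs <- scale(x, tr$mu, tr$sd)
      k <- min(spec$k, nrow(tr$x))
      # full test-by-train distance matrix, computed blockwise
      if (spec$metric == "euclidean") {
        d2 <- outer(rowSums(xs^2), rowSums(tr$x^2), "+") -
          2 * xs %*% t(tr$x)
        D <- sqrt(pmax(d2, 0))
      } else {
        D <- matrix(0, nrow(xs), nrow(tr$x))
        for (j in seq_len(ncol(xs))) {
          D <- D + abs(outer(xs[, j], tr$x[, j], "-"))
        }
      }
      score <- numeric(nrow(xs))
      for (i in seq_len(nrow(xs))) {
        nn <- order(D[i, ])[seq_len(k)]
        wts <- switch(spec$weight,
                      equal = rep(1, k),
                      inverse = 1 / pmax(D[i, nn], 1e-12),
                      squared_inverse = 1 / pmax(D[i, nn], 1e-12)^2)
        pos <- sum(wts[tr$y[nn] == 1]) * spec$fn_cost
        neg <- sum(wts[tr$y[nn] == 0])
        score[i] <- pos / (pos + neg)
      }
      list(label = as.integer(score > 0.5), score = score)
    },
    lda = {
      score <- as.numeric(x %*% object$fit$w + object$fit$b)
      list(label = as.integer(score > 0), score = score)
    },
    logistic = {
      score <- as.numeric(stats::predict(object$fit, x, type = "link"))
      list(label = as.integer(score > 0), score = score)
    },
    decision_tree = {
      p <- stats::predict(object$fit, as.data.frame(x), type = "prob")[, "1"]
      lab <- as.integer(as.character(
        stats::predict(object$fit, as.data.frame(x), type = "class")))
      list(label = lab, score = p)
    }
  )
}

#' Rank features by decision-tree relevance
#'
#' Fits the fixed decision tree (Gini split, minimum leaf 1, at most 15
#' splits) and orders features by the shallowest tree depth at which each
#' first splits; ties are broken by total Gini impurity decrease, then by
#' original column order. Features the tree never uses are appended in
#' original column order, so the ranking always covers every column.
#'
#' @param x Feature matrix/data frame.
#' @param y Integer 0/1 labels (both classes required).
#' @return Character vector of all feature names, most relevant first.
#' @export
rank_features_dt <- function(x, y) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) {
    stop("feature ranking needs both classes present")
  }
  fit <- fit_rpart_gini(x, y)
  vars <- colnames(x)
  first_depth <- stats::setNames(rep(Inf, length(vars)), vars)
  gain <- stats::setNames(rep(0, length(vars)), vars)
  fr <- fit$frame
  internal <- which(fr$var != "<leaf>")
  if (length(internal)) {
    depths <- floor(log2(as.numeric(rownames(fr)[internal])))
    improve <- if (!is.null(fit$splits)) {
      # with maxcompete = maxsurrogate = 0, splits rows are the primary
      # splits in node order
      fit$splits[, "improve"]
    } else rep(0, length(internal))
    for (j in seq_along(internal)) {
      v <- as.character(fr$var[internal[j]])
      first_depth[v] <- min(first_depth[v], depths[j])
      gain[v] <- gain[v] + improve[j]
    }
  }
  vars[order(first_depth, -gain, seq_along(vars))]
}
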