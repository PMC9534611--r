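# The eight classifier families. Every model is trained on a numeric
# feature matrix with a two-level factor response (positive class = GBM,
# the first level) and emits a probability-like score in [0, 1] for the
# positive class. Hyperparameters are fixed, documented defaults.

#' Classifier specifications
#'
#' `classifier_spec()` builds one specification; `default_classifiers()`
#' returns the full eight-family set with the package's fixed defaults:
#' RBF-kernel SVM with Platt-calibrated probabilities, Gaussian Naive
#' Bayes, a single-hidden-layer perceptron (8 units, weight decay 0.01),
#' a CART decision tree, discrete AdaBoost with 100 depth-1 stumps,
#' 5-nearest-neighbors, plain logistic regression, and a 100-tree random
#' forest.
#'
#' @param family One of `"SVM"`, `"NB"`, `"MLP"`, `"DT"`, `"ADA"`,
#'   `"KNN"`, `"LR"`, `"RF"`.
#' @param ... Family-specific hyperparameter overrides.
#' @return A `classifier_spec` object (list with `family`, `params`).
#' @export
#' @examples
#' classifier_spec("KNN", k = 7)
#' names(default_classifiers())
classifier_spec <- function(family, ...) {
  family <- match.arg(family, c("SVM", "NB", "MLP", "DT", "ADA", "KNN",
                                "LR", "RF"))
  defaults <- switch(family,
    SVM = list(cost = 1, gamma = NULL),
    NB = list(),
    MLP = list(size = 8, decay = 0.01, maxit = 200),
    DT = list(cp = 0.01, minsplit = 5),
    ADA = list(n_rounds = 100),
    KNN = list(k = 5),
    LR = list(),
    RF = list(ntree = 100)
  )
  params <- utils::modifyList(defaults, list(...))
  structure(list(family = family, params = params),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
default_classifiers <- function() {
  fams <- c("SVM", "NB", "MLP", "DT", "ADA", "KNN", "LR", "RF")
  setNames(lapply(fams, classifier_spec), fams)
}

positive_class <- function() "GBM"

train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  p <- spec$params
  pos <- positive_class()
  model <- switch(spec$family,
    SVM = {
      gamma <- p$gamma %||% (1 / ncol(X))
      e1071::svm(X, y, kernel = "radial", cost = p$cost, gamma = gamma,
                 probability = TRUE)
    },
    NB = e1071::naiveBayes(X, y),
    MLP = {
      yb <- as.numeric(y == pos)
      nnet::nnet(X, yb, size = p$size, decay = p$decay, maxit = p$maxit,
                 entropy = TRUE, trace = FALSE)
    },
    DT = {
      df <- data.frame(X, .label = y, check.names = FALSE)
      rpart::rpart(.label ~ ., df, method = "class",
                   control = rpart::rpart.control(cp = p$cp,
                                                  minsplit = p$minsplit))
    },
    ADA = train_adaboost(X, y, n_rounds = p$n_rounds),
    KNN = list(X = X, y = y, k = p$k),
    LR = {
      df <- data.frame(X, check.names = FALSE)
      suppressWarnings(
        glm(y == pos ~ ., data = df, family = binomial())
      )
    },
    RF = randomForest::randomForest(X, y, ntree = p$ntree)
  )
  structure(list(family = spec$family, model = model, columns = colnames(X)),
            class = "wavemics_model")
}

score_classifier <- function(fit, X) {
  pos <- positive_class()
  m <- fit$model
  switch(fit$family,
    SVM = {
      pr <- predict(m, X, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    NB = predict(m, X, type = "raw")[, pos],
    MLP = as.numeric(predict(m, X)),
    DT = {
      df <- data.frame(X, check.names = FALSE)
      predict(m, df, type = "prob")[, pos]
    },
    ADA = score_adaboost(m, X),
    KNN = {
      pr <- class::knn(m$X, X, m$y, k = m$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == pos, win, 1 - win)
    },
    LR = {
      df <- data.frame(X, check.names = FALSE)
      as.numeric(suppressWarnings(predict(m, df, type = "response")))
    },
    RF = predict(m, X, type = "prob")[, pos]
  )
}

# Discrete AdaBoost with depth-1 CART stumps; scores are calibrated from
# the additive margin via the standard logistic link p = 1/(1+exp(-2F)).
train_adaboost <- function(X, y, n_rounds = 100) {
  pos <- positive_class()
  yy <- ifelse(y == pos, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  df <- data.frame(X, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    df$.y <- factor(yy, levels = c(-1, 1))
    stump <- rpart::rpart(.y ~ ., df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = -1,
                                                         minsplit = 2,
                                                         xval = 0))
    pred <- ifelse(predict(stump, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

score_adaboost <- function(m, X) {
  df <- data.frame(X, check.names = FALSE)
  if (!length(m$stumps)) return(rep(0.5, nrow(df)))
  F <- rep(0, nrow(df))
  for (t in seq_along(m$stumps)) {
    pred <- ifelse(predict(m$stumps[[t]], df, type = "class") == "1", 1, -1)
    F <- F + m$alphas[t] * pred
  }
  1 / (1 + exp(-2 * F))
}
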