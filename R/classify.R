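#' The ten classifier configurations
#'
#' Short names follow the usual fatigue-detection benchmarking set:
#' KNN (k-nearest neighbors, k = 5), LS (linear-kernel SVM), RS
#' (RBF-kernel SVM, gamma = 2, C = 1), GP (Gaussian process), DT
#' (decision tree, max depth 10, no cost-complexity pruning), RF (random
#' forest, 10 trees, max depth 10), MLP (one hidden layer of 100 units,
#' at most 500 iterations), AB (discrete AdaBoost with 50 stumps), GNB
#' (Gaussian naive Bayes) and QDA (quadratic discriminant analysis).
#' @export
CLASSIFIER_NAMES <- c("KNN", "LS", "RS", "GP", "DT", "RF", "MLP", "AB",
                      "GNB", "QDA")

#' Specify one classifier configuration
#'
#' @param name one of \code{\link{CLASSIFIER_NAMES}}.
#' @param seed integer seed used by the stochastic learners (RF, MLP, AB)
#'   so repeated fits are identical.
#' @param ... hyperparameter overrides (e.g. \code{k}, \code{gamma},
#'   \code{cost}, \code{max_depth}, \code{n_trees}, \code{hidden},
#'   \code{maxit}, \code{n_rounds}).
#' @return object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(name, seed = 1L, ...) {
  if (!name %in% CLASSIFIER_NAMES)
    stop(sprintf("unknown classifier '%s'; valid names: %s", name,
                 paste(CLASSIFIER_NAMES, collapse = ", ")))
  defaults <- switch(name,
    KNN = list(k = 5L),
    LS  = list(cost = 1),
    RS  = list(gamma = 2, cost = 1),
    GP  = list(),
    DT  = list(max_depth = 10L),
    RF  = list(n_trees = 10L, max_depth = 10L),
    MLP = list(hidden = 100L, maxit = 500L),
    AB  = list(n_rounds = 50L),
    GNB = list(),
    QDA = list())
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0)
    stop(sprintf("invalid hyperparameter(s) for %s: %s", name,
                 paste(bad, collapse = ", ")))
  defaults[names(over)] <- over
  structure(list(name = name, hyper = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---- discrete AdaBoost (SAMME) over depth-1 rpart stumps --------------

.ada_fit <- function(X, y, n_rounds) {
  # y in {-1, +1}
  n <- length(y)
  w <- rep(1 / n, n)
  df <- data.frame(y = factor(y), X)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2,
                                                       minbucket = 1,
                                                       xval = 0))
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[t]] <- fit; alphas[t] <- alpha
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    if (err < 1e-8) break                      # perfect stump: stop early
  }
  list(stumps = stumps, alphas = alphas)
}

.ada_score <- function(model, X) {
  df <- data.frame(X)
  s <- numeric(nrow(df))
  for (t in seq_along(model$stumps))
    s <- s + model$alphas[t] *
      as.numeric(as.character(predict(model$stumps[[t]], df, type = "class")))
  s
}

# ---- uniform harness ---------------------------------------------------

.as_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

#' Build a trainable classifier from a specification
#'
#' Returns a uniform contract: \code{$fit(X, y)} trains on a numeric
#' matrix and a label factor (levels \code{normal}, \code{fatigue}),
#' \code{$predict(model, X)} returns predicted labels, and
#' \code{$score(model, X)} a continuous per-instance score oriented so
#' that higher means more fatigue-like (class probability where the
#' learner provides one, decision margin or vote fraction otherwise),
#' suitable for ROC/AUC. Stochastic learners are re-seeded from the
#' specification at every fit.
#'
#' @param spec a \code{\link{classifier_spec}} (or a name passed to it).
#' @return object of class \code{ef_classifier} with elements
#'   \code{name}, \code{spec}, \code{fit}, \code{predict}, \code{score}.
#' @export
build_classifier <- function(spec) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  h <- spec$hyper
  lv <- c("normal", "fatigue")
  as_y <- function(y) factor(y, levels = lv)

  fns <- switch(spec$name,
    KNN = list(
      fit = function(X, y) list(X = .as_matrix(X), y = as_y(y)),
      predict = function(m, X) {
        class::knn(m$X, .as_matrix(X), m$y, k = h$k)
      },
      score = function(m, X) {
        pr <- class::knn(m$X, .as_matrix(X), m$y, k = h$k, prob = TRUE)
        p <- attr(pr, "prob")                  # prob of the winning class
        ifelse(pr == "fatigue", p, 1 - p)
      }),
    LS = list(
      fit = function(X, y) e1071::svm(.as_matrix(X), as_y(y),
                                      kernel = "linear", cost = h$cost,
                                      scale = FALSE),
      predict = function(m, X) predict(m, .as_matrix(X)),
      score = function(m, X) {
        dv <- attr(predict(m, .as_matrix(X), decision.values = TRUE),
                   "decision.values")
        # decision value is positive toward the level named first
        if (colnames(dv) == "normal/fatigue") -dv[, 1] else dv[, 1]
      }),
    RS = list(
      fit = function(X, y) e1071::svm(.as_matrix(X), as_y(y),
                                      kernel = "radial", gamma = h$gamma,
                                      cost = h$cost, scale = FALSE),
      predict = function(m, X) predict(m, .as_matrix(X)),
      score = function(m, X) {
        dv <- attr(predict(m, .as_matrix(X), decision.values = TRUE),
                   "decision.values")
        if (colnames(dv) == "normal/fatigue") -dv[, 1] else dv[, 1]
      }),
    GP = list(
      # fixed unit-length-scale RBF kernel (kernlab sigma = 1/(2 l^2))
      fit = function(X, y) kernlab::gausspr(.as_matrix(X), as_y(y),
                                            type = "classification",
                                            kernel = "rbfdot",
                                            kpar = list(sigma = 0.5)),
      predict = function(m, X) kernlab::predict(m, .as_matrix(X)),
      score = function(m, X)
        kernlab::predict(m, .as_matrix(X), type = "probabilities")[, "fatigue"]),
    DT = list(
      # sklearn-style CART: depth cap only, no cost-complexity pruning
      fit = function(X, y) {
        df <- data.frame(y = as_y(y), .as_matrix(X))
        rpart::rpart(y ~ ., data = df,
                     control = rpart::rpart.control(maxdepth = h$max_depth,
                                                    cp = 0, minsplit = 2,
                                                    minbucket = 1, xval = 0))
      },
      predict = function(m, X)
        predict(m, data.frame(.as_matrix(X)), type = "class"),
      score = function(m, X)
        predict(m, data.frame(.as_matrix(X)), type = "prob")[, "fatigue"]),
    RF = list(
      fit = function(X, y) {
        df <- data.frame(y = as_y(y), .as_matrix(X))
        ranger::ranger(y ~ ., data = df, num.trees = h$n_trees,
                       max.depth = h$max_depth, probability = TRUE,
                       min.node.size = 1, seed = spec$seed,
                       num.threads = 1)
      },
      predict = function(m, X) {
        p <- predict(m, data.frame(.as_matrix(X)),
                     num.threads = 1)$predictions[, "fatigue"]
        factor(ifelse(p >= 0.5, "fatigue", "normal"), levels = lv)
      },
      score = function(m, X)
        predict(m, data.frame(.as_matrix(X)),
                num.threads = 1)$predictions[, "fatigue"]),
    MLP = list(
      fit = function(X, y) {
        set.seed(spec$seed)
        nnet::nnet(.as_matrix(X), as.numeric(as_y(y)) - 1, size = h$hidden,
                   maxit = h$maxit, entropy = TRUE, trace = FALSE,
                   MaxNWts = 100000)
      },
      predict = function(m, X) {
        p <- predict(m, .as_matrix(X))[, 1]
        factor(ifelse(p >= 0.5, "fatigue", "normal"), levels = lv)
      },
      score = function(m, X) predict(m, .as_matrix(X))[, 1]),
    AB = list(
      fit = function(X, y) {
        set.seed(spec$seed)
        .ada_fit(.as_matrix(X), ifelse(as_y(y) == "fatigue", 1, -1),
                 h$n_rounds)
      },
      predict = function(m, X) {
        s <- .ada_score(m, .as_matrix(X))
        factor(ifelse(s >= 0, "fatigue", "normal"), levels = lv)
      },
      score = function(m, X) .ada_score(m, .as_matrix(X))),
    GNB = list(
      fit = function(X, y) e1071::naiveBayes(.as_matrix(X), as_y(y)),
      predict = function(m, X) predict(m, .as_matrix(X)),
      score = function(m, X)
        predict(m, .as_matrix(X), type = "raw")[, "fatigue"]),
    QDA = list(
      fit = function(X, y) MASS::qda(.as_matrix(X), as_y(y)),
      predict = function(m, X) predict(m, .as_matrix(X))$class,
      score = function(m, X) predict(m, .as_matrix(X))$posterior[, "fatigue"]))

  structure(c(list(name = spec$name, spec = spec), fns),
            class = "ef_classifier")
}

#' @export
print.ef_classifier <- function(x, ...) {
  hp <- x$spec$hyper
  cat(sprintf("<ef_classifier> %s(%s)\n", x$name,
              paste(names(hp), unlist(hp), sep = "=", collapse = ", ")))
  invisible(x)
}
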