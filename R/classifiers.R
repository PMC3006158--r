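#' Classifier adapter
#'
#' A uniform contract over classification backends: `fit(x, y)` takes a
#' features x samples matrix and a label vector and returns a model;
#' `predict(model, newx)` takes a features x new-samples matrix and returns
#' one label per column, always drawn from the training label set. All
#' built-in adapters are deterministic.
#'
#' @param name adapter name.
#' @param fit function(x, y) -> model.
#' @param predict function(model, newx) -> character labels.
#' @param hyperparams named list recorded for reporting.
#' @return A list of class `ClassifierAdapter`.
#' @export
classifier_adapter <- function(name, fit, predict, hyperparams = list()) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict,
                 hyperparams = hyperparams),
            class = "ClassifierAdapter")
}

#' @export
print.ClassifierAdapter <- function(x, ...) {
  hp <- if (length(x$hyperparams))
    paste(names(x$hyperparams), unlist(x$hyperparams), sep = "=",
          collapse = ", ") else "none"
  cat("ClassifierAdapter '", x$name, "' (", hp, ")\n", sep = "")
  invisible(x)
}

#' k-nearest-neighbour classifier (Euclidean)
#'
#' Native kNN with deterministic tie handling: neighbours are ordered by
#' (distance, training index); on a vote tie the class of the nearest
#' neighbour belonging to a tied class wins, with the lexicographically
#' smaller label as final fallback.
#'
#' @param k number of neighbours (default 3; odd values avoid most ties).
#' @return A `ClassifierAdapter`.
#' @export
classifier_knn <- function(k = 3L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  classifier_adapter(
    name = "knn",
    hyperparams = list(k = k),
    fit = function(x, y) list(x = x, y = as.character(y), k = min(k, ncol(x))),
    predict = function(model, newx) {
      apply(newx, 2L, function(v) {
        d2 <- colSums((model$x - v)^2)
        ord <- order(d2, seq_along(d2))
        nn <- model$y[ord[seq_len(model$k)]]
        votes <- table(nn)
        winners <- names(votes)[votes == max(votes)]
        if (length(winners) == 1L) return(winners)
        first <- nn[nn %in% winners][1L]
        if (!is.na(first)) first else sort(winners)[1L]
      })
    })
}

#' Gaussian naive Bayes classifier
#'
#' Per-class, per-feature Gaussian likelihoods with sample (n-1) variances,
#' floored at `var_floor` to keep log-densities finite, plus empirical
#' class log-priors. Ties resolve to the lexicographically smaller class.
#'
#' @param var_floor minimum per-feature variance (default 1e-9).
#' @return A `ClassifierAdapter`.
#' @export
classifier_nb <- function(var_floor = 1e-9) {
  stopifnot(var_floor > 0)
  classifier_adapter(
    name = "nb",
    hyperparams = list(var_floor = var_floor),
    fit = function(x, y) {
      y <- as.character(y)
      classes <- sort(unique(y))
      stats_by <- lapply(classes, function(cl) {
        xc <- x[, y == cl, drop = FALSE]
        m <- rowMeans(xc)
        v <- pmax(rowSums((xc - m)^2) / (ncol(xc) - 1L), var_floor)
        list(mean = m, var = v, logprior = log(ncol(xc) / length(y)))
      })
      names(stats_by) <- classes
      list(classes = classes, stats = stats_by)
    },
    predict = function(model, newx) {
      ll <- vapply(model$classes, function(cl) {
        st <- model$stats[[cl]]
        colSums(stats::dnorm(newx, mean = st$mean, sd = sqrt(st$var),
                             log = TRUE)) + st$logprior
      }, numeric(ncol(newx)))
      ll <- matrix(ll, ncol = length(model$classes))
      model$classes[max.col(ll, ties.method = "first")]
    })
}

#' Nearest-shrunken-centroid classifier (PAM-style)
#'
#' Class centroids are shrunken towards the overall centroid by soft
#' thresholding of the standardized centroid differences
#' d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0)), with pooled within-class
#' standard deviations s_i, offset s0 = median(s_i), and
#' m_k = sqrt(1/n_k - 1/n). A sample is assigned to the class minimizing
#' the discriminant sum((x - xbar'_k)^2 / (s_i + s0)^2) - 2 log(prior_k).
#' The default threshold 0 performs no shrinkage (nearest centroid in the
#' standardized metric).
#'
#' @param threshold shrinkage amount Delta >= 0 (default 0).
#' @return A `ClassifierAdapter`.
#' @export
classifier_nsc <- function(threshold = 0) {
  stopifnot(threshold >= 0)
  classifier_adapter(
    name = "nsc",
    hyperparams = list(threshold = threshold),
    fit = function(x, y) {
      y <- as.character(y)
      classes <- sort(unique(y))
      n <- length(y)
      nk <- vapply(classes, function(cl) sum(y == cl), integer(1))
      overall <- rowMeans(x)
      cent <- vapply(classes, function(cl)
        rowMeans(x[, y == cl, drop = FALSE]), numeric(nrow(x)))
      cent <- matrix(cent, nrow = nrow(x),
                     dimnames = list(rownames(x), classes))
      # pooled within-class variance
      wss <- rowSums(vapply(classes, function(cl) {
        xc <- x[, y == cl, drop = FALSE]
        rowSums((xc - rowMeans(xc))^2)
      }, numeric(nrow(x))))
      s <- sqrt(wss / (n - length(classes)))
      s0 <- stats::median(s)
      if (s0 == 0) s0 <- 1e-6
      shrunk <- cent
      for (j in seq_along(classes)) {
        mk <- sqrt(1 / nk[j] - 1 / n)
        d <- (cent[, j] - overall) / (mk * (s + s0))
        d <- sign(d) * pmax(abs(d) - threshold, 0)
        shrunk[, j] <- overall + mk * (s + s0) * d
      }
      list(classes = classes, centroids = shrunk, scale = s + s0,
           logprior = log(nk / n))
    },
    predict = function(model, newx) {
      disc <- vapply(seq_along(model$classes), function(j) {
        colSums(((newx - model$centroids[, j]) / model$scale)^2) -
          2 * model$logprior[j]
      }, numeric(ncol(newx)))
      disc <- matrix(disc, ncol = length(model$classes))
      model$classes[max.col(-disc, ties.method = "first")]
    })
}

#' Decision-tree classifier (CART via rpart)
#'
#' @param ... passed to [rpart::rpart.control()].
#' @return A `ClassifierAdapter`.
#' @export
classifier_dt <- function(...) {
  control <- rpart::rpart.control(...)
  classifier_adapter(
    name = "dt",
    hyperparams = list(),
    fit = function(x, y) {
      df <- as.data.frame(t(x))
      names(df) <- make.names(rownames(x))
      df$.class <- factor(as.character(y))
      list(tree = rpart::rpart(.class ~ ., data = df, method = "class",
                               control = control),
           features = rownames(x))
    },
    predict = function(model, newx) {
      df <- as.data.frame(t(newx[model$features, , drop = FALSE]))
      names(df) <- make.names(model$features)
      as.character(stats::predict(model$tree, newdata = df, type = "class"))
    })
}

#' Support vector machine classifier (linear kernel via e1071)
#'
#' @param kernel kernel name (default `"linear"`, the high-dimension /
#'   low-sample convention).
#' @param cost soft-margin cost (default 1).
#' @return A `ClassifierAdapter`.
#' @export
classifier_svm <- function(kernel = "linear", cost = 1) {
  classifier_adapter(
    name = "svm",
    hyperparams = list(kernel = kernel, cost = cost),
    fit = function(x, y) {
      list(model = e1071::svm(x = t(x), y = factor(as.character(y)),
                              kernel = kernel, cost = cost, scale = FALSE),
           features = rownames(x))
    },
    predict = function(model, newx) {
      as.character(stats::predict(model$model,
                                  t(newx[model$features, , drop = FALSE])))
    })
}

#' Built-in classifier adapters
#'
#' @param names which adapters to return (default: all of `"knn"`, `"nb"`,
#'   `"nsc"`, `"dt"`, `"svm"`). Unknown names raise an error listing the
#'   available ones.
#' @return Named list of `ClassifierAdapter`s.
#' @export
builtin_classifiers <- function(names = NULL) {
  all <- list(knn = classifier_knn(), nb = classifier_nb(),
              nsc = classifier_nsc(), dt = classifier_dt(),
              svm = classifier_svm())
  if (is.null(names)) return(all)
  unknown <- setdiff(names, base::names(all))
  if (length(unknown))
    stop("unknown classifier(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(base::names(all), collapse = ", "))
  all[names]
}
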