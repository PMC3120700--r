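#' Best decision stump under weighted 0/1 error
#'
#' Exhaustively searches all features, both polarities and all thresholds at
#' midpoints between consecutive distinct sorted feature values (plus
#' \code{-Inf}/\code{+Inf} sentinels) for the stump minimizing the weighted
#' misclassification error. Ties are broken by lowest feature index, then
#' smallest threshold, then polarity \code{+1} before \code{-1}.
#'
#' A stump with polarity \code{+1} predicts the positive class where the
#' feature value exceeds the threshold; polarity \code{-1} predicts positive
#' below it.
#'
#' @param X numeric feature matrix (samples x features, column names used as
#'   feature names).
#' @param y labels in \code{-1 / +1}.
#' @param w sample weights (non-negative, positive sum); normalized
#'   internally. Default uniform.
#' @return A list of class \code{stump}: \code{feature}, \code{index},
#'   \code{threshold}, \code{polarity}, \code{error} (weighted, in
#'   \eqn{[0, 0.5]} unless the input is degenerate). If \code{y} has a
#'   single class, a constant stump is returned with attribute
#'   \code{degenerate = TRUE}.
#' @export
best_stump <- function(X, y, w = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1 / n, n)
  if (any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  if (ncol(X) < 1L) stop("need at least one feature", call. = FALSE)
  check_labels(y)
  w <- w / sum(w)
  orders <- lapply(seq_len(ncol(X)), function(j)
    order(X[, j], method = "radix"))
  s <- stump_search(X, y, w, orders)
  if (length(unique(y)) == 1L) attr(s, "degenerate") <- TRUE
  s
}

check_labels <- function(y) {
  if (!is.numeric(y) || !all(y %in% c(-1, 1)))
    stop("labels must be -1 / +1", call. = FALSE)
  invisible(y)
}

# internal stump search with precomputed per-column sort orders.
# For sorted values x[1..n], candidate i in 0..n splits after position i
# ("above" polarity predicts + for x > thr):
#   err_above(i) = W+(<=i) + W-(>i);  err_below(i) = 1 - err_above(i).
stump_search <- function(X, y, w, orders) {
  n <- nrow(X)
  best <- list(err = Inf, j = NA_integer_, thr = NA_real_, pol = NA_real_)
  for (j in seq_len(ncol(X))) {
    o <- orders[[j]]
    xs <- X[o, j]
    ys <- y[o]
    ws <- w[o]
    wp <- cumsum(ws * (ys > 0))
    wn <- cumsum(ws * (ys < 0))
    Wp <- wp[n]; Wn <- wn[n]
    err_above <- c(Wn, wp + (Wn - wn))      # candidates i = 0..n
    err_below <- (Wp + Wn) - err_above
    valid <- c(TRUE, xs[-n] < xs[-1], TRUE)
    err_above[!valid] <- Inf
    err_below[!valid] <- Inf
    m <- min(err_above, err_below)
    if (m >= best$err) next
    iA <- which(err_above == m)[1]
    iB <- which(err_below == m)[1]
    thr_at <- function(i) {
      if (i == 1L) -Inf else if (i == n + 1L) Inf
      else (xs[i - 1L] + xs[i]) / 2
    }
    if (!is.na(iA) && (is.na(iB) || iA <= iB)) {
      best <- list(err = m, j = j, thr = thr_at(iA), pol = 1)
    } else {
      best <- list(err = m, j = j, thr = thr_at(iB), pol = -1)
    }
  }
  feat <- colnames(X)[best$j]
  if (is.null(feat)) feat <- paste0("V", best$j)
  structure(list(feature = feat, index = best$j, threshold = best$thr,
                 polarity = best$pol, error = best$err),
            class = "stump")
}

stump_h <- function(x, threshold, polarity) {
  polarity * (2 * (x > threshold) - 1)
}

#' Boosting classifier over decision stumps
#'
#' Discrete AdaBoost with decision stumps as the weak learners: weights
#' start uniform; each round fits the [best_stump()] under the current
#' weights, receives the vote \eqn{\alpha = \frac12 \ln((1-\epsilon)/\epsilon)},
#' and the sample weights are multiplied by \eqn{\exp(-\alpha y h(x))} and
#' renormalized. Training stops early when a round achieves zero weighted
#' error (the stump is kept) or no stump beats chance
#' (\eqn{\epsilon \ge 0.5}). Training is deterministic given the input: all
#' stochasticity in the surrounding analysis lives in the resampling layer.
#'
#' The round-1 stump's feature is the model's "top predictive feature" (the
#' single feature with the greatest standalone weighted-error reduction);
#' see [top_features()].
#'
#' @param x feature matrix (samples x features), or a formula.
#' @param y labels: \code{-1 / +1} numeric, logical (\code{TRUE} positive),
#'   or a two-level factor (second level positive).
#' @param rounds maximum boosting rounds (default 100).
#' @param data,... for the formula method: the data.frame holding the model
#'   variables, and arguments passed on.
#' @return An object of class \code{coreboost}: list with \code{stumps}
#'   (one row per round: feature, index, threshold, polarity, error, alpha),
#'   \code{feature_names}, \code{rounds_trained}, \code{train_error} (final
#'   training 0/1 error), \code{error_bound} (the AdaBoost bound
#'   \eqn{\prod_t 2\sqrt{\epsilon_t(1-\epsilon_t)}}), \code{exp_loss}
#'   (per-round training exponential loss) and \code{levels} (label coding).
#' @seealso [predict.coreboost()], [top_features()], [write_boost_model()]
#' @export
coreboost <- function(x, ...) UseMethod("coreboost")

#' @rdname coreboost
#' @export
coreboost.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- as.matrix(mf[, -1, drop = FALSE])
  coreboost.default(X, y, ...)
}

#' @rdname coreboost
#' @export
coreboost.default <- function(x, y, rounds = 100L, ...) {
  if (rounds < 1L) stop("rounds must be >= 1", call. = FALSE)
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  lev <- NULL
  if (is.factor(y)) {
    lev <- levels(y)
    if (length(lev) != 2L) stop("y must have two classes", call. = FALSE)
    y <- ifelse(y == lev[2], 1, -1)
  } else if (is.logical(y)) {
    lev <- c("FALSE", "TRUE")
    y <- ifelse(y, 1, -1)
  }
  check_labels(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  n <- nrow(X)
  w <- rep(1 / n, n)
  orders <- lapply(seq_len(ncol(X)), function(j)
    order(X[, j], method = "radix"))
  stumps <- vector("list", rounds)
  margins <- numeric(n)          # y * F(x), running
  exp_loss <- numeric(rounds)
  t <- 0L
  eps_floor <- 1e-12
  repeat {
    s <- stump_search(X, y, w, orders)
    eps <- s$error
    if (eps >= 0.5) break
    t <- t + 1L
    alpha <- 0.5 * log((1 - eps) / max(eps, eps_floor))
    h <- stump_h(X[, s$index], s$threshold, s$polarity)
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
    margins <- margins + alpha * y * h
    exp_loss[t] <- mean(exp(-margins))
    stumps[[t]] <- data.frame(feature = s$feature, index = s$index,
                              threshold = s$threshold, polarity = s$polarity,
                              error = eps, alpha = alpha,
                              stringsAsFactors = FALSE)
    if (eps == 0 || t >= rounds) break
  }
  if (t == 0L)
    stop("no stump beats chance on the training data", call. = FALSE)
  stumps <- do.call(rbind, stumps[seq_len(t)])
  rownames(stumps) <- NULL
  model <- structure(list(
    stumps = stumps,
    feature_names = colnames(X),
    rounds_trained = t,
    levels = lev,
    exp_loss = exp_loss[seq_len(t)],
    error_bound = prod(2 * sqrt(stumps$error * (1 - stumps$error)))
  ), class = "coreboost")
  model$train_error <- mean(sign0(predict(model, X, type = "score")) != y)
  model
}

sign0 <- function(s) ifelse(s > 0, 1, -1)   # score ties predict negative

#' Predict from a boosting model
#'
#' The score is the weighted stump vote \eqn{\sum_t \alpha_t h_t(x)}; the
#' label is its sign, with a zero score mapped to the negative class.
#'
#' @param object a [coreboost] model.
#' @param newdata matrix or data.frame whose columns include the model's
#'   feature names.
#' @param type \code{"label"} (default) or \code{"score"}.
#' @param ... unused.
#' @return Numeric vector of \code{-1 / +1} labels or real scores.
#' @export
predict.coreboost <- function(object, newdata,
                              type = c("label", "score"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing))
    stop("newdata lacks model feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  X <- newdata[, object$feature_names, drop = FALSE]
  X <- if (is.data.frame(X)) data.matrix(X) else as.matrix(X)
  score <- numeric(nrow(X))
  st <- object$stumps
  for (i in seq_len(nrow(st))) {
    score <- score + st$alpha[i] *
      stump_h(X[, st$feature[i]], st$threshold[i], st$polarity[i])
  }
  if (type == "score") score else sign0(score)
}

#' Ranked predictive features of a boosting model
#'
#' Rank 1 is the feature of the first-round stump (the top predictive
#' feature); later ranks follow the round in which a feature first appears.
#' The alternative \code{by = "alpha"} ranking orders features by their
#' total absolute vote across rounds.
#'
#' @param model a [coreboost] model.
#' @param k number of features to return (default all selected).
#' @param by \code{"first_round"} (default) or \code{"alpha"}.
#' @return Character vector of feature names.
#' @export
top_features <- function(model, k = Inf, by = c("first_round", "alpha")) {
  by <- match.arg(by)
  ranked <- if (by == "first_round") {
    unique(model$stumps$feature)
  } else {
    imp <- tapply(abs(model$stumps$alpha), model$stumps$feature, sum)
    names(sort(imp, decreasing = TRUE))
  }
  utils::head(ranked, k)
}

#' @export
print.coreboost <- function(x, ...) {
  cat("coreboost model: ", x$rounds_trained, " stump(s) over ",
      length(x$feature_names), " features\n", sep = "")
  cat("  top feature: ", x$stumps$feature[1],
      "  (round-1 weighted error ", sprintf("%.4f", x$stumps$error[1]),
      ")\n", sep = "")
  if (!is.null(x$train_error))
    cat("  training 0/1 error: ", sprintf("%.4f", x$train_error),
        "  (bound ", sprintf("%.4f", x$error_bound), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.coreboost <- function(object, ...) {
  out <- list(stumps = object$stumps,
              rounds_trained = object$rounds_trained,
              train_error = object$train_error,
              error_bound = object$error_bound,
              top = top_features(object, 10))
  class(out) <- "summary.coreboost"
  out
}

#' @export
print.summary.coreboost <- function(x, ...) {
  cat("coreboost: ", x$rounds_trained, " rounds, training error ",
      sprintf("%.4f", x$train_error), " (bound ",
      sprintf("%.4f", x$error_bound), ")\n", sep = "")
  cat("top features:", paste(x$top, collapse = ", "), "\n")
  cat("per-round trace (first 10):\n")
  print(utils::head(x$stumps, 10), row.names = FALSE)
  invisible(x)
}

#' @export
coef.coreboost <- function(object, ...) {
  imp <- tapply(abs(object$stumps$alpha), object$stumps$feature, sum)
  sort(unclass(imp), decreasing = TRUE)
}

#' Plot a boosting model's feature importances
#'
#' Horizontal bar chart of the total absolute stump vote per feature.
#'
#' @param x a [coreboost] model.
#' @param k number of features shown.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.coreboost <- function(x, k = 15, ...) {
  imp <- rev(utils::head(coef(x), k))
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "total |alpha|", ...)
  invisible(x)
}

#' Per-round training trace as TSV
#'
#' @param model a [coreboost] model.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_boost_trace <- function(model, path) {
  utils::write.table(model$stumps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
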