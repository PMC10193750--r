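# RBF-kernel SVM over the assembled features (libsvm via e1071), with
# symmetric min-max scaling fitted on the training split and a seeded,
# deterministic Platt sigmoid for coding probabilities.

# Platt (1999) sigmoid fit P(y=1|f) = 1/(1+exp(A f + B)), Newton iterations
# with the Lin, Lin & Weng (2007) safeguards.
platt_fit <- function(decision, is_pos, max_iter = 100L) {
  prior1 <- sum(is_pos)
  prior0 <- sum(!is_pos)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(is_pos, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  f <- decision
  fApB <- A * f + B
  nll <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- nll(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- nll(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA
        B <- newB
        fval <- newf
        break
      }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

platt_prob <- function(decision, platt) {
  fApB <- platt$A * decision + platt$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

fit_scaler <- function(X) {
  list(min = apply(X, 2L, min), max = apply(X, 2L, max))
}

apply_scaler <- function(X, scaler) {
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1 # constant training features map to a constant
  sweep(sweep(X, 2L, scaler$min), 2L, rng, "/") * 2 - 1
}

# decision values oriented so that positive = coding
coding_decision <- function(svm_fit, X) {
  pr <- stats::predict(svm_fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  d <- as.numeric(dv[, 1L])
  lev <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
  if (lev[1L] != "coding") d <- -d
  d
}

features_to_matrix <- function(features) {
  stopifnot(is.data.frame(features), "id" %in% names(features))
  X <- as.matrix(features[setdiff(names(features), c("id", "label"))])
  storage.mode(X) <- "double"
  rownames(X) <- features$id
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("Non-finite feature value: transcript '%s', feature '%s'.",
                  rownames(X)[bad[1L, 1L]], colnames(X)[bad[1L, 2L]]))
  }
  X
}

#' Fit the RBF-SVM coding-potential classifier
#'
#' Scales every feature to `[-1, 1]` (min/max fitted on the training split
#' only), trains a radial-basis-function SVM (libsvm via e1071) with the
#' given `C` and `gamma`, and fits a Platt sigmoid on cross-validated
#' decision values so predictions carry a coding probability. The
#' calibration folds are drawn from a seeded RNG, making the whole fit
#' deterministic.
#'
#' @param features A tibble with an `id` column, a `label` column over
#'   `{"coding", "noncoding"}` (or pass `labels` separately), and numeric
#'   feature columns.
#' @param labels Optional character vector of labels aligned with
#'   `features` rows; overrides a `label` column.
#' @param C,gamma RBF-SVM hyperparameters (defaults 300 and 0.4).
#' @param scaling `"minmax_symmetric"` (default) or `"none"`.
#' @param threshold Decision threshold on the coding probability
#'   (default 0.5).
#' @param probability Fit the Platt calibration (default `TRUE`); when
#'   `FALSE`, predictions expose the raw decision value as the score.
#' @param calibration_folds Folds for the calibration decision values
#'   (default 3).
#' @param seed Seed for the calibration fold assignment.
#' @return An object of class `coding_svm`.
#' @export
fit_coding_svm <- function(features, labels = NULL, C = 300, gamma = 0.4,
                           scaling = c("minmax_symmetric", "none"),
                           threshold = 0.5, probability = TRUE,
                           calibration_folds = 3L, seed = 1L) {
  scaling <- match.arg(scaling)
  if (C <= 0 || gamma <= 0) abort("`C` and `gamma` must be positive.")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  labels <- labels %||% features$label
  if (is.null(labels)) abort("Provide `labels` or a `label` column.")
  check_labels(labels)
  if (length(unique(labels)) < 2L) {
    abort("Training requires both classes; got a single class.")
  }
  if (min(table(labels)) < 2L) abort("Need >= 2 samples per class.")
  X <- features_to_matrix(features)
  stopifnot(nrow(X) == length(labels))
  y <- factor(labels, levels = c("coding", "noncoding"))

  scaler <- if (scaling == "minmax_symmetric") fit_scaler(X) else NULL
  Xs <- if (is.null(scaler)) X else apply_scaler(X, scaler)

  svm_fit <- e1071::svm(x = Xs, y = y, scale = FALSE, kernel = "radial",
                        cost = C, gamma = gamma)

  platt <- NULL
  if (probability) {
    folds <- with_local_seed(seed, {
      sample(rep_len(seq_len(calibration_folds), nrow(Xs)))
    })
    dec <- numeric(nrow(Xs))
    for (k in seq_len(calibration_folds)) {
      hold <- folds == k
      fit_k <- e1071::svm(x = Xs[!hold, , drop = FALSE], y = y[!hold],
                          scale = FALSE, kernel = "radial", cost = C,
                          gamma = gamma)
      dec[hold] <- coding_decision(fit_k, Xs[hold, , drop = FALSE])
    }
    platt <- platt_fit(dec, y == "coding")
  }

  structure(
    list(svm = svm_fit, scaler = scaler, platt = platt,
         feature_names = colnames(X),
         config = list(C = C, gamma = gamma, scaling = scaling,
                       threshold = threshold, probability = probability,
                       calibration_folds = as.integer(calibration_folds),
                       seed = as.integer(seed)),
         n_train = nrow(X), class_counts = table(labels)),
    class = "coding_svm")
}

#' Predict coding potential with a fitted classifier
#'
#' @param object A `coding_svm` from [fit_coding_svm()].
#' @param features A feature tibble whose feature columns match the
#'   training feature names exactly (a mismatch is an error listing the
#'   difference).
#' @param ... Unused.
#' @return A tibble with columns `id`, `label` (`"coding"` iff
#'   `coding_prob >= threshold`), `coding_prob` and `decision_value`.
#' @export
predict.coding_svm <- function(object, features, ...) {
  X <- features_to_matrix(features)
  have <- colnames(X)
  want <- object$feature_names
  if (!identical(have, want)) {
    miss <- setdiff(want, have)
    extra <- setdiff(have, want)
    msg <- "Feature names do not match the trained model."
    if (length(miss)) msg <- paste0(msg, " Missing: ",
                                    paste(utils::head(miss, 5L), collapse = ", "), ".")
    if (length(extra)) msg <- paste0(msg, " Unexpected: ",
                                     paste(utils::head(extra, 5L), collapse = ", "), ".")
    if (!length(miss) && !length(extra)) msg <- paste(msg, "Column order differs.")
    abort(msg)
  }
  Xs <- if (is.null(object$scaler)) X else apply_scaler(X, object$scaler)
  dec <- coding_decision(object$svm, Xs)
  prob <- if (is.null(object$platt)) {
    1 / (1 + exp(-dec)) # uncalibrated squash of the decision value
  } else {
    platt_prob(dec, object$platt)
  }
  tibble(id = features$id,
         label = ifelse(prob >= object$config$threshold, "coding", "noncoding"),
         coding_prob = prob,
         decision_value = dec)
}

#' @export
print.coding_svm <- function(x, ...) {
  cat(sprintf("RBF-SVM coding-potential classifier: %d features, %d training samples (C=%g, gamma=%g)\n",
              length(x$feature_names), x$n_train, x$config$C, x$config$gamma))
  invisible(x)
}

#' Tidy a fitted coding-potential classifier
#'
#' @param x A `coding_svm`.
#' @param ... Unused.
#' @return One row per feature: name and the training min/max used for
#'   scaling.
#' @export
tidy.coding_svm <- function(x, ...) {
  tibble(feature = x$feature_names,
         train_min = if (is.null(x$scaler)) NA_real_ else unname(x$scaler$min),
         train_max = if (is.null(x$scaler)) NA_real_ else unname(x$scaler$max))
}

#' Glance at a fitted coding-potential classifier
#'
#' @param x A `coding_svm`.
#' @param ... Unused.
#' @return A one-row tibble of fit summaries.
#' @export
glance.coding_svm <- function(x, ...) {
  tibble(n_train = x$n_train,
         n_features = length(x$feature_names),
         n_support_vectors = x$svm$tot.nSV,
         C = x$config$C, gamma = x$config$gamma,
         calibrated = !is.null(x$platt))
}
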