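#' Implicit calibration: surrogate-augmented classifiers (predictive mode)
#'
#' In predictive mode the radiome is not explicitly corrected; instead the
#' classifier receives the qualified surrogates as additional covariates and
#' calibrates implicitly, `b-hat = f(r, s_qualified)`. Variants:
#'
#' * `technome_glm` — logistic regression on the standardised radiome
#'   features plus the union of the per-feature qualified surrogate sets.
#'   With all-empty sets this reduces *exactly* to `glm_features_only`.
#' * `glm_features_only` / `rf_features_only` — uncalibrated baselines.
#' * `naive_glm` — features plus surrogates chosen by mRMR (against the
#'   label) and best-subset AIC, no qualification.
#' * `naive_rf` — random forest on features plus all surrogates.
#' * `ravel_like_pred` — features plus the retained principal components of
#'   the surrogate matrix.
#'
#' Logistic fits are unpenalised; on separation or non-convergence a minimal
#' ridge (`lambda = 1e-6`) fallback is used with a warning. All covariates
#' are z-scored with training statistics.
#'
#' @param cohort A [tn_cohort()] supplying training rows.
#' @param sets A `tn_sets` from [select_qualified()] (used by
#'   `technome_glm`).
#' @param variant One of the variants above.
#' @param rows Optional training row indices.
#' @param k_max mRMR/AIC budget for `naive_glm`.
#' @param seed Seed for the random-forest variants.
#' @param var_explained Variance fraction for `ravel_like_pred` components.
#' @param n_trees Trees for the random-forest variants.
#' @return A `tn_pred` model for [predict_proba()].
#' @export
fit_predictive <- function(cohort, sets = NULL,
                           variant = c("technome_glm", "glm_features_only",
                                       "rf_features_only", "naive_glm",
                                       "naive_rf", "ravel_like_pred"),
                           rows = NULL, k_max = 10, seed = 1,
                           var_explained = 0.95, n_trees = 500) {
  variant <- match.arg(variant)
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  b <- label_vector(cohort, rows)
  if (length(unique(b)) < 2) abort("training labels contain a single class")

  pca <- NULL
  if (variant == "technome_glm") {
    stopifnot(inherits(sets, "tn_sets"))
    surr <- qualified_union(sets)
  } else if (variant %in% c("glm_features_only", "rf_features_only")) {
    surr <- character()
  } else if (variant == "naive_glm") {
    surr <- naive_pred_select(R, S, b, k_max)
  } else if (variant == "naive_rf") {
    surr <- colnames(S)
  } else { # ravel_like_pred
    center <- colMeans(S)
    scl <- apply(S, 2, sd)
    Xs <- standardise_cols(S, center, scl)
    sv <- svd(Xs)
    ev <- sv$d^2 / sum(sv$d^2)
    N <- which(cumsum(ev) >= var_explained - 1e-12)[1]
    N <- min(N, sum(sv$d^2 > max(sv$d^2) * 1e-12), na.rm = TRUE)
    pca <- list(center = center, scale = scl,
                V = sv$v[, seq_len(N), drop = FALSE])
    surr <- character()
  }

  X <- build_design(R, S, colnames(R), surr, pca)
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  Xz <- standardise_cols(X, center, scl)

  model <- list(variant = variant, features = colnames(R),
                surrogates_used = surr, center = center, scale = scl,
                pca = pca)
  if (variant %in% c("rf_features_only", "naive_rf")) {
    model$forest <- withr::with_seed(sub_seed(seed, 97L), {
      randomForest::randomForest(x = Xz, y = factor(b, levels = c(0, 1)),
                                 ntree = n_trees)
    })
  } else {
    model$beta <- fit_logistic(Xz, b)
  }
  model <- structure(model, class = "tn_pred")
  model$train_scores <- predict_proba(model, cohort, rows = rows)
  model
}

build_design <- function(R, S, features, surr, pca) {
  X <- R[, features, drop = FALSE]
  if (length(surr)) X <- cbind(X, S[, surr, drop = FALSE])
  if (!is.null(pca)) {
    Xs <- standardise_cols(S[, names(pca$center), drop = FALSE],
                           pca$center, pca$scale)
    scores <- Xs %*% pca$V
    colnames(scores) <- paste0("svd", seq_len(ncol(scores)))
    X <- cbind(X, scores)
  }
  X
}

# unpenalised logistic fit; minimal ridge fallback on separation
fit_logistic <- function(Xz, b) {
  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(`(Intercept)` = 1, Xz), b, family = binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  if (separated || anyNA(beta)) {
    warn("separation or rank deficiency in logistic fit; using ridge (1e-6)")
    beta <- ridge_logistic(Xz, b, lambda = 1e-6)
  }
  beta
}

# L2-penalised IRLS (intercept unpenalised); the minimal-ridge fallback for
# separated or rank-deficient logistic designs
ridge_logistic <- function(Xz, b, lambda = 1e-6, maxit = 30, tol = 1e-9) {
  X <- cbind(`(Intercept)` = 1, Xz)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (b - mu) / w
    XtW <- t(X * w)
    new_beta <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) solve(XtW %*% X + pen + diag(1e-8, p), XtW %*% z)
    )
    new_beta <- drop(new_beta)
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) break
  }
  setNames(beta, colnames(X))
}

# naive predictive selection: mRMR against the label, then best-subset AIC
# of the logistic model (features always included)
naive_pred_select <- function(R, S, b, k_max) {
  cand <- mrmr_rank(b, S, k_max)
  n <- length(b)
  dev_aic <- function(surr) {
    X <- cbind(R, S[, surr, drop = FALSE])
    X <- standardise_cols(X, colMeans(X), apply(X, 2, sd))
    fit <- suppressWarnings(glm.fit(cbind(1, X), b, family = binomial()))
    fit$deviance + 2 * (ncol(X) + 1)
  }
  best <- list(aic = dev_aic(character()), surr = character())
  if (length(cand) > 10) cand <- cand[1:10]
  for (mask in seq_len(2^length(cand) - 1)) {
    surr <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0]
    aic <- dev_aic(surr)
    if (aic < best$aic - 1e-12) best <- list(aic = aic, surr = surr)
  }
  best$surr
}

#' Predict class-1 probabilities
#'
#' Applies a fitted predictive model to (possibly unseen) rows using the
#' training standardisation stored in the model; the model is never refitted.
#'
#' @param model A `tn_pred` from [fit_predictive()].
#' @param cohort A [tn_cohort()].
#' @param rows Optional row indices.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, cohort, rows = NULL) {
  stopifnot(inherits(model, "tn_pred"))
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  need <- setdiff(c(model$features, model$surrogates_used,
                    names(model$pca$center)), c(colnames(R), colnames(S)))
  if (length(need)) abort(paste("missing column:", need[1]))
  X <- build_design(R, S, model$features, model$surrogates_used, model$pca)
  Xz <- standardise_cols(X[, names(model$center), drop = FALSE],
                         model$center, model$scale)
  if (!is.null(model$forest)) {
    unname(predict(model$forest, newdata = Xz, type = "prob")[, "1"])
  } else {
    eta <- model$beta[1] + drop(Xz %*% model$beta[colnames(Xz)])
    stats::plogis(eta)
  }
}

#' Rank-based AUC with midrank tie handling
#'
#' The Mann-Whitney statistic: the probability that a random positive scores
#' above a random negative, with ties counted one half.
#'
#' @param scores Numeric scores (higher = more class-1).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("auc_score needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.tn_pred <- function(x, ...) {
  cat(sprintf("<tn_pred: %s> %d features + %d surrogate column(s)%s\n",
              x$variant, length(x$features), length(x$surrogates_used),
              if (!is.null(x$pca)) sprintf(" + %d components", ncol(x$pca$V))
              else ""))
  invisible(x)
}

#' @method tidy tn_pred
#' @export
tidy.tn_pred <- function(x, ...) {
  if (is.null(x$beta)) {
    abort("tidy() is only defined for the linear predictive variants")
  }
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @method glance tn_pred
#' @export
glance.tn_pred <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 n_features = length(x$features),
                 n_surrogates = length(x$surrogates_used),
                 n_components = if (is.null(x$pca)) 0L else ncol(x$pca$V))
}
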