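#' Explicit feature calibration (stabilisation mode)
#'
#' All explicit calibrations share one contract: a model `g_j` is fitted per
#' radiome feature on training rows, and calibration subtracts its prediction,
#' `r*_ij = r_ij - g_j(s_i)`, where surrogate deviations are always taken
#' against the *training* surrogate means stored in the model (never
#' re-centred on test data). Variants:
#'
#' * `fit_technome_stabilisation()` — per feature, ordinary least squares of
#'   the feature on the centred *qualified* surrogates (covariate
#'   adjustment). Features with an empty qualified set get the identity
#'   calibration.
#' * `fit_naive_glm()` — same regression, but surrogates are chosen naively
#'   per feature by mRMR (correlation-based MID variant) followed by
#'   best-subset selection under AIC.
#' * `fit_naive_rf()` — a random-forest regression of the feature deviation
#'   on the deviations of *all* surrogates.
#' * `fit_ravel_like()` — feature-level singular-value-decomposition
#'   calibration: column-standardise the surrogates, keep the smallest
#'   number of right-singular components explaining at least `var_explained`
#'   of training variance, fit each feature on those components (plus the
#'   label term, protecting biological signal), and subtract only the
#'   component part.
#'
#' @param cohort A [tn_cohort()] supplying training data.
#' @param sets A `tn_sets` from [select_qualified()].
#' @param rows Optional training row indices (default: all rows).
#' @return A `tn_stab` model usable with [apply_calibration()].
#' @name stabilisation
NULL

new_stab <- function(variant, features, per_feature, extra = list()) {
  structure(c(list(variant = variant, features = features,
                   per_feature = per_feature), extra),
            class = "tn_stab")
}

# OLS of y on centred columns `surr` of S; drops aliased columns with a
# warning. Returns NULL for an empty surrogate list (identity calibration).
fit_feature_ols <- function(y, S, surr) {
  if (length(surr) == 0) return(NULL)
  means <- colMeans(S[, surr, drop = FALSE])
  D <- sweep(S[, surr, drop = FALSE], 2, means)
  fit <- lm.fit(cbind(`(Intercept)` = 1, D), y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    keep <- names(beta)[-1][!is.na(beta[-1])]
    warn(sprintf("dropping %d collinear surrogate column(s)",
                 sum(is.na(beta))))
    return(fit_feature_ols(y, S, keep))
  }
  list(surrogates = surr, coef = beta, means = means,
       residuals = fit$residuals)
}

#' @rdname stabilisation
#' @export
fit_technome_stabilisation <- function(cohort, sets, rows = NULL) {
  stopifnot(inherits(sets, "tn_sets"))
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  per <- purrr::map(colnames(R), function(j) {
    surr <- sets$sets[[j]] %||% character()
    if (length(surr) >= nrow(R) - 1 && length(surr) > 0) {
      abort(sprintf("feature %s: %d qualified surrogates for %d rows (rank guard)",
                    j, length(surr), nrow(R)))
    }
    fit_feature_ols(R[, j], S, surr)
  })
  names(per) <- colnames(R)
  new_stab("technome", colnames(R), per)
}

# correlation-based mRMR (MID: relevance minus mean redundancy), greedy,
# deterministic tie-break by surrogate name
mrmr_rank <- function(y, S, k_max) {
  rel <- abs(apply(S, 2, function(s) safe_cor(s, y)))
  cand <- colnames(S)
  picked <- character()
  while (length(picked) < min(k_max, ncol(S))) {
    rest <- setdiff(cand, picked)
    score <- vapply(rest, function(l) {
      red <- if (length(picked) == 0) 0 else {
        mean(abs(vapply(picked, function(p) safe_cor(S[, l], S[, p]),
                        numeric(1))))
      }
      rel[[l]] - red
    }, numeric(1))
    ord <- order(-score, rest)
    picked <- c(picked, rest[ord[1]])
  }
  picked
}

# gaussian AIC from residual sum of squares (additive constant dropped);
# used for best-subset comparisons only
rss_aic <- function(rss, n, k) n * log(rss / n) + 2 * (k + 1)

best_subset_aic <- function(y, S, candidates) {
  n <- length(y)
  best <- list(aic = rss_aic(sum((y - mean(y))^2), n, 0), surr = character())
  if (length(candidates) == 0) return(best$surr)
  stopifnot(length(candidates) <= 16)
  for (mask in seq_len(2^length(candidates) - 1)) {
    surr <- candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) > 0]
    D <- sweep(S[, surr, drop = FALSE], 2, colMeans(S[, surr, drop = FALSE]))
    fit <- lm.fit(cbind(1, D), y)
    rank_ok <- !anyNA(fit$coefficients)
    if (!rank_ok) next
    aic <- rss_aic(sum(fit$residuals^2), n, length(surr))
    if (aic < best$aic - 1e-12 ||
        (abs(aic - best$aic) <= 1e-12 && length(surr) < length(best$surr))) {
      best <- list(aic = aic, surr = surr)
    }
  }
  best$surr
}

#' @rdname stabilisation
#' @param k_max Maximum number of mRMR-ranked candidates entering the AIC
#'   best-subset search (exhaustive for `k_max <= 10`).
#' @export
fit_naive_glm <- function(cohort, rows = NULL, k_max = 10) {
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  per <- purrr::map(colnames(R), function(j) {
    cand <- mrmr_rank(R[, j], S, k_max)
    surr <- if (k_max <= 10) {
      best_subset_aic(R[, j], S, cand)
    } else {
      forward_aic(R[, j], S, cand)
    }
    fit_feature_ols(R[, j], S, surr)
  })
  names(per) <- colnames(R)
  new_stab("naive_glm", colnames(R), per)
}

forward_aic <- function(y, S, candidates) {
  n <- length(y)
  current <- character()
  current_aic <- rss_aic(sum((y - mean(y))^2), n, 0)
  repeat {
    rest <- setdiff(candidates, current)
    if (!length(rest)) break
    aics <- vapply(rest, function(l) {
      surr <- c(current, l)
      D <- sweep(S[, surr, drop = FALSE], 2,
                 colMeans(S[, surr, drop = FALSE]))
      fit <- lm.fit(cbind(1, D), y)
      if (anyNA(fit$coefficients)) Inf else
        rss_aic(sum(fit$residuals^2), n, length(surr))
    }, numeric(1))
    if (min(aics) >= current_aic) break
    current <- c(current, rest[which.min(aics)])
    current_aic <- min(aics)
  }
  current
}

#' @rdname stabilisation
#' @param seed Integer seed for the random forest.
#' @param n_trees Number of trees.
#' @export
fit_naive_rf <- function(cohort, rows = NULL, seed = 1, n_trees = 500) {
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  s_means <- colMeans(S)
  D <- sweep(S, 2, s_means)
  per <- purrr::map(seq_len(ncol(R)), function(jx) {
    y <- R[, jx]
    forest <- withr::with_seed(sub_seed(seed, jx), {
      suppressWarnings(
        randomForest::randomForest(x = D, y = y - mean(y), ntree = n_trees)
      )
    })
    list(surrogates = colnames(S), forest = forest, means = s_means)
  })
  names(per) <- colnames(R)
  new_stab("naive_rf", colnames(R), per)
}

#' @rdname stabilisation
#' @param var_explained Fraction of training surrogate variance the retained
#'   singular components must reach (0.95 by default).
#' @param protect_label Include the label as a covariate in the per-feature
#'   fit (its contribution is never subtracted), so biological signal is not
#'   removed along with the technical components.
#' @export
fit_ravel_like <- function(cohort, rows = NULL, var_explained = 0.95,
                           protect_label = TRUE) {
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  b <- label_vector(cohort, rows)
  if (nrow(R) < 3) abort("fit_ravel_like needs at least 3 training rows")
  center <- colMeans(S)
  scale <- apply(S, 2, sd)
  Xs <- standardise_cols(S, center, scale)
  sv <- svd(Xs)
  ev <- sv$d^2 / sum(sv$d^2)
  nonnull <- sv$d^2 > max(sv$d^2) * 1e-12
  cum <- cumsum(ev)
  N <- which(cum >= var_explained - 1e-12)[1]
  if (is.na(N)) N <- sum(nonnull)
  N <- min(N, sum(nonnull))
  V <- sv$v[, seq_len(N), drop = FALSE]
  scores <- Xs %*% V
  colnames(scores) <- paste0("svd", seq_len(N))
  per <- purrr::map(colnames(R), function(j) {
    X <- cbind(`(Intercept)` = 1, scores)
    if (protect_label) X <- cbind(X, label = b)
    fit <- lm.fit(X, R[, j])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    list(coef = beta, residuals = fit$residuals)
  })
  names(per) <- colnames(R)
  new_stab("ravel_like", colnames(R), per,
           extra = list(center = center, scale = scale, V = V, n_components = N,
                        var_explained_reached = cum[N],
                        eigenshare = ev, protect_label = protect_label))
}

#' Apply an explicit calibration to (possibly unseen) data
#'
#' Subtracts each fitted `g_j` from the respective feature. All centring and
#' standardisation uses statistics stored at training time.
#'
#' @param model A `tn_stab` model.
#' @param cohort A [tn_cohort()] holding the rows to calibrate (training or
#'   unseen test rows).
#' @return A [tn_cohort()] with the radiome replaced by calibrated values.
#' @export
apply_calibration <- function(model, cohort) {
  stopifnot(inherits(model, "tn_stab"))
  R <- radiome_matrix(cohort)
  S <- surrogate_matrix(cohort)
  missing_f <- setdiff(model$features, colnames(R))
  if (length(missing_f)) abort(paste("missing feature column:", missing_f[1]))
  Rstar <- R
  for (j in model$features) {
    pf <- model$per_feature[[j]]
    if (model$variant %in% c("technome", "naive_glm")) {
      if (is.null(pf)) next  # identity calibration
      need <- setdiff(pf$surrogates, colnames(S))
      if (length(need)) abort(paste("missing surrogate column:", need[1]))
      D <- sweep(S[, pf$surrogates, drop = FALSE], 2, pf$means)
      g <- pf$coef[1] + drop(D %*% pf$coef[-1])
    } else if (model$variant == "naive_rf") {
      need <- setdiff(pf$surrogates, colnames(S))
      if (length(need)) abort(paste("missing surrogate column:", need[1]))
      D <- sweep(S[, pf$surrogates, drop = FALSE], 2, pf$means)
      # only the predicted deviation is subtracted: the forest models the
      # feature's departure from its training mean, not its location
      g <- unname(predict(pf$forest, newdata = D))
    } else if (model$variant == "ravel_like") {
      need <- setdiff(names(model$center), colnames(S))
      if (length(need)) abort(paste("missing surrogate column:", need[1]))
      Xs <- standardise_cols(S[, names(model$center), drop = FALSE],
                             model$center, model$scale)
      scores <- Xs %*% model$V
      k <- ncol(scores)
      g <- pf$coef[1] + drop(scores %*% pf$coef[1 + seq_len(k)])
    } else {
      abort(paste("unknown variant", model$variant))
    }
    Rstar[, j] <- R[, j] - g
  }
  out <- cohort
  out$radiome <- tibble::as_tibble(cbind(tibble::tibble(id = cohort$radiome$id),
                                         tibble::as_tibble(Rstar)))
  out
}

#' Stabilisation performance: mean variance reduction
#'
#' `Perf_j = 1 - var(r*_j) / var(r_j)` per feature, averaged over features;
#' evaluated on held-out rows. Negative values mean the calibration added
#' variance. Features with zero pre-calibration variance are skipped with a
#' warning.
#'
#' @param before,after [tn_cohort()]s (or radiome matrices) before and after
#'   calibration, matched rows and features.
#' @return Mean per-feature variance reduction (scalar).
#' @export
stabilisation_performance <- function(before, after) {
  B <- if (inherits(before, "tn_cohort")) radiome_matrix(before) else before
  A <- if (inherits(after, "tn_cohort")) radiome_matrix(after) else after
  stopifnot(identical(dim(B), dim(A)))
  v0 <- apply(B, 2, var)
  if (any(v0 == 0)) {
    warn(sprintf("skipping %d zero-variance feature(s)", sum(v0 == 0)))
  }
  keep <- v0 > 0
  mean(1 - apply(A[, keep, drop = FALSE], 2, var) / v0[keep])
}

#' @export
print.tn_stab <- function(x, ...) {
  sel <- if (x$variant == "ravel_like") {
    sprintf("%d components (%.1f%% variance)", x$n_components,
            100 * x$var_explained_reached)
  } else {
    paste0("|S| = ", paste(vapply(x$per_feature, function(p) {
      if (is.null(p)) 0L else length(p$surrogates)
    }, integer(1)), collapse = ","))
  }
  cat(sprintf("<tn_stab: %s> %d features, %s\n", x$variant,
              length(x$features), sel))
  invisible(x)
}

#' @method tidy tn_stab
#' @export
tidy.tn_stab <- function(x, ...) {
  if (x$variant == "ravel_like") {
    return(purrr::map_dfr(x$features, function(j) {
      cf <- x$per_feature[[j]]$coef
      tibble::tibble(feature = j, term = names(cf), estimate = unname(cf))
    }))
  }
  purrr::map_dfr(x$features, function(j) {
    pf <- x$per_feature[[j]]
    if (is.null(pf) || is.null(pf$coef)) {
      return(tibble::tibble(feature = j, term = character(),
                            estimate = numeric()))
    }
    tibble::tibble(feature = j, term = names(pf$coef),
                   estimate = unname(pf$coef))
  })
}

#' Export a fitted calibration model as JSON
#'
#' Serialises the portable parts of a stabilisation model — variant,
#' per-feature surrogate lists, coefficients and training means, and for the
#' SVD variant the column statistics and component vectors — so a
#' calibration can be archived or applied outside R. Random-forest models
#' carry no closed-form parameters and are rejected.
#'
#' @param model A `tn_stab` model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_model_json <- function(model, path) {
  stopifnot(inherits(model, "tn_stab"))
  if (model$variant == "naive_rf") {
    abort("random-forest models have no closed-form JSON representation")
  }
  payload <- list(variant = model$variant, features = model$features)
  if (model$variant == "ravel_like") {
    payload$center <- as.list(model$center)
    payload$scale <- as.list(model$scale)
    payload$n_components <- model$n_components
    payload$components <- apply(model$V, 2, identity, simplify = FALSE)
    payload$coefficients <- purrr::map(model$per_feature,
                                       ~as.list(.x$coef))
  } else {
    payload$per_feature <- purrr::map(model$per_feature, function(pf) {
      if (is.null(pf)) return(list(identity = TRUE))
      list(surrogates = pf$surrogates, coefficients = as.list(pf$coef),
           training_means = as.list(pf$means))
    })
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
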