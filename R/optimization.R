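#' Configure the technome construction loss
#'
#' The construction loop minimises `L(theta) = L_train(S^q(theta)) +
#' L_calib(theta)` over the criterion weights. `L_train` is the negative
#' training performance (mean explained variance in stabilisation mode,
#' training AUC — in-sample or inner 10-fold CV — in predictive mode);
#' `L_calib = -alpha / sum(theta)` rewards small weights, i.e. admits only
#' highly qualified surrogates.
#'
#' `alpha` trades training performance against calibration pressure and is
#' interpreted on the same scale as `L_train` (which this package keeps on
#' the fraction scale, AUC and R-squared in `[0, 1]`). The preset configs use
#' `alpha = 0.002` (predictive) and `0.001` (stabilisation) — the
#' fraction-scale equivalents of 0.2 / 0.1 on a percentage performance scale.
#'
#' @param mode `"stabilisation"` or `"predictive"`.
#' @param alpha Calibration-loss scale, >= 0. `0` switches calibration
#'   pressure off.
#' @param criteria Active qualification criteria; inactive criteria are
#'   dropped from both the combined score and the weight sum.
#' @param bounds Length-2 numeric, per-weight lower/upper bound.
#' @param inner Training-loss evaluation in predictive mode: `"in_sample"`
#'   AUC or `"cv10_inner"` (inner 10-fold CV AUC, pooled scores).
#' @param q_min Qualification threshold (1.0 throughout; configurable for
#'   sweeps only).
#' @param calib_form `"inverse"` for `-alpha / sum(theta)`; `"literal"` for
#'   the alternative `-alpha * sum(theta)` form.
#' @param init_points,n_iter,kappa Bayesian-optimisation budget and
#'   exploration weight (reference settings: 8 initial points, 500
#'   iterations, kappa 5; the presets use a reduced 8 + 50 budget).
#' @param optimizer `"bayes"` or the `"random"`-search fallback.
#' @return A `tn_loss_config` list.
#' @export
loss_config <- function(mode = c("predictive", "stabilisation"),
                        alpha = 0.002,
                        criteria = c("invivo", "insilico", "invitro",
                                     "orthog"),
                        bounds = c(0.01, 10),
                        inner = c("in_sample", "cv10_inner"),
                        q_min = 1.0,
                        calib_form = c("inverse", "literal"),
                        init_points = 8, n_iter = 50, kappa = 5,
                        optimizer = c("bayes", "random")) {
  mode <- match.arg(mode)
  inner <- match.arg(inner)
  calib_form <- match.arg(calib_form)
  optimizer <- match.arg(optimizer)
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (alpha < 0) abort("`alpha` must be >= 0")
  if (length(criteria) < 1) abort("at least one active criterion is required")
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1])
  structure(list(mode = mode, alpha = alpha, criteria = criteria,
                 bounds = bounds, inner = inner, q_min = q_min,
                 calib_form = calib_form, init_points = init_points,
                 n_iter = n_iter, kappa = kappa, optimizer = optimizer),
            class = "tn_loss_config")
}

#' Training losses
#'
#' `l_train_stabilisation()` returns minus the mean per-feature explained
#' variance (R-squared) of the qualified-surrogate regressions; empty sets
#' contribute 0. `l_train_predictive()` returns minus the training AUC of
#' the surrogate-augmented logistic model, either in-sample or by inner
#' 10-fold cross-validation with pooled held-out scores. Loss evaluations
#' use the ridge-stabilised (`lambda = 1e-6`) logistic solver throughout:
#' inner folds separate routinely once many surrogates are admitted, and the
#' minimal ridge leaves non-separated fits unchanged to numerical precision.
#'
#' @param cohort A [tn_cohort()].
#' @param sets A `tn_sets`.
#' @param rows Training row indices (default all).
#' @return A scalar loss (more negative = better training performance).
#' @export
l_train_stabilisation <- function(cohort, sets, rows = NULL) {
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  r2 <- vapply(colnames(R), function(j) {
    surr <- sets$sets[[j]] %||% character()
    if (length(surr) == 0) return(0)
    y <- R[, j]
    fit <- suppressWarnings(fit_feature_ols(y, S, surr))
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    1 - sum(fit$residuals^2) / tss
  }, numeric(1))
  -mean(r2)
}

#' @rdname l_train_stabilisation
#' @param inner `"in_sample"` or `"cv10_inner"`.
#' @param seed Seed for the inner folds.
#' @export
l_train_predictive <- function(cohort, sets, rows = NULL,
                               inner = c("in_sample", "cv10_inner"),
                               seed = 1) {
  inner <- match.arg(inner)
  rows <- rows %||% seq_len(nrow(cohort$labels))
  b <- label_vector(cohort, rows)
  if (length(unique(b)) < 2) abort("training labels contain a single class")
  R <- radiome_matrix(cohort)
  S <- surrogate_matrix(cohort)
  surr <- qualified_union(sets)
  X <- build_design(R, S, colnames(R), surr, pca = NULL)
  fit_score <- function(tr, te) {
    Xtr <- X[tr, , drop = FALSE]
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, sd)
    beta <- ridge_logistic(standardise_cols(Xtr, ctr, scl), b[match(tr, rows)])
    Xte <- standardise_cols(X[te, , drop = FALSE], ctr, scl)
    stats::plogis(beta[1] + drop(Xte %*% beta[-1]))
  }
  if (inner == "in_sample") return(-auc_score(fit_score(rows, rows), b))
  folds <- inner_folds(b, k = 10, seed = seed)
  scores <- numeric(length(rows))
  for (f in seq_len(max(folds))) {
    tr <- rows[folds != f]
    te <- rows[folds == f]
    if (length(unique(b[folds != f])) < 2) next
    scores[folds == f] <- fit_score(tr, te)
  }
  -auc_score(scores, b)
}

# label-stratified fold ids for inner CV (rows are already grouped upstream:
# the outer split keeps patients intact, inner CV is a training-side device)
inner_folds <- function(b, k = 10, seed = 1) {
  withr::with_seed(seed, {
    out <- integer(length(b))
    counter <- 0L
    for (cl in sort(unique(b))) {
      idx <- which(b == cl)
      idx <- idx[sample.int(length(idx))]
      out[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
    out
  })
}

#' Calibration loss
#'
#' `-alpha / sum(theta)` over the active weights (Eq.-10 form): smaller
#' weight sums — stricter qualification — are rewarded. The `"literal"` form
#' `-alpha * sum(theta)` is also available (it instead rewards large
#' weights; see the methods vignette for why the inverse form is the
#' default).
#'
#' @param theta Named non-negative weights (active criteria only).
#' @param alpha Scale parameter, >= 0.
#' @param form `"inverse"` or `"literal"`.
#' @param lo_sum Singularity guard: `sum(theta)` below this errors.
#' @return A scalar, <= 0 for the inverse form.
#' @export
l_calib <- function(theta, alpha, form = c("inverse", "literal"),
                    lo_sum = 0.01 * length(theta)) {
  form <- match.arg(form)
  if (alpha < 0) abort("`alpha` must be >= 0")
  if (alpha == 0) return(0)
  s <- sum(theta)
  if (form == "literal") return(-alpha * s)
  if (s < lo_sum) abort("sum(theta) below the lower-bound guard")
  -alpha / s
}

#' Gaussian-process Bayesian optimisation (UCB acquisition)
#'
#' Minimises a deterministic black-box objective over a box. A
#' squared-exponential GP with a nugget (the qualification objective is
#' piecewise constant, so observations are treated as noisy) is fitted to
#' all evaluations; the next point minimises the lower confidence bound
#' `mu - kappa * sd` over a seeded random candidate set plus jittered copies
#' of the incumbent. Fully deterministic given the seed. A pure
#' random-search fallback is available for flat or adversarial landscapes.
#'
#' @param objective Function taking a named numeric vector and returning a
#'   scalar loss. Non-finite returns are penalised (worst observed + 1) and
#'   logged in the trace.
#' @param bounds Named list; each element `c(lo, hi)` for one dimension.
#' @param seed Integer seed.
#' @param init_points Number of uniform initial evaluations.
#' @param n_iter Number of model-guided iterations.
#' @param kappa Exploration weight of the confidence bound.
#' @param method `"bayes"` or `"random"`.
#' @return A `tn_opt`: `best_par`, `best_loss`, and the evaluation `trace`
#'   (one row per evaluation, in order).
#' @export
bayes_optimize <- function(objective, bounds, seed = 1, init_points = 8,
                           n_iter = 500, kappa = 5,
                           method = c("bayes", "random")) {
  method <- match.arg(method)
  d <- length(bounds)
  stopifnot(d >= 1, !is.null(names(bounds)))
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  stopifnot(all(is.finite(lo)), all(is.finite(hi)), all(hi > lo))

  evals_x <- matrix(numeric(0), ncol = d, dimnames = list(NULL, names(bounds)))
  evals_y <- numeric(0)
  bad <- logical(0)
  eval_at <- function(x) {
    names(x) <- names(bounds)
    y <- objective(x)
    ok <- is.finite(y)
    if (!ok) {
      y <- if (any(is.finite(evals_y))) max(evals_y[is.finite(evals_y)]) + 1 else 1e6
      warn("objective returned a non-finite value; penalised")
    }
    evals_x <<- rbind(evals_x, x)
    evals_y <<- c(evals_y, y)
    bad <<- c(bad, !ok)
    invisible(y)
  }

  withr::with_seed(seed, {
    for (i in seq_len(init_points)) eval_at(lo + runif(d) * (hi - lo))
    if (method == "random") {
      for (i in seq_len(n_iter)) eval_at(lo + runif(d) * (hi - lo))
    } else {
      for (i in seq_len(n_iter)) {
        Xn <- sweep(sweep(evals_x, 2, lo), 2, hi - lo, "/")
        mu_y <- mean(evals_y)
        sd_y <- sd(evals_y)
        if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
        yz <- (evals_y - mu_y) / sd_y
        gp <- gp_fit(Xn, yz)
        n_cand <- 256L
        cand <- matrix(runif(n_cand * d), ncol = d)
        inc <- Xn[which.min(evals_y), ]
        jit <- matrix(rep(inc, each = 32L), ncol = d) +
          matrix(rnorm(32L * d, sd = 0.05), ncol = d)
        cand <- rbind(cand, pmin(pmax(jit, 0), 1))
        pred <- gp_predict(gp, cand)
        lcb <- pred$mu - kappa * pred$sd
        xn <- cand[which.min(lcb), ]
        eval_at(lo + xn * (hi - lo))
      }
    }
  })

  best <- which.min(evals_y)
  trace <- tibble::as_tibble(as.data.frame(evals_x))
  trace$loss <- evals_y
  trace$penalised <- bad
  trace$eval <- seq_along(evals_y)
  best_par <- setNames(as.numeric(evals_x[best, , drop = FALSE]),
                       colnames(evals_x))
  structure(list(best_par = best_par, best_loss = evals_y[best],
                 trace = trace, seed = seed, method = method),
            class = "tn_opt")
}

# SE-kernel GP with fixed lengthscale on unit-box inputs and a nugget for
# the step-function objective
gp_fit <- function(Xn, yz, lengthscale = 0.3, nugget = 1e-2) {
  K <- se_kernel(Xn, Xn, lengthscale)
  diag(K) <- diag(K) + nugget
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, yz, transpose = TRUE))
  list(X = Xn, L = L, alpha = alpha, lengthscale = lengthscale)
}

gp_predict <- function(gp, Xnew) {
  Ks <- se_kernel(Xnew, gp$X, gp$lengthscale)
  mu <- drop(Ks %*% gp$alpha)
  v <- backsolve(gp$L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu, sd = sqrt(s2))
}

se_kernel <- function(A, B, ls) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-0.5 * pmax(d2, 0) / ls^2)
}

#' @export
print.tn_opt <- function(x, ...) {
  cat(sprintf("<tn_opt: %s> %d evaluations, best loss %.4f at (%s)\n",
              x$method, nrow(x$trace), x$best_loss,
              paste(sprintf("%s=%.3g", names(x$best_par), x$best_par),
                    collapse = ", ")))
  invisible(x)
}

#' Construct a technome: qualification, weight optimisation, final fit
#'
#' Runs the full construction loop on training rows: compute the
#' qualification tensor once, minimise `L_train + L_calib` over the
#' criterion weights by Bayesian optimisation, select the qualified
#' surrogate sets at the optimal weights, and refit the final model
#' (stabilisation regressions or the surrogate-augmented classifier) on all
#' training rows.
#'
#' @param cohort A [tn_cohort()].
#' @param perturbation,phantom Optional auxiliary series for the in-silico /
#'   in-vitro criteria (must be present when those criteria are active).
#' @param config A [loss_config()].
#' @param rows Training row indices (default: all rows). All qualification
#'   statistics, weights and fits derive from these rows only.
#' @param seed Integer seed (optimiser and inner folds).
#' @return A `tn_technome`: qualification tensor, optimal weights `theta`,
#'   qualified `sets`, the fitted `model`, and the optimisation result
#'   `opt` whose trace carries the `l_train`/`l_calib` decomposition.
#' @export
construct_technome <- function(cohort, perturbation = NULL, phantom = NULL,
                               config = loss_config(), rows = NULL,
                               seed = 1) {
  stopifnot(inherits(config, "tn_loss_config"))
  qual <- qualify_surrogates(cohort, perturbation, phantom, rows = rows,
                             criteria = config$criteria)
  comp <- new.env(parent = emptyenv())
  comp$l_train <- numeric(0)
  comp$l_calib <- numeric(0)
  objective <- function(theta) {
    sets <- select_qualified(combine_q(qual, theta), config$q_min,
                             exclude = qual$degenerate)
    lt <- if (config$mode == "stabilisation") {
      l_train_stabilisation(cohort, sets, rows)
    } else {
      l_train_predictive(cohort, sets, rows, inner = config$inner,
                         seed = sub_seed(seed, 11L))
    }
    lc <- l_calib(theta, config$alpha, form = config$calib_form,
                  lo_sum = config$bounds[1] * length(theta))
    comp$l_train <- c(comp$l_train, lt)
    comp$l_calib <- c(comp$l_calib, lc)
    lt + lc
  }
  bounds <- purrr::map(setNames(config$criteria, config$criteria),
                       ~config$bounds)
  opt <- bayes_optimize(objective, bounds, seed = seed,
                        init_points = config$init_points,
                        n_iter = config$n_iter, kappa = config$kappa,
                        method = config$optimizer)
  opt$trace$l_train <- comp$l_train[seq_len(nrow(opt$trace))]
  opt$trace$l_calib <- comp$l_calib[seq_len(nrow(opt$trace))]
  theta <- opt$best_par
  sets <- select_qualified(combine_q(qual, theta), config$q_min,
                           exclude = qual$degenerate)
  model <- if (config$mode == "stabilisation") {
    suppressWarnings(fit_technome_stabilisation(cohort, sets, rows))
  } else {
    suppressWarnings(fit_predictive(cohort, sets, "technome_glm", rows = rows))
  }
  structure(list(mode = config$mode, qual = qual, theta = theta, sets = sets,
                 model = model, opt = opt, config = config, seed = seed),
            class = "tn_technome")
}

#' @export
print.tn_technome <- function(x, ...) {
  cat(sprintf("<tn_technome: %s mode>\n", x$mode))
  cat(sprintf("  theta: %s\n",
              paste(sprintf("%s=%.3g", names(x$theta), x$theta),
                    collapse = ", ")))
  cat(sprintf("  qualified surrogates: %s\n",
              paste(sprintf("%s=%d", names(x$sets$sets),
                            lengths(x$sets$sets)), collapse = ", ")))
  cat(sprintf("  best loss: %.4f (%d evaluations)\n", x$opt$best_loss,
              nrow(x$opt$trace)))
  invisible(x)
}

#' @method glance tn_technome
#' @export
glance.tn_technome <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    best_loss = x$opt$best_loss,
    n_evals = nrow(x$opt$trace),
    n_qualified = length(qualified_union(x$sets)),
    !!!setNames(as.list(x$theta), paste0("theta_", names(x$theta)))
  )
}
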