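# subset a cohort (and the patient-indexed parts of a perturbation series)
# to given rows; used to evaluate on held-out data
subset_cohort <- function(cohort, rows) {
  tn_cohort(cohort$radiome[rows, , drop = FALSE],
            cohort$surrogates[rows, , drop = FALSE],
            cohort$labels[rows, , drop = FALSE],
            cr_map = cohort$cr_map)
}

#' Run a full outer-validation experiment
#'
#' For each outer fold of the chosen scheme, a technome is constructed on
#' the training side (qualification, weight optimisation, final fit) and
#' evaluated strictly on the held-out side: mean variance reduction in
#' stabilisation mode, AUC in predictive mode. Folds whose training side
#' contains a single class are skipped with a warning.
#'
#' @param cohort A [tn_cohort()].
#' @param perturbation,phantom Optional series for the in-silico / in-vitro
#'   criteria.
#' @param config A [loss_config()].
#' @param scheme `"cv10"` or `"ssd"`.
#' @param seed Integer seed (splits and optimiser).
#' @return A `tn_experiment`: per-fold tibble (`fold`, `metric`, chosen
#'   weights, qualified-set size) plus the mean metric.
#' @export
run_experiment <- function(cohort, perturbation = NULL, phantom = NULL,
                           config = loss_config(), scheme = c("cv10", "ssd"),
                           seed = 1) {
  scheme <- match.arg(scheme)
  splits <- split_train_test(cohort, scheme, seed = seed)
  folds <- purrr::pmap(splits, function(fold, train, test) {
    if (config$mode == "predictive" &&
        length(unique(label_vector(cohort, train))) < 2) {
      warn(sprintf("fold %d skipped: single-class training data", fold))
      return(NULL)
    }
    tech <- construct_technome(cohort, perturbation, phantom, config,
                               rows = train, seed = sub_seed(seed, fold))
    metric <- evaluate_technome(tech, cohort, test)
    tibble::tibble(fold = fold, metric = metric,
                   n_qualified = length(qualified_union(tech$sets)),
                   theta = list(tech$theta))
  })
  folds <- dplyr::bind_rows(folds)
  structure(list(scheme = scheme, mode = config$mode, folds = folds,
                 mean_metric = mean(folds$metric), seed = seed),
            class = "tn_experiment")
}

evaluate_technome <- function(tech, cohort, test_rows) {
  test <- subset_cohort(cohort, test_rows)
  if (tech$mode == "stabilisation") {
    stabilisation_performance(test, apply_calibration(tech$model, test))
  } else {
    auc_score(predict_proba(tech$model, cohort, rows = test_rows),
              label_vector(cohort, test_rows))
  }
}

#' @export
print.tn_experiment <- function(x, ...) {
  cat(sprintf("<tn_experiment: %s, %s mode> mean metric %.3f over %d fold(s)\n",
              x$scheme, x$mode, x$mean_metric, nrow(x$folds)))
  invisible(x)
}

#' @method tidy tn_experiment
#' @export
tidy.tn_experiment <- function(x, ...) {
  dplyr::select(x$folds, "fold", "metric", "n_qualified")
}

#' @method glance tn_experiment
#' @export
glance.tn_experiment <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, mode = x$mode,
                 mean_metric = x$mean_metric, n_folds = nrow(x$folds))
}

#' Head-to-head comparison of all methods under identical folds
#'
#' Evaluates the technome and its baselines — RAVEL-like, naive GLM
#' (mRMR + AIC), naive random forest, and the feature-only models in
#' predictive mode — on exactly the same outer folds (shared split seed).
#'
#' @inheritParams run_experiment
#' @param methods Methods to include (defaults depend on the mode).
#' @return A tibble: one row per method and fold, with the held-out metric.
#' @export
run_baseline_suite <- function(cohort, perturbation = NULL, phantom = NULL,
                               config = loss_config(),
                               scheme = c("cv10", "ssd"), seed = 1,
                               methods = NULL) {
  scheme <- match.arg(scheme)
  methods <- methods %||% if (config$mode == "stabilisation") {
    c("technome", "ravel_like", "naive_glm", "naive_rf")
  } else {
    c("technome", "ravel_like", "naive_glm", "naive_rf",
      "glm_features_only", "rf_features_only")
  }
  splits <- split_train_test(cohort, scheme, seed = seed)
  purrr::map_dfr(methods, function(m) {
    purrr::pmap_dfr(splits, function(fold, train, test) {
      metric <- suppressWarnings(
        eval_method(m, cohort, perturbation, phantom, config, train, test,
                    seed = sub_seed(seed, fold))
      )
      tibble::tibble(method = m, fold = fold, metric = metric,
                     n_train = length(train), n_test = length(test))
    })
  })
}

eval_method <- function(method, cohort, perturbation, phantom, config,
                        train, test, seed) {
  if (method == "technome") {
    tech <- construct_technome(cohort, perturbation, phantom, config,
                               rows = train, seed = seed)
    return(evaluate_technome(tech, cohort, test))
  }
  if (config$mode == "stabilisation") {
    model <- switch(method,
      ravel_like = fit_ravel_like(cohort, rows = train),
      naive_glm = fit_naive_glm(cohort, rows = train),
      naive_rf = fit_naive_rf(cohort, rows = train, seed = seed),
      abort(paste("unknown stabilisation method", method))
    )
    test_c <- subset_cohort(cohort, test)
    stabilisation_performance(test_c, apply_calibration(model, test_c))
  } else {
    variant <- switch(method,
      ravel_like = "ravel_like_pred",
      naive_glm = "naive_glm",
      naive_rf = "naive_rf",
      glm_features_only = "glm_features_only",
      rf_features_only = "rf_features_only",
      abort(paste("unknown predictive method", method))
    )
    model <- fit_predictive(cohort, sets = NULL, variant, rows = train,
                            seed = seed)
    auc_score(predict_proba(model, cohort, rows = test),
              label_vector(cohort, test))
  }
}

#' Sweep the qualification weight space
#'
#' Samples criterion weights uniformly within bounds (or a grid of `q_min`
#' thresholds), builds a model at each sample *without* loss optimisation on
#' one shared SSD-ratio train/test split, and records the held-out metric
#' together with a region tag: `OC` (overconstrained — every qualified set
#' empty, no calibration), `UC` (underconstrained — at least 90% of all
#' surrogates qualified for some feature), or `intermediate`.
#'
#' @inheritParams run_experiment
#' @param n_samples Number of sampled weight vectors (or `q_min` values).
#' @param sweep_mode `"vary_theta"` (random weights, fixed `q_min`) or
#'   `"vary_qmin"` (fixed unit weights, `q_min` grid).
#' @param sampling Weight sampling for `"vary_theta"`: `"log_uniform"`
#'   (default — weights span three decades, and the qualification structure
#'   near the overconstrained border lives at small weights) or
#'   `"uniform"`.
#' @return A `tn_sweep`: tibble of samples with weights, test metric, mean
#'   qualification of the selected surrogates and region tag.
#' @export
weight_sweep <- function(cohort, perturbation = NULL, phantom = NULL,
                         config = loss_config(), n_samples = 200, seed = 1,
                         sweep_mode = c("vary_theta", "vary_qmin"),
                         sampling = c("log_uniform", "uniform")) {
  sweep_mode <- match.arg(sweep_mode)
  sampling <- match.arg(sampling)
  split <- split_train_test(cohort, "ssd", seed = seed)
  train <- split$train[[1]]
  test <- split$test[[1]]
  qual <- qualify_surrogates(cohort, perturbation, phantom, rows = train,
                             criteria = config$criteria)
  n_surr <- length(qual$surrogates)
  d <- length(config$criteria)
  thetas <- withr::with_seed(sub_seed(seed, 5L), {
    if (sweep_mode == "vary_theta") {
      u <- if (sampling == "log_uniform") {
        exp(runif(n_samples * d, log(config$bounds[1]),
                  log(config$bounds[2])))
      } else {
        runif(n_samples * d, config$bounds[1], config$bounds[2])
      }
      matrix(u, ncol = d, dimnames = list(NULL, config$criteria))
    } else {
      matrix(1, n_samples, d, dimnames = list(NULL, config$criteria))
    }
  })
  qmins <- if (sweep_mode == "vary_qmin") {
    seq(0.05, d, length.out = n_samples)
  } else {
    rep(config$q_min, n_samples)
  }
  samples <- purrr::map_dfr(seq_len(n_samples), function(k) {
    theta <- setNames(thetas[k, ], config$criteria)
    sets <- select_qualified(combine_q(qual, theta), qmins[k],
                             exclude = qual$degenerate)
    sizes <- lengths(sets$sets)
    tag <- if (all(sizes == 0)) "OC"
      else if (any(sizes >= 0.9 * n_surr)) "UC"
      else "intermediate"
    metric <- suppressWarnings(
      sweep_metric(cohort, sets, config, train, test,
                   seed = sub_seed(seed, 23L))
    )
    sel <- qualified_union(sets)
    mean_qual <- if (length(sel)) {
      mean(purrr::map_dbl(qual$q, ~mean(.x[, sel, drop = FALSE])))
    } else {
      NA_real_
    }
    tibble::tibble(sample = k, !!!as.list(theta), q_min = qmins[k],
                   metric = metric, mean_qualification = mean_qual,
                   region = tag)
  })
  structure(list(samples = samples, mode = config$mode,
                 sweep_mode = sweep_mode, seed = seed,
                 train = train, test = test),
            class = "tn_sweep")
}

sweep_metric <- function(cohort, sets, config, train, test, seed) {
  if (config$mode == "stabilisation") {
    model <- fit_technome_stabilisation(cohort, sets, rows = train)
    test_c <- subset_cohort(cohort, test)
    stabilisation_performance(test_c, apply_calibration(model, test_c))
  } else {
    model <- fit_predictive(cohort, sets, "technome_glm", rows = train,
                            seed = seed)
    auc_score(predict_proba(model, cohort, rows = test),
              label_vector(cohort, test))
  }
}

#' @export
print.tn_sweep <- function(x, ...) {
  tab <- table(x$samples$region)
  cat(sprintf("<tn_sweep: %s, %s> %d samples (%s)\n", x$sweep_mode, x$mode,
              nrow(x$samples),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @method tidy tn_sweep
#' @export
tidy.tn_sweep <- function(x, ...) x$samples

#' Read out the technome: which control regions calibrate which feature
#'
#' For every feature, groups its qualified surrogates by control region and
#' attributes explained variance by refitting the feature's stabilisation
#' regression on each CR's qualified surrogates alone (training rows of the
#' technome). CRs are ordered by that explained-variance share. Features
#' with empty qualified sets are reported as robust (no calibration
#' required).
#'
#' @param technome A `tn_technome` from [construct_technome()].
#' @param cohort The cohort the technome was constructed on.
#' @param rows The technome's training rows (default: all rows).
#' @return A `tn_discovery`: tibble with columns `feature`, `cr`,
#'   `surrogates` (list), `explained_variance`, `robust`.
#' @export
discovery_report <- function(technome, cohort, rows = NULL) {
  stopifnot(inherits(technome, "tn_technome"))
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  cr_of <- setNames(cohort$cr_map$cr, cohort$cr_map$surrogate)
  rows_out <- purrr::map_dfr(feature_names(cohort), function(j) {
    surr <- technome$sets$sets[[j]] %||% character()
    if (length(surr) == 0) {
      return(tibble::tibble(feature = j, cr = NA_character_,
                            surrogates = list(character()),
                            explained_variance = NA_real_, robust = TRUE))
    }
    crs <- unique(cr_of[surr])
    purrr::map_dfr(crs, function(cr) {
      in_cr <- surr[cr_of[surr] == cr]
      y <- R[, j]
      fit <- suppressWarnings(fit_feature_ols(y, S, in_cr))
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      tibble::tibble(feature = j, cr = cr, surrogates = list(sort(in_cr)),
                     explained_variance = r2, robust = FALSE)
    })
  })
  rows_out <- dplyr::arrange(rows_out, .data$feature,
                             dplyr::desc(.data$explained_variance))
  structure(list(report = rows_out), class = "tn_discovery")
}

#' @export
print.tn_discovery <- function(x, ...) {
  cat(format_discovery(x), sep = "\n")
  invisible(x)
}

#' Format a discovery report as a Markdown table
#'
#' @param x A `tn_discovery`.
#' @return Character vector of Markdown lines.
#' @export
format_discovery <- function(x) {
  out <- c("| Feature | CR | Qualified surrogates | Explained variance |",
           "|---|---|---|---|")
  for (i in seq_len(nrow(x$report))) {
    r <- x$report[i, ]
    if (r$robust) {
      out <- c(out, sprintf("| %s | - | (robust, no calibration) | - |",
                            r$feature))
    } else {
      out <- c(out, sprintf("| %s | %s | %s | %.3f |", r$feature, r$cr,
                            paste(r$surrogates[[1]], collapse = ", "),
                            r$explained_variance))
    }
  }
  out
}

#' @method tidy tn_discovery
#' @export
tidy.tn_discovery <- function(x, ...) x$report
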