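empty_sets <- function(features) {
  Q <- matrix(0, length(features), 1,
              dimnames = list(features, "none"))
  select_qualified(Q, 1)
}

all_sets <- function(features, surrogates) {
  Q <- matrix(2, length(features), length(surrogates),
              dimnames = list(features, surrogates))
  select_qualified(Q, 1)
}

test_that("empty qualified sets give the identity calibration", {
  coh <- tiny_cohort()
  m <- fit_technome_stabilisation(coh, empty_sets(feature_names(coh)))
  out <- apply_calibration(m, coh)
  expect_equal(out$radiome, coh$radiome)
  expect_equal(stabilisation_performance(coh, out), 0)
})

test_that("an exact linear confounder is removed completely", {
  withr::with_seed(3, {
    ids <- sprintf("p%02d", 1:40)
    s <- rnorm(40)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = 2 * s + 5),
      surrogates = tibble::tibble(id = ids, `a::s` = s),
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), 40))
    )
  })
  m <- fit_technome_stabilisation(coh, all_sets("f1", "a::s"))
  cf <- m$per_feature$f1$coef
  expect_equal(unname(cf["a::s"]), 2, tolerance = 1e-10)
  # centred parametrisation: intercept absorbs 5 + 2 * mean(s)
  expect_equal(unname(cf["(Intercept)"]), 5 + 2 * mean(s), tolerance = 1e-10)
  expect_lt(var(m$per_feature$f1$residuals), 1e-20)

  # new rows from the same law calibrate to a constant
  withr::with_seed(4, {
    s_new <- rnorm(30) + 1  # shifted surrogate distribution
    new <- tn_cohort(
      radiome = tibble::tibble(id = as.character(1:30), f1 = 2 * s_new + 5),
      surrogates = tibble::tibble(id = as.character(1:30), `a::s` = s_new),
      labels = tibble::tibble(id = as.character(1:30),
                              label = rep_len(c(0, 1), 30))
    )
  })
  out <- apply_calibration(m, new)
  expect_lt(var(out$radiome$f1), 1e-16)
  # the prediction must use the *training* surrogate mean: recompute by hand
  g <- cf["(Intercept)"] + cf["a::s"] * (s_new - mean(s))
  expect_equal(out$radiome$f1, unname(2 * s_new + 5 - g), tolerance = 1e-12)
})

test_that("technome OLS equals the direct normal-equation oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 50
      S <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("a::s", 1:10)))
      R <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
      ids <- as.character(1:n)
      coh <- tn_cohort(
        radiome = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                          as.data.frame(R))),
        surrogates = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                             as.data.frame(S))),
        labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), n))
      )
    })
    m <- fit_technome_stabilisation(coh, all_sets(colnames(R), colnames(S)))
    D <- cbind(1, sweep(S, 2, colMeans(S)))
    for (j in colnames(R)) {
      oracle <- drop(qr.solve(crossprod(D), crossprod(D, R[, j])))
      expect_lt(max(abs(m$per_feature[[j]]$coef - oracle)), 1e-8)
    }
  }
})

test_that("collinear qualified surrogates are dropped with a warning", {
  withr::with_seed(8, {
    ids <- as.character(1:30)
    s <- rnorm(30)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = s + rnorm(30, sd = 0.1)),
      surrogates = tibble::tibble(id = ids, `a::s1` = s, `a::s2` = 2 * s),
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), 30))
    )
  })
  expect_warning(
    m <- fit_technome_stabilisation(coh, all_sets("f1", c("a::s1", "a::s2"))),
    "collinear"
  )
  expect_length(m$per_feature$f1$surrogates, 1)
})

test_that("RAVEL-like keeps the smallest component set reaching the
           variance target", {
  # rank-1 surrogate matrix: one component carries everything
  withr::with_seed(5, {
    n <- 40
    u <- rnorm(n)
    S <- outer(u, c(1, -2, 0.5))
    colnames(S) <- paste0("a::s", 1:3)
    ids <- as.character(1:n)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = 3 * u + 1),
      surrogates = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                           as.data.frame(S))),
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), n))
    )
  })
  m <- fit_ravel_like(coh, var_explained = 0.95, protect_label = FALSE)
  expect_equal(m$n_components, 1)
  expect_gte(m$var_explained_reached, 0.95)
  out <- apply_calibration(m, coh)
  expect_equal(stabilisation_performance(coh, out), 1, tolerance = 1e-10)
})

test_that("RAVEL-like with var_explained = 1 matches full least squares", {
  withr::with_seed(6, {
    n <- 30
    S <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("a::s", 1:5)))
    y <- rnorm(n)
    ids <- as.character(1:n)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = y),
      surrogates = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                           as.data.frame(S))),
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), n))
    )
  })
  m <- fit_ravel_like(coh, var_explained = 1, protect_label = FALSE)
  expect_equal(m$n_components, 5)
  full <- lm.fit(cbind(1, S), y)
  expect_lt(max(abs(m$per_feature$f1$residuals - full$residuals)), 1e-8)
})

test_that("RAVEL-like on isotropic noise needs almost all components", {
  withr::with_seed(7, {
    n <- 400
    S <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("a::s", 1:10)))
    ids <- as.character(1:n)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = rnorm(n)),
      surrogates = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                           as.data.frame(S))),
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), n))
    )
  })
  m <- fit_ravel_like(coh, var_explained = 0.95)
  expect_gte(m$n_components, 9)
})

test_that("naive GLM finds the single informative surrogate by mRMR + AIC", {
  withr::with_seed(9, {
    n <- 80
    t <- rnorm(n)
    S <- cbind(`a::oracle` = t + rnorm(n, sd = 0.05),
               matrix(rnorm(n * 6), n, dimnames = list(NULL,
                                                       paste0("a::n", 1:6))))
    ids <- as.character(1:n)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = 2 * t + rnorm(n, sd = 0.2)),
      surrogates = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                           as.data.frame(S))),
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), n))
    )
  })
  m <- fit_naive_glm(coh, k_max = 7)
  sel <- m$per_feature$f1$surrogates
  expect_true("a::oracle" %in% sel)
  # independent oracle: exhaustive AIC over every subset of all 7 surrogates
  y <- coh$radiome$f1
  Smat <- as.matrix(coh$surrogates[, -1])
  best <- list(aic = Inf, surr = NULL)
  for (mask in 0:(2^7 - 1)) {
    surr <- colnames(Smat)[bitwAnd(mask, 2^(0:6)) > 0]
    X <- cbind(1, Smat[, surr, drop = FALSE])
    fit <- lm.fit(X, y)
    aic <- n * log(sum(fit$residuals^2) / n) + 2 * (length(surr) + 1)
    if (aic < best$aic) best <- list(aic = aic, surr = surr)
  }
  expect_setequal(sel, best$surr)
})

test_that("mRMR admits only one of two duplicated informative surrogates
           before noise", {
  withr::with_seed(10, {
    n <- 60
    t <- rnorm(n)
    S <- cbind(`a::dup1` = t + rnorm(n, sd = 0.01),
               `a::dup2` = t + rnorm(n, sd = 0.01),
               matrix(rnorm(n * 4), n,
                      dimnames = list(NULL, paste0("a::n", 1:4))))
    y <- 2 * t + rnorm(n, sd = 0.3)
  })
  ranked <- technome:::mrmr_rank(y, S, k_max = 3)
  expect_equal(ranked[1], "a::dup1")
  expect_false("a::dup2" %in% ranked[1:2])  # redundancy pushes the twin back
})

test_that("all-noise surrogates usually yield the intercept-only model", {
  # single candidate: AIC admits a pure-noise regressor only when its LRT
  # statistic exceeds 2, i.e. ~16% of the time
  solo <- vapply(1:40, function(seed) {
    withr::with_seed(seed, {
      n <- 300
      S <- matrix(rnorm(n), n, dimnames = list(NULL, "a::n1"))
      y <- rnorm(n)
    })
    length(technome:::best_subset_aic(y, S, colnames(S))) == 0
  }, logical(1))
  expect_gte(mean(solo), 0.7)

  # several candidates: selected subsets stay very small
  sizes <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 300
      S <- matrix(rnorm(n * 5), n,
                  dimnames = list(NULL, paste0("a::n", 1:5)))
      y <- rnorm(n)
    })
    length(technome:::best_subset_aic(y, S, colnames(S)))
  }, integer(1))
  expect_lte(stats::median(sizes), 1)
  expect_lte(max(sizes), 3)
})

test_that("random-forest calibration handles constants and beats the GLM on
           a nonlinear confounder", {
  withr::with_seed(12, {
    ids <- as.character(1:60)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = 7),
      surrogates = tibble::tibble(id = ids, `a::s` = rnorm(60)),
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), 60))
    )
  })
  m <- fit_naive_rf(coh, seed = 1, n_trees = 100)
  out <- apply_calibration(m, coh)
  expect_lt(max(abs(out$radiome$f1 - 7)), 0.15)

  wins <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 160
      t <- runif(n, -2, 2)
      ids <- as.character(1:n)
      coh <- tn_cohort(
        radiome = tibble::tibble(id = ids, f1 = t^2 + rnorm(n, sd = 0.05)),
        surrogates = tibble::tibble(id = ids, `a::s` = t),
        labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), n))
      )
    })
    train <- 1:80
    test <- 81:160
    test_c <- technome:::subset_cohort(coh, test)
    rf <- fit_naive_rf(coh, rows = train, seed = seed, n_trees = 200)
    gl <- fit_naive_glm(coh, rows = train, k_max = 1)
    perf_rf <- stabilisation_performance(test_c, apply_calibration(rf, test_c))
    perf_gl <- stabilisation_performance(test_c, apply_calibration(gl, test_c))
    perf_rf > perf_gl
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("stabilisation_performance arithmetic and guards", {
  B <- cbind(f1 = sqrt(4 / var(c(1, 2, 3))) * c(1, 2, 3))  # var 4
  A <- cbind(f1 = B[, 1] * sqrt(0.4 / 4))                  # var 0.4
  expect_equal(stabilisation_performance(B, A), 0.9)
  expect_equal(stabilisation_performance(B, B), 0)
  noisier <- cbind(f1 = B[, 1] * sqrt(2))                  # var doubles
  expect_equal(stabilisation_performance(B, noisier), -1)
  expect_warning(
    p <- stabilisation_performance(cbind(f = rep(1, 4), g = 1:4),
                                   cbind(f = rep(1, 4), g = c(1, 1, 1, 2))),
    "zero-variance"
  )
})

test_that("calibration is affine-equivariant and the metric scale-invariant", {
  for (seed in 1:5) {
    gen <- generate_cohort(cohort_preset("linear", n = 80), seed = seed)
    coh <- gen$cohort
    sets <- all_sets(feature_names(coh), "trachea::s01")
    scaled <- coh
    scaled$radiome$f1 <- 3 * coh$radiome$f1 - 7
    m1 <- fit_technome_stabilisation(coh, sets, rows = 1:40)
    m2 <- fit_technome_stabilisation(scaled, sets, rows = 1:40)
    test_c1 <- technome:::subset_cohort(coh, 41:80)
    test_c2 <- technome:::subset_cohort(scaled, 41:80)
    out1 <- apply_calibration(m1, test_c1)
    out2 <- apply_calibration(m2, test_c2)
    # the additive shift is absorbed by the fitted intercept, so calibrated
    # values transform by the scale factor alone
    expect_equal(out2$radiome$f1, 3 * out1$radiome$f1, tolerance = 1e-8)
    expect_equal(stabilisation_performance(test_c1, out1),
                 stabilisation_performance(test_c2, out2), tolerance = 1e-8)
  }
})

test_that("linear models export to JSON with full precision", {
  gen <- generate_cohort(cohort_preset("linear", n = 60), seed = 21)
  m <- fit_technome_stabilisation(
    gen$cohort, all_sets(feature_names(gen$cohort), "trachea::s01"))
  path <- withr::local_tempfile(fileext = ".json")
  export_model_json(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$variant, "technome")
  expect_equal(back$per_feature$f1$coefficients$`trachea::s01`,
               unname(m$per_feature$f1$coef["trachea::s01"]))
  rf <- fit_naive_rf(gen$cohort, seed = 1, n_trees = 20)
  expect_error(export_model_json(rf, path), "random-forest")
})
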