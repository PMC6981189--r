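# Shared fixture builders; everything is generated in code at test time.

# a tiny hand-made cohort with known columns
tiny_cohort <- function(n = 20, seed = 42) {
  withr::with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n))
    t <- rnorm(n)
    b <- rep(c(0, 1), length.out = n)
    tn_cohort(
      radiome = tibble::tibble(id = ids,
                               f1 = 2 * t + rnorm(n, sd = 0.1),
                               f2 = -t + b + rnorm(n, sd = 0.1)),
      surrogates = tibble::tibble(id = ids,
                                  `air::s1` = t + rnorm(n, sd = 0.05),
                                  `air::s2` = rnorm(n),
                                  `trachea::s1` = rnorm(n)),
      labels = tibble::tibble(id = ids, label = b, group_id = ids)
    )
  })
}

# a perturbation series built by hand from explicit per-column responses;
# slopes named by column, one value per column of the cohort
manual_perturbation <- function(cohort, slopes_r, slopes_s,
                                magnitudes = (1:5) / 5) {
  R0 <- technome:::radiome_matrix(cohort)
  S0 <- technome:::surrogate_matrix(cohort)
  fams <- c("gaussian", "rayleigh", "poisson", "gamma")
  variants <- tidyr::expand_grid(family = fams, level = 1:5)
  variants$magnitude <- magnitudes[variants$level]
  variants$radiome <- purrr::map(variants$magnitude, function(m) {
    sweep(R0, 2, slopes_r[colnames(R0)] * m, "+")
  })
  variants$surrogates <- purrr::map(variants$magnitude, function(m) {
    sweep(S0, 2, slopes_s[colnames(S0)] * m, "+")
  })
  perturbation_series(baseline = list(radiome = R0, surrogates = S0),
                      variants = variants)
}

# small confounded scenario for fast end-to-end runs (same structure as the
# copd_like preset, scaled down)
small_confounded_spec <- function(n = 150) {
  surr <- tibble::tribble(
    ~name,          ~cr,       ~type,         ~loading, ~sigma,
    "trachea::s1",  "trachea", "genuine",     1,        0.1,
    "air::s1",      "air",     "genuine",     1,        0.1,
    "liver::d1",    "liver",   "decoy_bio",   0.4,      1,
    "heart::d1",    "heart",   "decoy_bio",   0.4,      1,
    "air::n1",      "air",     "decoy_noise", 0,        1,
    "liver::n1",    "liver",   "decoy_noise", 0,        1,
    "heart::n1",    "heart",   "decoy_noise", 0,        1,
    "spleen::n1",   "spleen",  "decoy_noise", 0,        1
  )
  synthetic_cohort_spec(
    n = n,
    features = tibble::tibble(name = c("laa910", "laa950"),
                              beta_b = 1, gamma = 2, sigma = 0.7),
    surrogates = surr,
    confounding = 0.3
  )
}

expect_tn_cohort_equal <- function(a, b) {
  expect_identical(a$radiome, b$radiome)
  expect_identical(a$surrogates, b$surrogates)
  expect_identical(a$labels, b$labels)
  expect_identical(a$cr_map, b$cr_map)
}
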