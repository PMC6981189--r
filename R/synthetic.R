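#' Specify a synthetic confounded cohort
#'
#' The generator emulates the statistical structure the calibration method
#' assumes: a binary biological label, a per-patient latent technical factor
#' (think "patient size drives noise level") that imprints on both the
#' target-region features and on genuine control-region surrogates, and
#' several kinds of decoy surrogates that should *fail* qualification.
#'
#' The generative model, per patient \eqn{i}:
#' \deqn{b_i \sim Bernoulli(p), \quad t_i = \kappa (2 b_i - 1) + w_i,\; w_i \sim N(0,1)}
#' \deqn{r_{ij} = \beta_j b_i + \gamma_j t_i + \epsilon_{ij}}
#' Surrogate columns by `type`:
#' * `genuine` / `noisy`: \eqn{s = a\, t + \eta} (a true technical readout;
#'   `noisy` just uses a larger noise sd),
#' * `decoy_bio`: \eqn{s = a (2 b - 1) + \eta} (leaks biology — must be
#'   rejected by the orthogonality criterion),
#' * `decoy_noise`: \eqn{s = \eta} (pure noise).
#'
#' Because \eqn{t} given \eqn{b} is Gaussian with class-independent variance,
#' the joint law of any column subset given the class is Gaussian with equal
#' covariance, and the Bayes-optimal AUC has the closed form
#' \eqn{\Phi(\sqrt{\Delta^\top \Sigma^{-1} \Delta / 2})} computed by
#' [bayes_auc()].
#'
#' @param n Number of patients.
#' @param features Tibble with columns `name`, `beta_b` (label loading),
#'   `gamma` (technical-factor loading), `sigma` (noise sd).
#' @param surrogates Tibble with columns `name` (conventionally
#'   `"CR::feature"`), `cr`, `type` (`genuine`, `noisy`, `decoy_bio`,
#'   `decoy_noise`), `loading`, `sigma`.
#' @param p_label Label prevalence.
#' @param confounding \eqn{\kappa \in [-1, 1]}: class shift of the technical
#'   factor (0 = technical variation independent of biology).
#' @return A `tn_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n, features, surrogates, p_label = 0.5,
                                  confounding = 0) {
  features <- tibble::as_tibble(features)
  surrogates <- tibble::as_tibble(surrogates)
  stopifnot(all(c("name", "beta_b", "gamma", "sigma") %in% names(features)),
            all(c("name", "cr", "type", "loading", "sigma") %in%
                  names(surrogates)))
  if (abs(confounding) > 1) abort("`confounding` must lie in [-1, 1]")
  bad <- setdiff(surrogates$type,
                 c("genuine", "noisy", "decoy_bio", "decoy_noise"))
  if (length(bad)) abort(paste("unknown surrogate type:", bad[1]))
  if (!all(is.finite(features$gamma)) || !all(is.finite(surrogates$loading))) {
    abort("loadings must be finite")
  }
  structure(list(n = as.integer(n), features = features,
                 surrogates = surrogates, p_label = p_label,
                 confounding = confounding),
            class = "tn_cohort_spec")
}

#' Built-in cohort scenarios
#'
#' * `"copd_like"`: the headline scenario. n = 500 patients, 2
#'   emphysema-score-like features (`laa910`, `laa950`; label loading 1,
#'   technical loading 2, noise sd 0.7), confounding 0.3, and 7 control
#'   regions with 12 surrogates each (84 total): 4 genuine technical
#'   surrogates (one each in trachea, air, adipose, heart; noise sd 0.1),
#'   8 biology-leaking decoys (loading 0.4) and 72 pure-noise decoys.
#' * `"linear"`: a small stabilisation scenario for parameter recovery.
#'   n = 200, 2 features with technical loading 2 and noise sd 0.1, one clean
#'   trachea surrogate (noise sd 0.05), a biology decoy and noise decoys;
#'   no confounding.
#'
#' @param name Preset name.
#' @param n Optionally override the number of patients.
#' @return A [synthetic_cohort_spec()].
#' @export
cohort_preset <- function(name = c("copd_like", "linear"), n = NULL) {
  name <- match.arg(name)
  if (name == "copd_like") {
    crs <- c("trachea", "air", "adipose", "heart", "liver", "spleen", "aorta")
    surr <- tidyr::expand_grid(cr = crs, idx = 1:12)
    surr$name <- sprintf("%s::s%02d", surr$cr, surr$idx)
    genuine <- sprintf("%s::s01", c("trachea", "air", "adipose", "heart"))
    decoys <- c(sprintf("%s::s01", c("liver", "spleen", "aorta")),
                sprintf("%s::s02", c("trachea", "air", "adipose", "heart",
                                     "liver")))
    surr$type <- dplyr::case_when(
      surr$name %in% genuine ~ "genuine",
      surr$name %in% decoys ~ "decoy_bio",
      TRUE ~ "decoy_noise"
    )
    surr$loading <- dplyr::case_when(
      surr$type == "genuine" ~ 1,
      surr$type == "decoy_bio" ~ 0.4,
      TRUE ~ 0
    )
    surr$sigma <- ifelse(surr$type == "genuine", 0.1, 1)
    synthetic_cohort_spec(
      n = n %||% 500L,
      features = tibble::tibble(name = c("laa910", "laa950"),
                                beta_b = 1, gamma = 2, sigma = 0.7),
      surrogates = surr[, c("name", "cr", "type", "loading", "sigma")],
      confounding = 0.3
    )
  } else {
    surr <- tibble::tribble(
      ~name,            ~cr,       ~type,         ~loading, ~sigma,
      "trachea::s01",   "trachea", "genuine",     1,        0.05,
      "adipose::d01",   "adipose", "decoy_bio",   0.4,      1,
      "air::n01",       "air",     "decoy_noise", 0,        1,
      "air::n02",       "air",     "decoy_noise", 0,        1,
      "air::n03",       "air",     "decoy_noise", 0,        1
    )
    synthetic_cohort_spec(
      n = n %||% 200L,
      features = tibble::tibble(name = c("f1", "f2"),
                                beta_b = 1, gamma = 2, sigma = 0.1),
      surrogates = surr,
      confounding = 0
    )
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param seed Integer seed; output is bit-identical given the seed.
#' @return A list with elements `cohort` (a [tn_cohort()]) and `truth` (the
#'   spec, the latent technical factor `t`, and the genuine surrogate names).
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "tn_cohort_spec"))
  n <- spec$n
  out <- withr::with_seed(seed, {
    b <- rbinom(n, 1, spec$p_label)
    w <- rnorm(n)
    t <- spec$confounding * (2 * b - 1) + w
    R <- vapply(seq_len(nrow(spec$features)), function(j) {
      f <- spec$features[j, ]
      f$beta_b * b + f$gamma * t + rnorm(n, sd = f$sigma)
    }, numeric(n))
    colnames(R) <- spec$features$name
    S <- vapply(seq_len(nrow(spec$surrogates)), function(l) {
      s <- spec$surrogates[l, ]
      base <- switch(s$type,
        genuine = ,
        noisy = s$loading * t,
        decoy_bio = s$loading * (2 * b - 1),
        decoy_noise = rep(0, n)
      )
      base + rnorm(n, sd = s$sigma)
    }, numeric(n))
    colnames(S) <- spec$surrogates$name
    list(b = b, t = t, R = R, S = S)
  })
  ids <- sprintf("p%04d", seq_len(n))
  cohort <- tn_cohort(
    radiome = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                      tibble::as_tibble(out$R))),
    surrogates = tibble::as_tibble(cbind(tibble::tibble(id = ids),
                                         tibble::as_tibble(out$S))),
    labels = tibble::tibble(id = ids, label = out$b, group_id = ids),
    cr_map = tibble::tibble(surrogate = spec$surrogates$name,
                            cr = spec$surrogates$cr)
  )
  truth <- list(
    spec = spec,
    t = out$t,
    seed = seed,
    genuine = spec$surrogates$name[spec$surrogates$type %in%
                                     c("genuine", "noisy")],
    decoys_bio = spec$surrogates$name[spec$surrogates$type == "decoy_bio"],
    decoys_noise = spec$surrogates$name[spec$surrogates$type == "decoy_noise"]
  )
  list(cohort = cohort, truth = truth)
}

#' Closed-form Bayes-optimal AUC of a synthetic cohort spec
#'
#' Conditional on the class, all observed columns of the generative model are
#' jointly Gaussian with a class-independent covariance \eqn{\Sigma} and mean
#' difference \eqn{\Delta}, so the best attainable AUC over a column subset
#' is \eqn{\Phi(\sqrt{\Delta^\top \Sigma^{-1}\Delta/2})}. This is the
#' generator's analytic performance ceiling, computed before any data are
#' drawn.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param columns Which columns the classifier observes: `"features"` (the
#'   radiome only), `"oracle"` (radiome plus the genuine technical
#'   surrogates — the information a perfectly qualified calibration uses), or
#'   `"all"` (every column, including biology-leaking decoys).
#' @return AUC in `[0.5, 1]`.
#' @export
bayes_auc <- function(spec, columns = c("oracle", "features", "all")) {
  columns <- match.arg(columns)
  f <- spec$features
  s <- spec$surrogates
  kappa <- spec$confounding
  delta_f <- f$beta_b + 2 * kappa * f$gamma
  load_f <- f$gamma
  var_f <- f$sigma^2
  delta_s <- ifelse(s$type %in% c("genuine", "noisy"), 2 * kappa * s$loading,
                    ifelse(s$type == "decoy_bio", 2 * s$loading, 0))
  load_s <- ifelse(s$type %in% c("genuine", "noisy"), s$loading, 0)
  var_s <- s$sigma^2
  keep <- switch(columns,
    features = rep(FALSE, nrow(s)),
    oracle = s$type %in% c("genuine", "noisy"),
    all = rep(TRUE, nrow(s))
  )
  delta <- c(delta_f, delta_s[keep])
  load <- c(load_f, load_s[keep])
  vars <- c(var_f, var_s[keep])
  Sigma <- tcrossprod(load) + diag(vars, length(vars))
  d2 <- drop(crossprod(delta, solve(Sigma, delta)))
  pnorm(sqrt(d2 / 2))
}

#' Generate an in-silico noise perturbation series
#'
#' Emulates re-measuring every feature and surrogate after superimposing
#' Gaussian, Rayleigh, Poisson and Gamma noise at five monotonically
#' increasing levels. At the feature level each responsive column shifts
#' linearly in the noise magnitude with a family-specific slope; genuine
#' technical feature/surrogate pairs co-respond while decoy surrogates do
#' not. Responses are exact linear shifts by default (`jitter_sd = 0`):
#' genuine pairs then reach an in-silico score of exactly 1 and
#' zero-response decoys exactly 0. Optional measurement jitter scales with
#' the magnitude, so a zero-magnitude variant always reproduces the
#' baseline exactly.
#'
#' @param cohort A [tn_cohort()] (the unperturbed baseline).
#' @param truth Ground truth from [generate_cohort()] (identifies responsive
#'   columns and their loadings).
#' @param level_magnitudes Five increasing unit magnitudes.
#' @param family_scale Named multiplier per noise family.
#' @param jitter_sd Measurement jitter sd per unit magnitude.
#' @param seed Integer seed.
#' @return A [perturbation_series()].
#' @export
generate_perturbation_series <- function(cohort, truth,
                                         level_magnitudes = (1:5) / 5,
                                         family_scale = c(gaussian = 1,
                                                          rayleigh = 0.8,
                                                          poisson = 1.2,
                                                          gamma = 0.9),
                                         jitter_sd = 0, seed = 1) {
  stopifnot(length(level_magnitudes) == 5, length(family_scale) == 4)
  if (is.unsorted(level_magnitudes)) {
    abort("`level_magnitudes` must be monotonically increasing")
  }
  R0 <- radiome_matrix(cohort)
  S0 <- surrogate_matrix(cohort)
  spec <- truth$spec
  slope_f <- setNames(rep(1, ncol(R0)), colnames(R0))
  slope_s <- setNames(
    ifelse(spec$surrogates$type %in% c("genuine", "noisy"),
           spec$surrogates$loading, 0),
    spec$surrogates$name
  )[colnames(S0)]
  variants <- withr::with_seed(seed, {
    rows <- tidyr::expand_grid(family = names(family_scale), level = 1:5)
    rows$magnitude <- family_scale[rows$family] *
      level_magnitudes[rows$level]
    rows$radiome <- purrr::map(rows$magnitude, function(m) {
      R0 + matrix(slope_f * m, nrow(R0), ncol(R0), byrow = TRUE) +
        matrix(rnorm(length(R0), sd = jitter_sd * m), nrow(R0))
    })
    rows$surrogates <- purrr::map(rows$magnitude, function(m) {
      S0 + matrix(slope_s * m, nrow(S0), ncol(S0), byrow = TRUE) +
        matrix(rnorm(length(S0), sd = jitter_sd * m), nrow(S0))
    })
    rows
  })
  perturbation_series(baseline = list(radiome = R0, surrogates = S0),
                      variants = variants)
}

#' Generate a phantom protocol series
#'
#' Emulates scanning one fixed object (no biological variation) under
#' `n_protocols` acquisition protocols. A latent protocol severity drives
#' every technical-variation-sensitive column: all radiome features (unit
#' slope) and the genuine technical surrogates (their loading); decoy
#' surrogates are protocol-independent noise.
#'
#' @param spec A [synthetic_cohort_spec()] (supplies the column design).
#' @param n_protocols Number of protocol conditions (>= 3).
#' @param noise_sd Measurement noise sd for responsive columns.
#' @param seed Integer seed.
#' @return A [phantom_series()].
#' @export
generate_phantom_series <- function(spec, n_protocols = 30, noise_sd = 0.05,
                                    seed = 1) {
  if (n_protocols < 3) abort("`n_protocols` must be >= 3")
  withr::with_seed(seed, {
    p <- runif(n_protocols, -1, 1)
    R <- vapply(seq_len(nrow(spec$features)), function(j) {
      p + rnorm(n_protocols, sd = noise_sd)
    }, numeric(n_protocols))
    colnames(R) <- spec$features$name
    S <- vapply(seq_len(nrow(spec$surrogates)), function(l) {
      s <- spec$surrogates[l, ]
      if (s$type %in% c("genuine", "noisy")) {
        s$loading * p + rnorm(n_protocols, sd = noise_sd)
      } else {
        rnorm(n_protocols, sd = s$sigma)
      }
    }, numeric(n_protocols))
    colnames(S) <- spec$surrogates$name
    phantom_series(R, S, protocol = tibble::tibble(
      protocol = seq_len(n_protocols), severity = p
    ))
  })
}
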