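test_that("q_invivo is |Pearson r| with defined fallbacks", {
  withr::with_seed(1, {
    ids <- sprintf("p%02d", 1:30)
    x <- rnorm(30)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = x),
      surrogates = tibble::tibble(id = ids,
                                  `a::same` = x,          # identical column
                                  `a::flip` = -2 * x + 1, # affine, anticorrelated
                                  `a::const` = 1),        # zero variance
      labels = tibble::tibble(id = ids, label = rep_len(c(0, 1), 30))
    )
  })
  q <- q_invivo(coh)
  expect_equal(q["f1", "a::same"], 1.0)
  expect_equal(q["f1", "a::flip"], 1.0)
  expect_equal(q["f1", "a::const"], 0.0)
  expect_error(q_invivo(coh, rows = 1:2), "3 patients")
})

test_that("null in-vivo associations score low at n = 1000", {
  withr::with_seed(11, {
    n <- 1000
    ids <- sprintf("p%04d", 1:n)
    coh <- tn_cohort(
      radiome = tibble::as_tibble(
        cbind(tibble::tibble(id = ids),
              as.data.frame(matrix(rnorm(n * 4), n,
                                   dimnames = list(NULL, paste0("f", 1:4)))))),
      surrogates = tibble::as_tibble(
        cbind(tibble::tibble(id = ids),
              as.data.frame(matrix(rnorm(n * 30), n,
                                   dimnames = list(NULL,
                                                   paste0("a::s", 1:30)))))),
      labels = tibble::tibble(id = ids, label = rbinom(n, 1, 0.5))
    )
  })
  q <- q_invivo(coh)
  expect_gte(mean(q < 0.1), 0.99)
})

test_that("q_insilico rewards co-response and gates on the in-vivo sign", {
  coh <- tiny_cohort()
  # f1 ~ 2t, air::s1 ~ t: in-vivo sign positive
  slopes_r <- c(f1 = 1, f2 = 1)
  co <- manual_perturbation(coh,
                            slopes_r,
                            c(`air::s1` = 0.5, `air::s2` = 0,
                              `trachea::s1` = -0.5))
  q <- q_insilico(coh, co)
  expect_equal(q["f1", "air::s1"], 1.0, tolerance = 1e-12)  # perfect co-response
  expect_equal(q["f1", "air::s2"], 0.0)                     # unresponsive
  # trachea::s1 responds with opposite sign to its (random, weak) in-vivo
  # association half the time; force the gate with an explicit sign matrix
  sgn <- matrix(1, 2, 3, dimnames = list(c("f1", "f2"),
                                         surrogate_names(coh)))
  q2 <- q_insilico(coh, co, sign_matrix = sgn)
  expect_equal(q2["f1", "trachea::s1"], 0.0)  # sign mismatch gate
})

test_that("q_insilico demands the full family x level grid", {
  coh <- tiny_cohort()
  co <- manual_perturbation(coh, c(f1 = 1, f2 = 1),
                            c(`air::s1` = 1, `air::s2` = 0,
                              `trachea::s1` = 0))
  broken <- co
  broken$variants <- broken$variants[-3, ]
  expect_error(q_insilico(coh, broken), "missing levels")
  expect_error(perturbation_series(co$baseline, co$variants[-3, ]),
               "levels 1..5")
})

test_that("q_invitro tracks association across phantom protocols", {
  withr::with_seed(5, {
    p <- runif(25, -1, 1)
    R <- cbind(f1 = 3 * p + rnorm(25, sd = 0.01))
    S <- cbind(`a::lin` = -0.5 * p + 1 + rnorm(25, sd = 0.01),
               `a::indep` = rnorm(25))
    phan <- phantom_series(R, S)
  })
  q <- q_invitro(phan)
  expect_gt(q["f1", "a::lin"], 0.99)
  expect_lt(q["f1", "a::indep"], 0.5)
  expect_error(phantom_series(R[1, , drop = FALSE], S[1, , drop = FALSE]),
               ">= 2 protocol")
  expect_error(q_invitro(phantom_series(R[1:2, , drop = FALSE],
                                        S[1:2, , drop = FALSE])),
               "3 protocol")
})

test_that("q_invitro null associations stay below 0.5 for 20+ conditions", {
  hits <- vapply(1:40, function(seed) {
    withr::with_seed(seed, {
      q <- q_invitro(phantom_series(cbind(f = rnorm(20)),
                                    cbind(`a::s` = rnorm(20))))
    })
    q[1, 1] < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("q_orthog is one minus |point-biserial| and exact by construction", {
  withr::with_seed(2, {
    n <- 40
    ids <- sprintf("p%02d", 1:n)
    b <- rep_len(c(0, 1), n)
    s_free <- rnorm(n)
    coh <- tn_cohort(
      radiome = tibble::tibble(id = ids, f1 = rnorm(n)),
      surrogates = tibble::tibble(id = ids, `a::leak` = b,
                                  `a::free` = s_free, `a::const` = 0),
      labels = tibble::tibble(id = ids, label = b)
    )
  })
  q <- q_orthog(coh)
  expect_equal(q["f1", "a::leak"], 0.0)
  expect_equal(q["f1", "a::const"], 1.0)
  pb <- abs(cor(s_free, coh$labels$label))
  expect_equal(q["f1", "a::free"], 1 - pb, tolerance = 1e-12)

  one_class <- coh
  one_class$labels$label <- 1
  expect_error(q_orthog(one_class), "both classes")
})

test_that("label-independent surrogates score high on orthogonality", {
  hits <- vapply(1:50, function(seed) {
    withr::with_seed(seed, {
      n <- 1000
      1 - abs(cor(rnorm(n), rbinom(n, 1, 0.5)))
    }) > 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("combine_q implements the weighted sum and select_qualified the
           strict threshold", {
  qual <- structure(list(
    q = list(invivo = matrix(0.9, 1, 1, dimnames = list("f", "s")),
             insilico = matrix(0.8, 1, 1, dimnames = list("f", "s")),
             invitro = matrix(0.1, 1, 1, dimnames = list("f", "s")),
             orthog = matrix(1.0, 1, 1, dimnames = list("f", "s"))),
    criteria = c("invivo", "insilico", "invitro", "orthog"),
    features = "f", surrogates = "s", degenerate = character()
  ), class = "tn_qual")

  Q <- combine_q(qual, c(invivo = 1, insilico = 0.5, invitro = 0,
                         orthog = 0.2))
  expect_equal(Q["f", "s"], 0.9 + 0.4 + 0 + 0.2)

  half <- qual
  for (cr in names(half$q)) half$q[[cr]][] <- 0.5
  expect_equal(combine_q(half, c(invivo = 1, insilico = 1, invitro = 1,
                                 orthog = 1))["f", "s"], 2.0)
  expect_equal(combine_q(half, c(invivo = 0, insilico = 0, invitro = 0,
                                 orthog = 0))["f", "s"], 0)
  expect_error(combine_q(qual, c(invivo = -1)), "non-negative")

  expect_true("s" %in% select_qualified(Q, 1.0)$sets$f)       # 1.5 > 1
  expect_length(select_qualified(Q, 1.5)$sets$f, 0)           # 1.5 not > 1.5
  zero <- combine_q(half, c(invivo = 0, insilico = 0, invitro = 0,
                            orthog = 0))
  expect_length(select_qualified(zero, 1.0)$sets$f, 0)        # all-zero weights
})

test_that("raising any weight never removes a qualified surrogate", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      q <- list()
      for (cr in c("invivo", "insilico", "invitro", "orthog")) {
        q[[cr]] <- matrix(runif(12), 3, 4,
                          dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
      }
      qual <- structure(list(q = q, criteria = names(q),
                             features = paste0("f", 1:3),
                             surrogates = paste0("s", 1:4),
                             degenerate = character()), class = "tn_qual")
      theta <- runif(4, 0, 2)
      names(theta) <- names(q)
      theta2 <- theta
      bump <- sample(4, 1)
      theta2[bump] <- theta2[bump] + runif(1, 0, 3)
      s1 <- select_qualified(combine_q(qual, theta))$sets
      s2 <- select_qualified(combine_q(qual, theta2))$sets
      for (f in names(s1)) expect_true(all(s1[[f]] %in% s2[[f]]))
    })
  }
})

test_that("criterion scores live in [0,1] and the tensor tidies to long form", {
  gen <- generate_cohort(small_confounded_spec(n = 80), seed = 4)
  pert <- generate_perturbation_series(gen$cohort, gen$truth, seed = 5)
  phan <- generate_phantom_series(gen$truth$spec, seed = 6)
  qual <- qualify_surrogates(gen$cohort, pert, phan)
  for (cr in names(qual$q)) {
    expect_true(all(qual$q[[cr]] >= 0 & qual$q[[cr]] <= 1))
  }
  Q <- combine_q(qual, c(invivo = 1, insilico = 1, invitro = 1, orthog = 1))
  expect_true(all(Q <= 4 + 1e-12))
  long <- tidy(qual)
  expect_equal(nrow(long), 2 * 8 * 4)
  expect_named(long, c("feature", "surrogate", "criterion", "score"))
})

test_that("genuine surrogates dominate biology-leaking decoys on
           q_invivo * q_orthog", {
  margins <- vapply(1:20, function(seed) {
    gen <- generate_cohort(small_confounded_spec(n = 150), seed = seed)
    qual <- qualify_surrogates(gen$cohort, criteria = c("invivo", "orthog"))
    prod <- qual$q$invivo * qual$q$orthog
    mean(prod[, gen$truth$genuine]) - mean(prod[, gen$truth$decoys_bio])
  }, numeric(1))
  expect_gte(min(margins), 0.2)
})
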