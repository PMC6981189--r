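#' Surrogate qualification criteria
#'
#' Four criteria score every (feature, surrogate) pair in `[0, 1]`; together
#' they decide whether a control-region surrogate is a trustworthy proxy of
#' technical variation for a given feature:
#'
#' * `q_invivo()` — association in the cohort itself: the absolute Pearson
#'   correlation between the feature and the surrogate over (training)
#'   patients.
#' * `q_insilico()` — the in-vivo association must be re-identifiable under
#'   simulated noise: per noise family, the correlation between the feature's
#'   and the surrogate's mean response across the five ordered noise levels
#'   (responses are per-level cohort-mean deviations from the unperturbed
#'   baseline), gated to 0 when the response sign contradicts the in-vivo
#'   sign, then averaged over the four families.
#' * `q_invitro()` — association across phantom acquisitions, where all
#'   variation is technical: absolute Pearson correlation between feature and
#'   surrogate across protocol conditions.
#' * `q_orthog()` — a statistical validity requirement on covariates: one
#'   minus the absolute point-biserial correlation between the surrogate and
#'   the biological label (identical for every feature; materialised
#'   per-feature for a uniform tensor shape).
#'
#' Zero-variance columns score 0 in the association criteria and 1 in
#' orthogonality (no measurable association, by convention; they are flagged
#' by [validate_cohort()] and excluded from selection upstream).
#'
#' @param cohort A [tn_cohort()].
#' @param rows Optional integer row indices restricting computation to
#'   training patients. Always pass the training side of a split here —
#'   qualification is part of model fitting.
#' @return A features x surrogates numeric matrix with entries in `[0, 1]`.
#' @name qualification-criteria
NULL

#' @rdname qualification-criteria
#' @export
q_invivo <- function(cohort, rows = NULL) {
  q_invivo_m(cohort, rows, "pearson")
}

# signed in-vivo correlation; q_insilico's sign gate compares against this
invivo_sign <- function(cohort, rows = NULL) {
  sign(safe_cor_matrix(radiome_matrix(cohort, rows),
                       surrogate_matrix(cohort, rows)))
}

#' @rdname qualification-criteria
#' @param perturbation A perturbation-kind [perturbation_series()].
#' @param sign_matrix Features x surrogates sign matrix of the in-vivo
#'   association (defaults to the training-row signs from `cohort`).
#' @export
q_insilico <- function(cohort, perturbation, rows = NULL,
                       sign_matrix = NULL) {
  stopifnot(inherits(perturbation, "tn_series"))
  if (perturbation$kind != "perturbation") {
    abort("`perturbation` must be a perturbation-kind series")
  }
  if (is.null(perturbation$baseline)) abort("perturbation baseline absent")
  if (is.null(sign_matrix)) sign_matrix <- invivo_sign(cohort, rows)
  R0 <- perturbation$baseline$radiome
  S0 <- perturbation$baseline$surrogates
  sub <- function(m) if (is.null(rows)) m else m[rows, , drop = FALSE]
  base_r <- colMeans(sub(R0))
  base_s <- colMeans(sub(S0))
  fams <- sort(unique(perturbation$variants$family))
  acc <- matrix(0, ncol(R0), ncol(S0),
                dimnames = list(colnames(R0), colnames(S0)))
  for (f in fams) {
    v <- dplyr::arrange(
      dplyr::filter(perturbation$variants, .data$family == f), .data$level
    )
    if (nrow(v) != 5) abort(sprintf("family '%s' is missing levels", f))
    # 5 x n_features / 5 x n_surrogates response matrices
    dr <- t(vapply(v$radiome, function(m) colMeans(sub(m)) - base_r,
                   numeric(ncol(R0))))
    ds <- t(vapply(v$surrogates, function(m) colMeans(sub(m)) - base_s,
                   numeric(ncol(S0))))
    rho <- safe_cor_matrix(dr, ds)
    acc <- acc + abs(rho) * (sign(rho) == sign_matrix)
  }
  acc / length(fams)
}

#' @rdname qualification-criteria
#' @param phantom A phantom-kind [phantom_series()].
#' @export
q_invitro <- function(phantom) {
  stopifnot(inherits(phantom, "tn_series"))
  if (phantom$kind != "phantom") abort("`phantom` must be a phantom-kind series")
  if (nrow(phantom$radiome) < 3) {
    abort("q_invitro needs at least 3 protocol conditions")
  }
  abs(safe_cor_matrix(phantom$radiome, phantom$surrogates))
}

#' @rdname qualification-criteria
#' @export
q_orthog <- function(cohort, rows = NULL) {
  S <- surrogate_matrix(cohort, rows)
  b <- label_vector(cohort, rows)
  if (length(unique(b)) < 2) abort("q_orthog needs both classes")
  pb <- abs(drop(safe_cor_matrix(matrix(b, ncol = 1), S)))
  fn <- feature_names(cohort)
  matrix(pb, nrow = length(fn), ncol = ncol(S), byrow = TRUE,
         dimnames = list(fn, colnames(S))) * -1 + 1
}

#' Compute the full qualification tensor
#'
#' Evaluates the requested criteria (see [qualification-criteria]) on the
#' training rows and returns them as one object. Criteria whose auxiliary
#' series are unavailable must be dropped from `criteria` explicitly — e.g.
#' phantom-only runs use `criteria = "invivo"`.
#'
#' @inheritParams q_invivo
#' @param perturbation Optional [perturbation_series()] (required for
#'   `"insilico"`).
#' @param phantom Optional [phantom_series()] (required for `"invitro"`).
#' @param criteria Character subset of
#'   `c("invivo", "insilico", "invitro", "orthog")`.
#' @param method Correlation method for the association criteria
#'   (`"pearson"`, the default, matches the linear interaction model;
#'   `"spearman"` is available for heavy-tailed features).
#' @return A `tn_qual` object: list of criterion matrices plus metadata.
#' @export
qualify_surrogates <- function(cohort, perturbation = NULL, phantom = NULL,
                               rows = NULL,
                               criteria = c("invivo", "insilico", "invitro",
                                            "orthog"),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  criteria <- match.arg(criteria, several.ok = TRUE)
  q <- list()
  if ("invivo" %in% criteria) q$invivo <- q_invivo_m(cohort, rows, method)
  if ("insilico" %in% criteria) {
    if (is.null(perturbation)) abort("criterion 'insilico' needs `perturbation`")
    q$insilico <- q_insilico(cohort, perturbation, rows)
  }
  if ("invitro" %in% criteria) {
    if (is.null(phantom)) abort("criterion 'invitro' needs `phantom`")
    q$invitro <- q_invitro(phantom)
  }
  if ("orthog" %in% criteria) q$orthog <- q_orthog(cohort, rows)
  # hard pre-filter: degenerate surrogate columns can never qualify
  degenerate <- apply(surrogate_matrix(cohort, rows), 2, sd) == 0
  structure(list(q = q, criteria = criteria,
                 features = feature_names(cohort),
                 surrogates = surrogate_names(cohort),
                 degenerate = names(degenerate)[degenerate]),
            class = "tn_qual")
}

q_invivo_m <- function(cohort, rows, method) {
  R <- radiome_matrix(cohort, rows)
  S <- surrogate_matrix(cohort, rows)
  if (nrow(R) < 3) abort("q_invivo needs at least 3 patients")
  abs(safe_cor_matrix(R, S, method = method))
}

#' @export
print.tn_qual <- function(x, ...) {
  cat(sprintf("<tn_qual> %d features x %d surrogates, criteria: %s\n",
              length(x$features), length(x$surrogates),
              paste(x$criteria, collapse = ", ")))
  invisible(x)
}

#' @method tidy tn_qual
#' @export
tidy.tn_qual <- function(x, ...) {
  purrr::map_dfr(names(x$q), function(cr) {
    m <- x$q[[cr]]
    tibble::tibble(
      feature = rep(rownames(m), times = ncol(m)),
      surrogate = rep(colnames(m), each = nrow(m)),
      criterion = cr,
      score = as.vector(m)
    )
  })
}

#' Combine criterion scores into the weighted qualification score
#'
#' \eqn{Q_{jl}(\Theta) = \sum_c \theta_c\, q^c_{jl}} over the active
#' criteria.
#'
#' @param qual A `tn_qual` from [qualify_surrogates()].
#' @param theta Named non-negative weights; names must be a subset of the
#'   active criteria of `qual`.
#' @return Features x surrogates matrix of combined scores.
#' @export
combine_q <- function(qual, theta) {
  stopifnot(inherits(qual, "tn_qual"))
  if (is.null(names(theta)) || !all(names(theta) %in% names(qual$q))) {
    abort("`theta` must be named after active criteria")
  }
  if (any(theta < 0)) abort("weights must be non-negative")
  Q <- matrix(0, length(qual$features), length(qual$surrogates),
              dimnames = list(qual$features, qual$surrogates))
  for (cr in names(theta)) Q <- Q + theta[[cr]] * qual$q[[cr]]
  Q
}

#' Select per-feature qualified surrogate sets
#'
#' A surrogate is qualified for a feature when its combined score *strictly*
#' exceeds `q_min` (default 1.0). Sets may be empty — the overconstrained
#' regime in which no calibration takes place.
#'
#' @param Q Combined score matrix from [combine_q()].
#' @param q_min Qualification threshold.
#' @param exclude Surrogate names barred from selection (e.g. degenerate
#'   columns).
#' @return A `tn_sets` object: named list `sets` (per feature, character
#'   vectors of qualified surrogates) plus `Q` and `q_min`.
#' @export
select_qualified <- function(Q, q_min = 1.0, exclude = character()) {
  stopifnot(all(is.finite(Q)))
  sets <- purrr::map(rownames(Q), function(j) {
    l <- colnames(Q)[Q[j, ] > q_min]
    setdiff(l, exclude)
  })
  names(sets) <- rownames(Q)
  structure(list(sets = sets, Q = Q, q_min = q_min), class = "tn_sets")
}

#' @export
print.tn_sets <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("<tn_sets> q_min = %g; |S^q| per feature: %s\n", x$q_min,
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

# union of qualified surrogates over all features (predictive mode merge)
qualified_union <- function(sets) {
  sort(unique(unlist(sets$sets, use.names = FALSE)))
}
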