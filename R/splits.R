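#' Group-aware train/test splits
#'
#' Builds the two validation schemes used throughout the package: `cv10`
#' (10-fold cross-validation, 9/10 train and 1/10 test) and `ssd` (the
#' small-sample-detectability setting: a single split with 1/5 of the data in
#' training and 4/5 in test). Splitting is performed at the level of
#' `group_id` so that all rows of one patient (e.g. multiple lesions) land on
#' the same side of every split, and groups are label-stratified so small
#' training folds retain both classes whenever possible.
#'
#' @param cohort A [tn_cohort()] (its `labels` table supplies `label` and
#'   `group_id`).
#' @param scheme `"cv10"` or `"ssd"`.
#' @param seed Integer seed; splits are deterministic given the seed.
#' @return A tibble with columns `fold`, `train`, `test`; `train`/`test` are
#'   list-columns of integer row indices into the cohort. One row per fold
#'   (10 for `cv10`, 1 for `ssd`).
#' @export
split_train_test <- function(cohort, scheme = c("cv10", "ssd"), seed = 1) {
  scheme <- match.arg(scheme)
  labels <- cohort$labels
  groups <- dplyr::summarise(
    dplyr::group_by(labels, .data$group_id),
    glabel = as.integer(round(mean(.data$label))),
    .groups = "drop"
  )
  n_groups <- nrow(groups)
  n_folds <- if (scheme == "cv10") 10L else 5L
  if (n_groups < n_folds) {
    abort(sprintf("need at least %d groups for scheme '%s', got %d",
                  n_folds, scheme, n_groups))
  }
  if (scheme == "cv10" && nrow(labels) < 10) {
    abort("cv10 needs at least 10 rows")
  }
  # assign each group a fold id 1..n_folds, cycling within label strata with
  # a running counter so overall fold sizes stay balanced
  assignment <- withr::with_seed(seed, {
    out <- integer(n_groups)
    counter <- 0L
    for (cl in sort(unique(groups$glabel))) {
      idx <- which(groups$glabel == cl)
      idx <- idx[sample.int(length(idx))]
      out[idx] <- ((counter + seq_along(idx) - 1L) %% n_folds) + 1L
      counter <- counter + length(idx)
    }
    out
  })
  group_fold <- setNames(assignment, groups$group_id)
  row_fold <- unname(group_fold[labels$group_id])
  all_rows <- seq_len(nrow(labels))
  if (scheme == "cv10") {
    folds <- purrr::map(1:10, function(f) {
      list(train = all_rows[row_fold != f], test = all_rows[row_fold == f])
    })
    tibble::tibble(
      fold = 1:10,
      train = purrr::map(folds, "train"),
      test = purrr::map(folds, "test")
    )
  } else {
    # ssd: fold 1 of 5 is the (small) training side
    tibble::tibble(
      fold = 1L,
      train = list(all_rows[row_fold == 1L]),
      test = list(all_rows[row_fold != 1L])
    )
  }
}
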