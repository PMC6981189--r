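#' Assemble a cohort of radiome features, control-region surrogates and labels
#'
#' A cohort bundles three row-aligned tables: the *radiome* (quantitative
#' features measured in the target region of interest), the *surrogates*
#' (candidate technical-variation proxies measured in control regions, CRs),
#' and per-patient labels. Rows are matched by the `id` column; surrogate
#' columns carry their CR of origin either as a `"CR::feature"` column-name
#' prefix or via an explicit `cr_map`.
#'
#' @param radiome A data frame with an `id` column and one numeric column per
#'   radiome feature.
#' @param surrogates A data frame with an `id` column and one numeric column
#'   per surrogate. Column names of the form `"CR::feature"` encode the
#'   control region; otherwise supply `cr_map`.
#' @param labels A data frame with columns `id`, `label` (0/1) and optionally
#'   `group_id` (patient-level grouping when rows are lesions; defaults to
#'   `id`).
#' @param cr_map Optional data frame with columns `surrogate` and `cr`,
#'   overriding the `"CR::"` prefix convention.
#'
#' @return A `tn_cohort`: a list with tibbles `radiome`, `surrogates`,
#'   `labels` and `cr_map`.
#' @export
tn_cohort <- function(radiome, surrogates, labels, cr_map = NULL) {
  radiome <- tibble::as_tibble(radiome)
  surrogates <- tibble::as_tibble(surrogates)
  labels <- tibble::as_tibble(labels)
  for (nm in c("radiome", "surrogates", "labels")) {
    tab <- get(nm)
    if (!"id" %in% names(tab)) abort(paste0("`", nm, "` needs an `id` column"))
  }
  if (!"label" %in% names(labels)) abort("`labels` needs a `label` column")
  if (!"group_id" %in% names(labels)) labels$group_id <- as.character(labels$id)
  labels$id <- as.character(labels$id)
  radiome$id <- as.character(radiome$id)
  surrogates$id <- as.character(surrogates$id)

  ids <- radiome$id
  if (anyDuplicated(ids)) abort("duplicate ids in `radiome`")
  orphan <- function(other, nm) {
    missing <- setdiff(ids, other$id)
    extra <- setdiff(other$id, ids)
    if (length(missing) || length(extra)) {
      abort(paste0(
        "id mismatch between radiome and ", nm, ": ",
        paste(head(c(missing, extra), 5), collapse = ", ")
      ))
    }
  }
  orphan(surrogates, "surrogates")
  orphan(labels, "labels")
  # align by id join so row order of the other tables never matters
  surrogates <- surrogates[match(ids, surrogates$id), , drop = FALSE]
  labels <- labels[match(ids, labels$id), , drop = FALSE]

  check_numeric <- function(tab, nm) {
    vals <- dplyr::select(tab, -"id")
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    if (length(bad)) {
      abort(paste0("non-numeric column(s) in ", nm, ": ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    if (anyNA(vals)) {
      j <- names(vals)[vapply(vals, anyNA, logical(1))][1]
      i <- tab$id[which(is.na(vals[[j]]))[1]]
      abort(paste0("missing value in ", nm, " at id ", i, ", column ", j))
    }
  }
  check_numeric(radiome, "radiome")
  check_numeric(surrogates, "surrogates")
  if (anyNA(labels$label)) {
    abort(paste0("missing label for id ",
                 labels$id[which(is.na(labels$label))[1]]))
  }
  if (!all(labels$label %in% c(0, 1))) abort("`label` must be 0/1")
  labels$label <- as.integer(labels$label)
  labels$group_id <- as.character(labels$group_id)
  if (nrow(radiome) < 2) abort("a cohort needs at least 2 patients")

  fnames <- setdiff(names(radiome), "id")
  snames <- setdiff(names(surrogates), "id")
  if (anyDuplicated(fnames)) abort("feature names must be unique")
  if (anyDuplicated(snames)) abort("surrogate names must be unique")

  if (is.null(cr_map)) {
    cr <- ifelse(grepl("::", snames, fixed = TRUE),
                 sub("::.*$", "", snames), "unknown")
    cr_map <- tibble::tibble(surrogate = snames, cr = cr)
  } else {
    cr_map <- tibble::as_tibble(cr_map)
    if (!all(c("surrogate", "cr") %in% names(cr_map))) {
      abort("`cr_map` needs columns `surrogate` and `cr`")
    }
    if (!all(snames %in% cr_map$surrogate)) {
      abort("`cr_map` must cover every surrogate")
    }
    cr_map <- cr_map[match(snames, cr_map$surrogate), c("surrogate", "cr")]
  }

  structure(
    list(radiome = radiome, surrogates = surrogates, labels = labels,
         cr_map = cr_map),
    class = "tn_cohort"
  )
}

#' @export
print.tn_cohort <- function(x, ...) {
  cat(sprintf(
    "<tn_cohort> %d patients, %d radiome features, %d surrogates in %d CRs\n",
    nrow(x$radiome), length(feature_names(x)), length(surrogate_names(x)),
    dplyr::n_distinct(x$cr_map$cr)
  ))
  cat(sprintf("  labels: %d/%d positive\n",
              sum(x$labels$label), nrow(x$labels)))
  invisible(x)
}

#' @rdname tn_cohort
#' @param cohort A `tn_cohort`.
#' @export
feature_names <- function(cohort) setdiff(names(cohort$radiome), "id")

#' @rdname tn_cohort
#' @export
surrogate_names <- function(cohort) setdiff(names(cohort$surrogates), "id")

# numeric matrix views (rownames = patient ids)
radiome_matrix <- function(cohort, rows = NULL) {
  m <- as.matrix(cohort$radiome[, feature_names(cohort), drop = FALSE])
  rownames(m) <- cohort$radiome$id
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

surrogate_matrix <- function(cohort, rows = NULL) {
  m <- as.matrix(cohort$surrogates[, surrogate_names(cohort), drop = FALSE])
  rownames(m) <- cohort$surrogates$id
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

label_vector <- function(cohort, rows = NULL) {
  b <- cohort$labels$label
  if (!is.null(rows)) b <- b[rows]
  b
}

#' Read a cohort from CSV files
#'
#' Files are comma-separated UTF-8 with a header row and a leading `id`
#' column; the labels file has columns `id`, `label` and optionally
#' `group_id`. Rows are joined by id, so file row order is irrelevant.
#'
#' @param radiome_path,surrogate_path,labels_path Paths to the three CSV
#'   files.
#' @inheritParams tn_cohort
#' @return A [tn_cohort()].
#' @export
read_cohort <- function(radiome_path, surrogate_path, labels_path,
                        cr_map = NULL) {
  # base read.csv parses doubles with correctly-rounded strtod, so a
  # write_cohort()/read_cohort() round trip is bit-identical
  rd <- function(p) tibble::as_tibble(utils::read.csv(p, check.names = FALSE))
  tn_cohort(rd(radiome_path), rd(surrogate_path), rd(labels_path), cr_map)
}

#' Write a cohort to CSV files
#'
#' Values are written at full precision so a save/load round trip reproduces
#' the cohort bit-identically.
#'
#' @param cohort A [tn_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("radiome.csv", "surrogates.csv", "labels.csv",
                            "cr_map.csv"))
  wr <- function(x, p) readr::write_csv(x, p)
  wr(cohort$radiome, paths[1])
  wr(cohort$surrogates, paths[2])
  wr(cohort$labels, paths[3])
  wr(cohort$cr_map, paths[4])
  invisible(paths)
}

#' Report data issues that would break qualification or model fitting
#'
#' Flags zero-variance (constant) columns, missing values and single-class
#' label vectors. Constant surrogate columns cannot carry correlation-based
#' qualification scores and are excluded from selection downstream.
#'
#' @param cohort A [tn_cohort()].
#' @return A tibble with columns `table`, `column`, `issue`; zero rows when
#'   the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  issues <- list()
  flag <- function(table, column, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      table = table, column = column, issue = issue
    )
  }
  for (tab in c("radiome", "surrogates")) {
    m <- if (tab == "radiome") radiome_matrix(cohort) else surrogate_matrix(cohort)
    sds <- apply(m, 2, sd)
    for (j in colnames(m)[sds == 0]) flag(tab, j, "zero variance")
    for (j in colnames(m)[apply(m, 2, anyNA)]) flag(tab, j, "missing values")
  }
  b <- label_vector(cohort)
  if (length(unique(b)) < 2) flag("labels", "label", "single class")
  if (length(issues) == 0) {
    tibble::tibble(table = character(), column = character(),
                   issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
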