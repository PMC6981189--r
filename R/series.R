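#' Series containers: in-silico perturbation and phantom protocol series
#'
#' Two kinds of auxiliary series feed surrogate qualification:
#'
#' * A *perturbation* series holds in-silico noise variants of a cohort:
#'   for each of the four noise families (Gaussian, Rayleigh, Poisson,
#'   Gamma) and five monotonically increasing noise levels, the radiome and
#'   surrogate tables re-measured under that degradation, plus the
#'   unperturbed baseline.
#' * A *phantom* series holds repeated measurements of one fixed object under
#'   varying acquisition protocols — pure technical variation with no
#'   biology. One row per protocol.
#'
#' @param baseline List with matrices `radiome` and `surrogates` (patients in
#'   rows), the unperturbed measurement.
#' @param variants Tibble with columns `family`, `level`, `magnitude` and
#'   list-columns `radiome`, `surrogates` holding the per-condition matrices.
#' @return A `tn_series` object of the respective `kind`.
#' @export
perturbation_series <- function(baseline, variants) {
  variants <- tibble::as_tibble(variants)
  fams <- sort(unique(variants$family))
  if (length(fams) != 4) {
    abort("a perturbation series needs exactly 4 noise families")
  }
  for (f in fams) {
    lv <- sort(variants$level[variants$family == f])
    if (!identical(as.integer(lv), 1:5)) {
      abort(sprintf("family '%s' must have levels 1..5", f))
    }
  }
  if (is.null(baseline$radiome) || is.null(baseline$surrogates)) {
    abort("baseline must hold `radiome` and `surrogates` matrices")
  }
  structure(list(kind = "perturbation", baseline = baseline,
                 variants = variants),
            class = "tn_series")
}

#' @rdname perturbation_series
#' @param radiome,surrogates Numeric matrices, one row per protocol
#'   condition.
#' @param protocol Optional tibble describing the per-protocol acquisition
#'   parameters.
#' @export
phantom_series <- function(radiome, surrogates, protocol = NULL) {
  if (nrow(radiome) != nrow(surrogates)) {
    abort("phantom radiome and surrogate matrices must have matching rows")
  }
  if (nrow(radiome) < 2) abort("a phantom series needs >= 2 protocol conditions")
  structure(list(kind = "phantom", radiome = radiome, surrogates = surrogates,
                 protocol = protocol %||%
                   tibble::tibble(protocol = seq_len(nrow(radiome)))),
            class = "tn_series")
}

#' @export
print.tn_series <- function(x, ...) {
  if (x$kind == "perturbation") {
    cat(sprintf("<tn_series: perturbation> %d families x 5 levels, %d patients\n",
                length(unique(x$variants$family)), nrow(x$baseline$radiome)))
  } else {
    cat(sprintf("<tn_series: phantom> %d protocol conditions\n",
                nrow(x$radiome)))
  }
  invisible(x)
}
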