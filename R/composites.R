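#' Standardized cognition composites
#'
#' Builds domain composites as the standardized sum of standardized task
#' scores: each task is z-scored across the cohort (after sign-flipping
#' tasks where lower raw scores mean better performance, e.g. reaction
#' times and error counts), task z-scores are summed within domain and the
#' sum is z-scored again; the global composite is the z-scored sum of the
#' domain composites. Higher values always indicate better performance,
#' and every composite has cohort mean 0 and SD 1 by construction.
#'
#' @param scores data frame of raw task scores, one row per subject.
#' @param domain_map named list: domain -> character vector of task column
#'   names.
#' @param higher_better named logical per task column; missing tasks
#'   default to `TRUE`.
#' @return data frame with one `cognition_<domain>` column per domain and
#'   `cognition_global`.
#' @examples
#' sc <- data.frame(a = c(1, 2, 3), b = c(3, 1, 2))
#' build_composites(sc, list(mem = c("a", "b")))
#' @export
build_composites <- function(scores, domain_map, higher_better = NULL) {
  if (nrow(scores) < 2L) stop("need >= 2 subjects to standardize scores")
  zscore <- function(x, col) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate-score-error: zero variance in '", col, "'")
    }
    (x - mean(x)) / s
  }
  domains <- lapply(names(domain_map), function(dom) {
    cols <- domain_map[[dom]]
    missing <- setdiff(cols, names(scores))
    if (length(missing)) stop("missing task column(s): ",
                              paste(missing, collapse = ", "))
    z <- vapply(cols, function(cl) {
      hb <- if (is.null(higher_better) || is.na(higher_better[cl])) TRUE else
        higher_better[[cl]]
      zscore(if (hb) scores[[cl]] else -scores[[cl]], cl)
    }, numeric(nrow(scores)))
    zscore(rowSums(as.matrix(z)), paste0(dom, " composite"))
  })
  names(domains) <- paste0("cognition_", names(domain_map))
  out <- as.data.frame(domains)
  out$cognition_global <- zscore(rowSums(as.matrix(out)), "global composite")
  out
}
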