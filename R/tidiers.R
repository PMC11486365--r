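#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a torsion-space comparison
#'
#' @param x a `ts_comparison` from [compare_structures()].
#' @param ... unused.
#' @return the per-residue tibble: one row per target residue with its
#'   MCQ, number of aggregated differences and severity band.
#' @exportS3Method generics::tidy
tidy.ts_comparison <- function(x, ...) {
  x$per_residue
}

#' @rdname tidy.ts_comparison
#' @return `glance()`: a one-row tibble with the global MCQ, its term
#'   count, the coverage fractions and the LCS-TA segment length.
#' @exportS3Method generics::glance
glance.ts_comparison <- function(x, ...) {
  cov <- x$coverage
  out <- tibble::tibble(
    global_mcq = x$global_mcq,
    n_terms = x$global_n_terms,
    n_paired = nrow(x$pairing),
    lcs_length = x$lcs$length,
    lcs_mcq = x$lcs$mcq
  )
  for (i in seq_len(nrow(cov))) {
    out[[paste0("coverage_", cov$threshold[i])]] <- cov$fraction[i]
  }
  out
}

#' Tidy a k-medoids clustering
#'
#' @param x a `ts_kmedoids` from [k_medoids()].
#' @param ... unused.
#' @return the assignment tibble (`label`, `cluster`, `is_medoid`,
#'   `dissimilarity` to the own medoid).
#' @exportS3Method generics::tidy
tidy.ts_kmedoids <- function(x, ...) {
  x$assignment
}

#' @rdname tidy.ts_kmedoids
#' @exportS3Method generics::glance
glance.ts_kmedoids <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    total_cost = x$total_cost,
    n = nrow(x$assignment)
  )
}
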