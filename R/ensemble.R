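#' All-pairs MCQ dissimilarity matrix
#'
#' Computes the symmetric model-by-model matrix of global MCQ values, with
#' residues paired by sequence LCS for every pair. The diagonal is zero.
#' A pair with an empty pairing (no shared letters) yields an `NA` entry
#' with a warning; the downstream embedding/clustering operations require
#' a fully defined matrix.
#'
#' @param models a named list of `ts_torsions` or `ts_structure` objects
#'   (at least two). Unnamed lists get labels `model_1`, `model_2`, ...
#' @param angles angle kinds entering the MCQ sums.
#' @return an n x n symmetric numeric matrix (degrees) with model labels
#'   as dimnames.
#' @export
mcq_dissimilarity <- function(models, angles = mcq_default_angles()) {
  if (!is.list(models) || length(models) < 2) {
    stop("need at least two models to build a dissimilarity matrix",
         call. = FALSE)
  }
  tors <- lapply(models, as_torsions)
  labels <- names(tors)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- paste0("model_", seq_along(tors))
  }
  n <- length(tors)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- as.numeric(global_mcq(tors[[i]], tors[[j]], angles = angles))
      if (is.na(v)) {
        warning("no comparable residues between ", labels[i], " and ",
                labels[j], "; dissimilarity undefined", call. = FALSE)
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

check_dissim <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("dissimilarity must be a square matrix", call. = FALSE)
  }
  if (anyNA(m)) {
    stop("dissimilarity matrix has undefined entries; ",
         "all pairs must be comparable", call. = FALSE)
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("model_", seq_len(nrow(m)))
  }
  m
}

#' Classical (Torgerson-Gower) multidimensional scaling
#'
#' Embeds the models in a low-dimensional Euclidean space from the
#' dissimilarity matrix: squared dissimilarities are double-centered
#' (B = -J D^2 J / 2), eigendecomposed, and the top axes scaled by the
#' square root of their eigenvalues. Negative eigenvalues -- inevitable
#' for angular dissimilarities, which are not exactly Euclidean -- are
#' clamped to zero, zeroing the corresponding axes. The embedding is
#' centred at the origin; its orientation and axis signs are arbitrary.
#'
#' @param m symmetric dissimilarity matrix with zero diagonal.
#' @param dims number of output dimensions (default 2).
#' @return a `ts_mds` tibble with columns `label`, `dim1`, `dim2`, ...;
#'   attributes `eigenvalues` (all n of them) and `degenerate` (TRUE when
#'   fewer than 3 points were embedded).
#' @export
mds_embed <- function(m, dims = 2) {
  m <- check_dissim(m)
  n <- nrow(m)
  # cmdscale warns when clamped (non-positive) eigenvalues truncate the
  # requested dimensionality; that case is part of the contract here
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = min(dims, n - 1), eig = TRUE)
  )
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < dims) {
    extra <- matrix(0, n, dims - ncol(pts))
    pts <- cbind(pts, extra)
  }
  pts[, which(fit$eig[seq_len(dims)] < 0)] <- 0
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(pts[, seq_len(dims), drop = FALSE]),
    paste0("dim", seq_len(dims))
  ))
  out <- dplyr::bind_cols(tibble::tibble(label = rownames(m)), out)
  attr(out, "eigenvalues") <- fit$eig
  attr(out, "degenerate") <- n < 3
  class(out) <- c("ts_mds", class(out))
  out
}

pam_cost <- function(m, med) {
  sum(apply(m[, med, drop = FALSE], 1, min))
}

pam_swap <- function(m, med) {
  n <- nrow(m)
  repeat {
    cost <- pam_cost(m, med)
    best <- NULL
    best_cost <- cost
    for (mi in seq_along(med)) {
      for (h in setdiff(seq_len(n), med)) {
        cand <- med
        cand[mi] <- h
        cc <- pam_cost(m, cand)
        if (cc < best_cost - 1e-12) {
          best_cost <- cc
          best <- cand
        }
      }
    }
    if (is.null(best)) return(med)
    med <- best
  }
}

#' k-medoids (PAM) clustering on a dissimilarity matrix
#'
#' Partitioning Around Medoids operating directly on the dissimilarity
#' matrix, so cluster centres are always actual models.
#'
#' For small problems (`choose(n, k)` up to `exact_limit`, which covers
#' every ensemble a structure-comparison run realistically produces) the
#' medoid set is found by exact enumeration, so the reported clustering is
#' the global cost optimum, deterministically, with ties broken by the
#' lexicographically smallest medoid index set. Beyond that limit the
#' classic PAM search is used: deterministic BUILD initialization (greedy
#' cost-minimizing medoid additions), then SWAP passes exchanging a medoid
#' for a non-medoid while any exchange reduces the total cost (the sum of
#' each point's dissimilarity to its nearest medoid). BUILD+SWAP is a
#' local search and can stop short of the global optimum; optional seeded
#' random restarts explore additional starting sets and keep the best
#' final cost. With the default `restarts = 0` every path is fully
#' deterministic.
#'
#' @param m symmetric dissimilarity matrix with zero diagonal.
#' @param k number of clusters, 1 <= k <= n.
#' @param method `"auto"` (exact when small, else PAM), `"exact"` or
#'   `"pam"`.
#' @param exact_limit largest `choose(n, k)` solved by enumeration under
#'   `method = "auto"`.
#' @param restarts number of extra random-initialization restarts (PAM
#'   path only).
#' @param seed integer seed used only when `restarts > 0`.
#' @return a `ts_kmedoids` object: list with `k`, `medoids` (labels),
#'   `assignment` tibble (`label`, `cluster`, `is_medoid`,
#'   `dissimilarity` to own medoid), `total_cost` and `method` used.
#' @export
k_medoids <- function(m, k, method = c("auto", "exact", "pam"),
                      exact_limit = 1e4, restarts = 0, seed = 1) {
  method <- match.arg(method)
  m <- check_dissim(m)
  n <- nrow(m)
  if (k < 1 || k > n) {
    stop("k must be between 1 and the number of models (", n, ")",
         call. = FALSE)
  }
  if (method == "auto") {
    method <- if (choose(n, k) <= exact_limit) "exact" else "pam"
  }
  if (method == "exact") {
    combos <- utils::combn(n, k)
    costs <- apply(combos, 2, function(med) pam_cost(m, med))
    best_med <- combos[, which.min(costs)]
    return(kmedoids_result(m, k, best_med, method))
  }
  # BUILD: start from the most central point, then greedy additions
  med <- which.min(colSums(m))
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    costs <- vapply(cand, function(h) pam_cost(m, c(med, h)), numeric(1))
    med <- c(med, cand[which.min(costs)])
  }
  med <- pam_swap(m, sort(med))
  best_med <- med
  best_cost <- pam_cost(m, med)
  if (restarts > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    for (r in seq_len(restarts)) {
      med_r <- pam_swap(m, sort(sample(n, k)))
      cost_r <- pam_cost(m, med_r)
      if (cost_r < best_cost - 1e-12) {
        best_cost <- cost_r
        best_med <- med_r
      }
    }
  }
  kmedoids_result(m, k, best_med, method)
}

kmedoids_result <- function(m, k, med, method) {
  n <- nrow(m)
  med <- sort(med)
  nearest <- apply(m[, med, drop = FALSE], 1, which.min)
  assignment <- tibble::tibble(
    label = rownames(m),
    cluster = as.integer(nearest),
    is_medoid = seq_len(n) %in% med,
    dissimilarity = m[cbind(seq_len(n), med[nearest])]
  )
  structure(
    list(k = k, medoids = rownames(m)[med], assignment = assignment,
         total_cost = pam_cost(m, med), method = method),
    class = "ts_kmedoids"
  )
}

#' @export
print.ts_kmedoids <- function(x, ...) {
  cat("k-medoids clustering, k =", x$k, "\n")
  cat("  medoids:", paste(x$medoids, collapse = ", "), "\n")
  cat("  total cost:", round(x$total_cost, 3), "deg\n")
  invisible(x)
}

#' Average-linkage dendrogram of a dissimilarity matrix
#'
#' Agglomerative clustering (UPGMA) of the models; merge heights are mean
#' between-group MCQ dissimilarities in degrees.
#'
#' @param m symmetric dissimilarity matrix with zero diagonal.
#' @return an [stats::hclust] object.
#' @seealso [as_newick()] to serialize with branch lengths.
#' @export
mcq_dendrogram <- function(m) {
  m <- check_dissim(m)
  stats::hclust(stats::as.dist(m), method = "average")
}

#' Serialize a dendrogram to Newick
#'
#' @param hc an [stats::hclust] object, e.g. from [mcq_dendrogram()].
#' @return a single Newick string with branch lengths.
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
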