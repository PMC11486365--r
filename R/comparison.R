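#' Minimum circular difference between two angles
#'
#' `delta(a, b) = min(|a - b| mod 360, 360 - |a - b| mod 360)`: the
#' smaller of the two arcs between the directions, always in [0, 180],
#' regardless of the representation the inputs use.
#'
#' @param a,b numeric vectors of angles in degrees; `NA` propagates.
#' @return numeric vector of differences in degrees in [0, 180].
#' @examples
#' angle_diff(350, 10) # 20
#' angle_diff(-170, 170) # 20
#' @export
angle_diff <- function(a, b) {
  d <- abs(wrap360(a) - wrap360(b)) %% 360
  pmin(d, 360 - d)
}

#' Mean of circular quantities
#'
#' Aggregates a set of angular differences into a single dissimilarity:
#' each difference is decomposed into sine and cosine components, the
#' components are summed, and the two-argument arctangent recombines them.
#' Because every difference lies in [0, 180] the sine sum is non-negative
#' and the result lands in [0, 180]; the two-argument form keeps values
#' above 90 in the correct quadrant where a plain arctangent would not.
#' `NA` differences are skipped.
#'
#' @param d numeric vector of angular differences in degrees (each in
#'   [0, 180], as produced by [angle_diff()]).
#' @return scalar MCQ in degrees, with attribute `n_terms` (number of
#'   defined differences aggregated); `NA` when no difference is defined.
#' @examples
#' mcq(c(30, 30, 30)) # 30
#' mcq(c(0, 90)) # 45
#' @export
mcq <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    return(structure(NA_real_, n_terms = 0L))
  }
  val <- wrap180(rad2deg(atan2(sum(sin(deg2rad(d))),
                               sum(cos(deg2rad(d))))))
  structure(val, n_terms = length(d))
}

#' Severity band of an angular difference
#'
#' The four bands used to colour per-residue comparison heatmaps:
#' `[0,15)`, `[15,30)`, `[30,60)` and `[60,180]`.
#'
#' @param x numeric vector of differences/MCQ values in degrees.
#' @return factor with the four band labels.
#' @export
severity_bin <- function(x) {
  cut(x, breaks = c(0, 15, 30, 60, 180 + 1e-9), right = FALSE,
      include.lowest = TRUE,
      labels = c("[0,15)", "[15,30)", "[30,60)", "[60,180]"))
}

#' Pair residues by longest common subsequence
#'
#' Aligns two nucleotide sequences by their longest common subsequence
#' (case-insensitive, so modified residues mapped to lowercase parent
#' letters pair with their parents). Among co-optimal alignments the
#' leftmost-in-target, then leftmost-in-model traceback is returned.
#'
#' @param target_seq,model_seq sequence strings of one-letter codes.
#' @return tibble with columns `target_pos`, `model_pos` (1-based
#'   positions), strictly increasing in both; zero rows when the sequences
#'   share no letter.
#' @examples
#' pair_residues("ACGU", "AGU")
#' @export
pair_residues <- function(target_seq, model_seq) {
  t <- strsplit(toupper(target_seq), "")[[1]]
  m <- strsplit(toupper(model_seq), "")[[1]]
  n <- length(t)
  k <- length(m)
  if (n == 0 || k == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  # L[i, j] = LCS length of t[i..n] vs m[j..k] (1-padded suffix table)
  L <- matrix(0L, n + 1, k + 1)
  for (i in n:1) {
    for (j in k:1) {
      L[i, j] <- if (t[i] == m[j]) L[i + 1, j + 1] + 1L
                 else max(L[i + 1, j], L[i, j + 1])
    }
  }
  tp <- integer(0)
  mp <- integer(0)
  i <- 1L
  j <- 1L
  while (i <= n && j <= k && L[i, j] > 0L) {
    if (t[i] == m[j]) {
      tp <- c(tp, i)
      mp <- c(mp, j)
      i <- i + 1L
      j <- j + 1L
    } else if (L[i, j + 1] == L[i, j]) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(target_pos = tp, model_pos = mp)
}

# Sequence string of a torsion table, rows in (chain, res_seq) order.
torsions_sequence <- function(torsions) {
  paste(torsions$one_letter, collapse = "")
}

check_angles <- function(angles) {
  bad <- setdiff(angles, comparable_angles())
  if (length(angles) == 0) {
    stop("angle selection must be non-empty", call. = FALSE)
  }
  if (length(bad) > 0) {
    stop("not comparable angle kind(s): ", paste(bad, collapse = ", "),
         " (the pseudorotation phase is derived, not a torsion); ",
         "valid kinds: ", paste(comparable_angles(), collapse = ", "),
         call. = FALSE)
  }
  angles
}

#' Per-angle differences between paired residues
#'
#' @param target,model `ts_torsions` tibbles.
#' @param pairing residue pairing from [pair_residues()]; default: pairing
#'   of the two one-letter sequences.
#' @param angles character vector of angle kinds to compare; default
#'   backbone + glycosidic ([mcq_default_angles()]).
#' @return long tibble with one row per paired residue and angle kind:
#'   `target_pos`, `model_pos`, `kind`, `target_value`, `model_value`,
#'   `delta`.
#' @export
residue_diffs <- function(target, model, pairing = NULL,
                          angles = mcq_default_angles()) {
  angles <- check_angles(angles)
  if (is.null(pairing)) {
    pairing <- pair_residues(torsions_sequence(target),
                             torsions_sequence(model))
  }
  if (nrow(pairing) == 0) {
    return(tibble::tibble(target_pos = integer(), model_pos = integer(),
                          kind = character(), target_value = numeric(),
                          model_value = numeric(), delta = numeric()))
  }
  dplyr::bind_rows(lapply(angles, function(k) {
    tv <- target[[k]][pairing$target_pos]
    mv <- model[[k]][pairing$model_pos]
    tibble::tibble(
      target_pos = pairing$target_pos, model_pos = pairing$model_pos,
      kind = k, target_value = tv, model_value = mv,
      delta = angle_diff(tv, mv)
    )
  }))
}

#' Per-residue MCQ against a target
#'
#' For each paired residue, the MCQ over the defined differences of the
#' selected angle kinds at that residue, with its severity band. Unpaired
#' target residues are reported with an undefined MCQ.
#'
#' @inheritParams residue_diffs
#' @return tibble with one row per target residue: `target_pos`,
#'   `model_pos`, `chain`, `auth_number`, `ins_code`, `one_letter`, `mcq`,
#'   `n_terms`, `severity`.
#' @export
per_residue_mcq <- function(target, model, pairing = NULL,
                            angles = mcq_default_angles()) {
  angles <- check_angles(angles)
  if (is.null(pairing)) {
    pairing <- pair_residues(torsions_sequence(target),
                             torsions_sequence(model))
  }
  d <- residue_diffs(target, model, pairing, angles)
  per <- d |>
    dplyr::group_by(.data$target_pos, .data$model_pos) |>
    dplyr::summarise(
      mcq = as.numeric(mcq(.data$delta)),
      n_terms = sum(!is.na(.data$delta)),
      .groups = "drop"
    )
  out <- tibble::tibble(
    target_pos = seq_len(nrow(target)),
    chain = target$chain, auth_number = target$auth_number,
    ins_code = target$ins_code, one_letter = target$one_letter
  ) |>
    dplyr::left_join(per, by = "target_pos") |>
    dplyr::mutate(
      n_terms = dplyr::coalesce(.data$n_terms, 0L),
      severity = severity_bin(.data$mcq)
    )
  out[, c("target_pos", "model_pos", "chain", "auth_number", "ins_code",
          "one_letter", "mcq", "n_terms", "severity")]
}

#' Global MCQ between two structures
#'
#' One MCQ over the pooled defined differences of all paired residues --
#' not the mean of per-residue MCQs.
#'
#' @inheritParams residue_diffs
#' @return scalar MCQ in degrees with attribute `n_terms`; `NA` when the
#'   pool is empty (e.g. disjoint sequences).
#' @export
global_mcq <- function(target, model, pairing = NULL,
                       angles = mcq_default_angles()) {
  angles <- check_angles(angles)
  if (is.null(pairing)) {
    pairing <- pair_residues(torsions_sequence(target),
                             torsions_sequence(model))
  }
  if (nrow(pairing) == 0) {
    return(structure(NA_real_, n_terms = 0L))
  }
  d <- residue_diffs(target, model, pairing, angles)
  mcq(d$delta)
}

#' Fraction of residues under dissimilarity thresholds
#'
#' @param values numeric vector of per-residue MCQ values in degrees.
#' @param thresholds ascending thresholds in degrees; defaults to the
#'   severity-band edges 15, 30, 60.
#' @return tibble with columns `threshold`, `fraction` (of defined values
#'   strictly below the threshold; `NA` when none defined), `n_defined`.
#' @export
coverage_fractions <- function(values, thresholds = c(15, 30, 60)) {
  if (is.unsorted(thresholds)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  v <- values[!is.na(values)]
  tibble::tibble(
    threshold = thresholds,
    fraction = if (length(v) == 0) NA_real_
               else vapply(thresholds, function(t) mean(v < t), numeric(1)),
    n_defined = length(v)
  )
}

#' Longest continuous segment under an MCQ threshold (LCS-TA)
#'
#' Finds the longest run of consecutively paired residues (consecutive in
#' both target and model) whose pooled MCQ over the selected angles stays
#' at or below `threshold`. All candidate windows are evaluated with
#' incremental sine/cosine prefix sums, scanning lengths longest-first;
#' the exhaustive scan is used because window feasibility is not monotone
#' in window length for circular means, so a binary search on length can
#' miss the optimum. Ties at equal length are broken by smaller MCQ, then
#' by leftmost target position.
#'
#' @inheritParams residue_diffs
#' @param threshold MCQ threshold in degrees (inclusive).
#' @return one-row tibble `target_start`, `model_start`, `length`, `mcq`,
#'   `n_terms`. When no single paired residue is under the threshold,
#'   `length` is 0 and the positions are `NA`.
#' @export
lcs_ta <- function(target, model, pairing = NULL,
                   angles = mcq_default_angles(), threshold = 15) {
  angles <- check_angles(angles)
  if (is.null(threshold) || is.na(threshold) || threshold <= 0) {
    stop("threshold must be a positive number of degrees", call. = FALSE)
  }
  if (is.null(pairing)) {
    pairing <- pair_residues(torsions_sequence(target),
                             torsions_sequence(model))
  }
  empty <- tibble::tibble(target_start = NA_integer_,
                          model_start = NA_integer_, length = 0L,
                          mcq = NA_real_, n_terms = 0L)
  if (nrow(pairing) == 0) return(empty)
  d <- residue_diffs(target, model, pairing, angles)
  pos <- d |>
    dplyr::group_by(.data$target_pos, .data$model_pos) |>
    dplyr::summarise(
      s = sum(sin(deg2rad(.data$delta)), na.rm = TRUE),
      c = sum(cos(deg2rad(.data$delta)), na.rm = TRUE),
      m = sum(!is.na(.data$delta)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$target_pos)
  # runs of pairs consecutive in BOTH chains
  np <- nrow(pos)
  new_run <- c(TRUE, diff(pos$target_pos) != 1 | diff(pos$model_pos) != 1)
  run_id <- cumsum(new_run)
  best <- empty
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    S <- c(0, cumsum(pos$s[idx]))
    C <- c(0, cumsum(pos$c[idx]))
    M <- c(0, cumsum(pos$m[idx]))
    L <- length(idx)
    for (len in L:1) {
      if (len < best$length) break
      starts <- seq_len(L - len + 1)
      ds <- S[starts + len] - S[starts]
      dc <- C[starts + len] - C[starts]
      dm <- M[starts + len] - M[starts]
      v <- wrap180(rad2deg(atan2(ds, dc)))
      ok <- dm > 0 & v <= threshold
      if (any(ok)) {
        w <- which(ok)
        w <- w[order(v[w], w)][1]
        cand <- tibble::tibble(
          target_start = pos$target_pos[idx[w]],
          model_start = pos$model_pos[idx[w]],
          length = len, mcq = v[w], n_terms = as.integer(dm[w])
        )
        take <- len > best$length ||
          (len == best$length &&
             (is.na(best$mcq) || cand$mcq < best$mcq ||
                (cand$mcq == best$mcq &&
                   cand$target_start < best$target_start)))
        if (take) best <- cand
        break
      }
    }
  }
  best
}

#' Compare a model against a target structure in torsion space
#'
#' High-level model-vs-target comparison: pairs residues by sequence LCS,
#' computes per-residue and global MCQ over the selected angles, coverage
#' fractions under the severity thresholds, and the LCS-TA segment.
#'
#' @param target,model `ts_torsions` tibbles (or `ts_structure` tibbles,
#'   which are run through [calc_torsions()] first).
#' @param angles angle kinds used for all MCQ sums.
#' @param lcs_threshold LCS-TA threshold in degrees.
#' @return a `ts_comparison` object; see [tidy()][generics::tidy] for the
#'   per-residue table and [glance()][generics::glance] for the one-row
#'   summary.
#' @export
compare_structures <- function(target, model,
                               angles = mcq_default_angles(),
                               lcs_threshold = 15) {
  target <- as_torsions(target)
  model <- as_torsions(model)
  pairing <- pair_residues(torsions_sequence(target),
                           torsions_sequence(model))
  per <- per_residue_mcq(target, model, pairing, angles)
  gl <- global_mcq(target, model, pairing, angles)
  cov <- coverage_fractions(per$mcq)
  lcs <- lcs_ta(target, model, pairing, angles, lcs_threshold)
  structure(
    list(
      pairing = pairing,
      per_residue = per,
      diffs = residue_diffs(target, model, pairing, angles),
      global_mcq = as.numeric(gl),
      global_n_terms = attr(gl, "n_terms"),
      coverage = cov,
      lcs = lcs,
      angles = angles,
      lcs_threshold = lcs_threshold,
      target = target,
      model = model
    ),
    class = "ts_comparison"
  )
}

as_torsions <- function(x) {
  if (inherits(x, "ts_torsions")) return(x)
  if (inherits(x, "ts_structure")) return(calc_torsions(x))
  stop("expected a ts_torsions or ts_structure object", call. = FALSE)
}

#' @export
print.ts_comparison <- function(x, ...) {
  cat("Torsion-space comparison (",
      paste(x$angles, collapse = ", "), ")\n", sep = "")
  cat("  paired residues:", nrow(x$pairing), "of", nrow(x$target),
      "target residues\n")
  cat("  global MCQ:", round(x$global_mcq, 2), "deg over",
      x$global_n_terms, "differences\n")
  cov <- x$coverage
  cat("  coverage:",
      paste(sprintf("%.0f%% < %g deg", 100 * cov$fraction, cov$threshold),
            collapse = ", "), "\n")
  cat("  LCS-TA (<= ", x$lcs_threshold, " deg): length ", x$lcs$length,
      " at target position ", x$lcs$target_start, "\n", sep = "")
  invisible(x)
}
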