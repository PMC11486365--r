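# CSV report writers behind the three analysis scenarios. All numbers are
# rendered with 2 decimal places, undefined values as blank fields, and
# repeated runs with the same configuration produce identical files.

round2 <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  function(x) round(x, 2)))
}

write_report_csv <- function(df, path) {
  readr::write_csv(round2(df), path, na = "")
  path
}

model_labels <- function(paths) {
  lab <- sub("\\.[^.]*$", "", basename(paths))
  make.unique(lab, sep = "_")
}

load_selected <- function(input, model = NULL, chains = NULL,
                          range = NULL, auth = FALSE) {
  struct <- read_structure(input)
  select_region(struct, model = model, chains = chains, range = range,
                auth = auth)
}

#' Single-structure torsion report
#'
#' Computes the full angular record of one structure and writes
#' `torsions.csv` (one row per residue, all angle kinds, pucker and
#' glycosidic class), `statistics.csv` (per-kind circular statistics and
#' syn/anti tallies) and `histograms.csv` (angular histograms).
#'
#' @param input path to a PDB or mmCIF file.
#' @param out_dir output directory (created if needed).
#' @param model,chains,range,auth selection, see [select_region()].
#' @param bin_width histogram bin width in degrees.
#' @param break_cutoff chain-break O3'-P cutoff in Angstroms.
#' @return (invisibly) named character vector of the files written.
#' @export
run_single <- function(input, out_dir, model = NULL, chains = NULL,
                       range = NULL, auth = FALSE, bin_width = 15,
                       break_cutoff = 2.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  struct <- load_selected(input, model, chains, range, auth)
  tor <- calc_torsions(struct, break_cutoff = break_cutoff)
  tor_out <- tor |>
    dplyr::select("chain", "auth_number", "ins_code", "res_name",
                  "one_letter", dplyr::all_of(angle_kinds()), "pucker",
                  "glycosidic")
  stats_out <- dplyr::bind_rows(
    torsion_summary(tor),
    syn_anti_counts(tor) |>
      tidyr::pivot_longer(dplyr::everything(),
                          names_to = "kind", values_to = "n_defined") |>
      dplyr::mutate(kind = paste0("glycosidic_", .data$kind))
  )
  hist_out <- torsion_histograms(tor, bin_width = bin_width)
  files <- c(
    torsions = write_report_csv(tor_out, file.path(out_dir,
                                                   "torsions.csv")),
    statistics = write_report_csv(stats_out,
                                  file.path(out_dir, "statistics.csv")),
    histograms = write_report_csv(hist_out,
                                  file.path(out_dir, "histograms.csv"))
  )
  invisible(files)
}

#' Model(s)-versus-target comparison report
#'
#' Compares up to 10 models against a target structure and writes
#' `per_residue_mcq.csv` (target residues x models, long format, with
#' severity bands), `global.csv`, `coverage.csv` (percentage of residues
#' under 15/30/60 degrees per model), `lcs_ta.csv` (segment position,
#' length and MCQ per model) and one `differences_<model>.csv` per model
#' with the per-residue per-angle circular differences. A model whose
#' sequence shares nothing with the target is reported with undefined
#' values rather than aborting the other comparisons.
#'
#' @param target path to the target structure file.
#' @param models character vector of 1 to 10 model file paths.
#' @param out_dir output directory.
#' @param model,chains,range,auth selection applied to the target.
#' @param angles angle kinds used in all MCQ sums.
#' @param lcs_threshold LCS-TA threshold in degrees.
#' @param break_cutoff chain-break O3'-P cutoff in Angstroms.
#' @return (invisibly) named character vector of the files written.
#' @export
run_vs_target <- function(target, models, out_dir, model = NULL,
                          chains = NULL, range = NULL, auth = FALSE,
                          angles = mcq_default_angles(),
                          lcs_threshold = 15, break_cutoff = 2.5) {
  if (length(models) < 1 || length(models) > 10) {
    stop("between 1 and 10 model files are handled in one task; got ",
         length(models), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tt <- calc_torsions(load_selected(target, model, chains, range, auth),
                      break_cutoff = break_cutoff)
  labels <- model_labels(models)
  per_all <- list()
  glob_all <- list()
  cov_all <- list()
  lcs_all <- list()
  files <- character()
  for (i in seq_along(models)) {
    mt <- calc_torsions(read_structure(models[i]),
                        break_cutoff = break_cutoff)
    cmpr <- compare_structures(tt, mt, angles = angles,
                               lcs_threshold = lcs_threshold)
    per_all[[i]] <- dplyr::mutate(cmpr$per_residue, model = labels[i],
                                  .before = 1)
    glob_all[[i]] <- tibble::tibble(model = labels[i],
                                    mcq = cmpr$global_mcq,
                                    n_terms = cmpr$global_n_terms,
                                    n_paired = nrow(cmpr$pairing))
    cov_all[[i]] <- dplyr::mutate(cmpr$coverage, model = labels[i],
                                  percent = 100 * .data$fraction,
                                  .before = 1)
    lcs_all[[i]] <- dplyr::mutate(cmpr$lcs, model = labels[i],
                                  .before = 1)
    diffs_wide <- cmpr$diffs |>
      dplyr::select("target_pos", "model_pos", "kind", "delta") |>
      tidyr::pivot_wider(names_from = "kind", values_from = "delta")
    f <- file.path(out_dir, paste0("differences_", labels[i], ".csv"))
    files[paste0("differences_", labels[i])] <-
      write_report_csv(diffs_wide, f)
  }
  files["per_residue_mcq"] <- write_report_csv(
    dplyr::bind_rows(per_all), file.path(out_dir, "per_residue_mcq.csv")
  )
  files["global"] <- write_report_csv(
    dplyr::bind_rows(glob_all), file.path(out_dir, "global.csv")
  )
  files["coverage"] <- write_report_csv(
    dplyr::bind_rows(cov_all) |>
      dplyr::select("model", "threshold", "percent", "n_defined"),
    file.path(out_dir, "coverage.csv")
  )
  files["lcs_ta"] <- write_report_csv(
    dplyr::bind_rows(lcs_all), file.path(out_dir, "lcs_ta.csv")
  )
  invisible(files)
}

#' Model-versus-model ensemble report
#'
#' Computes the all-pairs MCQ dissimilarity matrix of two or more models
#' and writes `dissimilarity.csv` (square matrix), `mds.csv` (2D
#' classical-MDS embedding), `dendrogram.newick` (average-linkage tree)
#' and, when `k` is given, `clusters.csv` (k-medoids assignment with
#' medoid flags).
#'
#' @param inputs character vector of at least two structure file paths.
#' @param out_dir output directory.
#' @param angles angle kinds used in the MCQ sums.
#' @param k optional number of k-medoids clusters.
#' @param restarts,seed optional k-medoids random restarts (default none:
#'   fully deterministic).
#' @param break_cutoff chain-break O3'-P cutoff in Angstroms.
#' @return (invisibly) named character vector of the files written.
#' @export
run_vs_models <- function(inputs, out_dir,
                          angles = mcq_default_angles(), k = NULL,
                          restarts = 0, seed = 1, break_cutoff = 2.5) {
  if (length(inputs) < 2) {
    stop("the model-vs-model scenario needs at least two structure ",
         "files; got ", length(inputs), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- model_labels(inputs)
  tors <- lapply(inputs, function(p) {
    calc_torsions(read_structure(p), break_cutoff = break_cutoff)
  })
  names(tors) <- labels
  m <- mcq_dissimilarity(tors, angles = angles)
  files <- character()
  files["dissimilarity"] <- write_report_csv(
    dplyr::bind_cols(tibble::tibble(model = rownames(m)),
                     tibble::as_tibble(m)),
    file.path(out_dir, "dissimilarity.csv")
  )
  files["mds"] <- write_report_csv(
    tibble::as_tibble(mds_embed(m)),
    file.path(out_dir, "mds.csv")
  )
  if (!is.null(k)) {
    km <- k_medoids(m, k, restarts = restarts, seed = seed)
    files["clusters"] <- write_report_csv(
      km$assignment, file.path(out_dir, "clusters.csv")
    )
  }
  nwk <- as_newick(mcq_dendrogram(m))
  f <- file.path(out_dir, "dendrogram.newick")
  writeLines(nwk, f)
  files["dendrogram"] <- f
  invisible(files)
}
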