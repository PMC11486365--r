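#' @importFrom rlang .data
NULL

# One-letter codes for common standard and modified nucleotides. Unknown
# codes fall back to a lowercase guess from the base atoms (see
# guess_one_letter), else "n".
MODIFIED_ONE_LETTER <- c(
  A = "A", ADE = "A", G = "G", GUA = "G", C = "C", CYT = "C",
  U = "U", URA = "U", T = "T", THY = "T",
  DA = "A", DG = "G", DC = "C", DT = "T", DU = "U",
  PSU = "U", `1MA` = "A", `2MG` = "G", M2G = "G", `7MG` = "G",
  OMG = "G", OMC = "C", `5MC` = "C", `5MU` = "U", H2U = "U",
  `4SU` = "U", I = "I", DI = "I"
)

# Atoms that make a residue count as a nucleotide (ribose core). DNA lacks
# only O2', which is not required.
SUGAR_CORE_ATOMS <- c("C1'", "C3'", "C4'", "O4'")

new_structure <- function(df, source_format) {
  df <- tibble::as_tibble(df)
  attr(df, "source_format") <- source_format
  class(df) <- c("ts_structure", class(df))
  df
}

#' Read a nucleic-acid structure file
#'
#' Parses a PDB or PDBx/mmCIF file into a flat atom table: one row per
#' atom, with residue identity (`model`, `chain`, `res_seq`, `auth_number`,
#' `ins_code`, `res_name`), derived residue annotation (`one_letter`,
#' `base_class`) and coordinates. All models are retained. Waters, ions and
#' amino acids are dropped; modified nucleotides (anything with an intact
#' ribose/deoxyribose core) are kept. Alternate locations are resolved
#' deterministically: highest occupancy wins, ties broken by the
#' lexicographically smallest altloc identifier.
#'
#' @param path path to a structure file.
#' @param format `"auto"` (default), `"pdb"` or `"mmcif"`. Auto-detection
#'   looks for mmCIF `data_`/`loop_`/`_atom_site` tokens.
#' @return a `ts_structure` tibble of atoms.
#' @seealso [parse_structure()] to parse text already in memory,
#'   [write_structure()], [select_region()], [calc_torsions()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }
  parse_structure(readLines(path, warn = FALSE), format = format)
}

#' Parse structure text
#'
#' @param text character: either a single string or a vector of lines in
#'   PDB or PDBx/mmCIF format.
#' @inheritParams read_structure
#' @return a `ts_structure` tibble of atoms.
#' @export
parse_structure <- function(text, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  if (format == "auto") {
    format <- detect_format(lines)
  }
  raw <- switch(format,
    pdb = parse_pdb_lines(lines),
    mmcif = parse_mmcif_lines(lines)
  )
  finalize_structure(raw, format)
}

detect_format <- function(lines) {
  head_lines <- utils::head(lines[nzchar(trimws(lines))], 50)
  if (any(grepl("^data_", head_lines)) ||
      any(grepl("_atom_site\\.", lines)) ||
      any(grepl("^\\s*loop_", head_lines))) {
    return("mmcif")
  }
  if (any(grepl("^(ATOM|HETATM|MODEL|HEADER|CRYST1|REMARK|COMPND|TER|END)",
                lines))) {
    return("pdb")
  }
  stop("cannot detect structure format: first line is ",
       deparse(substr(lines[1], 1, 60)), call. = FALSE)
}

sub_col <- function(lines, from, to) {
  trimws(substr(lines, from, to))
}

parse_pdb_lines <- function(lines) {
  model_no <- 1L
  model_of <- integer(length(lines))
  is_atom <- logical(length(lines))
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (startsWith(rec, "MODEL")) {
      num <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 80))))
      model_no <- if (is.na(num)) model_no + 1L else num
    } else if (startsWith(rec, "ATOM") || startsWith(rec, "HETATM")) {
      is_atom[i] <- TRUE
      model_of[i] <- model_no
    }
  }
  al <- lines[is_atom]
  if (length(al) == 0) {
    stop("no ATOM/HETATM records found; first line: ",
         deparse(substr(lines[1], 1, 60)), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(sub_col(al, 31, 38)))
  y <- suppressWarnings(as.numeric(sub_col(al, 39, 46)))
  z <- suppressWarnings(as.numeric(sub_col(al, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop("unparseable coordinates in PDB record: ",
         deparse(substr(al[bad[1]], 1, 60)), call. = FALSE)
  }
  occ <- suppressWarnings(as.numeric(sub_col(al, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- sub_col(al, 77, 78)
  name <- gsub("*", "'", sub_col(al, 13, 16), fixed = TRUE)
  auth <- suppressWarnings(as.integer(sub_col(al, 23, 26)))
  if (anyNA(auth)) {
    stop("unparseable residue number in PDB record: ",
         deparse(substr(al[which(is.na(auth))[1]], 1, 60)), call. = FALSE)
  }
  tibble::tibble(
    model = model_of[is_atom],
    chain = substr(al, 22, 22),
    auth_number = auth,
    ins_code = sub_col(al, 27, 27),
    res_name = toupper(sub_col(al, 18, 20)),
    atom = name,
    altloc = sub_col(al, 17, 17),
    element = elem,
    x = x, y = y, z = z,
    occupancy = occ
  )
}

# Tokenize one mmCIF data line, honouring single/double quotes.
cif_tokens <- function(line) {
  scan(text = line, what = character(), quiet = TRUE,
       quote = "\"'", strip.white = TRUE)
}

cif_na <- function(v, default = "") {
  v[v %in% c("?", ".")] <- default
  v
}

parse_mmcif_lines <- function(lines) {
  loop_idx <- grep("^\\s*loop_\\s*$", lines)
  tags <- character()
  data_lines <- character()
  for (li in loop_idx) {
    j <- li + 1
    cur_tags <- character()
    while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
      cur_tags <- c(cur_tags, trimws(lines[j]))
      j <- j + 1
    }
    if (length(cur_tags) > 0 && all(startsWith(cur_tags, "_atom_site."))) {
      tags <- sub("^_atom_site\\.", "", cur_tags)
      while (j <= length(lines)) {
        ln <- lines[j]
        if (grepl("^\\s*(_|loop_|#|data_)", ln)) break
        if (nzchar(trimws(ln))) data_lines <- c(data_lines, ln)
        j <- j + 1
      }
      break
    }
  }
  if (length(tags) == 0) {
    stop("no _atom_site loop found in mmCIF input", call. = FALSE)
  }
  toks <- unlist(lapply(data_lines, cif_tokens), use.names = FALSE)
  if (length(toks) %% length(tags) != 0) {
    stop("mmCIF atom_site loop has ", length(toks),
         " values, not a multiple of ", length(tags), " columns",
         call. = FALSE)
  }
  m <- matrix(toks, ncol = length(tags), byrow = TRUE)
  colnames(m) <- tags
  col <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% tags) return(m[, nm])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(default, nrow(m))
  }
  xyz <- suppressWarnings(cbind(
    as.numeric(col("Cartn_x")),
    as.numeric(col("Cartn_y")),
    as.numeric(col("Cartn_z"))
  ))
  if (anyNA(xyz)) {
    stop("unparseable mmCIF coordinates in atom_site row ",
         which(rowSums(is.na(xyz)) > 0)[1], call. = FALSE)
  }
  occ <- suppressWarnings(as.numeric(cif_na(col("occupancy"), "1")))
  occ[is.na(occ)] <- 1
  model <- suppressWarnings(as.integer(cif_na(col("pdbx_PDB_model_num"), "1")))
  model[is.na(model)] <- 1L
  auth <- suppressWarnings(
    as.integer(cif_na(col("auth_seq_id", "label_seq_id")))
  )
  if (anyNA(auth)) {
    stop("unparseable residue number in mmCIF atom_site row ",
         which(is.na(auth))[1], call. = FALSE)
  }
  tibble::tibble(
    model = model,
    chain = cif_na(col("auth_asym_id", "label_asym_id", "A")),
    auth_number = auth,
    ins_code = cif_na(col("pdbx_PDB_ins_code")),
    res_name = toupper(cif_na(col("label_comp_id", "auth_comp_id"))),
    atom = gsub("\"", "", cif_na(col("label_atom_id", "auth_atom_id"))),
    altloc = cif_na(col("label_alt_id")),
    element = cif_na(col("type_symbol")),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ
  )
}

guess_one_letter <- function(base_class, atoms) {
  if (base_class == "purine") {
    if ("N6" %in% atoms) return("a")
    if ("O6" %in% atoms) return("g")
    return("n")
  }
  if (base_class == "pyrimidine") {
    if ("N4" %in% atoms) return("c")
    if ("O4" %in% atoms) return("u")
    return("n")
  }
  "n"
}

finalize_structure <- function(raw, source_format) {
  # altloc resolution: highest occupancy, then smallest altloc id ("" first)
  raw <- raw |>
    dplyr::group_by(.data$model, .data$chain, .data$auth_number,
                    .data$ins_code, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  # restore file order of residues within each model/chain
  raw <- raw[order(raw$model), , drop = FALSE]

  key <- paste(raw$model, raw$chain, raw$auth_number, raw$ins_code,
               sep = "\r")
  res_atoms <- split(raw$atom, key)
  nucleic <- vapply(res_atoms, function(a) all(SUGAR_CORE_ATOMS %in% a),
                    logical(1))
  keep <- nucleic[key]
  if (!any(keep)) {
    stop("no nucleic-acid residues found in input ",
         "(waters, ions and amino acids are excluded)", call. = FALSE)
  }
  raw <- raw[keep, , drop = FALSE]
  key <- key[keep]

  atoms_of <- split(raw$atom, key)
  base_class <- vapply(atoms_of, function(a) {
    if (all(c("N9", "C4") %in% a)) "purine"
    else if (all(c("N1", "C2") %in% a) && !("N9" %in% a)) "pyrimidine"
    else "unknown"
  }, character(1))
  one <- vapply(names(atoms_of), function(k) {
    nm <- raw$res_name[match(k, key)]
    if (nm %in% names(MODIFIED_ONE_LETTER)) MODIFIED_ONE_LETTER[[nm]]
    else guess_one_letter(base_class[[k]], atoms_of[[k]])
  }, character(1))
  raw$base_class <- unname(base_class[key])
  raw$one_letter <- unname(one[key])

  # residue ordinal within each model/chain, in file order
  mc <- paste(raw$model, raw$chain, sep = "\r")
  raw$res_seq <- as.integer(
    stats::ave(key, mc, FUN = function(k) match(k, unique(k)))
  )

  out <- raw |>
    dplyr::select("model", "chain", "res_seq", "auth_number", "ins_code",
                  "res_name", "one_letter", "base_class", "atom", "element",
                  "x", "y", "z", "occupancy")
  new_structure(out, source_format)
}

residue_table <- function(struct) {
  struct |>
    dplyr::distinct(.data$model, .data$chain, .data$res_seq,
                    .data$auth_number, .data$ins_code, .data$res_name,
                    .data$one_letter, .data$base_class) |>
    dplyr::arrange(.data$model, .data$chain, .data$res_seq)
}

#' Per-chain nucleotide sequence
#'
#' @param struct a `ts_structure` tibble.
#' @return tibble with one row per model/chain and a `sequence` string of
#'   one-letter codes in residue order.
#' @export
nt_sequence <- function(struct) {
  residue_table(struct) |>
    dplyr::group_by(.data$model, .data$chain) |>
    dplyr::summarise(
      sequence = paste(.data$one_letter, collapse = ""),
      n_residues = dplyr::n(),
      .groups = "drop"
    )
}

#' Detect chain breaks
#'
#' A chain break is flagged after residue `i` when the O3'(i)-P(i+1)
#' distance exceeds `cutoff`, or when either atom is missing. Inter-residue
#' angles (alpha, epsilon, zeta, and the pseudo-torsions) are never
#' computed across a break.
#'
#' @param struct a `ts_structure` tibble.
#' @param cutoff distance cutoff in Angstroms; the default 2.5 covers the
#'   ~1.6 Angstrom covalent O3'-P bond with slack.
#' @return tibble with columns `model`, `chain`, `pos` (residue ordinal
#'   before the break).
#' @export
chain_breaks <- function(struct, cutoff = 2.5) {
  res <- residue_table(struct)
  out <- res |>
    dplyr::group_by(.data$model, .data$chain) |>
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      if (n < 2) return(tibble::tibble(pos = integer()))
      sub <- struct[struct$model == key$model & struct$chain == key$chain, ]
      o3 <- atom_coords(sub, g, "O3'")
      p <- atom_coords(sub, g, "P")
      d <- sqrt(rowSums((o3[-n, , drop = FALSE] - p[-1, , drop = FALSE])^2))
      tibble::tibble(pos = which(is.na(d) | d > cutoff))
    }) |>
    dplyr::ungroup()
  out
}

# n_res x 3 coordinate matrix of one named atom per residue (NA if absent).
atom_coords <- function(sub, res, atom_name) {
  sub <- sub[sub$atom == atom_name, , drop = FALSE]
  idx <- match(paste(res$res_seq, res$auth_number, res$ins_code),
               paste(sub$res_seq, sub$auth_number, sub$ins_code))
  unname(cbind(sub$x[idx], sub$y[idx], sub$z[idx]))
}

#' Select a model, chains and residue range
#'
#' @param struct a `ts_structure` tibble.
#' @param model model number; default: the first model present.
#' @param chains character vector of chain ids; default: all chains of the
#'   model.
#' @param range length-2 integer vector, 1-based inclusive residue
#'   positions within each selected chain (e.g. `c(3, 5)` keeps the 3rd to
#'   5th residues). Default: full range.
#' @param auth if `TRUE`, interpret `range` as author residue numbers
#'   instead of chain positions.
#' @return the trimmed `ts_structure` tibble (residue identities and
#'   numbering preserved).
#' @export
select_region <- function(struct, model = NULL, chains = NULL, range = NULL,
                          auth = FALSE) {
  models <- sort(unique(struct$model))
  if (is.null(model)) model <- models[1]
  if (!model %in% models) {
    stop("model ", model, " not present; available models: ",
         paste(models, collapse = ", "), call. = FALSE)
  }
  out <- struct[struct$model == model, , drop = FALSE]
  avail <- unique(out$chain)
  if (is.null(chains)) chains <- avail
  missing_ch <- setdiff(chains, avail)
  if (length(missing_ch) > 0) {
    stop("chain(s) ", paste(missing_ch, collapse = ", "),
         " not present; available chains: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  out <- out[out$chain %in% chains, , drop = FALSE]
  if (!is.null(range)) {
    if (length(range) != 2 || anyNA(range) || range[1] > range[2]) {
      stop("range must be c(first, last) with first <= last", call. = FALSE)
    }
    if (auth) {
      keep <- out$auth_number >= range[1] & out$auth_number <= range[2]
    } else {
      lens <- tapply(out$res_seq, out$chain, max)
      if (range[1] < 1 || any(range[2] > lens)) {
        stop("range [", range[1], ", ", range[2], "] out of bounds; ",
             "chain lengths: ",
             paste(names(lens), lens, sep = "=", collapse = ", "),
             call. = FALSE)
      }
      keep <- out$res_seq >= range[1] & out$res_seq <= range[2]
    }
    out <- out[keep, , drop = FALSE]
    if (nrow(out) == 0) {
      stop("selection is empty: no residues in range [", range[1], ", ",
           range[2], "]", call. = FALSE)
    }
  }
  new_structure(out, attr(struct, "source_format"))
}

#' Write a structure to PDB or mmCIF text
#'
#' Serializes an atom table back to a minimal standards-conformant file
#' (ATOM/TER/END records, or an `atom_site` loop) that round-trips through
#' [parse_structure()].
#'
#' @param struct a `ts_structure` tibble.
#' @param format `"pdb"` or `"mmcif"`. PDB output requires single-character
#'   chain ids; mmCIF has no such restriction.
#' @param path optional output file path.
#' @return (invisibly) the file text as a character vector of lines.
#' @export
write_structure <- function(struct, format = c("pdb", "mmcif"),
                            path = NULL) {
  format <- match.arg(format)
  if (nrow(struct) == 0) {
    stop("cannot write an empty structure", call. = FALSE)
  }
  lines <- if (format == "pdb") write_pdb_lines(struct)
           else write_mmcif_lines(struct)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

write_pdb_lines <- function(struct) {
  if (any(nchar(struct$chain) > 1)) {
    stop("PDB format restricts chain ids to one character; offending: ",
         paste(unique(struct$chain[nchar(struct$chain) > 1]),
               collapse = ", "),
         "; use mmCIF instead", call. = FALSE)
  }
  models <- sort(unique(struct$model))
  multi <- length(models) > 1
  out <- character()
  for (m in models) {
    sub <- struct[struct$model == m, , drop = FALSE]
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    serial <- 0L
    for (ch in unique(sub$chain)) {
      cs <- sub[sub$chain == ch, , drop = FALSE]
      nm <- ifelse(nchar(cs$atom) >= 4, cs$atom,
                   paste0(" ", cs$atom))
      rec <- sprintf(
        "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial + seq_len(nrow(cs)), nm, cs$res_name, ch, cs$auth_number,
        ifelse(nzchar(cs$ins_code), cs$ins_code, " "),
        cs$x, cs$y, cs$z, cs$occupancy, 0, cs$element
      )
      serial <- serial + nrow(cs)
      last <- cs[nrow(cs), ]
      ter <- sprintf("TER   %5d      %3s %1s%4d%1s", serial + 1L,
                     last$res_name, ch, last$auth_number,
                     ifelse(nzchar(last$ins_code), last$ins_code, " "))
      serial <- serial + 1L
      out <- c(out, rec, ter)
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

write_mmcif_lines <- function(struct) {
  quote_tok <- function(v) {
    ifelse(grepl("['\"\\s]", v), paste0('"', v, '"'), v)
  }
  rows <- sprintf(
    "%-6s %d %-2s %-5s . %-3s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %d",
    "ATOM", seq_len(nrow(struct)),
    ifelse(nzchar(struct$element), struct$element, "."),
    quote_tok(struct$atom), struct$res_name, struct$chain,
    struct$res_seq,
    ifelse(nzchar(struct$ins_code), struct$ins_code, "?"),
    struct$x, struct$y, struct$z, struct$occupancy,
    struct$auth_number, struct$chain, struct$model
  )
  c(
    "data_torsionspace",
    "#",
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
      "pdbx_PDB_model_num"
    )),
    rows,
    "#"
  )
}
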