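#' Angle kinds
#'
#' The 17 angular parameters computed per residue: the six backbone
#' torsions alpha-zeta, the glycosidic torsion chi, the five ribose ring
#' torsions nu0-nu4, the pseudorotation phase P derived from them, and the
#' four pseudo-torsions eta, theta, eta', theta' defined over non-bonded
#' P/C4'/C1' atoms of adjacent residues.
#'
#' @return character vector of angle kind names.
#' @export
angle_kinds <- function() {
  c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi",
    "nu0", "nu1", "nu2", "nu3", "nu4", "pseudorotation",
    "eta", "theta", "eta_prime", "theta_prime")
}

#' Default angle selection for MCQ comparison
#'
#' Backbone torsions plus the glycosidic angle. The ring torsions and the
#' pseudo-torsions can be opted in; the pseudorotation phase is derived
#' from the ring torsions and is never part of an MCQ sum.
#'
#' @return character vector of angle kind names.
#' @export
mcq_default_angles <- function() {
  c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
}

# Angle kinds that may enter an MCQ comparison.
comparable_angles <- function() {
  setdiff(angle_kinds(), "pseudorotation")
}

# 18-degree pucker wheel, sector centres at 0, 18, ..., 342 degrees.
# Twist forms sit at even multiples of 18, envelopes at odd multiples;
# anchors: 0 = C2'-exo-C3'-endo twist, 90 = O4'-endo, 270 = O4'-exo.
PUCKER_WHEEL <- c(
  "C2'-exo-C3'-endo", "C3'-endo", "C3'-endo-C4'-exo", "C4'-exo",
  "C4'-exo-O4'-endo", "O4'-endo", "O4'-endo-C1'-exo", "C1'-exo",
  "C1'-exo-C2'-endo", "C2'-endo", "C2'-endo-C3'-exo", "C3'-exo",
  "C3'-exo-C4'-endo", "C4'-endo", "C4'-endo-O4'-exo", "O4'-exo",
  "O4'-exo-C1'-endo", "C1'-endo", "C1'-endo-C2'-exo", "C2'-exo"
)

#' Sugar pseudorotation phase and pucker name
#'
#' Collapses the five correlated ring torsions nu0-nu4 into the
#' pseudorotation phase angle
#' `P = atan2((nu4 + nu1) - (nu3 + nu0), 2 * nu2 * (sin 36 + sin 72))`,
#' reported in [0, 360). The two-argument arctangent keeps the nu2 <= 0
#' half of the wheel in the correct quadrant, where a plain arctangent
#' would be off by 180 degrees. Each 18-degree sector of P carries the
#' standard envelope/twist conformation name: P = 0 is the
#' C2'-exo-C3'-endo twist, P = 90 is O4'-endo and P = 270 is O4'-exo.
#'
#' A flat ring (numerator and denominator both ~0) or any undefined nu
#' yields `NA`.
#'
#' @param nu0,nu1,nu2,nu3,nu4 numeric vectors of ring torsions in degrees.
#' @return tibble with columns `P` (degrees in [0, 360)) and `pucker`
#'   (conformation name, `NA` when P is undefined).
#' @export
pseudorotation <- function(nu0, nu1, nu2, nu3, nu4) {
  num <- (nu4 + nu1) - (nu3 + nu0)
  den <- 2 * nu2 * (sin(deg2rad(36)) + sin(deg2rad(72)))
  p <- wrap360(rad2deg(atan2(num, den)))
  p[!is.na(num) & !is.na(den) & sqrt(num^2 + den^2) < 1e-9] <- NA_real_
  tibble::tibble(P = p, pucker = pucker_name(p))
}

#' @rdname pseudorotation
#' @param P pseudorotation phase in degrees.
#' @export
pucker_name <- function(P) {
  sector <- (floor((wrap360(P) + 9) / 18) %% 20) + 1
  PUCKER_WHEEL[sector]
}

#' Classify the glycosidic bond orientation
#'
#' `syn` for chi in (-90, 90] (base folded back over the sugar), `anti`
#' otherwise -- the textbook window around chi = 0.
#'
#' @param chi glycosidic torsion in degrees (any representation; wrapped
#'   internally).
#' @return character vector of `"syn"`, `"anti"` or `NA`.
#' @export
classify_glycosidic <- function(chi) {
  w <- wrap180(chi)
  out <- ifelse(w > -90 & w <= 90, "syn", "anti")
  out[is.na(w)] <- NA_character_
  out
}

#' Compute all torsion and pseudo-torsion angles
#'
#' Returns one row per residue with the full angular record: backbone
#' torsions alpha (O3'(i-1)-P-O5'-C5'), beta (P-O5'-C5'-C4'), gamma
#' (O5'-C5'-C4'-C3'), delta (C5'-C4'-C3'-O3'), epsilon
#' (C4'-C3'-O3'-P(i+1)), zeta (C3'-O3'-P(i+1)-O5'(i+1)); the glycosidic
#' torsion chi (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines);
#' the ring torsions nu0-nu4; the pseudorotation phase `P` and pucker
#' name; the pseudo-torsions eta (C4'(i-1)-P-C4'-P(i+1)), theta
#' (P-C4'-P(i+1)-C4'(i+1)) and their C1'-based primed variants; and the
#' syn/anti glycosidic class.
#'
#' Any angle whose atom quadruple crosses a chain break (see
#' [chain_breaks()]) or references a missing atom or neighbour is `NA`:
#' alpha, eta and eta' at the 5' terminus; epsilon, zeta, theta and theta'
#' at the 3' terminus. Torsions are reported in (-180, 180], `P` in
#' [0, 360).
#'
#' @param struct a `ts_structure` tibble from [read_structure()],
#'   [parse_structure()] or [build_chain()].
#' @param break_cutoff O3'-P distance cutoff in Angstroms defining chain
#'   breaks.
#' @return a `ts_torsions` tibble, one row per residue.
#' @export
calc_torsions <- function(struct, break_cutoff = 2.5) {
  res <- residue_table(struct)
  groups <- split(
    seq_len(nrow(res)),
    paste(res$model, res$chain, sep = "\r")
  )
  out <- lapply(groups, function(idx) {
    g <- res[idx, , drop = FALSE]
    sub <- struct[struct$model == g$model[1] & struct$chain == g$chain[1], ,
                  drop = FALSE]
    chain_torsions(sub, g, break_cutoff)
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$model, .data$chain, .data$res_seq)
  class(out) <- c("ts_torsions", class(out))
  out
}

chain_torsions <- function(sub, g, break_cutoff) {
  n <- nrow(g)
  co <- function(nm) atom_coords(sub, g, nm)
  P <- co("P"); O5 <- co("O5'"); C5 <- co("C5'"); C4s <- co("C4'")
  C3 <- co("C3'"); O3 <- co("O3'"); O4s <- co("O4'"); C1 <- co("C1'")
  C2s <- co("C2'")
  prev <- function(m) rbind(NA, m[-n, , drop = FALSE])
  nxt <- function(m) rbind(m[-1, , drop = FALSE], NA)

  # break after residue i: O3'(i)-P(i+1) too long or either atom missing
  if (n > 1) {
    d <- sqrt(rowSums((O3[-n, , drop = FALSE] - P[-1, , drop = FALSE])^2))
    break_after <- c(is.na(d) | d > break_cutoff, TRUE)
  } else {
    break_after <- TRUE
  }
  break_before <- c(TRUE, break_after[-n])

  mask <- function(x, bad) {
    x[bad] <- NA_real_
    x
  }
  alpha <- mask(dihedral(prev(O3), P, O5, C5), break_before)
  beta <- dihedral(P, O5, C5, C4s)
  gamma <- dihedral(O5, C5, C4s, C3)
  delta <- dihedral(C5, C4s, C3, O3)
  epsilon <- mask(dihedral(C4s, C3, O3, nxt(P)), break_after)
  zeta <- mask(dihedral(C3, O3, nxt(P), nxt(O5)), break_after)
  eta <- mask(dihedral(prev(C4s), P, C4s, nxt(P)),
              break_before | break_after)
  theta <- mask(dihedral(P, C4s, nxt(P), nxt(C4s)), break_after)
  eta_prime <- mask(dihedral(prev(C1), P, C1, nxt(P)),
                    break_before | break_after)
  theta_prime <- mask(dihedral(P, C1, nxt(P), nxt(C1)), break_after)

  nu0 <- dihedral(C4s, O4s, C1, C2s)
  nu1 <- dihedral(O4s, C1, C2s, C3)
  nu2 <- dihedral(C1, C2s, C3, C4s)
  nu3 <- dihedral(C2s, C3, C4s, O4s)
  nu4 <- dihedral(C3, C4s, O4s, C1)
  ps <- pseudorotation(nu0, nu1, nu2, nu3, nu4)

  gly_n <- ifelse(g$base_class == "purine", "N9",
                  ifelse(g$base_class == "pyrimidine", "N1", NA))
  gly_c <- ifelse(g$base_class == "purine", "C4",
                  ifelse(g$base_class == "pyrimidine", "C2", NA))
  Nb <- matrix(NA_real_, n, 3)
  Cb <- matrix(NA_real_, n, 3)
  for (cls in c("purine", "pyrimidine")) {
    rows <- which(g$base_class == cls)
    if (length(rows) > 0) {
      Nb[rows, ] <- co(if (cls == "purine") "N9" else "N1")[rows, ,
                                                            drop = FALSE]
      Cb[rows, ] <- co(if (cls == "purine") "C4" else "C2")[rows, ,
                                                            drop = FALSE]
    }
  }
  chi <- dihedral(O4s, C1, Nb, Cb)

  tibble::tibble(
    model = g$model, chain = g$chain, res_seq = g$res_seq,
    auth_number = g$auth_number, ins_code = g$ins_code,
    res_name = g$res_name, one_letter = g$one_letter,
    base_class = g$base_class,
    alpha = alpha, beta = beta, gamma = gamma, delta = delta,
    epsilon = epsilon, zeta = zeta, chi = chi,
    nu0 = nu0, nu1 = nu1, nu2 = nu2, nu3 = nu3, nu4 = nu4,
    pseudorotation = ps$P, pucker = ps$pucker,
    eta = eta, theta = theta,
    eta_prime = eta_prime, theta_prime = theta_prime,
    glycosidic = classify_glycosidic(chi)
  )
}
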