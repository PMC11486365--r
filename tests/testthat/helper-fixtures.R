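# Shared fixtures, all generated in code -- no binary data, no downloads.

# A single guanosine with the 12 ribose + backbone + base atoms, frozen as
# literal PDB text so parser tests do not depend on the chain builder.
guanosine_pdb <- function() {
  c(
    "ATOM      1  P     G A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  O5'   G A   1       1.593   0.000   0.000  1.00  0.00           O",
    "ATOM      3  C5'   G A   1       2.332   0.000   1.236  1.00  0.00           C",
    "ATOM      4  C4'   G A   1       3.821  -0.049   0.989  1.00  0.00           C",
    "ATOM      5  C3'   G A   1       4.370   1.031   0.065  1.00  0.00           C",
    "ATOM      6  O3'   G A   1       4.572   2.238   0.792  1.00  0.00           O",
    "ATOM      7  O4'   G A   1       2.815   0.726   1.706  1.00  0.00           O",
    "ATOM      8  C1'   G A   1       2.377   1.858   0.978  1.00  0.00           C",
    "ATOM      9  C2'   G A   1       3.148   1.857  -0.344  1.00  0.00           C",
    "ATOM     10  N9    G A   1       0.930   1.730   0.754  1.00  0.00           N",
    "ATOM     11  C4    G A   1       0.202   2.351  -0.226  1.00  0.00           C",
    "ATOM     12  C8    G A   1       0.048   0.972   1.479  1.00  0.00           C",
    "TER      13        G A   1",
    "END"
  )
}

# Z-RNA-like (CGCGCG-type) hexamer: guanosines syn (chi ~ +60), cytosines
# anti (chi ~ -160), alternating along the chain.
zrna_chain <- function() {
  letters6 <- strsplit("GCGCGC", "")[[1]]
  build_chain(torsion_prescription(
    "GCGCGC",
    chi = ifelse(letters6 == "G", 60, -160)
  ))
}

# Minimal synthetic torsion table: the columns the comparison layer uses,
# with random angles -- fast stand-in for a full 3D build.
synthetic_torsions <- function(n, sequence = NULL,
                               angles = mcq_default_angles()) {
  if (is.null(sequence)) {
    sequence <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                      collapse = "")
  }
  out <- tibble::tibble(
    model = 1L, chain = "A", res_seq = seq_len(n), auth_number = seq_len(n),
    ins_code = "", one_letter = strsplit(sequence, "")[[1]]
  )
  for (k in angles) out[[k]] <- runif(n, -180, 180)
  class(out) <- c("ts_torsions", class(out))
  out
}

# Exhaustive O(n^2) LCS-TA oracle: evaluate every contiguous window of
# consecutively paired residues directly with mcq().
lcs_ta_oracle <- function(target, model, pairing, angles, threshold) {
  d <- residue_diffs(target, model, pairing, angles)
  per <- split(d$delta, match(
    paste(d$target_pos, d$model_pos),
    paste(pairing$target_pos, pairing$model_pos)
  ))
  np <- nrow(pairing)
  best_len <- 0L
  best_mcq <- NA_real_
  best_start <- NA_integer_
  for (i in seq_len(np)) {
    for (j in i:np) {
      # contiguity in both chains
      if (pairing$target_pos[j] - pairing$target_pos[i] != j - i) break
      if (pairing$model_pos[j] - pairing$model_pos[i] != j - i) break
      pooled <- unlist(per[as.character(i:j)], use.names = FALSE)
      v <- mcq(pooled)
      if (attr(v, "n_terms") == 0 || as.numeric(v) > threshold) next
      len <- j - i + 1L
      better <- len > best_len ||
        (len == best_len &&
           (as.numeric(v) < best_mcq ||
              (as.numeric(v) == best_mcq &&
                 pairing$target_pos[i] < best_start)))
      if (better) {
        best_len <- len
        best_mcq <- as.numeric(v)
        best_start <- pairing$target_pos[i]
      }
    }
  }
  list(length = best_len, mcq = best_mcq, target_start = best_start)
}

# Brute-force k-medoids optimum by enumerating all medoid subsets.
pam_bruteforce_cost <- function(m, k) {
  combos <- utils::combn(nrow(m), k)
  min(apply(combos, 2, function(med) {
    sum(apply(m[, med, drop = FALSE], 1, min))
  }))
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_dissim <- function(n, max_d = 100) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, max_d)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("m", seq_len(n))
  m
}

# Euclidean distance matrix of random planar points.
planar_dissim <- function(n) {
  pts <- matrix(runif(2 * n, -10, 10), ncol = 2)
  as.matrix(stats::dist(pts))
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

transform_structure <- function(struct, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(struct[, c("x", "y", "z")]) %*% t(rot)
  struct$x <- xyz[, 1] + shift[1]
  struct$y <- xyz[, 2] + shift[2]
  struct$z <- xyz[, 3] + shift[3]
  struct
}
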