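test_that("angle_diff takes the minimum arc in any representation", {
  expect_equal(angle_diff(350, 10), 20)
  expect_equal(angle_diff(90, 270), 180)
  expect_equal(angle_diff(-170, 170), 20)
  expect_equal(angle_diff(0, 0), 0)
  # symmetry and bounds on random pairs
  set.seed(41)
  a <- runif(200, -720, 720)
  b <- runif(200, -720, 720)
  expect_equal(angle_diff(a, b), angle_diff(b, a))
  expect_true(all(angle_diff(a, b) >= 0 & angle_diff(a, b) <= 180))
  expect_true(is.na(angle_diff(NA, 10)))
})

test_that("mcq aggregates differences in the correct quadrant", {
  expect_equal(as.numeric(mcq(c(30, 30, 30))), 30)
  # above 90 degrees a plain arctangent would give -10; atan2 must not
  expect_equal(as.numeric(mcq(c(170, 170))), 170)
  expect_equal(as.numeric(mcq(c(0, 90))), 45)
  expect_equal(attr(mcq(c(10, NA, 20)), "n_terms"), 2L)
  expect_true(is.na(mcq(c(NA_real_, NA_real_))))
  expect_equal(attr(mcq(rep(NA_real_, 3)), "n_terms"), 0L)
})

test_that("severity bins partition [0, 180] without gaps or overlap", {
  x <- c(0, 14.999, 15, 29.999, 30, 59.999, 60, 179.999, 180)
  got <- as.character(severity_bin(x))
  expect_equal(got, c("[0,15)", "[0,15)", "[15,30)", "[15,30)", "[30,60)",
                      "[30,60)", "[60,180]", "[60,180]", "[60,180]"))
  set.seed(42)
  expect_false(anyNA(severity_bin(runif(500, 0, 180))))
})

test_that("residue pairing is a leftmost maximum common subsequence", {
  p <- pair_residues("ACGU", "AGU")
  expect_equal(p$target_pos, c(1, 3, 4))
  expect_equal(p$model_pos, c(1, 2, 3))

  expect_equal(nrow(pair_residues("ACGT", "TGCA")), 1)

  ident <- pair_residues("GGCAU", "GGCAU")
  expect_equal(ident$target_pos, 1:5)
  expect_equal(ident$model_pos, 1:5)

  # no shared letter: empty pairing, not an error
  expect_equal(nrow(pair_residues("AAA", "CCC")), 0)
  expect_error(pair_residues("", "ACGU"), "non-empty")
})

test_that("pairing length matches an exhaustive subsequence oracle", {
  lcs_len_oracle <- function(a, b) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    best <- 0
    for (mask in 0:(2^length(a) - 1)) {
      sub <- a[bitwAnd(mask, 2^(seq_along(a) - 1)) > 0]
      if (length(sub) <= best) next
      # is sub a subsequence of b?
      j <- 1
      for (ch in b) {
        if (j <= length(sub) && ch == sub[j]) j <- j + 1
      }
      if (j == length(sub) + 1) best <- length(sub)
    }
    best
  }
  set.seed(43)
  for (i in 1:15) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(3:8, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(3:8, 1),
                      replace = TRUE), collapse = "")
    p <- pair_residues(a, b)
    expect_equal(nrow(p), lcs_len_oracle(a, b))
    if (nrow(p) > 1) {
      expect_true(all(diff(p$target_pos) > 0))
      expect_true(all(diff(p$model_pos) > 0))
    }
  }
})

test_that("per-residue MCQ localizes differences and matches the formula", {
  set.seed(44)
  target <- synthetic_torsions(6)
  identical_model <- target
  per <- per_residue_mcq(target, identical_model)
  expect_equal(per$mcq, rep(0, 6))
  expect_equal(as.character(unique(per$severity)), "[0,15)")

  shifted <- target
  shifted$gamma[2] <- wrap180(shifted$gamma[2] + 40)
  per <- per_residue_mcq(target, shifted, angles = "gamma")
  expect_equal(per$mcq, c(0, 40, 0, 0, 0, 0), tolerance = 1e-9)
  expect_equal(as.character(per$severity[2]), "[30,60)")

  two <- target
  two$alpha[3] <- wrap180(two$alpha[3] + 10)
  two$gamma[3] <- wrap180(two$gamma[3] + 20)
  per <- per_residue_mcq(target, two, angles = c("alpha", "gamma"))
  want <- atan2(sin(10 * pi / 180) + sin(20 * pi / 180),
                cos(10 * pi / 180) + cos(20 * pi / 180)) * 180 / pi
  expect_equal(per$mcq[3], want, tolerance = 1e-9)
})

test_that("global MCQ pools differences rather than averaging residues", {
  set.seed(45)
  target <- synthetic_torsions(4)
  model <- target
  offs <- c(10, 20, 30, 40)
  model$gamma <- wrap180(model$gamma + offs)
  got <- global_mcq(target, model, angles = "gamma")
  want <- atan2(sum(sin(offs * pi / 180)),
                sum(cos(offs * pi / 180))) * 180 / pi
  expect_equal(as.numeric(got), want, tolerance = 1e-9)
  expect_equal(attr(got, "n_terms"), 4L)

  expect_equal(as.numeric(global_mcq(target, target)), 0)

  disjoint <- synthetic_torsions(4, sequence = "AAAA")
  other <- synthetic_torsions(4, sequence = "CCCC")
  expect_true(is.na(global_mcq(disjoint, other)))
})

test_that("global MCQ is symmetric and bounded", {
  set.seed(46)
  for (i in 1:10) {
    a <- synthetic_torsions(8, sequence = "ACGUACGU")
    b <- synthetic_torsions(8, sequence = "ACGUACGU")
    ab <- as.numeric(global_mcq(a, b))
    ba <- as.numeric(global_mcq(b, a))
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_gte(ab, 0)
    expect_lte(ab, 180)
    pa <- per_residue_mcq(a, b)$mcq
    pb <- per_residue_mcq(b, a)$mcq
    expect_equal(pa, pb, tolerance = 1e-12)
  }
})

test_that("coverage fractions count residues strictly under thresholds", {
  cov <- coverage_fractions(c(10, 20, 40, 70))
  expect_equal(cov$fraction, c(0.25, 0.5, 0.75))
  expect_equal(coverage_fractions(rep(0, 5))$fraction, c(1, 1, 1))
  allna <- coverage_fractions(c(NA_real_, NA_real_))
  expect_true(all(is.na(allna$fraction)))
  expect_equal(allna$n_defined, rep(0L, 3))
  expect_error(coverage_fractions(1:3, thresholds = c(30, 15)),
               "ascending")
})

test_that("LCS-TA finds the longest continuous under-threshold segment", {
  set.seed(47)
  target <- synthetic_torsions(10)
  model <- target
  # corrupt residue 6: all selected angles shifted by 90. Pooling dilutes
  # one bad residue among perfect ones (7 diffs of 90 among 63 zeros pool
  # to ~6.3 degrees), so a 5-degree threshold is what isolates it.
  for (k in mcq_default_angles()) {
    model[[k]][6] <- wrap180(model[[k]][6] + 90)
  }
  seg <- lcs_ta(target, model, threshold = 5)
  expect_equal(seg$length, 5L)
  expect_equal(seg$target_start, 1L) # prefix wins the leftmost tie-break
  expect_equal(seg$mcq, 0, tolerance = 1e-9)

  # identical structures: full range at any threshold
  seg <- lcs_ta(target, target, threshold = 1)
  expect_equal(seg$length, 10L)
  expect_equal(seg$target_start, 1L)

  # threshold 180 always admits the full paired range
  seg <- lcs_ta(target, model, threshold = 180)
  expect_equal(seg$length, 10L)

  # nothing under threshold: zero-length segment
  all_off <- target
  for (k in mcq_default_angles()) {
    all_off[[k]] <- wrap180(all_off[[k]] + 120)
  }
  seg <- lcs_ta(target, all_off, threshold = 15)
  expect_equal(seg$length, 0L)
  expect_true(is.na(seg$target_start))
})

test_that("LCS-TA equals the exhaustive oracle on random instances", {
  set.seed(48)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    seqs <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                  collapse = "")
    target <- synthetic_torsions(n, sequence = seqs)
    model <- synthetic_torsions(n, sequence = seqs)
    # mixture of near and far residues makes thresholds interesting
    near <- runif(n) < 0.6
    for (k in mcq_default_angles()) {
      model[[k]][near] <- wrap180(target[[k]][near] + runif(sum(near), -12, 12))
    }
    pairing <- pair_residues(seqs, seqs)
    thr <- runif(1, 5, 60)
    got <- lcs_ta(target, model, pairing, threshold = thr)
    want <- lcs_ta_oracle(target, model, pairing, mcq_default_angles(),
                          thr)
    expect_equal(got$length, want$length)
    if (got$length > 0) {
      expect_equal(got$mcq, want$mcq, tolerance = 1e-9)
      expect_equal(got$target_start, want$target_start)
    }
  }
})

test_that("LCS-TA length is non-decreasing in the threshold", {
  set.seed(49)
  n <- 20
  seqs <- paste(rep("ACGU", 5), collapse = "")
  target <- synthetic_torsions(n, sequence = seqs)
  model <- synthetic_torsions(n, sequence = seqs)
  for (k in mcq_default_angles()) {
    model[[k]] <- wrap180(target[[k]] + runif(n, -90, 90))
  }
  lens <- vapply(c(5, 15, 30, 60, 120, 180), function(thr) {
    lcs_ta(target, model, threshold = thr)$length
  }, integer(1))
  expect_true(all(diff(lens) >= 0))
  expect_equal(lens[length(lens)], n)
})

test_that("pairing gaps split LCS-TA runs", {
  set.seed(50)
  target <- synthetic_torsions(9, sequence = "AAACAAAAA")
  model <- synthetic_torsions(8, sequence = "AAAAAAAA")
  for (k in mcq_default_angles()) {
    model[[k]] <- target[[k]][-4]
  }
  # pairing skips target position 4: runs 1-3 and 5-9, never joined
  seg <- lcs_ta(target, model, threshold = 15)
  expect_equal(seg$length, 5L)
  expect_equal(seg$target_start, 5L)
})

test_that("the angle selection is validated", {
  set.seed(51)
  a <- synthetic_torsions(4)
  expect_error(per_residue_mcq(a, a, angles = character(0)), "non-empty")
  expect_error(per_residue_mcq(a, a, angles = "pseudorotation"),
               "not comparable")
  expect_error(global_mcq(a, a, angles = "bogus"), "bogus")
})

test_that("compare_structures assembles a coherent report object", {
  s <- build_chain(torsion_prescription("GCGCGC"))
  cmp <- compare_structures(s, perturb_chain(s, "gamma", 40,
                                             positions = 2),
                            angles = c("alpha", "gamma"))
  expect_s3_class(cmp, "ts_comparison")
  td <- generics::tidy(cmp)
  expect_equal(nrow(td), 6)
  expect_equal(td$mcq[2], 20.0, tolerance = 1e-6) # pooled alpha 0, gamma 40
  gl <- generics::glance(cmp)
  expect_equal(gl$n_paired, 6)
  expect_true(gl$global_mcq > 0)
  expect_output(print(cmp), "global MCQ")
})
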