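#' Circular mean and dispersion
#'
#' `circular_summary()` computes the circular mean direction
#' `atan2(sum sin, sum cos)`, the mean resultant length in [0, 1] and the
#' Mardia circular standard deviation `sqrt(-2 log R)` (reported in
#' degrees). With an (anti)podal balanced sample the resultant length is
#' ~0 and the mean is undefined (`NA`). `circular_mean()` returns just the
#' mean direction.
#'
#' @param x numeric vector of angles in degrees; `NA`s are dropped.
#' @return `circular_summary()`: a one-row tibble with columns
#'   `n_defined`, `mean`, `resultant_length`, `circular_std`;
#'   `circular_mean()`: a scalar in (-180, 180].
#' @export
circular_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(n_defined = 0L, mean = NA_real_,
                          resultant_length = NA_real_,
                          circular_std = NA_real_))
  }
  s <- sum(sin(deg2rad(x)))
  c_ <- sum(cos(deg2rad(x)))
  r <- sqrt(s^2 + c_^2) / n
  m <- if (r < 1e-12) NA_real_ else wrap180(rad2deg(atan2(s, c_)))
  std <- if (r < 1e-12) NA_real_ else rad2deg(sqrt(-2 * log(min(r, 1))))
  tibble::tibble(n_defined = n, mean = m, resultant_length = r,
                 circular_std = std)
}

#' @rdname circular_summary
#' @export
circular_mean <- function(x) {
  circular_summary(x)$mean
}

#' Angular histogram
#'
#' Bins wrapped angle values into half-open bins `[lo, lo + width)` tiling
#' one full turn starting at `range_start`. The bin width must divide 360
#' so the bins tile the circle exactly.
#'
#' @param x numeric vector of angles in degrees; `NA`s are dropped.
#' @param bin_width bin width in degrees (a divisor of 360); the default
#'   15 matches the finest severity band of the comparison heatmaps.
#' @param range_start lower edge of the first bin: -180 for torsions
#'   (default), 0 for the pseudorotation phase.
#' @return tibble with columns `bin_lo`, `bin_hi`, `count`; counts sum to
#'   the number of defined values.
#' @export
angle_histogram <- function(x, bin_width = 15, range_start = -180) {
  if (bin_width <= 0 || 360 %% bin_width != 0) {
    stop("bin_width must be a positive divisor of 360, got ", bin_width,
         call. = FALSE)
  }
  x <- x[!is.na(x)]
  lo <- seq(range_start, range_start + 360 - bin_width, by = bin_width)
  w <- ((x - range_start) %% 360)
  idx <- pmin(floor(w / bin_width) + 1, length(lo))
  counts <- tabulate(idx, nbins = length(lo))
  tibble::tibble(bin_lo = lo, bin_hi = lo + bin_width, count = counts)
}

#' Per-kind circular statistics of a torsion table
#'
#' @param torsions a `ts_torsions` tibble from [calc_torsions()].
#' @return tibble with one row per angle kind (see [angle_kinds()]) and
#'   the columns of [circular_summary()].
#' @export
torsion_summary <- function(torsions) {
  kinds <- angle_kinds()
  dplyr::bind_rows(lapply(kinds, function(k) {
    dplyr::bind_cols(tibble::tibble(kind = k),
                     circular_summary(torsions[[k]]))
  }))
}

#' Tally syn/anti glycosidic conformations
#'
#' @param torsions a `ts_torsions` tibble.
#' @return tibble with columns `syn`, `anti`, `undefined`.
#' @export
syn_anti_counts <- function(torsions) {
  g <- torsions$glycosidic
  tibble::tibble(
    syn = sum(g == "syn", na.rm = TRUE),
    anti = sum(g == "anti", na.rm = TRUE),
    undefined = sum(is.na(g))
  )
}

#' All angular histograms of a torsion table
#'
#' @inheritParams torsion_summary
#' @inheritParams angle_histogram
#' @return tibble with columns `kind`, `bin_lo`, `bin_hi`, `count`; the
#'   pseudorotation phase is binned over [0, 360), all torsions over
#'   (-180, 180].
#' @export
torsion_histograms <- function(torsions, bin_width = 15) {
  kinds <- angle_kinds()
  dplyr::bind_rows(lapply(kinds, function(k) {
    h <- angle_histogram(torsions[[k]], bin_width = bin_width,
                         range_start = if (k == "pseudorotation") 0
                                       else -180)
    dplyr::bind_cols(tibble::tibble(kind = k), h)
  }))
}
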