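#' Fluorescence histogram container
#'
#' A flow-cytometry histogram as (channel, count) pairs: relative
#' fluorescence on an ordered channel axis and the number of nuclei
#' recorded per channel. The sample of interest is run together with an
#' internal reference standard, so a two-peak histogram is the normal
#' case.
#'
#' @param channel strictly increasing numeric vector of fluorescence
#'   channels (arbitrary units).
#' @param count non-negative integer event counts, one per channel, with a
#'   positive total.
#' @param sample,standard labels for the sample and the internal standard.
#' @return Object of class \code{"fluor_histogram"}.
#' @export
fluor_histogram <- function(channel, count, sample = NA_character_,
                            standard = NA_character_) {
  channel <- as.numeric(channel); count <- as.numeric(count)
  if (length(channel) != length(count))
    stop("'channel' and 'count' differ in length")
  if (any(diff(channel) <= 0)) stop("channels must be strictly increasing")
  if (any(count < 0)) stop("negative counts")
  if (sum(count) <= 0) stop("histogram holds no events")
  structure(list(channel = channel, count = count, sample = sample,
                 standard = standard), class = "fluor_histogram")
}

#' @export
print.fluor_histogram <- function(x, ...) {
  cat(sprintf("fluor_histogram: %d channels [%g..%g], %g events",
              length(x$channel), min(x$channel), max(x$channel),
              sum(x$count)))
  if (!is.na(x$sample)) cat(", sample =", x$sample)
  cat("\n")
  invisible(x)
}

#' Read a fluorescence histogram from two-column delimited text
#'
#' Expects a header line and two columns, channel then count; separator is
#' chosen from the extension (\code{.csv} comma, otherwise tab).
#'
#' @param path input file.
#' @inheritParams fluor_histogram
#' @export
read_histogram <- function(path, sample = NA_character_,
                           standard = NA_character_) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  fluor_histogram(df[[1]], df[[2]], sample = sample, standard = standard)
}

#' Locate fluorescence peaks in a histogram
#'
#' Smooths the counts with a centered moving average, finds local maxima,
#' and keeps the \code{n_expected} most prominent modes that do not fall
#' within 20\% of an already-accepted mode. Each peak is then summarized
#' from the raw counts inside a window of ±20\% around its mode: the peak
#' mean is the count-weighted average channel and the CV is the weighted
#' standard deviation over the mean — the conventional quality figure for
#' flow-cytometry peaks.
#'
#' @param h a \code{fluor_histogram}.
#' @param n_expected number of peaks to report (>= 1).
#' @param smooth_window moving-average window in channels (odd; default 5).
#' @return Data frame with columns \code{mean} and \code{cv}, one row per
#'   peak, ordered by ascending mean.
#' @export
find_peaks <- function(h, n_expected = 2, smooth_window = 5) {
  if (n_expected < 1) stop("'n_expected' must be at least 1")
  y <- h$count
  k <- max(1L, as.integer(smooth_window))
  if (k %% 2 == 0) k <- k + 1L
  sm <- as.numeric(stats::filter(c(rep(y[1], k %/% 2), y,
                                   rep(y[length(y)], k %/% 2)),
                                 rep(1 / k, k), sides = 2))
  sm <- sm[(k %/% 2 + 1):(k %/% 2 + length(y))]
  n <- length(sm)
  # boundary channels never qualify: a mode at the edge of the acquisition
  # range cannot be summarized by a symmetric window
  left <- c(Inf, sm[-n]); right <- c(sm[-1], Inf)
  is_max <- sm >= left & sm >= right & (sm > left | sm > right)
  cand <- which(is_max)
  if (!length(cand)) stop("peaks not found")
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  modes <- numeric(0)
  for (i in cand) {
    ch <- h$channel[i]
    if (!length(modes) || all(abs(ch - modes) > 0.2 * modes)) {
      modes <- c(modes, ch)
      if (length(modes) == n_expected) break
    }
  }
  if (length(modes) < n_expected)
    stop("peaks not found: expected ", n_expected, ", detected ",
         length(modes))
  peaks <- lapply(modes, function(c0) {
    w <- h$channel >= 0.8 * c0 & h$channel <= 1.2 * c0
    ch <- h$channel[w]; ct <- h$count[w]
    mu <- sum(ct * ch) / sum(ct)
    sdv <- sqrt(sum(ct * (ch - mu)^2) / sum(ct))
    c(mean = mu, cv = sdv / mu)
  })
  out <- as.data.frame(do.call(rbind, peaks))
  out[order(out$mean), , drop = FALSE]
}

#' DNA index: sample peak over standard peak
#'
#' @param sample_peak,standard_peak peak mean fluorescences (> 0).
#' @return Unitless ratio, proportional to relative genome size.
#' @export
dna_index <- function(sample_peak, standard_peak) {
  if (any(c(sample_peak, standard_peak) <= 0))
    stop("peak means must be positive")
  sample_peak / standard_peak
}

#' 2C DNA amount from the DNA index and the standard's 2C value
#'
#' The internal standard ties the fluorescence scale to absolute DNA
#' amounts: 2C = index x standard 2C. The default standard value is the
#' literature 2C of \emph{Pisum sativum} 'Ctirad' (9.09 pg).
#'
#' @param index DNA index from [dna_index()].
#' @param standard_2c 2C value of the internal standard in pg (> 0).
#' @return 2C value in pg (unrounded; round for reporting).
#' @export
estimate_2c <- function(index, standard_2c = 9.09) {
  if (is.null(standard_2c) || is.na(standard_2c) || standard_2c <= 0)
    stop("a positive 2C value for the internal standard is required")
  index * standard_2c
}

#' Haploid genome size in Mbp from a 2C value
#'
#' Uses the standard conversion 1 pg = 978 Mbp on the 1C amount:
#' round-half-up of (2C / 2) x 978.
#'
#' @param two_c 2C value in pg (> 0).
#' @return Integer megabase pairs.
#' @examples
#' genome_size_mbp(2.92)  # 1428
#' @export
genome_size_mbp <- function(two_c) {
  if (any(two_c <= 0)) stop("'two_c' must be positive")
  as.integer(round_half_up(two_c / 2 * 978))
}

#' Ploidy call relative to a diploid reference
#'
#' Scales the 2C value against a known-diploid reference (for a uniform
#' panel, typically its median 2C) and rounds to the nearest integer
#' ploidy; calls whose scaled value sits further than \code{rel_tol} from
#' an integer are flagged inconclusive rather than rejected.
#'
#' @param two_c sample 2C value in pg.
#' @param diploid_reference_2c 2C of a diploid reference (> 0).
#' @param rel_tol maximum distance from an integer ploidy before the call
#'   is flagged (default 0.1).
#' @return List with \code{ploidy} (integer), \code{ratio} (the scaled
#'   value 2 x 2C / reference) and \code{inconclusive} (logical).
#' @export
ploidy_call <- function(two_c, diploid_reference_2c, rel_tol = 0.1) {
  if (diploid_reference_2c <= 0) stop("diploid reference must be positive")
  ratio <- 2 * two_c / diploid_reference_2c
  p <- round_half_up(ratio)
  list(ploidy = as.integer(p), ratio = ratio,
       inconclusive = abs(ratio - p) > rel_tol)
}

#' Mean and standard deviation over replicate measurements
#'
#' @param values numeric vector of >= 2 replicate values (e.g. 2C pg from
#'   independent flow-cytometry runs).
#' @return List with \code{mean} and \code{sd} (sample SD, n - 1), both
#'   rounded half-up to 2 decimals for reporting.
#' @export
replicate_summary <- function(values) {
  if (length(values) < 2) stop("need at least two replicate values")
  list(mean = round_half_up(mean(values), 2),
       sd = round_half_up(stats::sd(values), 2))
}

#' End-to-end 2C estimate from a two-peak histogram
#'
#' Finds the two peaks, takes the sample peak as the lower (or higher)
#' one, and returns the DNA index and 2C value against the internal
#' standard.
#'
#' @param h a \code{fluor_histogram} containing sample and standard peaks.
#' @param standard_2c 2C of the internal standard in pg.
#' @param sample_is which peak belongs to the sample: \code{"lower"}
#'   (default; standard larger than sample, as with a Pisum standard on a
#'   small-genome ornamental) or \code{"higher"}.
#' @return List with \code{sample_peak}, \code{standard_peak},
#'   \code{dna_index} and \code{two_c}.
#' @export
estimate_from_histogram <- function(h, standard_2c = 9.09,
                                    sample_is = c("lower", "higher")) {
  sample_is <- match.arg(sample_is)
  pk <- find_peaks(h, n_expected = 2)
  s <- if (sample_is == "lower") pk$mean[1] else pk$mean[2]
  std <- if (sample_is == "lower") pk$mean[2] else pk$mean[1]
  idx <- dna_index(s, std)
  list(sample_peak = s, standard_peak = std, dna_index = idx,
       two_c = estimate_2c(idx, standard_2c))
}
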