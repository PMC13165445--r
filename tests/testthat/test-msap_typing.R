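test_that("the four digest patterns map onto types I-IV exhaustively", {
  expect_identical(classify_site(1, 1), "I")
  expect_identical(classify_site(0, 1), "II")
  expect_identical(classify_site(1, 0), "III")
  expect_identical(classify_site(0, 0), "IV")
  # total on {0,1}^2, mutually exclusive, NA propagates
  grid <- expand.grid(h = c(0, 1), m = c(0, 1))
  ty <- classify_site(grid$h, grid$m)
  expect_setequal(ty, c("I", "II", "III", "IV"))
  expect_true(is.na(classify_site(NA, 1)))
  expect_error(classify_site(2, 0), "0, 1 or NA")
})

test_that("a sample with one locus of each type profiles to counts (1,1,1,1)", {
  d <- toy_digest_pair()
  p <- profile_sample(d$hpa, d$msp, "A")
  expect_identical(p$typeI_total, 1L)
  expect_identical(p$typeII, 1L)
  expect_identical(p$typeIII, 1L)
  expect_identical(p$typeIV, 1L)
  expect_identical(p$total_amplified, 4L)
  expect_error(profile_sample(d$hpa, d$msp, "Z"), "absent")
})

test_that("a panel with no methylation anywhere has zero indices", {
  one <- matrix(1L, 3, 5, dimnames = list(c("A", "B", "C"), paste0("L", 1:5)))
  hpa <- band_matrix(one, marker_system = "MSAP_HPAII")
  msp <- band_matrix(one, marker_system = "MSAP_MSPI")
  prof <- msap_profiles(hpa, msp)
  expect_true(all(prof$typeI_total == 5L))
  expect_true(all(prof$typeI_ms == 0L))
  expect_true(all(prof$msap_pct == 0))
  expect_true(all(prof$fully_methylated_pct == 0))
})

test_that("profiles on a synthetic panel match a per-cell brute-force tally", {
  p <- simulate_marker_panel(panel_config(), seed = 42)
  prof <- msap_profiles(p$hpa, p$msp)
  # independent loop over every cell, bypassing the package's type matrix
  H <- p$hpa$values; M <- p$msp$values
  for (s in c("A1", "B3", "Outgroup")) {
    cnt <- c(I = 0L, II = 0L, III = 0L, IV = 0L)
    for (j in seq_len(ncol(H))) {
      h <- H[s, j]; m <- M[s, j]
      k <- if (h == 1 && m == 1) "I" else if (h == 0 && m == 1) "II"
           else if (h == 1 && m == 0) "III" else "IV"
      cnt[k] <- cnt[k] + 1L
    }
    row <- prof[prof$sample_id == s, ]
    expect_identical(row$typeI_total, cnt[["I"]])
    expect_identical(row$typeII, cnt[["II"]])
    expect_identical(row$typeIII, cnt[["III"]])
    expect_identical(row$typeIV, cnt[["IV"]])
  }
})

test_that("type counts sum to one constant panel size for every sample", {
  p <- simulate_marker_panel(panel_config(), seed = 1)
  prof <- msap_profiles(p$hpa, p$msp)
  sums <- prof$typeI_total + prof$typeII + prof$typeIII + prof$typeIV
  expect_true(all(sums == prof$total_amplified))
  expect_identical(length(unique(prof$total_amplified)), 1L)
  expect_true(all(prof$typeI_ms <= prof$typeI_total))
  expect_true(all(prof$msap_pct >= 0 & prof$msap_pct <= 100))
})

test_that("methylation indices follow the total-methylated and II+IV formulas", {
  idx <- methylation_indices(101, 210, 155, 90, total = 668)
  expect_equal(idx$msap_pct, 83.23)
  expect_equal(idx$fully_methylated_pct, 44.91)
  # alternative convention: type IV only
  alt <- methylation_indices(101, 210, 155, 90, total = 668,
                             fully_methylated = "IV")
  expect_equal(alt$fully_methylated_pct, round(100 * 90 / 668, 2))
  zero <- methylation_indices(0, 0, 0, 0, total = 10)
  expect_equal(zero$msap_pct, 0)
  expect_equal(zero$fully_methylated_pct, 0)
  expect_error(methylation_indices(1, 1, 1, 1, total = 0), "positive")
})

test_that("clade tallies recover planted shared and private fragment counts", {
  p <- simulate_marker_panel(panel_config(), seed = 42)
  ing <- c(p$truth$clade_a, p$truth$clade_b)
  tly <- clade_fragment_tally(subset_samples(p$hpa, ing),
                              subset_samples(p$msp, ing),
                              list(p$truth$clade_a, p$truth$clade_b))
  shared <- setNames(tly$shared_all, tly$type)
  priv_a <- setNames(tly$private_A, tly$type)
  priv_b <- setNames(tly$private_B, tly$type)
  for (k in c("I", "II", "III")) {
    expect_identical(shared[[k]], length(p$truth$msap_shared[[k]]))
    expect_identical(priv_a[[k]], length(p$truth$msap_private_a[[k]]))
    expect_identical(priv_b[[k]], length(p$truth$msap_private_b[[k]]))
  }
  # loci unamplified throughout one clade mirror the other side's privates
  expect_identical(priv_a[["IV"]],
                   length(unlist(p$truth$msap_private_b)))
  expect_identical(priv_b[["IV"]],
                   length(unlist(p$truth$msap_private_a)))
})

test_that("identical samples put every locus in shared-all with no privates", {
  one <- matrix(rep(c(1L, 0L, 1L, 0L), 3), 3, 4, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), paste0("L", 1:4)))
  two <- matrix(rep(c(1L, 1L, 0L, 0L), 3), 3, 4, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), paste0("L", 1:4)))
  hpa <- band_matrix(one, marker_system = "MSAP_HPAII")
  msp <- band_matrix(two, marker_system = "MSAP_MSPI")
  tly <- clade_fragment_tally(hpa, msp, list("A", c("B", "C")))
  # L4 is type IV in every sample, hence amplified nowhere and outside the
  # panel; the three panel loci are all shared, none private
  expect_identical(sum(tly$shared_all), 3L)
  expect_identical(sum(tly$private_A) + sum(tly$private_B), 0L)
})

test_that("a single-sample side's private counts equal its exclusive fragments", {
  set.seed(9)
  H <- matrix(rbinom(40, 1, 0.6), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("L", 1:10)))
  M <- matrix(rbinom(40, 1, 0.6), 4, 10, dimnames = dimnames(H))
  hpa <- band_matrix(H, marker_system = "MSAP_HPAII")
  msp <- band_matrix(M, marker_system = "MSAP_MSPI")
  tly <- clade_fragment_tally(hpa, msp, list("s1", paste0("s", 2:4)))
  ty <- matrix(classify_site(as.vector(H), as.vector(M)), 4, 10,
               dimnames = dimnames(H))
  keep <- colSums(H == 1) + colSums(M == 1) > 0
  ty <- ty[, keep, drop = FALSE]
  for (k in c("I", "II", "III", "IV")) {
    # set-difference oracle: loci of type k in s1 minus loci of type k anywhere else
    s1_loci <- colnames(ty)[ty["s1", ] == k]
    other <- colnames(ty)[apply(ty[-1, , drop = FALSE] == k, 2, any)]
    expect_identical(tly$private_A[tly$type == k],
                     length(setdiff(s1_loci, other)))
  }
  expect_error(clade_fragment_tally(hpa, msp, list(character(0), paste0("s", 1:4))),
               "empty")
  expect_error(clade_fragment_tally(hpa, msp, list("s1", c("s1", "s2"))),
               "disjoint")
})

test_that("recovered type proportions converge to the generator's targets", {
  # panel of purely independent loci: planted classes switched off
  cfg <- panel_config(n_loci_msap = 2000,
                      msap_shared = c(I = 0, II = 0, III = 0),
                      msap_private_a = c(I = 0, II = 0, III = 0),
                      msap_private_b = c(I = 0, II = 0, III = 0))
  p <- simulate_marker_panel(cfg, seed = 101)
  prof <- msap_profiles(p$hpa, p$msp)
  n <- prof$total_amplified[1]
  for (s in p$truth$clade_b[1:4]) {
    row <- prof[prof$sample_id == s, ]
    got <- c(row$typeI_total, row$typeII, row$typeIII, row$typeIV) / n
    pb <- p$truth$msap_probs_b
    tol <- 3 * sqrt(pb * (1 - pb) / n)
    expect_true(all(abs(got - pb) <= tol + 2 / n))
  }
})
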