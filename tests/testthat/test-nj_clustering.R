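test_that("Nei-Li distance follows the band-sharing formula", {
  expect_equal(nei_li_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(nei_li_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(nei_li_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  # shared absences carry no signal
  x <- c(1, 1, 0); y <- c(1, 0, 1)
  expect_equal(nei_li_distance(c(x, 0, 0, 0), c(y, 0, 0, 0)),
               nei_li_distance(x, y))
  # pairwise deletion of missing loci
  expect_equal(nei_li_distance(c(1, 1, 0, NA), c(1, 0, NA, 1)),
               nei_li_distance(c(1, 1), c(1, 0)))
  # no presence anywhere -> 0 by convention
  expect_equal(nei_li_distance(c(0, 0), c(0, 0)), 0)
  expect_error(nei_li_distance(c(NA, 1), c(1, NA)), "no usable loci")
  expect_error(nei_li_distance(c(1, 0), c(1)), "length")
})

test_that("distance matrices match hand-computed a/b/c tallies and relabel consistently", {
  v <- rbind(A = c(1, 1, 0, 1, 0), B = c(1, 0, 1, 1, 0), C = c(0, 1, 1, 0, 1))
  colnames(v) <- paste0("L", 1:5)
  m <- band_matrix(v)
  D <- distance_matrix(m)
  for (i in 1:2) for (j in (i + 1):3) {
    k <- abc_counts(v[i, ], v[j, ])
    expect_equal(D[i, j], 1 - 2 * k["a"] / (2 * k["a"] + k["b"] + k["c"]),
                 ignore_attr = TRUE)
    expect_equal(D[i, j], D[j, i])
  }
  expect_true(all(diag(D) == 0))

  two <- band_matrix(v[c(1, 1), ] , sample_ids = c("A", "A2"))
  expect_equal(unname(distance_matrix(two)), matrix(0, 2, 2))

  perm <- c("C", "A", "B")
  D2 <- distance_matrix(band_matrix(v[perm, ]))
  expect_equal(D2, D[perm, perm])
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.1)
  expect_equal(bl[["B"]], 0.1)
  expect_equal(bl[["C"]], 0.3)
  expect_equal(total_branch_length(tr), 0.5)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices and agrees with an independent NJ", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    gen <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, .05, .5)))
    d <- ape::cophenetic.phylo(gen)
    tr <- neighbor_joining(d)
    # all-pairs path-length oracle
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
    expect_equal(unname(suppressWarnings(phangorn::RF.dist(tr, ape::nj(d)))), 0)
  }
})

test_that("negative branch estimates are clamped to zero with the pair path preserved", {
  # a strongly non-additive matrix that drives one cherry branch negative
  d <- matrix(c(0, .1, .6, .55,
                .1, 0, .7, .05,
                .6, .7, 0, .6,
                .55, .05, .6, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("taxa at distance zero form a zero-length cherry", {
  v <- rbind(A = c(1, 1, 0, 1), B = c(1, 1, 0, 1),
             C = c(0, 1, 1, 0), D = c(1, 0, 1, 0))
  tr <- neighbor_joining(distance_matrix(band_matrix(v)))
  mrca <- ape::getMRCA(tr, c("A", "B"))
  tips_ab <- match(c("A", "B"), tr$tip.label)
  lens <- tr$edge.length[match(tips_ab, tr$edge[, 2])]
  expect_equal(lens, c(0, 0))
  expect_identical(length(ape::extract.clade(tr, mrca)$tip.label), 2L)
})

test_that("scaling all distances by k scales the NJ tree length by k", {
  set.seed(21)
  v <- matrix(rbinom(6 * 40, 1, 0.5), 6, 40,
              dimnames = list(paste0("s", 1:6), paste0("L", 1:40)))
  d <- distance_matrix(band_matrix(v))
  t1 <- neighbor_joining(d)
  t3 <- neighbor_joining(3 * d)
  expect_equal(total_branch_length(t3), 3 * total_branch_length(t1))
  expect_equal(total_branch_length(neighbor_joining(0 * d + 0)), 0)
})

test_that("outgroup rooting preserves path lengths and is idempotent", {
  p <- simulate_marker_panel(panel_config(n_clade_a = 2, n_clade_b = 5,
                                          n_loci_aflp = 120,
                                          aflp_private_a = 10,
                                          aflp_private_b = 10),
                             seed = 5)
  tr <- neighbor_joining(distance_matrix(filter_monomorphic(p$aflp)))
  rt <- root_with_outgroup(tr, "Outgroup")
  expect_true(ape::is.rooted(rt))
  expect_equal(ape::cophenetic.phylo(rt)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-12)
  rt2 <- root_with_outgroup(rt, "Outgroup")
  expect_equal(unname(suppressWarnings(phangorn::RF.dist(rt2, rt))), 0)
  expect_error(root_with_outgroup(tr, "nope"), "not a leaf")
})

test_that("three-taxon rooting yields the only resolution ((A,B),C)", {
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  rt <- root_with_outgroup(neighbor_joining(d), "C")
  ing <- ape::extract.clade(rt, ape::getMRCA(rt, c("A", "B")))
  expect_setequal(ing$tip.label, c("A", "B"))
})

test_that("degenerate resampling of identical locus copies gives 100% everywhere", {
  base <- c(1, 0, 1, 0, 0, 1)
  v <- cbind(L1 = base, L2 = 1 - base, L3 = base, L4 = 1 - base,
             L5 = base, L6 = 1 - base)
  rownames(v) <- paste0("s", 1:6)
  bt <- bootstrap_supports(band_matrix(v), n_reps = 50, seed = 3)
  expect_true(all(as.numeric(bt$node.label) == 100))
})

test_that("bootstrap supports are seed-reproducible and lie in [0, 100]", {
  # >= 20 clade-diagnostic loci: the regime where the clade split is
  # expected to be strongly supported
  p <- simulate_marker_panel(panel_config(n_clade_a = 2, n_clade_b = 5,
                                          n_loci_aflp = 150,
                                          aflp_private_a = 20,
                                          aflp_private_b = 20),
                             seed = 11)
  fm <- filter_monomorphic(p$aflp)
  b1 <- bootstrap_supports(fm, n_reps = 80, seed = 42)
  b2 <- bootstrap_supports(fm, n_reps = 80, seed = 42)
  expect_identical(b1$node.label, b2$node.label)
  s <- as.numeric(b1$node.label)
  expect_true(all(s >= 0 & s <= 100))
  b3 <- bootstrap_supports(fm, n_reps = 80, seed = 43)
  # a different stream may move supports, but the strong clade stays strong
  expect_gte(bipartition_support(b3, p$truth$clade_a), 95)
  expect_gte(bipartition_support(b1, p$truth$clade_a), 95)
  expect_error(bootstrap_supports(fm, n_reps = 0), "at least 1")
})
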