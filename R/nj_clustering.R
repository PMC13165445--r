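#' Nei-Li band-sharing distance between two band vectors
#'
#' For dominant markers, similarity is measured on shared band presences
#' only: with \eqn{a} = bands present in both samples, \eqn{b} and \eqn{c}
#' the bands private to each, the distance is
#' \deqn{D = 1 - \frac{2a}{2a + b + c},}
#' the complement of the Dice/Nei-Li band-sharing coefficient. Shared
#' absences carry no signal (an absent dominant band is uninformative).
#' Loci missing in either vector are excluded pairwise; if no band is
#' present in either sample over the usable loci the distance is 0 by
#' convention.
#'
#' @param x,y numeric vectors of band scores in \{0, 1, NA\}, equal length.
#' @return Distance in [0, 1].
#' @examples
#' nei_li_distance(c(1, 1, 0), c(1, 0, 1))  # a=1, b=1, c=1 -> 0.5
#' @export
nei_li_distance <- function(x, y) {
  if (length(x) != length(y)) stop("band vectors differ in length")
  use <- !is.na(x) & !is.na(y)
  if (!any(use)) stop("no usable loci: every locus is missing in a vector")
  x <- x[use]; y <- y[use]
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  denom <- 2 * a + b + cc
  if (denom == 0) return(0)
  1 - 2 * a / denom
}

# Pairwise Nei-Li distances on a plain 0/1/NA matrix (samples x loci).
nei_li_pairwise <- function(v) {
  obs <- !is.na(v)
  P <- (v == 1) & obs; P[!obs] <- FALSE
  A <- (v == 0) & obs; A[!obs] <- FALSE
  storage.mode(P) <- "numeric"; storage.mode(A) <- "numeric"
  usable <- obs %*% t(obs)
  if (any(usable[upper.tri(usable)] == 0))
    stop("a sample pair has no jointly scored locus")
  a <- P %*% t(P)
  b <- P %*% t(A)
  denom <- 2 * a + b + t(b)
  D <- matrix(0, nrow(v), nrow(v), dimnames = list(rownames(v), rownames(v)))
  nz <- denom > 0
  D[nz] <- 1 - 2 * a[nz] / denom[nz]
  diag(D) <- 0
  D
}

#' Pairwise Nei-Li distance matrix for a band matrix
#'
#' @param m a \code{band_matrix} with at least two samples.
#' @return Symmetric numeric matrix with zero diagonal, entries in [0, 1],
#'   dimnames taken from the sample labels.
#' @seealso [nei_li_distance()], [neighbor_joining()]
#' @export
distance_matrix <- function(m) {
  if (n_samples(m) < 2) stop("need at least two samples")
  nei_li_pairwise(m$values)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output file.
#' @export
write_distance_matrix <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the rate-corrected Q criterion.
#' At each step the pair minimizing
#' \eqn{Q(i,j) = (n-2)d_{ij} - r_i - r_j} (with \eqn{r_i = \sum_k d_{ik}})
#' is joined; ties are broken deterministically in favor of the lowest
#' active-pair index. Estimated branch lengths that come out negative are
#' clamped to zero with the deficit transferred to the sister branch, so
#' the joined pair's path length is preserved and all reported branch
#' lengths are non-negative. The result is the unrooted NJ tree (ape
#' \code{"phylo"} object with a basal trifurcation); NJ is exact on
#' additive distances.
#'
#' @param d symmetric distance matrix (or \code{dist}) over >= 3 taxa,
#'   labelled.
#' @return Unrooted \code{ape::phylo} tree with branch lengths.
#' @examples
#' d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- neighbor_joining(d)   # branches 0.1, 0.1, 0.3
#' @export
neighbor_joining <- function(d) {
  D <- as.matrix(d)
  labs <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  active <- seq_len(n)          # node ids: tips 1..n, internals n+1, ...
  next_id <- n + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  DD <- D
  while (length(active) > 2) {
    k <- length(active)
    r <- rowSums(DD)
    Q <- (k - 2) * DD - outer(r, r, `+`)
    diag(Q) <- Inf
    cand <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- DD[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    vj <- DD[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    parent <- c(parent, u, u)
    child <- c(child, active[i], active[j])
    elen <- c(elen, vi, vj)
    dnew <- (DD[i, ] + DD[j, ] - DD[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    DD <- DD[-c(i, j), -c(i, j), drop = FALSE]
    DD <- rbind(cbind(DD, dnew), c(dnew, 0))
    active <- c(active[-c(i, j)], u)
  }
  # connect the last two lineages; root the edge list at an internal node
  last <- max(0, DD[1, 2])
  a1 <- active[1]; a2 <- active[2]
  root_old <- if (a2 > n) a2 else a1
  tip_side <- if (root_old == a2) a1 else a2
  parent <- c(parent, root_old); child <- c(child, tip_side)
  elen <- c(elen, last)
  build_phylo(parent, child, elen, labs, n, root_old)
}

# Assemble an ape "phylo" from a parent/child edge list, renumbering
# internal nodes in preorder from the root (ape convention: root = n+1).
build_phylo <- function(parent, child, elen, labs, n, root_old) {
  kids <- split(seq_along(parent), parent)
  newid <- integer(max(parent))
  newid[seq_len(n)] <- seq_len(n)
  n_internal <- length(unique(parent))
  counter <- n
  edge <- matrix(0L, length(parent), 2)
  edge_len <- numeric(length(parent))
  pos <- 0L
  visit <- function(old) {
    counter <<- counter + 1L
    newid[old] <<- counter
    for (e in kids[[as.character(old)]]) {
      ch <- child[e]
      pos <<- pos + 1L
      row <- pos
      if (ch <= n) {
        edge[row, ] <<- c(newid[old], ch)
        edge_len[row] <<- elen[e]
      } else {
        edge[row, 1] <<- newid[old]
        edge_len[row] <<- elen[e]
        # child id filled after recursion assigns it
        visit(ch)
        edge[row, 2] <<- newid[ch]
      }
    }
  }
  visit(root_old)
  tr <- list(edge = edge, edge.length = edge_len, tip.label = labs,
             Nnode = n_internal)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Root a tree on the branch subtending an outgroup leaf
#'
#' @param t an ape \code{phylo} tree.
#' @param outgroup leaf label to root with.
#' @return Rooted \code{phylo}; re-rooting on the same leaf is idempotent
#'   and leaf-to-leaf path lengths are preserved.
#' @export
root_with_outgroup <- function(t, outgroup) {
  if (!outgroup %in% t$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  ape::root(t, outgroup = outgroup, resolve.root = TRUE)
}

#' Locus-resampling bootstrap supports for the NJ tree
#'
#' Resamples loci (columns) with replacement to the original locus count,
#' rebuilds the Nei-Li/NJ tree for each replicate, and reports for every
#' internal branch of the full-data tree the percentage of replicates whose
#' tree contains the same bipartition. Supports are attached to the
#' full-data tree as node labels. The replicate stream is driven by a
#' single seeded generator, so results are reproducible given \code{seed}.
#'
#' @param m a \code{band_matrix} (monomorphic loci already filtered).
#' @param n_reps number of bootstrap replicates (>= 1); default 1000.
#' @param seed integer seed for the resampling stream.
#' @return The full-data NJ tree with \code{node.label} holding percentage
#'   supports in [0, 100] (the basal node carries the trivial 100).
#' @export
bootstrap_supports <- function(m, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("'n_reps' must be at least 1")
  full <- neighbor_joining(nei_li_pairwise(m$values))
  v <- m$values
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(v), ncol(v), replace = TRUE)
    reps[[b]] <- neighbor_joining(nei_li_pairwise(v[, cols, drop = FALSE]))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- round_half_up(100 * counts / n_reps, 1)
  full
}

#' Bootstrap support of a given bipartition
#'
#' Looks up, on a tree annotated by [bootstrap_supports()], the support of
#' the branch splitting \code{tips} from the remaining leaves.
#'
#' @param t a \code{phylo} with \code{node.label} supports.
#' @param tips leaf labels on one side of the bipartition.
#' @return Support value, or \code{NA} if no branch of the tree induces
#'   that bipartition.
#' @export
bipartition_support <- function(t, tips) {
  if (is.null(t$node.label)) stop("tree carries no support labels")
  pp <- ape::prop.part(t)
  labs <- attr(pp, "labels")
  if (!all(tips %in% labs)) stop("unknown leaf label(s)")
  target <- sort(match(tips, labs))
  all_i <- seq_along(labs)
  for (i in seq_along(pp)) {
    s <- sort(pp[[i]])
    if (identical(s, target) ||
        identical(sort(setdiff(all_i, s)), target))
      return(as.numeric(t$node.label[i]))
  }
  NA_real_
}

#' Total branch length of a tree
#'
#' @param t an ape \code{phylo} tree with branch lengths.
#' @return Sum of all branch lengths.
#' @export
total_branch_length <- function(t) {
  if (is.null(t$edge.length)) stop("tree has no branch lengths")
  sum(t$edge.length)
}
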