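#' Read a binary morphological character matrix
#'
#' Thin wrapper over [read_band_matrix()] with the \code{MORPHOLOGY} tag;
#' the expected layout is taxa in columns (rows are characters) or, with
#' \code{orientation = "samples"}, taxa in rows. States are \code{0}
#' (absent), \code{1} (present) or \code{?} (not scored).
#'
#' @inheritParams read_band_matrix
#' @return A \code{band_matrix} with \code{marker_system = "MORPHOLOGY"};
#'   its \code{$values} (taxa x characters) is what the mapping functions
#'   consume.
#' @export
read_character_matrix <- function(path, orientation = c("loci", "samples")) {
  read_band_matrix(path, orientation = match.arg(orientation),
                   marker_system = "MORPHOLOGY")
}

# Accept a band_matrix or a plain taxa x characters matrix.
as_character_values <- function(m) {
  if (inherits(m, "band_matrix")) m$values else as.matrix(m)
}

# Fitch/Hartigan pass for one binary character on a (possibly
# multifurcating) tree. State sets are 2-bit masks: 1 = {0}, 2 = {1},
# 3 = {0,1}. Down-pass: at each internal node keep the states contained in
# the maximal number of child sets (K) and add (children - K) steps; for
# bifurcations this is exactly Fitch's intersection/union rule. Up-pass:
# the root takes the smallest state in its set (0 preferred); a child keeps
# the parent's state when its own set allows it, otherwise its smallest.
fitch_engine <- function(t, states) {
  tips <- t$tip.label
  if (!all(tips %in% names(states)))
    stop("character states missing for leaves: ",
         paste(setdiff(tips, names(states)), collapse = ", "))
  s <- states[tips]
  if (all(is.na(s))) stop("at least one leaf must have a scored state")
  if (!all(s %in% c(0, 1) | is.na(s)))
    stop("character states must be 0, 1 or NA")
  n <- length(tips)
  nodeset <- integer(n + t$Nnode)
  nodeset[seq_len(n)] <- ifelse(is.na(s), 3L, ifelse(s == 1, 2L, 1L))
  po <- ape::reorder.phylo(t, "postorder")
  internal <- unique(po$edge[, 1])        # postorder; root comes last
  steps <- 0L
  for (p in internal) {
    ch <- po$edge[po$edge[, 1] == p, 2]
    k0 <- sum(bitwAnd(nodeset[ch], 1L) > 0)
    k1 <- sum(bitwAnd(nodeset[ch], 2L) > 0)
    K <- max(k0, k1)
    nodeset[p] <- bitwOr(if (k0 == K) 1L else 0L, if (k1 == K) 2L else 0L)
    steps <- steps + length(ch) - K
  }
  root <- internal[length(internal)]
  assign <- integer(n + t$Nnode)
  assign[root] <- if (bitwAnd(nodeset[root], 1L) > 0) 0L else 1L
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    want <- if (assign[p] == 0L) 1L else 2L
    assign[ch] <- if (bitwAnd(nodeset[ch], want) > 0) assign[p]
                  else if (bitwAnd(nodeset[ch], 1L) > 0) 0L else 1L
  }
  names(assign) <- c(tips, paste0("node", seq_len(t$Nnode) + n))
  list(steps = steps, node_states = assign,
       ambiguous = any(nodeset[internal] == 3L), root = root)
}

#' Minimum parsimony steps for one character on a fixed tree
#'
#' Counts the minimum number of unordered (Fitch) state changes a binary
#' character requires on a given tree. Missing leaf states are wildcards
#' and never force a change; multifurcations are handled by the
#' count-maximizing generalization of the Fitch set rule, which reduces to
#' the classic intersection/union rule on bifurcating trees.
#'
#' @param t an ape \code{phylo} tree (rooted or unrooted; the score does
#'   not depend on the root).
#' @param states numeric vector of 0/1/\code{NA} states named by the
#'   tree's leaf labels.
#' @return Integer step count (0 iff invariant among scored leaves).
#' @export
fitch_steps <- function(t, states) fitch_engine(t, states)$steps

#' Total parsimony steps of a character matrix on a tree
#'
#' @param t an ape \code{phylo} tree.
#' @param m a taxa-by-characters matrix of 0/1/\code{NA} states (rownames
#'   are taxa), or a \code{band_matrix} holding one.
#' @return Sum of [fitch_steps()] over the characters.
#' @export
total_steps <- function(t, m) {
  v <- as_character_values(m)
  sum(vapply(seq_len(ncol(v)), function(j) fitch_steps(t, v[, j]),
             integer(1)))
}

#' Classify a character's fit on a rooted tree
#'
#' Maps one binary character onto a tree rooted with the outgroup, whose
#' state defines the plesiomorphic condition, and classifies the pattern:
#' \describe{
#'   \item{plesiomorphic}{invariant among scored leaves (0 steps);}
#'   \item{autapomorphy}{a single change with the derived state confined to
#'     one ingroup leaf;}
#'   \item{synapomorphy}{a single change with the derived state shared by
#'     two or more leaves — necessarily a clade on the rooted tree;}
#'   \item{homoplastic}{more than one change, i.e. independent repeated
#'     origin or reversal.}
#' }
#'
#' @param t an ape \code{phylo} tree containing the outgroup leaf; rooted
#'   on it internally via [root_with_outgroup()].
#' @param states numeric vector of 0/1/\code{NA} named by leaf labels; the
#'   outgroup state must not be missing.
#' @param outgroup outgroup leaf label.
#' @param label optional character label carried through to the result.
#' @return An object of class \code{"character_fit"}: list with
#'   \code{label}, \code{steps}, \code{classification},
#'   \code{derived_state}, \code{derived_leaves}, \code{node_states} (one
#'   deterministic optimal internal labeling) and \code{ambiguous} (TRUE
#'   when several optimal labelings exist).
#' @export
classify_character <- function(t, states, outgroup, label = NA_character_) {
  rt <- root_with_outgroup(t, outgroup)
  if (is.na(states[outgroup]))
    stop("outgroup state is missing; the plesiomorphic state is undefined")
  fit <- fitch_engine(rt, states)
  plesio <- states[[outgroup]]
  derived <- 1 - plesio
  obs <- states[rt$tip.label]
  derived_leaves <- names(obs)[!is.na(obs) & obs == derived]
  ingroup_derived <- setdiff(derived_leaves, outgroup)
  classification <-
    if (fit$steps == 0) "plesiomorphic"
    else if (fit$steps > 1) "homoplastic"
    else if (length(ingroup_derived) == 1) "autapomorphy"
    else "synapomorphy"
  structure(list(label = label, steps = fit$steps,
                 classification = classification,
                 derived_state = derived, derived_leaves = derived_leaves,
                 node_states = fit$node_states, ambiguous = fit$ambiguous),
            class = "character_fit")
}

#' @export
print.character_fit <- function(x, ...) {
  cat(sprintf("character %s: %d step(s), %s%s\n",
              if (is.na(x$label)) "<unnamed>" else x$label, x$steps,
              x$classification,
              if (x$ambiguous) " (labeling ambiguous)" else ""))
  if (length(x$derived_leaves))
    cat("  derived state", x$derived_state, "at:",
        paste(x$derived_leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Map and classify every character of a matrix on a rooted tree
#'
#' @inheritParams classify_character
#' @param m taxa-by-characters matrix (or \code{band_matrix}).
#' @return Data frame with one row per character: \code{character},
#'   \code{steps}, \code{classification}, \code{ambiguous}.
#' @export
map_characters <- function(t, m, outgroup) {
  v <- as_character_values(m)
  labs <- colnames(v)
  if (is.null(labs)) labs <- paste0("C", seq_len(ncol(v)))
  rows <- lapply(seq_len(ncol(v)), function(j) {
    f <- classify_character(t, v[, j], outgroup, label = labs[j])
    data.frame(character = labs[j], steps = f$steps,
               classification = f$classification, ambiguous = f$ambiguous,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
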