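#' Classify an MSAP locus from its paired digest states
#'
#' MSAP scores every CCGG locus twice, once per isoschizomer digest:
#' EcoRI/HpaII (HpaII is blocked by methylation of the internal cytosine on
#' both strands) and EcoRI/MspI (MspI is blocked by external-cytosine
#' methylation). The joint presence pattern identifies the methylation
#' state of the site:
#' \describe{
#'   \item{type I}{band in both digests — non-methylated;}
#'   \item{type II}{band only in the MspI digest — fully methylated
#'     internal cytosines;}
#'   \item{type III}{band only in the HpaII digest — hemimethylated;}
#'   \item{type IV}{band in neither digest — fully methylated on both
#'     strands (or the site is absent; the two are indistinguishable for a
#'     dominant marker).}
#' }
#'
#' @param h presence (1) or absence (0) in the EcoRI/HpaII digest;
#'   vectorized.
#' @param m presence (1) or absence (0) in the EcoRI/MspI digest.
#' @return Character vector over \code{c("I","II","III","IV")}; \code{NA}
#'   where either digest state is missing.
#' @examples
#' classify_site(1, 1)  # "I"
#' classify_site(0, 1)  # "II"
#' @export
classify_site <- function(h, m) {
  if (!all(h %in% c(0, 1) | is.na(h)) || !all(m %in% c(0, 1) | is.na(m)))
    stop("digest states must be 0, 1 or NA")
  out <- rep(NA_character_, length(h))
  out[h == 1 & m == 1] <- "I"
  out[h == 0 & m == 1] <- "II"
  out[h == 1 & m == 0] <- "III"
  out[h == 0 & m == 0] <- "IV"
  out
}

# Align the two digest matrices on a common sample set and on the panel of
# loci amplified (in either digest) in at least one sample; returns the
# samples x panel matrix of type calls.
msap_type_matrix <- function(hpa, msp) {
  if (!setequal(sample_ids(hpa), sample_ids(msp)))
    stop("HpaII and MspI matrices must share the same samples")
  if (!setequal(locus_ids(hpa), locus_ids(msp)))
    stop("HpaII and MspI matrices must share the same locus panels")
  samp <- sample_ids(hpa)
  loci <- locus_ids(hpa)
  H <- hpa$values[samp, loci, drop = FALSE]
  M <- msp$values[samp, loci, drop = FALSE]
  amplified <- colSums(H == 1, na.rm = TRUE) + colSums(M == 1, na.rm = TRUE) > 0
  H <- H[, amplified, drop = FALSE]
  M <- M[, amplified, drop = FALSE]
  ty <- classify_site(as.vector(H), as.vector(M))
  matrix(ty, nrow(H), ncol(H), dimnames = dimnames(H))
}

# Default methylation-sensitivity predicate for type-I loci: a type-I call
# is counted as methylation-sensitive for a sample when the same locus is
# non-type-I in at least one other sample (i.e. the locus is
# methylation-polymorphic across the panel).
ms_polymorphic_predicate <- function(types) {
  apply(types, 2, function(col) {
    obs <- col[!is.na(col)]
    any(obs != "I")
  })
}

#' Per-sample MSAP methylation profile
#'
#' Counts, for one sample or for every sample, the loci of each methylation
#' type over the common amplified panel, and derives the two standard
#' methylation indices (see [methylation_indices()]). The panel is the
#' union of loci amplified in either digest in at least one sample, so
#' type-IV counts are taken against a shared denominator and the four type
#' counts sum to the same panel size for every sample.
#'
#' Type-I loci are additionally split into a "methylation-sensitive"
#' subset: by default a sample's type-I locus counts as
#' methylation-sensitive when that locus is non-type-I in at least one
#' other sample. Pass a different \code{ms_predicate} to substitute another
#' definition; it receives the full samples-by-loci type matrix and must
#' return one logical per locus.
#'
#' @param hpa,msp \code{band_matrix} objects for the EcoRI/HpaII and
#'   EcoRI/MspI digests, over identical samples and loci.
#' @param sample_id for [profile_sample()], the sample to profile.
#' @param ms_predicate function(type matrix) -> logical per locus marking
#'   loci whose type-I calls are methylation-sensitive.
#' @param fully_methylated which classes enter the fully-methylated index:
#'   \code{"II+IV"} (default) or \code{"IV"}; see [methylation_indices()].
#' @return [msap_profiles()] returns a data frame with one row per sample
#'   and columns \code{sample_id}, \code{typeI_total}, \code{typeI_ms},
#'   \code{typeII}, \code{typeIII}, \code{typeIV}, \code{total_amplified},
#'   \code{msap_pct}, \code{fully_methylated_pct}. [profile_sample()]
#'   returns the single matching row.
#' @export
msap_profiles <- function(hpa, msp, ms_predicate = ms_polymorphic_predicate,
                          fully_methylated = c("II+IV", "IV")) {
  fully_methylated <- match.arg(fully_methylated)
  types <- msap_type_matrix(hpa, msp)
  ms_locus <- ms_predicate(types)
  if (length(ms_locus) != ncol(types) || !is.logical(ms_locus))
    stop("'ms_predicate' must return one logical per panel locus")
  panel <- ncol(types)
  rows <- lapply(rownames(types), function(s) {
    ty <- types[s, ]
    cnt <- vapply(c("I", "II", "III", "IV"),
                  function(k) sum(ty == k, na.rm = TRUE), integer(1))
    ms <- sum(ty == "I" & ms_locus, na.rm = TRUE)
    idx <- methylation_indices(typeI_ms = ms, typeII = cnt[["II"]],
                               typeIII = cnt[["III"]], typeIV = cnt[["IV"]],
                               total = panel,
                               fully_methylated = fully_methylated)
    data.frame(sample_id = s, typeI_total = cnt[["I"]], typeI_ms = ms,
               typeII = cnt[["II"]], typeIII = cnt[["III"]],
               typeIV = cnt[["IV"]], total_amplified = panel,
               msap_pct = idx$msap_pct,
               fully_methylated_pct = idx$fully_methylated_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname msap_profiles
#' @export
profile_sample <- function(hpa, msp, sample_id,
                           ms_predicate = ms_polymorphic_predicate,
                           fully_methylated = c("II+IV", "IV")) {
  if (!sample_id %in% sample_ids(hpa) || !sample_id %in% sample_ids(msp))
    stop("sample '", sample_id, "' absent from a digest matrix")
  prof <- msap_profiles(hpa, msp, ms_predicate, fully_methylated)
  prof[prof$sample_id == sample_id, , drop = FALSE]
}

#' Methylation indices from MSAP type counts
#'
#' The overall methylation level (MSAP\%) is the percentage of panel loci
#' carrying any methylation signal: the methylation-sensitive subset of
#' type I plus all of types II, III and IV, over the total amplified panel.
#' The fully-methylated ratio is, by default, the percentage of loci in
#' types II + IV (both have the internal cytosines methylated on both
#' strands); \code{fully_methylated = "IV"} restricts it to type IV only,
#' an alternative convention found in the MSAP literature. Both indices are
#' rounded half-up to two decimals for reporting.
#'
#' @param typeI_ms count of methylation-sensitive type-I loci.
#' @param typeII,typeIII,typeIV per-type locus counts.
#' @param total total amplified panel size (> 0).
#' @param fully_methylated \code{"II+IV"} (default) or \code{"IV"}.
#' @return List with numeric scalars \code{msap_pct} and
#'   \code{fully_methylated_pct}, both in [0, 100].
#' @examples
#' methylation_indices(101, 210, 155, 90, total = 668)
#' @export
methylation_indices <- function(typeI_ms, typeII, typeIII, typeIV, total,
                                fully_methylated = c("II+IV", "IV")) {
  fully_methylated <- match.arg(fully_methylated)
  if (total <= 0) stop("'total' must be positive")
  methylated <- typeI_ms + typeII + typeIII + typeIV
  full <- if (fully_methylated == "II+IV") typeII + typeIV else typeIV
  list(msap_pct = round_half_up(100 * methylated / total, 2),
       fully_methylated_pct = round_half_up(100 * full / total, 2))
}

#' Clade-shared and clade-private fragment tallies by methylation type
#'
#' For a two-way partition of the samples, counts per methylation type the
#' loci uniformly of that type in every sample (\code{shared_all}) and the
#' loci of that type in every member of one side while in no member of the
#' other (\code{private_A}, \code{private_B}) — the quantities used to
#' describe how much band variation separates two clades.
#'
#' @inheritParams msap_profiles
#' @param partition list of two disjoint character vectors of sample
#'   labels, jointly covering all samples.
#' @return Data frame with columns \code{type}, \code{shared_all},
#'   \code{private_A}, \code{private_B}, one row per type I--IV.
#' @export
clade_fragment_tally <- function(hpa, msp, partition) {
  if (length(partition) != 2)
    stop("'partition' must list exactly two sample sets")
  a <- partition[[1]]; b <- partition[[2]]
  if (!length(a) || !length(b)) stop("empty partition side")
  types <- msap_type_matrix(hpa, msp)
  all_s <- rownames(types)
  if (length(intersect(a, b)) || !setequal(c(a, b), all_s))
    stop("partition sides must be disjoint and cover all samples")
  tally_one <- function(k) {
    is_k <- types == k        # NA-safe: missing never counts as the type
    is_k[is.na(is_k)] <- FALSE
    in_all <- colSums(is_k) == nrow(is_k)
    all_a <- colSums(is_k[a, , drop = FALSE]) == length(a)
    all_b <- colSums(is_k[b, , drop = FALSE]) == length(b)
    none_a <- colSums(is_k[a, , drop = FALSE]) == 0
    none_b <- colSums(is_k[b, , drop = FALSE]) == 0
    c(shared_all = sum(in_all),
      private_A = sum(all_a & none_b),
      private_B = sum(all_b & none_a))
  }
  res <- t(vapply(c("I", "II", "III", "IV"), tally_one, numeric(3)))
  data.frame(type = rownames(res), shared_all = as.integer(res[, 1]),
             private_A = as.integer(res[, 2]),
             private_B = as.integer(res[, 3]),
             row.names = NULL, stringsAsFactors = FALSE)
}
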