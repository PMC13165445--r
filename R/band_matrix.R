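#' Binary band presence/absence matrix
#'
#' Constructs the central container of the package: a samples-by-loci matrix
#' of dominant-marker band scores (1 = band present, 0 = band absent,
#' \code{NA} = not scored), tagged with the marker system that produced it
#' and, optionally, a per-locus primer-combination label.
#'
#' @param values integer or logical matrix, samples in rows and loci in
#'   columns, entries in \{0, 1, NA\}. Row and column names, when present,
#'   are used as sample and locus labels.
#' @param sample_ids character vector of unique sample labels; defaults to
#'   the rownames of \code{values}.
#' @param locus_ids character vector of unique locus labels; defaults to the
#'   colnames of \code{values}.
#' @param marker_system one of \code{"AFLP"}, \code{"MSAP_HPAII"},
#'   \code{"MSAP_MSPI"}, \code{"MORPHOLOGY"}, \code{"COMBINED"}.
#' @param primer_combo optional character vector, one label per locus,
#'   recording which primer-pair combination generated each fragment.
#'
#' @return An object of class \code{"band_matrix"}: a list with elements
#'   \code{values} (integer matrix with dimnames), \code{marker_system} and
#'   \code{primer_combo}.
#' @examples
#' m <- band_matrix(rbind(A = c(1, 0, 1), B = c(1, 1, 0)),
#'                  locus_ids = c("L1", "L2", "L3"))
#' n_loci(m)
#' @export
band_matrix <- function(values, sample_ids = rownames(values),
                        locus_ids = colnames(values),
                        marker_system = c("AFLP", "MSAP_HPAII", "MSAP_MSPI",
                                          "MORPHOLOGY", "COMBINED"),
                        primer_combo = NULL) {
  marker_system <- match.arg(marker_system)
  values <- as.matrix(values)
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(locus_ids))
    locus_ids <- sprintf("L%d", seq_len(ncol(values)))
  sample_ids <- trimws(as.character(sample_ids))
  locus_ids <- trimws(as.character(locus_ids))
  if (length(sample_ids) != nrow(values))
    stop("length of 'sample_ids' does not match the number of rows")
  if (length(locus_ids) != ncol(values))
    stop("length of 'locus_ids' does not match the number of columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample labels: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus labels: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L) | is.na(values)))
    stop("band scores must be 0, 1 or NA")
  dimnames(values) <- list(sample_ids, locus_ids)
  if (!is.null(primer_combo)) {
    primer_combo <- as.character(primer_combo)
    if (length(primer_combo) != ncol(values))
      stop("'primer_combo' must give one label per locus")
    if (anyNA(primer_combo))
      stop("missing primer-combination labels")
  }
  structure(list(values = values, marker_system = marker_system,
                 primer_combo = primer_combo),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("band_matrix [%s]: %d samples x %d loci", x$marker_system,
              nrow(v), ncol(v)))
  if (!is.null(x$primer_combo))
    cat(sprintf(", %d primer combination(s)", length(unique(x$primer_combo))))
  nm <- sum(is.na(v))
  if (nm > 0) cat(sprintf(", %d missing cells", nm))
  cat("\n  samples: ", paste(utils::head(rownames(v), 6), collapse = ", "),
      if (nrow(v) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname band_matrix
#' @param m a \code{band_matrix}.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname band_matrix
#' @export
locus_ids <- function(m) colnames(m$values)

#' @rdname band_matrix
#' @export
n_samples <- function(m) nrow(m$values)

#' @rdname band_matrix
#' @export
n_loci <- function(m) ncol(m$values)

#' Read or write a band matrix as delimited text
#'
#' The canonical on-disk layout is gel-like: rows are loci, columns are
#' samples, with a header row of sample labels and a leading label column of
#' locus names. \code{orientation = "samples"} reads/writes the transpose
#' (rows are samples). Entries are \code{0}, \code{1}, or \code{?} for a
#' cell that could not be scored. The field separator is chosen from the
#' file extension (\code{.csv} is comma, anything else tab).
#'
#' An optional second label column named \code{primer_combo} (in the
#' loci-as-rows orientation) carries per-locus primer-combination labels.
#'
#' @param path file to read from or write to.
#' @param orientation \code{"loci"} (default; rows are loci) or
#'   \code{"samples"} (rows are samples).
#' @param marker_system marker-system tag to attach on reading.
#' @return \code{read_band_matrix} returns a \code{band_matrix};
#'   \code{write_band_matrix} invisibly returns \code{path}.
#' @export
read_band_matrix <- function(path, orientation = c("loci", "samples"),
                             marker_system = "AFLP") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  if (ncol(df) < 2) stop("band-matrix file needs a label column and data")
  row_labels <- trimws(df[[1]])
  df <- df[, -1, drop = FALSE]
  combo <- NULL
  if (orientation == "loci" && identical(names(df)[1], "primer_combo")) {
    combo <- trimws(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  col_labels <- trimws(names(df))
  vals <- as.matrix(df)
  bad <- !(vals %in% c("0", "1", "?"))
  if (any(bad))
    stop("non-binary token(s) in band matrix: ",
         paste(utils::head(unique(vals[bad]), 5), collapse = ", "))
  num <- matrix(NA_integer_, nrow(vals), ncol(vals))
  num[vals == "0"] <- 0L
  num[vals == "1"] <- 1L
  if (orientation == "loci") {
    band_matrix(t(num), sample_ids = col_labels, locus_ids = row_labels,
                marker_system = marker_system, primer_combo = combo)
  } else {
    band_matrix(num, sample_ids = row_labels, locus_ids = col_labels,
                marker_system = marker_system)
  }
}

#' @rdname read_band_matrix
#' @param m a \code{band_matrix} to write.
#' @export
write_band_matrix <- function(m, path, orientation = c("loci", "samples")) {
  orientation <- match.arg(orientation)
  v <- m$values
  tok <- matrix(as.character(v), nrow(v), ncol(v))
  tok[is.na(v)] <- "?"
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (orientation == "loci") {
    out <- data.frame(locus = colnames(v), check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (!is.null(m$primer_combo)) out$primer_combo <- m$primer_combo
    out <- cbind(out, as.data.frame(t(tok), stringsAsFactors = FALSE))
    names(out)[-seq_len(ncol(out) - nrow(v))] <- rownames(v)
  } else {
    out <- data.frame(sample = rownames(v), stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(tok, stringsAsFactors = FALSE))
    names(out)[-1] <- colnames(v)
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop monomorphic loci
#'
#' Retains exactly the loci showing at least two distinct observed states
#' across the sample panel; invariant bands carry no information for
#' band-sharing distances and are excluded before clustering. A locus with
#' missing cells still counts as variable if its scored cells show both
#' states.
#'
#' @param m a \code{band_matrix}.
#' @return A \code{band_matrix} with the same samples and the variable loci
#'   only (possibly zero loci).
#' @export
filter_monomorphic <- function(m) {
  keep <- apply(m$values, 2, function(col) {
    s <- unique(col[!is.na(col)])
    length(s) >= 2
  })
  band_matrix(m$values[, keep, drop = FALSE],
              marker_system = m$marker_system,
              primer_combo = m$primer_combo[keep])
}

#' Combine band matrices over a common sample panel
#'
#' Column-concatenates several marker matrices scored on the same samples
#' (in any row order) into a single \code{COMBINED} matrix, so that AFLP and
#' MSAP profiles can be clustered jointly. Locus labels are prefixed with
#' each input's marker system to keep them disjoint; sample order follows
#' the first input.
#'
#' @param ms list of \code{band_matrix} objects with identical sample sets.
#' @return A \code{band_matrix} with \code{marker_system = "COMBINED"}.
#' @export
merge_matrices <- function(ms) {
  if (!length(ms)) stop("no matrices to merge")
  ref <- sample_ids(ms[[1]])
  blocks <- lapply(ms, function(m) {
    if (!setequal(sample_ids(m), ref))
      stop("sample sets differ between matrices")
    v <- m$values[ref, , drop = FALSE]
    colnames(v) <- paste(m$marker_system, colnames(v), sep = ".")
    v
  })
  combos <- unlist(lapply(ms, function(m) {
    if (is.null(m$primer_combo)) rep(NA_character_, n_loci(m))
    else m$primer_combo
  }))
  if (all(is.na(combos))) combos <- NULL
  band_matrix(do.call(cbind, blocks), marker_system = "COMBINED",
              primer_combo = combos)
}

#' Fragment and polymorphism counts per primer combination
#'
#' Tallies, for each primer-pair combination, the number of fragments it
#' generated and how many of those are variable (not monomorphic) across
#' the panel, together with panel-wide totals — the standard summary table
#' of a dominant-marker fingerprinting experiment.
#'
#' @param m a \code{band_matrix} with \code{primer_combo} populated.
#' @return A list of class \code{"polymorphism_summary"} with a data frame
#'   \code{per_combo} (columns \code{primer_combo}, \code{n_fragments},
#'   \code{n_variable}) and scalars \code{total_fragments},
#'   \code{total_variable}.
#' @export
polymorphism_summary <- function(m) {
  if (is.null(m$primer_combo))
    stop("primer-combination labels are required for a polymorphism summary")
  variable <- colnames(filter_monomorphic(m)$values)
  is_var <- locus_ids(m) %in% variable
  combo <- factor(m$primer_combo, levels = unique(m$primer_combo))
  per <- data.frame(
    primer_combo = levels(combo),
    n_fragments = as.integer(table(combo)),
    n_variable = as.integer(tapply(is_var, combo, sum)),
    stringsAsFactors = FALSE
  )
  structure(list(per_combo = per,
                 total_fragments = sum(per$n_fragments),
                 total_variable = sum(per$n_variable)),
            class = "polymorphism_summary")
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  print(x$per_combo, row.names = FALSE)
  cat(sprintf("Total fragments: %d; total variable fragments: %d\n",
              x$total_fragments, x$total_variable))
  invisible(x)
}
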