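#' Configuration for a synthetic two-clade marker panel
#'
#' Describes the statistical structure of the panels the generator emits: a
#' small clade A (default 2 samples) against a larger clade B (default 12)
#' plus one divergent outgroup, AFLP and MSAP locus counts, the fraction of
#' AFLP loci that are polymorphic, planted clade-private fragment counts,
#' and per-clade MSAP type proportions for the unstructured loci. The
#' defaults emulate a published 14-cultivar ornamental panel: 549 AFLP loci
#' with 53.2\% polymorphic, 667 MSAP loci whose per-sample type I--IV
#' counts land in the ranges 200--221 / 181--216 / 144--164 / 84--134, with
#' 116/84/77 type I/II/III loci uniform across the panel and
#' 39/20/21 vs 51/22/25 loci private to each clade.
#'
#' @param n_clade_a,n_clade_b samples per clade.
#' @param outgroup_label label of the outgroup sample (set \code{NULL} to
#'   omit the outgroup).
#' @param n_loci_aflp total AFLP loci.
#' @param frac_polymorphic fraction of AFLP loci that are variable.
#' @param aflp_private_a,aflp_private_b AFLP loci fixed present in one
#'   clade and absent in the other (clade-diagnostic).
#' @param msap_shared named count vector (types I--III) of loci of uniform
#'   type in every ingroup sample.
#' @param msap_private_a,msap_private_b named count vectors (types
#'   I--III): loci of that type throughout one clade and unamplified
#'   (type IV) throughout the other.
#' @param n_loci_msap total MSAP loci; the remainder over the planted
#'   classes is drawn independently per sample.
#' @param msap_probs_a,msap_probs_b type I--IV draw probabilities for the
#'   unstructured MSAP loci, per clade (each sums to 1).
#' @param outgroup_presence presence probability of the outgroup at
#'   variable AFLP loci.
#' @param noise_presence within-clade presence probability at
#'   non-diagnostic variable AFLP loci.
#' @return List of class \code{"panel_config"}.
#' @export
panel_config <- function(n_clade_a = 2, n_clade_b = 12,
                         outgroup_label = "Outgroup",
                         n_loci_aflp = 549, frac_polymorphic = 0.532,
                         aflp_private_a = 29, aflp_private_b = 38,
                         msap_shared = c(I = 116, II = 84, III = 77),
                         msap_private_a = c(I = 39, II = 20, III = 21),
                         msap_private_b = c(I = 51, II = 22, III = 25),
                         n_loci_msap = 667,
                         msap_probs_a = c(I = 0.281, II = 0.394,
                                          III = 0.217, IV = 0.108),
                         msap_probs_b = c(I = 0.193, II = 0.492,
                                          III = 0.255, IV = 0.060),
                         outgroup_presence = 0.35,
                         noise_presence = 0.5) {
  cfg <- list(n_clade_a = n_clade_a, n_clade_b = n_clade_b,
              outgroup_label = outgroup_label,
              n_loci_aflp = n_loci_aflp, frac_polymorphic = frac_polymorphic,
              aflp_private_a = aflp_private_a,
              aflp_private_b = aflp_private_b,
              msap_shared = msap_shared, msap_private_a = msap_private_a,
              msap_private_b = msap_private_b, n_loci_msap = n_loci_msap,
              msap_probs_a = msap_probs_a / sum(msap_probs_a),
              msap_probs_b = msap_probs_b / sum(msap_probs_b),
              outgroup_presence = outgroup_presence,
              noise_presence = noise_presence)
  n_var <- round(cfg$n_loci_aflp * cfg$frac_polymorphic)
  if (cfg$aflp_private_a + cfg$aflp_private_b > n_var)
    stop("clade-diagnostic AFLP loci exceed the polymorphic budget")
  if (sum(cfg$msap_shared) + sum(cfg$msap_private_a) +
      sum(cfg$msap_private_b) > cfg$n_loci_msap)
    stop("planted MSAP loci exceed the panel size")
  if (cfg$n_clade_a < 1 || cfg$n_clade_b < 1)
    stop("each clade needs at least one sample")
  class(cfg) <- "panel_config"
  cfg
}

msap_type_pair <- function(type) {
  switch(type, I = c(1L, 1L), II = c(0L, 1L), III = c(1L, 0L),
         IV = c(0L, 0L))
}

#' Simulate a two-clade AFLP + MSAP marker panel
#'
#' Draws a full marker panel with known ("planted") structure. AFLP loci
#' fall in three classes: monomorphic (present in every sample including
#' the outgroup), clade-diagnostic (fixed present in one clade, absent in
#' the other), and within-clade polymorphic noise (independent Bernoulli
#' presence per ingroup sample, redrawn so that every noise locus really is
#' variable and not accidentally clade-patterned — the planted counts are
#' therefore exact, not merely expected). MSAP loci are generated as types
#' first — panel-uniform, clade-private, or independently drawn from
#' per-clade type proportions — and then emitted as the (HpaII, MspI)
#' digest pair through the inverse of the type-classification rule, which
#' guarantees round-trip consistency. The outgroup draws independent
#' states everywhere it is not fixed, making the ingroup monophyletic.
#'
#' @param cfg a [panel_config()].
#' @param seed integer seed; the generator is a pure function of
#'   (\code{cfg}, \code{seed}).
#' @return List with \code{aflp}, \code{hpa}, \code{msp} (band matrices)
#'   and \code{truth}, a list recording the clade partition, the planted
#'   locus ids per class and the per-clade type proportions.
#' @export
simulate_marker_panel <- function(cfg = panel_config(), seed = 42) {
  set.seed(seed)
  a_ids <- paste0("A", seq_len(cfg$n_clade_a))
  b_ids <- paste0("B", seq_len(cfg$n_clade_b))
  ingroup <- c(a_ids, b_ids)
  samples <- c(ingroup, cfg$outgroup_label)
  ns <- length(samples)
  out_row <- ns

  ## ---- AFLP ----
  n_var <- round(cfg$n_loci_aflp * cfg$frac_polymorphic)
  n_mono <- cfg$n_loci_aflp - n_var
  n_noise <- n_var - cfg$aflp_private_a - cfg$aflp_private_b
  aflp <- matrix(0L, ns, cfg$n_loci_aflp,
                 dimnames = list(samples,
                                 paste0("AF", seq_len(cfg$n_loci_aflp))))
  idx_mono <- seq_len(n_mono)
  idx_da <- seq_len(cfg$aflp_private_a) + n_mono
  idx_db <- seq_len(cfg$aflp_private_b) + n_mono + cfg$aflp_private_a
  idx_noise <- seq_len(n_noise) + n_mono + cfg$aflp_private_a +
    cfg$aflp_private_b
  aflp[, idx_mono] <- 1L
  aflp[a_ids, idx_da] <- 1L
  aflp[b_ids, idx_db] <- 1L
  for (j in idx_noise) {
    repeat {
      v <- stats::rbinom(length(ingroup), 1, cfg$noise_presence)
      all_a <- all(v[seq_along(a_ids)] == 1)
      none_a <- all(v[seq_along(a_ids)] == 0)
      all_b <- all(v[-seq_along(a_ids)] == 1)
      none_b <- all(v[-seq_along(a_ids)] == 0)
      variable <- !(all_a && all_b) && !(none_a && none_b)
      diagnostic <- (all_a && none_b) || (none_a && all_b)
      if (variable && !diagnostic) break
    }
    aflp[ingroup, j] <- v
  }
  aflp[out_row, c(idx_da, idx_db, idx_noise)] <-
    stats::rbinom(n_var, 1, cfg$outgroup_presence)

  ## ---- MSAP: draw a type per (sample, locus), then emit digest pairs ----
  types <- c("I", "II", "III", "IV")
  n_planted <- sum(cfg$msap_shared) + sum(cfg$msap_private_a) +
    sum(cfg$msap_private_b)
  n_free <- cfg$n_loci_msap - n_planted
  ty <- matrix(NA_character_, ns, cfg$n_loci_msap,
               dimnames = list(samples,
                               paste0("MS", seq_len(cfg$n_loci_msap))))
  j <- 0
  shared_idx <- list(); private_a_idx <- list(); private_b_idx <- list()
  for (k in names(cfg$msap_shared)) {
    idx <- j + seq_len(cfg$msap_shared[[k]]); j <- j + cfg$msap_shared[[k]]
    ty[ingroup, idx] <- k
    shared_idx[[k]] <- idx
  }
  for (k in names(cfg$msap_private_a)) {
    idx <- j + seq_len(cfg$msap_private_a[[k]])
    j <- j + cfg$msap_private_a[[k]]
    ty[a_ids, idx] <- k; ty[b_ids, idx] <- "IV"
    private_a_idx[[k]] <- idx
  }
  for (k in names(cfg$msap_private_b)) {
    idx <- j + seq_len(cfg$msap_private_b[[k]])
    j <- j + cfg$msap_private_b[[k]]
    ty[b_ids, idx] <- k; ty[a_ids, idx] <- "IV"
    private_b_idx[[k]] <- idx
  }
  free_idx <- j + seq_len(n_free)
  for (jj in free_idx) {
    repeat {
      va <- sample(types, length(a_ids), replace = TRUE,
                   prob = cfg$msap_probs_a)
      vb <- sample(types, length(b_ids), replace = TRUE,
                   prob = cfg$msap_probs_b)
      v <- c(va, vb)
      uniform <- length(unique(v)) == 1
      # a free locus must not mimic a planted class: uniform type across
      # the ingroup, or any type fixed in one clade and absent from the
      # other, would inflate the planted shared/private counts
      priv <- function(x, y, k) all(x == k) && !any(y == k)
      chance_private <- any(vapply(types, function(k)
        priv(va, vb, k) || priv(vb, va, k), logical(1)))
      if (!uniform && !chance_private) break
    }
    ty[ingroup, jj] <- v
  }
  # outgroup: independent types everywhere, uniform over the four classes
  ty[out_row, ] <- sample(types, cfg$n_loci_msap, replace = TRUE)

  pair_h <- matrix(0L, ns, cfg$n_loci_msap, dimnames = dimnames(ty))
  pair_m <- pair_h
  for (k in types) {
    p <- msap_type_pair(k)
    sel <- ty == k
    pair_h[sel] <- p[1]
    pair_m[sel] <- p[2]
  }

  truth <- list(
    clade_a = a_ids, clade_b = b_ids, outgroup = cfg$outgroup_label,
    aflp_monomorphic = colnames(aflp)[idx_mono],
    aflp_private_a = colnames(aflp)[idx_da],
    aflp_private_b = colnames(aflp)[idx_db],
    msap_shared = lapply(shared_idx, function(i) colnames(ty)[i]),
    msap_private_a = lapply(private_a_idx, function(i) colnames(ty)[i]),
    msap_private_b = lapply(private_b_idx, function(i) colnames(ty)[i]),
    msap_types = ty,
    msap_probs_a = cfg$msap_probs_a, msap_probs_b = cfg$msap_probs_b)

  list(aflp = band_matrix(aflp, marker_system = "AFLP"),
       hpa = band_matrix(pair_h, marker_system = "MSAP_HPAII"),
       msp = band_matrix(pair_m, marker_system = "MSAP_MSPI"),
       truth = truth)
}

#' Restrict a band matrix to a subset of samples
#'
#' @param m a \code{band_matrix}.
#' @param samples sample labels to keep, in the requested order.
#' @export
subset_samples <- function(m, samples) {
  if (!all(samples %in% sample_ids(m)))
    stop("unknown sample(s): ",
         paste(setdiff(samples, sample_ids(m)), collapse = ", "))
  band_matrix(m$values[samples, , drop = FALSE],
              marker_system = m$marker_system, primer_combo = m$primer_combo)
}

#' Simulate binary characters with planted parsimony step counts
#'
#' Plants characters of known minimal step count on a fixed tree:
#' synapomorphic characters place the derived state on one randomly chosen
#' proper ingroup clade (1 step), autapomorphic characters on one random
#' ingroup leaf (1 step), homoplastic characters on two random ingroup
#' leaves that do not form a two-leaf clade (2 steps). The outgroup always
#' carries the ancestral state 0.
#'
#' @param t an ape \code{phylo} tree with >= 4 leaves, containing
#'   \code{outgroup}.
#' @param n_synapomorphic,n_autapomorphic,n_homoplastic character counts
#'   per class.
#' @param outgroup outgroup leaf label (state 0 on every character).
#' @param seed integer seed.
#' @return List with \code{chars} (taxa x characters 0/1 matrix) and
#'   \code{truth} (data frame of per-character class and true minimal
#'   steps).
#' @export
simulate_characters <- function(t, n_synapomorphic, n_autapomorphic,
                                n_homoplastic, outgroup, seed = 42) {
  if (length(t$tip.label) < 4) stop("tree must have at least 4 leaves")
  set.seed(seed)
  rt <- root_with_outgroup(t, outgroup)
  tips <- rt$tip.label
  ingroup <- setdiff(tips, outgroup)
  n <- length(tips)
  # proper ingroup clades: >= 2 leaves, not the whole ingroup
  clades <- ape::prop.part(rt)
  clade_sets <- lapply(clades, function(i) tips[i])
  clade_sets <- Filter(function(s) {
    length(s) >= 2 && length(s) < length(ingroup) && !(outgroup %in% s)
  }, clade_sets)
  if (n_synapomorphic > 0 && !length(clade_sets))
    stop("tree has no proper ingroup clade to plant a synapomorphy on")
  cherries <- Filter(function(s) length(s) == 2, clade_sets)
  is_cherry <- function(pair) any(vapply(cherries, setequal, logical(1),
                                         y = pair))
  n_char <- n_synapomorphic + n_autapomorphic + n_homoplastic
  chars <- matrix(0L, n, n_char,
                  dimnames = list(tips, paste0("C", seq_len(n_char))))
  cls <- character(n_char); true_steps <- integer(n_char)
  j <- 0
  for (i in seq_len(n_synapomorphic)) {
    j <- j + 1
    s <- clade_sets[[sample.int(length(clade_sets), 1)]]
    chars[s, j] <- 1L
    cls[j] <- "synapomorphy"; true_steps[j] <- 1L
  }
  for (i in seq_len(n_autapomorphic)) {
    j <- j + 1
    chars[sample(ingroup, 1), j] <- 1L
    cls[j] <- "autapomorphy"; true_steps[j] <- 1L
  }
  for (i in seq_len(n_homoplastic)) {
    j <- j + 1
    repeat {
      pair <- sample(ingroup, 2)
      if (!is_cherry(pair)) break
    }
    chars[pair, j] <- 1L
    cls[j] <- "homoplastic"; true_steps[j] <- 2L
  }
  list(chars = chars,
       truth = data.frame(character = colnames(chars), class = cls,
                          true_steps = true_steps,
                          stringsAsFactors = FALSE))
}

#' Simulate a two-peak flow-cytometry histogram
#'
#' Places the sample and internal-standard peaks on a common channel scale
#' (the standard sits at \code{standard_channel}; the sample center is
#' proportional to \code{true_2c / standard_2c}), draws \code{n_events}
#' Gaussian fluorescence values per peak with relative width \code{cv},
#' and bins them onto an integer channel axis — event-sampling noise
#' therefore enters the per-channel counts naturally. Peaks whose centers
#' lie closer than four combined standard deviations are flagged with a
#' warning, since downstream peak finding cannot separate them reliably.
#'
#' @param true_2c true sample 2C value in pg.
#' @param standard_2c 2C of the internal standard in pg.
#' @param cv coefficient of variation of each peak (> 0).
#' @param n_events Gaussian events drawn per peak (>= 100).
#' @param seed integer seed.
#' @param n_channels channels on the axis (default 1024).
#' @param standard_channel center channel of the standard peak.
#' @return A \code{fluor_histogram} with attribute \code{"true_peaks"} =
#'   c(sample, standard) center channels.
#' @export
simulate_histogram <- function(true_2c, standard_2c = 9.09, cv = 0.03,
                               n_events = 10000, seed = 42,
                               n_channels = 1024, standard_channel = 300) {
  if (cv <= 0) stop("'cv' must be positive")
  if (n_events < 100) stop("need at least 100 events per peak")
  set.seed(seed)
  c_std <- standard_channel
  c_smp <- standard_channel * true_2c / standard_2c
  if (abs(c_std - c_smp) < 4 * (cv * c_std + cv * c_smp))
    warning("sample and standard peaks overlap; separation < 4 combined SD")
  ev <- c(stats::rnorm(n_events, c_smp, cv * c_smp),
          stats::rnorm(n_events, c_std, cv * c_std))
  ev <- pmin(pmax(round(ev), 1), n_channels)
  h <- fluor_histogram(seq_len(n_channels), tabulate(ev, n_channels))
  attr(h, "true_peaks") <- c(sample = c_smp, standard = c_std)
  h
}
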