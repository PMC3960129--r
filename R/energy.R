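# Scoring proteins with potential sets: per-residue-normalized folding
# free-energy terms at each dataset temperature, and the meso-thermo
# difference features used by the melting-temperature predictor.

#' Score one protein with a potential set
#'
#' Each of the four energy terms is the sum, over the protein's own
#' motif occurrences (counted with the same window / minimum-separation
#' parameters as the potentials), of the corresponding table entry,
#' divided by the residue count N. Energies are in kT units per residue.
#'
#' @param desc a [protein_descriptor].
#' @param pset a `potential_set`.
#' @param counts optional precomputed list of the protein's own
#'   `count_table`s (named by kind), e.g. after leave-one-out
#'   subtraction bookkeeping; counted from `desc` when absent.
#' @return object of class `energy_vector`: `protein_id`, `t_set`,
#'   and `terms`, a named numeric vector `(tor1, tor2, dist1, dist2)`.
#' @export
score_protein <- function(desc, pset, counts = NULL) {
  stopifnot(inherits(desc, "protein_descriptor"),
            inherits(pset, "potential_set"))
  if (desc$n < 1) stop("score_protein: empty descriptor")
  terms <- stats::setNames(numeric(4), POTENTIAL_KINDS)
  for (kind in POTENTIAL_KINDS) {
    ct <- if (!is.null(counts)) counts[[kind]] else
      count_motifs(desc, kind, window = pset$window, min_sep = pset$min_sep,
                   binning = pset$binning, domain_labels = pset$domain_labels,
                   tor2_domain = pset$tor2_domain)
    terms[kind] <- sum(ct$counts * pset[[kind]]$values) / desc$n
  }
  structure(list(protein_id = desc$id, t_set = pset$t_set, terms = terms),
            class = "energy_vector")
}

#' Folding free-energy features at the three dataset temperatures
#'
#' Scores the protein with the mesostable-, thermostable-, and
#' average-derived potential sets and appends the difference features
#' (meso term minus thermo term) used by the difference-based predictor.
#'
#' @param desc a [protein_descriptor].
#' @param psets named list with elements `meso`, `thermo`, `avg`, each a
#'   `potential_set`.
#' @param counts optional precomputed [protein_counts] of `desc`,
#'   shared across the three potential sets.
#' @return named numeric vector of 16 features:
#'   `<kind>_meso`, `<kind>_thermo`, `<kind>_avg`, `d_<kind>`.
#' @export
energy_features <- function(desc, psets, counts = NULL) {
  stopifnot(all(c("meso", "thermo", "avg") %in% names(psets)))
  if (is.null(counts)) {
    p <- psets$meso
    counts <- protein_counts(desc, window = p$window, min_sep = p$min_sep,
                             binning = p$binning,
                             domain_labels = p$domain_labels,
                             tor2_domain = p$tor2_domain)
  }
  ev <- lapply(psets[c("meso", "thermo", "avg")],
               function(p) score_protein(desc, p, counts = counts)$terms)
  out <- c(stats::setNames(ev$meso, paste0(POTENTIAL_KINDS, "_meso")),
           stats::setNames(ev$thermo, paste0(POTENTIAL_KINDS, "_thermo")),
           stats::setNames(ev$avg, paste0(POTENTIAL_KINDS, "_avg")),
           stats::setNames(ev$meso - ev$thermo,
                           paste0("d_", POTENTIAL_KINDS)))
  out
}

#' Feature matrix for a set of proteins
#'
#' @param descriptors list of [protein_descriptor] objects.
#' @param psets as in [energy_features].
#' @param counts_by_id optional named list of precomputed
#'   [protein_counts], keyed by descriptor id.
#' @return data.frame: one row per protein (`id` column + 16 features).
#' @export
feature_matrix <- function(descriptors, psets, counts_by_id = NULL) {
  rows <- lapply(descriptors, function(d)
    energy_features(d, psets, counts = counts_by_id[[d$id]]))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(id = vapply(descriptors, `[[`, "", "id"), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the predictor features of one mode
#'
#' `deltaG_A`: the four terms scored with the average-temperature
#' potentials (thermodynamic-stability route). `deltaDeltaG`: the four
#' meso-minus-thermo difference terms (temperature-dependent route).
#'
#' @param features data.frame from [feature_matrix].
#' @param mode `"deltaG_A"` or `"deltaDeltaG"`.
#' @return numeric matrix (n x 4) with protein ids as rownames.
#' @export
mode_features <- function(features, mode = c("deltaDeltaG", "deltaG_A")) {
  mode <- match.arg(mode)
  cols <- if (mode == "deltaG_A") paste0(POTENTIAL_KINDS, "_avg")
          else paste0("d_", POTENTIAL_KINDS)
  m <- as.matrix(features[, cols])
  rownames(m) <- features$id
  m
}
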