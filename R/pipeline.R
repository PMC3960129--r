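# End-to-end workflow: metadata + structures -> Tm estimation by the
# three rules -> meso/thermo/average dataset triple per rule ->
# averaged temperature-dependent potentials -> energy features ->
# fitted / cross-validated melting-temperature predictions.

derive_triple_psets <- function(counts_by_id, triples, params,
                                exclude_id = NULL) {
  t_of <- function(role) {
    mean(vapply(triples, function(tr)
      mean(tr[[role]]$tm[!tr[[role]]$id %in% exclude_id]), 0.0))
  }
  mk <- function(role) {
    count_sets <- lapply(triples, function(tr) {
      ids <- setdiff(tr[[role]]$id, exclude_id)
      lapply(stats::setNames(POTENTIAL_KINDS, POTENTIAL_KINDS),
             function(kind) {
               if (length(ids) == 0) {
                 # a held-out protein can empty a 1-member subset; an
                 # empty counting set carries no information and yields
                 # the zero potential
                 z <- counts_by_id[[1]][[kind]]
                 z$counts[] <- 0
                 z$n_total <- 0
                 z
               } else {
                 sum_count_tables(lapply(counts_by_id[ids], `[[`, kind))
               }
             })
    })
    derive_potential_set_counts(count_sets, t_set = t_of(role),
                                sigmas = params$sigmas, lam = params$lam)
  }
  list(meso = mk("meso"), thermo = mk("thermo"), avg = mk("average"))
}

#' Run the full melting-temperature prediction workflow
#'
#' Starting from protein records (metadata + sequences) and structures,
#' the pipeline (i) fills in estimated Tm values for unmeasured proteins
#' with each requested estimation rule, (ii) splits and culls each
#' rule's record set into mesostable / thermostable / average subsets,
#' (iii) derives the four averaged statistical potentials of each subset
#' (rules x shrinkage strengths variants averaged cell-wise), (iv)
#' scores the measured-Tm proteins to obtain energy features, and (v)
#' fits and jack-knife cross-validates the linear Tm predictor in the
#' requested modes.
#'
#' @param records protein record data.frame (see [read_protein_table]);
#'   `sequence` must be present.
#' @param chains optional named list of [chain_structure] objects (names
#'   = record ids); read from `records$structure_path` when absent.
#' @param methods Tm-estimation rules to use (each contributes its own
#'   dataset variant to the potential averaging).
#' @param identity_cutoff culling cutoff, see [split_and_cull].
#' @param sigmas,lam,window,min_sep,domain_table,binning,tor2_domain
#'   potential-derivation parameters, see [derive_potential_set].
#' @param modes predictor modes to fit.
#' @param strict if `TRUE`, the jack-knife re-derives the potentials and
#'   features without the held-out protein in every fold (slow); the
#'   default re-identifies the regression coefficients only.
#' @param exclude_worst if > 0, additionally run the iterative
#'   worst-predicted exclusion with this k.
#' @return object of class `tm_report`: `records` (with estimation
#'   variants), `triples` (per rule), `psets` (meso/thermo/avg),
#'   `features` (data.frame), and `fits` — per mode, a list with
#'   `direct` ([fit_tm]), `jackknife` ([jackknife_tm]) and optionally
#'   `worst_k` ([worst_k_exclusion]).
#' @export
tm_pipeline <- function(records, chains = NULL,
                        methods = c("est_global_regression",
                                    "est_family_regression",
                                    "est_seq_identity"),
                        identity_cutoff = 0.25,
                        sigmas = c(10, 50), lam = 0.5,
                        window = 8, min_sep = 2,
                        domain_table = default_domain_table(),
                        binning = distance_binning(),
                        tor2_domain = "first",
                        modes = c("deltaDeltaG", "deltaG_A"),
                        strict = FALSE, exclude_worst = 0) {
  if (is.null(chains)) {
    chains <- lapply(stats::setNames(records$structure_path, records$id),
                     read_chain, quiet = TRUE)
  }
  desc_by_id <- lapply(stats::setNames(names(chains), names(chains)),
                       function(id) protein_descriptor(
                         chains[[id]], domain_table, id = id))
  idm <- identity_matrix(stats::setNames(records$sequence, records$id))

  triples <- list()
  for (m in methods) {
    est <- estimate_tm_all(records, m, idm = idm)
    triples[[m]] <- split_and_cull(est, identity_cutoff, idm = idm)
  }
  params <- list(sigmas = sigmas, lam = lam, window = window,
                 min_sep = min_sep, binning = binning,
                 domain_labels = domain_table$labels,
                 tor2_domain = tor2_domain)
  counts_by_id <- lapply(desc_by_id, protein_counts, window = window,
                         min_sep = min_sep, binning = binning,
                         domain_labels = domain_table$labels,
                         tor2_domain = tor2_domain)
  psets <- derive_triple_psets(counts_by_id, triples, params)

  targets <- records[records$tm_source %in% "measured", , drop = FALSE]
  feats <- feature_matrix(desc_by_id[targets$id], psets,
                          counts_by_id = counts_by_id)

  fits <- list()
  for (mode in modes) {
    x <- mode_features(feats, mode)
    refit <- NULL
    if (strict) {
      refit <- function(held_id) {
        ps <- derive_triple_psets(counts_by_id, triples, params,
                                  exclude_id = held_id)
        mode_features(feature_matrix(desc_by_id[targets$id], ps,
                                     counts_by_id = counts_by_id), mode)
      }
    }
    direct <- fit_tm(x, targets$tm, mode, ids = targets$id,
                     families = targets$family)
    jk <- jackknife_tm(x, targets$tm, mode, ids = targets$id,
                       families = targets$family, refit_features = refit)
    fits[[mode]] <- list(direct = direct, jackknife = jk)
    if (exclude_worst > 0) {
      fits[[mode]]$worst_k <- worst_k_exclusion(
        x, targets$tm, mode, k = exclude_worst,
        ids = targets$id, families = targets$family)
    }
  }
  structure(list(records = records, triples = triples, psets = psets,
                 features = feats, fits = fits,
                 params = c(params, list(identity_cutoff = identity_cutoff,
                                         methods = methods,
                                         strict = strict,
                                         exclude_worst = exclude_worst))),
            class = "tm_report")
}

#' @export
print.tm_report <- function(x, ...) {
  cat(sprintf("tm_report: %d proteins (%d with measured Tm)\n",
              nrow(x$records), nrow(x$features)))
  for (mode in names(x$fits)) {
    f <- x$fits[[mode]]
    cat(sprintf("  %-12s direct: sigma %6.2f C, r %5.2f | jack-knife: sigma %6.2f C, r %5.2f\n",
                mode, f$direct$sigma, f$direct$r,
                f$jackknife$sigma, f$jackknife$r))
    if (!is.null(f$worst_k)) {
      cat(sprintf("  %-12s after excluding %d worst: sigma %6.2f C, r %5.2f\n",
                  "", length(f$worst_k$excluded), f$worst_k$fit$sigma,
                  f$worst_k$fit$r))
    }
  }
  invisible(x)
}
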