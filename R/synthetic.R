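# Synthetic homologous-family generator. Produces self-contained toy
# inputs (PDB structures, FASTA sequences, metadata TSV) in the exact
# schema of real inputs, with planted statistical structure:
#  - melting temperatures drawn in a configured range, with the host
#    environmental temperature derived by inverting a linear Tm-Tenv
#    model plus noise;
#  - sequences mutated from a family ancestor along an identity ladder
#    so redundancy culling has pairs above and below the cutoff;
#  - side-chain contacts whose counts in configured (amino-acid pair,
#    distance-bin) cells scale linearly with Tm, realized exactly by
#    placing side-chain centers at prescribed distances on an idealized
#    backbone.
# Geometry is deliberately non-physical beyond the backbone: only the
# binned side-chain-center distances are guaranteed, since those are all
# the downstream statistics consume.

#' Configuration of the synthetic family generator
#'
#' @param n_families number of homologous families.
#' @param proteins_per_family proteins per family.
#' @param residues_per_protein chain length.
#' @param planted_pairs data.frame with columns `aa1`, `aa2` (one-letter
#'   codes, not glycine), `d_lo`, `d_hi` (Angstrom range whose bins the
#'   contacts land in), `base` (contacts per protein at the Tm midpoint)
#'   and `slope` (contacts per degree C). The default plants a
#'   salt-bridge-like D-R enrichment that grows with Tm and a
#'   hydrophobic L-I contact that shrinks with Tm at the same rate, so
#'   the total contact count carries no overall-stability signal.
#' @param tm_range range (degrees C) of the uniformly drawn true Tm.
#' @param tenv_model list `slope`, `intercept`, `noise` (degrees C):
#'   Tenv is obtained by inverting `Tm = slope * Tenv + intercept` and
#'   adding Gaussian noise.
#' @param tm_noise measurement noise (SD, degrees C) added to reported
#'   measured Tm values.
#' @param measured_fraction fraction of proteins with a measured Tm
#'   (at least 3 per family, so every estimation rule has context).
#' @param mutation_rates per-protein substitution rates from the family
#'   ancestor (recycled); the default ladder spans pairs above and below
#'   a 25% identity cutoff.
#' @param helix_fraction fraction of residues built with helical
#'   torsion angles (the rest are extended).
#' @param min_sep minimum sequence separation of planted contact pairs.
#' @param seed mandatory RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_families = 2,
                             proteins_per_family = 14,
                             residues_per_protein = 60,
                             planted_pairs = data.frame(
                               aa1 = c("D", "L"), aa2 = c("R", "I"),
                               d_lo = c(3.8, 3.8), d_hi = c(4.2, 4.2),
                               base = c(5, 5), slope = c(0.1, -0.1),
                               stringsAsFactors = FALSE),
                             tm_range = c(35, 95),
                             tenv_model = list(slope = 0.9, intercept = 15,
                                               noise = 4),
                             tm_noise = 0,
                             measured_fraction = 0.6,
                             mutation_rates = NULL,
                             helix_fraction = 0.4,
                             min_sep = 2,
                             seed) {
  if (missing(seed)) stop("generator_config: seed is mandatory")
  if (is.null(mutation_rates)) {
    # two close homologs exercise the culling paths (pairs above the
    # 25% cutoff); the remaining rungs are distant enough to survive
    mutation_rates <- if (proteins_per_family >= 3) {
      c(0.2, 0.35, seq(0.6, 0.95,
                       length.out = proteins_per_family - 2))
    } else {
      seq(0.2, 0.95, length.out = proteins_per_family)
    }
  }
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0 &&
      any(planted_pairs$aa1 == "G" | planted_pairs$aa2 == "G")) {
    stop("generator_config: planted pairs may not involve glycine ",
         "(its side-chain center is tied to CA)")
  }
  stopifnot(n_families >= 1, proteins_per_family >= 1,
            residues_per_protein >= 1, tm_noise >= 0,
            tenv_model$noise >= 0)
  structure(list(n_families = n_families,
                 proteins_per_family = proteins_per_family,
                 residues_per_protein = residues_per_protein,
                 planted_pairs = planted_pairs, tm_range = tm_range,
                 tenv_model = tenv_model, tm_noise = tm_noise,
                 measured_fraction = measured_fraction,
                 mutation_rates = mutation_rates,
                 helix_fraction = helix_fraction,
                 min_sep = min_sep, seed = seed),
            class = "generator_config")
}

mutate_sequence <- function(anc, rate) {
  n <- length(anc)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(anc)
  pos <- sample.int(n, k)
  for (p in pos) {
    anc[p] <- sample(setdiff(AA1, anc[p]), 1)
  }
  anc
}

# Build one protein. The backbone is an idealized helix+strand ribbon
# that carries the torsion statistics. Tertiary geometry is decoupled
# from it: side-chain centers are drawn as a compact random cloud at
# protein-like density (about 134 cubic Angstrom per residue), which
# gives the distance bins a realistic, Tm-independent background mass;
# planted contacts then override the two members' centers to an exact
# prescribed distance. Only binned center-center distances feed the
# statistics downstream, so no packing realism is attempted.
build_protein_chain <- function(seq, helix_fraction, contacts, id) {
  n <- length(seq)
  n_hel <- round(helix_fraction * n)
  phi <- c(rep(-57, n_hel), rep(-139, n - n_hel)) + stats::runif(n, -6, 6)
  psi <- c(rep(-47, n_hel), rep(135, n - n_hel)) + stats::runif(n, -6, 6)
  bb <- build_backbone(phi, psi)
  radius <- 3.2 * n^(1 / 3)
  sc <- vector("list", n)
  for (i in seq_len(n)) {
    if (seq[i] != "G") {
      repeat {
        pt <- stats::runif(3, -radius, radius)
        if (sum(pt^2) <= radius^2) break
      }
      sc[[i]] <- pt
    }
  }
  if (nrow(contacts) > 0) {
    for (r in seq_len(nrow(contacts))) {
      i <- contacts$i[r]; j <- contacts$j[r]; d <- contacts$d[r]
      mid <- (sc[[i]] + sc[[j]]) / 2
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      sc[[i]] <- mid - u * d / 2
      sc[[j]] <- mid + u * d / 2
    }
  }
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    sidechain <- if (is.null(sc[[i]])) matrix(numeric(0), ncol = 3)
                 else matrix(sc[[i]], ncol = 3)
    residues[[i]] <- residue_atoms(seq[i], bb[[i]], sidechain)
  }
  chain_structure("A", residues, source_id = id)
}

write_chain_pdb <- function(chain, path) {
  xyz <- NULL; resno <- integer(0); resid <- character(0)
  elety <- character(0)
  for (i in seq_along(chain$residues)) {
    r <- chain$residues[[i]]
    for (nm in c("N", "CA", "C")) {
      xyz <- c(xyz, r$backbone[[nm]])
      resno <- c(resno, i); resid <- c(resid, AA3[[r$aa]])
      elety <- c(elety, nm)
    }
    if (nrow(r$sidechain) > 0) {
      for (k in seq_len(nrow(r$sidechain))) {
        xyz <- c(xyz, r$sidechain[k, ])
        resno <- c(resno, i); resid <- c(resid, AA3[[r$aa]])
        elety <- c(elety, "CB")
      }
    }
  }
  bio3d::write.pdb(file = path, xyz = round(xyz, 3), resno = resno,
                   chain = rep(chain$chain_id, length(resno)),
                   resid = resid, elety = elety,
                   o = rep(1, length(resno)), b = rep(0, length(resno)))
  invisible(path)
}

#' Generate synthetic homologous families
#'
#' Draws, for every protein, a true melting temperature, a host
#' environmental temperature consistent with the configured linear
#' Tm-Tenv model, a sequence mutated from the family ancestor, and an
#' idealized structure whose planted contact counts scale linearly with
#' Tm (see [generator_config]). A single seeded RNG stream drives the
#' whole run, so identical configurations reproduce identical output
#' byte for byte.
#'
#' @param config a [generator_config].
#' @param out_dir optional directory; when given, writes
#'   `proteins.tsv`, `sequences.fasta` and `pdb/<id>.pdb` files.
#' @return object of class `synthetic_families`: `records` (protein
#'   metadata data.frame incl. `tm_true`), `chains` (named list of
#'   [chain_structure]), `contacts` (named list of planted-contact
#'   data.frames with columns `i`, `j`, `d`, `pair`), `config`.
#' @export
generate_family <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  L <- config$residues_per_protein
  pp <- config$planted_pairs
  tm_mid <- mean(config$tm_range)
  recs <- list(); chains <- list(); contacts <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%d", f)
    anc <- sample(AA1, L, replace = TRUE)
    m <- config$proteins_per_family
    n_meas <- max(min(3, m), round(config$measured_fraction * m))
    meas_idx <- sample.int(m, n_meas)
    rates <- rep_len(config$mutation_rates, m)
    for (k in seq_len(m)) {
      id <- sprintf("%s_P%02d", fam, k)
      tm_true <- stats::runif(1, config$tm_range[1], config$tm_range[2])
      tenv <- (tm_true - config$tenv_model$intercept) /
        config$tenv_model$slope +
        stats::rnorm(1, 0, config$tenv_model$noise)
      seq <- mutate_sequence(anc, rates[k])
      # Planted contacts. Every protein carries the same number of
      # capacity slots per pair (composition held fixed so the
      # amino-acid background does not itself track Tm); only the
      # number of slots realized as short-range contacts scales with
      # the true Tm. Unrealized slots keep their default side-chain
      # placement and land in the background bins.
      con <- data.frame(i = integer(0), j = integer(0), d = numeric(0),
                        pair = character(0), stringsAsFactors = FALSE)
      if (!is.null(pp) && nrow(pp) > 0) {
        used <- logical(L)
        for (p in seq_len(nrow(pp))) {
          cap <- max(0, round(pp$base[p] + pp$slope[p] *
                                (config$tm_range - tm_mid)))
          n_con <- min(cap, max(0, round(pp$base[p] + pp$slope[p] *
                                           (tm_true - tm_mid))))
          for (cc in seq_len(cap)) {
            free <- which(!used)
            cand_i <- free[free + config$min_sep <= L]
            cand_i <- cand_i[vapply(cand_i, function(i)
              any(!used[(i + config$min_sep):L]), TRUE)]
            if (length(cand_i) == 0) {
              stop("generate_family: chain too short for requested contacts")
            }
            i <- if (length(cand_i) == 1) cand_i else sample(cand_i, 1)
            cand_j <- which(!used & seq_len(L) >= i + config$min_sep)
            j <- if (length(cand_j) == 1) cand_j else sample(cand_j, 1)
            used[c(i, j)] <- TRUE
            seq[i] <- pp$aa1[p]; seq[j] <- pp$aa2[p]
            if (cc <= n_con) {
              d <- stats::runif(1, pp$d_lo[p] + 0.01, pp$d_hi[p] - 0.01)
              con <- rbind(con, data.frame(
                i = i, j = j, d = d,
                pair = paste0(min(pp$aa1[p], pp$aa2[p]),
                              max(pp$aa1[p], pp$aa2[p])),
                stringsAsFactors = FALSE))
            }
          }
        }
      }
      chain <- build_protein_chain(seq, config$helix_fraction, con, id)
      measured <- k %in% meas_idx
      recs[[id]] <- data.frame(
        id = id, family = fam,
        tm = if (measured) tm_true + stats::rnorm(1, 0, config$tm_noise)
             else NA_real_,
        tenv = tenv,
        tm_source = if (measured) "measured" else NA_character_,
        sequence = paste(seq, collapse = ""),
        structure_path = file.path("pdb", paste0(id, ".pdb")),
        tm_true = tm_true, stringsAsFactors = FALSE)
      chains[[id]] <- chain
      contacts[[id]] <- con
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  out <- structure(list(records = records, chains = chains,
                        contacts = contacts, config = config),
                   class = "synthetic_families")
  if (!is.null(out_dir)) write_synthetic_families(out, out_dir)
  out
}

#' Write a synthetic family set to disk
#'
#' @param x a `synthetic_families` object.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_families <- function(x, out_dir) {
  dir.create(file.path(out_dir, "pdb"), recursive = TRUE,
             showWarnings = FALSE)
  tab <- data.frame(id = x$records$id, family = x$records$family,
                    tm_measured = x$records$tm, tenv = x$records$tenv,
                    structure_path = x$records$structure_path,
                    tm_true = x$records$tm_true,
                    seed = x$config$seed, stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(out_dir, "proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::AAStringSet(stats::setNames(x$records$sequence,
                                                  x$records$id))
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "sequences.fasta"))
  for (id in names(x$chains)) {
    write_chain_pdb(x$chains[[id]],
                    file.path(out_dir, "pdb", paste0(id, ".pdb")))
  }
  invisible(out_dir)
}

#' Feature-level synthetic benchmark
#'
#' Draws standard-normal feature 4-vectors and melting temperatures from
#' the planted linear model `Tm = intercept + features %*% beta + eps`,
#' `eps ~ N(0, tau)`. Used for predictor calibration tests, where the
#' structural pipeline is not needed.
#'
#' @param n number of proteins.
#' @param beta length-4 coefficient vector (degrees C per feature unit).
#' @param intercept intercept (degrees C).
#' @param tau noise SD (degrees C).
#' @param n_families number of family labels to assign cyclically.
#' @param seed RNG seed.
#' @return list with `x` (n x 4 matrix), `tm`, `ids`, `families`,
#'   `beta`, `intercept`, `tau`.
#' @export
simulate_tm_features <- function(n = 60, beta = c(-8, 4, -6, 3),
                                 intercept = 60, tau = 5,
                                 n_families = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(sprintf("P%03d", seq_len(n)),
                              paste0("f", 1:4)))
  tm <- intercept + as.numeric(x %*% beta) + stats::rnorm(n, 0, tau)
  list(x = x, tm = tm, ids = rownames(x),
       families = sprintf("F%d", (seq_len(n) - 1) %% n_families + 1),
       beta = beta, intercept = intercept, tau = tau)
}
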