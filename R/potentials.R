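# Knowledge-based statistical potentials. Occurrences of
# (sequence motif, structure motif) pairs are counted over a dataset of
# protein descriptors; distance counts are smoothed over neighboring
# bins; frequencies are Boltzmann-inverted into effective energies with
# a sparse-data shrinkage correction; and the variants obtained with
# different Tm-estimation rules and shrinkage strengths are averaged.
#
# Four potential kinds:
#   tor1  - (amino acid a_i, signed offset k) vs torsion domain t_{i+k}
#   tor2  - ordered amino-acid pair (a_i, a_j), 1 <= j - i <= window,
#           vs the torsion domain of one of the two residues
#   dist1 - single amino acid vs binned side-chain-center distance
#   dist2 - unordered amino-acid pair vs binned distance

POTENTIAL_KINDS <- c("tor1", "tor2", "dist1", "dist2")

motif_levels <- function(kind, window) {
  switch(kind,
         tor1 = as.vector(outer(AA1, -window:window,
                                function(a, k) paste0(a, "@", k))),
         tor2 = as.vector(outer(AA1, AA1, paste0)),
         dist1 = AA1,
         dist2 = unlist(lapply(seq_along(AA1), function(i)
           paste0(AA1[i], AA1[i:length(AA1)]))))
}

struct_levels <- function(kind, binning, domain_labels) {
  if (kind %in% c("tor1", "tor2")) domain_labels
  else as.character(seq_len(binning$n_bins))
}

new_count_table <- function(kind, counts, window, min_sep, binning,
                            domain_labels, tor2_domain) {
  structure(list(kind = kind, counts = counts, n_total = sum(counts),
                 window = window, min_sep = min_sep, binning = binning,
                 domain_labels = domain_labels, tor2_domain = tor2_domain),
            class = "count_table")
}

#' Construct a count table from a raw count matrix
#'
#' Wraps an arbitrary non-negative motif-by-structure count matrix in
#' the container consumed by [smooth_distance_counts] and
#' [boltzmann_potential]. Mainly useful for toy tables and checks; the
#' standard constructor is [count_motifs].
#'
#' @param kind one of the four potential kinds.
#' @param counts non-negative numeric matrix (sequence motifs in rows,
#'   structure motifs in columns).
#' @param window,min_sep,binning,domain_labels,tor2_domain counting
#'   metadata carried along (see [count_motifs]); `binning` must match
#'   the column count for distance kinds.
#' @return a `count_table`.
#' @export
count_table <- function(kind, counts, window = 8, min_sep = 2,
                        binning = NULL,
                        domain_labels = default_domain_table()$labels,
                        tor2_domain = "first") {
  kind <- match.arg(kind, POTENTIAL_KINDS)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("count_table: counts must be finite and non-negative")
  }
  if (kind %in% c("dist1", "dist2") && is.null(binning)) {
    nb <- ncol(counts)
    binning <- distance_binning(3, 3 + 0.2 * (nb - 2), 0.2)
  }
  new_count_table(kind, counts, window, min_sep, binning,
                  domain_labels, tor2_domain)
}

#' Count motif occurrences over a set of protein descriptors
#'
#' Tabulates the (sequence motif, structure motif) occurrences that
#' define one of the four statistical potentials. Residues with an
#' undefined torsion domain are skipped by the torsion kinds; residue
#' pairs with an unavailable side-chain center are skipped by the
#' distance kinds. The `dist1` table counts each residue pair once per
#' member (so an A-A pair contributes 2 to the A row).
#'
#' @param descriptors list of [protein_descriptor] objects (a single
#'   descriptor is accepted).
#' @param kind one of `"tor1"`, `"tor2"`, `"dist1"`, `"dist2"`.
#' @param window maximum sequence separation of the torsion kinds.
#' @param min_sep minimum sequence separation `j - i` of the distance
#'   kinds (excludes covalent neighbors).
#' @param binning a [distance_binning].
#' @param domain_labels the seven torsion-domain labels.
#' @param tor2_domain whether the `tor2` structure motif is the domain
#'   of the first or the second residue of the pair.
#' @return object of class `count_table` with a motif-by-structure
#'   `counts` matrix and `n_total = sum(counts)`.
#' @export
count_motifs <- function(descriptors, kind = POTENTIAL_KINDS,
                         window = 8, min_sep = 2,
                         binning = distance_binning(),
                         domain_labels = default_domain_table()$labels,
                         tor2_domain = c("first", "second")) {
  kind <- match.arg(kind)
  tor2_domain <- match.arg(tor2_domain)
  if (inherits(descriptors, "protein_descriptor")) {
    descriptors <- list(descriptors)
  }
  if (length(descriptors) == 0) stop("count_motifs: no descriptors")
  ml <- motif_levels(kind, window)
  sl <- struct_levels(kind, binning, domain_labels)
  nr <- length(ml)
  acc <- numeric(nr * length(sl))
  naa <- length(AA1)
  # row index of unordered pair (p <= q) in the dist2 motif ordering
  pair_start <- cumsum(c(1, naa + 1 - seq_len(naa - 1)))

  for (d in descriptors) {
    n <- d$n
    ai <- match(d$aa, AA1)
    di <- match(d$domains, domain_labels)
    row <- integer(0); col <- integer(0)
    if (kind == "tor1") {
      for (k in -window:window) {
        if (n - abs(k) < 1) next
        i <- if (k >= 0) seq_len(n - k) else seq.int(1 - k, n)
        j <- i + k
        ok <- !is.na(di[j])
        if (!any(ok)) next
        row <- c(row, ai[i[ok]] + (k + window) * naa)
        col <- c(col, di[j[ok]])
      }
    } else if (kind == "tor2") {
      for (off in seq_len(max(min(window, n - 1), 0))) {
        i <- seq_len(n - off)
        j <- i + off
        t_res <- if (tor2_domain == "first") i else j
        ok <- !is.na(di[t_res])
        if (!any(ok)) next
        row <- c(row, ai[i[ok]] + (ai[j[ok]] - 1L) * naa)
        col <- c(col, di[t_res[ok]])
      }
    } else if (n > min_sep) {
      ut <- which(upper.tri(d$dist) & !is.na(d$dist))
      pi_ <- ((ut - 1) %% n) + 1
      pj <- ((ut - 1) %/% n) + 1
      ok <- pj - pi_ >= min_sep
      pi_ <- pi_[ok]; pj <- pj[ok]
      if (length(pi_) > 0) {
        b <- bin_distance(d$dist[cbind(pi_, pj)], binning)
        a1 <- ai[pi_]; a2 <- ai[pj]
        if (kind == "dist2") {
          p <- pmin(a1, a2); q <- pmax(a1, a2)
          row <- pair_start[p] + (q - p)
          col <- b
        } else {
          row <- c(a1, a2)
          col <- c(b, b)
        }
      }
    }
    if (length(row)) {
      acc <- acc + tabulate((col - 1L) * nr + row, nbins = length(acc))
    }
  }
  counts <- matrix(acc, nrow = nr, dimnames = list(ml, sl))
  new_count_table(kind, counts, window, min_sep, binning,
                  domain_labels, tor2_domain)
}

#' Sum count tables over proteins
#'
#' Count tables are additive: the table of a dataset is the sum of its
#' members' tables. Used to assemble dataset counts from cached
#' per-protein counts.
#'
#' @param tables list of `count_table` objects with identical axes.
#' @return the summed `count_table`.
#' @export
sum_count_tables <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "count_table")))
  out <- tables[[1]]
  out$counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  out$n_total <- sum(out$counts)
  out
}

#' Per-protein count tables for all four kinds
#'
#' @param desc a [protein_descriptor].
#' @inheritParams count_motifs
#' @return named list of `count_table`s (one per kind).
#' @export
protein_counts <- function(desc, window = 8, min_sep = 2,
                           binning = distance_binning(),
                           domain_labels = default_domain_table()$labels,
                           tor2_domain = "first") {
  lapply(stats::setNames(POTENTIAL_KINDS, POTENTIAL_KINDS), function(kind)
    count_motifs(desc, kind, window = window, min_sep = min_sep,
                 binning = binning, domain_labels = domain_labels,
                 tor2_domain = tor2_domain))
}

#' Subtract one count table from another
#'
#' Used to remove a single protein's own occurrences from a dataset
#' count table before scoring it (leave-one-out hygiene).
#'
#' @param a,b `count_table` objects with identical axes; `b` must be
#'   contained in `a`.
#' @return a `count_table` with counts `a - b`.
#' @export
subtract_counts <- function(a, b) {
  stopifnot(inherits(a, "count_table"), inherits(b, "count_table"),
            a$kind == b$kind, all(dim(a$counts) == dim(b$counts)))
  cts <- a$counts - b$counts
  if (any(cts < -1e-9)) stop("subtract_counts: b is not contained in a")
  cts[cts < 0] <- 0
  out <- a
  out$counts <- cts
  out$n_total <- sum(cts)
  out
}

#' Smooth distance counts over neighboring bins
#'
#' Occurrences of neighboring core bins are summed with geometrically
#' decreasing weight `lam^|k|`, then each motif row is rescaled so its
#' total count mass is unchanged. The underflow and overflow bins are
#' left untouched. `lam = 0` is the identity.
#'
#' @param table a distance-kind `count_table`.
#' @param lam neighbor weight in `[0, 1)`.
#' @return the smoothed `count_table`.
#' @export
smooth_distance_counts <- function(table, lam = 0.5) {
  stopifnot(inherits(table, "count_table"))
  if (!table$kind %in% c("dist1", "dist2")) {
    stop("smooth_distance_counts: not a distance-kind table")
  }
  if (!is.finite(lam) || lam < 0 || lam >= 1) {
    stop("smooth_distance_counts: lam must be in [0, 1)")
  }
  if (lam == 0) return(table)
  nb <- table$binning$n_bins
  core <- 2:(nb - 1)
  W <- lam^abs(outer(seq_along(core), seq_along(core), "-"))
  old <- table$counts[, core, drop = FALSE]
  new <- old %*% W
  old_mass <- rowSums(old)
  new_mass <- rowSums(new)
  scale <- ifelse(new_mass > 0, old_mass / new_mass, 0)
  table$counts[, core] <- new * scale
  table$n_total <- sum(table$counts)
  table
}

#' Boltzmann inversion of a count table with sparse-data correction
#'
#' With relative frequencies `f(c,s) = n(c,s)/n_total`, marginals `f(c)`
#' and `f(s)`, and `m_c` the total occurrences of sequence motif `c`,
#' the corrected conditional frequency is the shrinkage
#' \deqn{\tilde f(s|c) = \frac{\sigma f(s) + m_c f(s|c)}{\sigma + m_c}}
#' and the potential, in kT units, is
#' \deqn{\Delta W(c,s) = -\ln\left[\tilde f(s|c) / f(s)\right].}
#' The correction drives the potential to 0 for motifs with few
#' observations (exactly 0 when `m_c = 0`) and reduces to plain
#' Boltzmann inversion `-ln[f(c,s)/(f(c)f(s))]` at `sigma = 0` for
#' abundantly observed motifs. Cells with zero corrected support
#' (including every cell where `f(s) = 0`) are set to 0 by convention,
#' so the table is finite everywhere.
#'
#' @param table a `count_table` with `n_total > 0`.
#' @param sigma shrinkage strength (>= 0), in occurrence counts.
#' @return object of class `potential_table`: `kind`, `values` (energy
#'   matrix in kT, same axes as the counts), `sigma`, `t_set`
#'   (filled by [derive_potential_set]), and the counting parameters.
#' @export
boltzmann_potential <- function(table, sigma = 0) {
  stopifnot(inherits(table, "count_table"))
  if (!is.finite(sigma) || sigma < 0) {
    stop("boltzmann_potential: sigma must be non-negative")
  }
  if (table$n_total <= 0) stop("boltzmann_potential: empty count table")
  cts <- table$counts
  f_s <- colSums(cts) / table$n_total
  m_c <- rowSums(cts)
  # sigma * f(s) + m_c * f(s|c) = sigma * f(s) + n(c,s)
  num <- outer(rep(sigma, nrow(cts)), f_s) + cts
  den <- sigma + m_c
  ftilde <- num / ifelse(den > 0, den, 1)
  ratio <- sweep(ftilde, 2, ifelse(f_s > 0, f_s, 1), "/")
  vals <- -log(ratio)
  vals[!is.finite(vals)] <- 0
  vals[, f_s == 0] <- 0
  vals[m_c == 0, ] <- 0
  dimnames(vals) <- dimnames(cts)
  structure(list(kind = table$kind, values = vals, sigma = sigma,
                 t_set = NA_real_, window = table$window,
                 min_sep = table$min_sep, binning = table$binning,
                 domain_labels = table$domain_labels,
                 tor2_domain = table$tor2_domain,
                 provenance = list()),
            class = "potential_table")
}

#' Cell-wise average of potential tables
#'
#' @param tables list of `potential_table` objects with identical axes.
#' @return a `potential_table` holding the mean energies.
#' @export
average_potentials <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "potential_table")))
  out <- tables[[1]]
  vals <- Reduce(`+`, lapply(tables, `[[`, "values")) / length(tables)
  out$values <- vals
  out$sigma <- mean(vapply(tables, `[[`, 0.0, "sigma"))
  out
}

#' Derive the four averaged potentials of one dataset
#'
#' For each of the four potential kinds: count the occurrences, smooth
#' (distance kinds only), Boltzmann-invert at each shrinkage strength,
#' and average cell-wise over every (descriptor set, sigma) variant.
#' When one descriptor set per Tm-estimation rule is supplied together
#' with the default two sigma values, this realizes the six-variant
#' averaging of the final potentials.
#'
#' @param descriptor_sets either a single list of [protein_descriptor]
#'   objects, or a list of such lists (one per Tm-estimation rule).
#' @param t_set representative temperature (degrees C) of the dataset,
#'   stored with the potentials.
#' @param sigmas numeric vector of shrinkage strengths.
#' @param lam neighbor-bin smoothing weight.
#' @param window,min_sep,binning,domain_labels,tor2_domain counting
#'   parameters, see [count_motifs].
#' @return object of class `potential_set` with elements `tor1`, `tor2`,
#'   `dist1`, `dist2` ([boltzmann_potential] tables) plus the shared
#'   parameters.
#' @export
derive_potential_set <- function(descriptor_sets, t_set,
                                 sigmas = c(10, 50), lam = 0.5,
                                 window = 8, min_sep = 2,
                                 binning = distance_binning(),
                                 domain_labels = default_domain_table()$labels,
                                 tor2_domain = "first") {
  if (length(descriptor_sets) == 0) stop("derive_potential_set: empty input")
  if (inherits(descriptor_sets[[1]], "protein_descriptor")) {
    descriptor_sets <- list(descriptor_sets)
  }
  count_sets <- lapply(descriptor_sets, function(ds) {
    lapply(stats::setNames(POTENTIAL_KINDS, POTENTIAL_KINDS), function(kind)
      count_motifs(ds, kind, window = window, min_sep = min_sep,
                   binning = binning, domain_labels = domain_labels,
                   tor2_domain = tor2_domain))
  })
  derive_potential_set_counts(count_sets, t_set, sigmas = sigmas, lam = lam)
}

#' Derive the four averaged potentials from precomputed counts
#'
#' Counts-level variant of [derive_potential_set]: takes one set of
#' already-summed count tables per Tm-estimation rule (e.g. assembled
#' with [sum_count_tables] from a per-protein cache) and performs the
#' smoothing, Boltzmann inversion, and variant averaging.
#'
#' @param count_sets list (one element per rule) of named lists of
#'   `count_table`s, one per kind.
#' @inheritParams derive_potential_set
#' @return a `potential_set`.
#' @export
derive_potential_set_counts <- function(count_sets, t_set,
                                        sigmas = c(10, 50), lam = 0.5) {
  stopifnot(length(count_sets) >= 1)
  ref <- count_sets[[1]][[1]]
  pset <- list()
  for (kind in POTENTIAL_KINDS) {
    variants <- list()
    for (cs in count_sets) {
      ct <- cs[[kind]]
      stopifnot(inherits(ct, "count_table"), ct$kind == kind)
      if (kind %in% c("dist1", "dist2")) {
        ct <- smooth_distance_counts(ct, lam)
      }
      for (s in sigmas) {
        variants[[length(variants) + 1]] <- if (ct$n_total > 0) {
          boltzmann_potential(ct, s)
        } else {
          # no observations at all: the sparse-data limit is the zero
          # potential everywhere
          zp <- boltzmann_potential(count_table(kind, ct$counts + 1,
                                                window = ct$window,
                                                min_sep = ct$min_sep,
                                                binning = ct$binning), s)
          zp$values[] <- 0
          zp$sigma <- s
          zp
        }
      }
    }
    tab <- average_potentials(variants)
    tab$t_set <- t_set
    pset[[kind]] <- tab
  }
  structure(c(pset, list(t_set = t_set, sigmas = sigmas, lam = lam,
                         window = ref$window, min_sep = ref$min_sep,
                         binning = ref$binning,
                         domain_labels = ref$domain_labels,
                         tor2_domain = ref$tor2_domain)),
            class = "potential_set")
}

#' @export
print.potential_set <- function(x, ...) {
  cat(sprintf("potential_set at T = %.1f C (window %d, min_sep %d, lam %.2f, sigmas %s)\n",
              x$t_set, x$window, x$min_sep, x$lam,
              paste(x$sigmas, collapse = "/")))
  invisible(x)
}

#' Write a potential set to TSV tables with a JSON sidecar
#'
#' One long-format TSV per kind (`<prefix>_<kind>.tsv` with columns
#' `motif`, `struct`, `energy`) plus `<prefix>_meta.json` holding the
#' derivation parameters.
#'
#' @param pset a `potential_set`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_potential_set <- function(pset, prefix) {
  stopifnot(inherits(pset, "potential_set"))
  for (kind in POTENTIAL_KINDS) {
    v <- pset[[kind]]$values
    df <- data.frame(motif = rep(rownames(v), ncol(v)),
                     struct = rep(colnames(v), each = nrow(v)),
                     energy = as.vector(v), stringsAsFactors = FALSE)
    utils::write.table(df, paste0(prefix, "_", kind, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  meta <- list(t_set = pset$t_set, sigmas = pset$sigmas, lam = pset$lam,
               window = pset$window, min_sep = pset$min_sep,
               binning = pset$binning[c("low", "high", "width")],
               domain_labels = pset$domain_labels,
               tor2_domain = pset$tor2_domain)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a potential set written by [write_potential_set]
#'
#' @param prefix path prefix used when writing.
#' @return a `potential_set`.
#' @export
read_potential_set <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  binning <- distance_binning(meta$binning$low, meta$binning$high,
                              meta$binning$width)
  pset <- list()
  for (kind in POTENTIAL_KINDS) {
    # na.strings disabled: "NA" is the Asn-Ala pair motif
    df <- utils::read.delim(paste0(prefix, "_", kind, ".tsv"),
                            colClasses = c("character", "character",
                                           "numeric"),
                            na.strings = character(0))
    ml <- motif_levels(kind, meta$window)
    sl <- struct_levels(kind, binning, meta$domain_labels)
    v <- matrix(0, length(ml), length(sl), dimnames = list(ml, sl))
    v[cbind(match(df$motif, ml), match(df$struct, sl))] <- df$energy
    pset[[kind]] <- structure(
      list(kind = kind, values = v, sigma = NA_real_, t_set = meta$t_set,
           window = meta$window, min_sep = meta$min_sep, binning = binning,
           domain_labels = meta$domain_labels,
           tor2_domain = meta$tor2_domain, provenance = list()),
      class = "potential_table")
  }
  structure(c(pset, list(t_set = meta$t_set, sigmas = meta$sigmas,
                         lam = meta$lam, window = meta$window,
                         min_sep = meta$min_sep, binning = binning,
                         domain_labels = meta$domain_labels,
                         tor2_domain = meta$tor2_domain)),
            class = "potential_set")
}
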