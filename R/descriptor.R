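# Per-protein structural descriptor: the only thing the potentials ever
# see. Sequence, torsion-domain string, and the matrix of side-chain
# geometric-center distances.

#' Extract the structural descriptor of a chain
#'
#' Computes, once per protein, everything the statistical potentials
#' consume: the amino-acid sequence, the torsion-angle-domain label of
#' every residue (fallback label where phi or psi is undefined), and the
#' full matrix of pairwise distances between side-chain geometric
#' centers (`NA` where a center is unavailable).
#'
#' @param chain a [chain_structure].
#' @param domain_table a `domain_table` (default [default_domain_table()]).
#' @param id identifier stored in the descriptor (default: the chain's
#'   source id).
#' @param sc_fallback passed to [sidechain_center] as `fallback`:
#'   if `TRUE`, CA stands in for missing side chains instead of the
#'   residue being dropped from distance statistics.
#' @return object of class `protein_descriptor` with elements `id`, `n`,
#'   `aa` (character vector), `domains` (character vector), `sc`
#'   (n x 3 matrix of centers, `NA` rows where unavailable), `dist`
#'   (n x n symmetric distance matrix, `NA` where either center is
#'   unavailable).
#' @export
protein_descriptor <- function(chain, domain_table = default_domain_table(),
                               id = chain$source_id, sc_fallback = FALSE) {
  stopifnot(inherits(chain, "chain_structure"))
  n <- length(chain$residues)
  aa <- chain_sequence(chain)
  tor <- torsion_angles(chain)
  domains <- assign_domain(tor$phi, tor$psi, domain_table)
  sc <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ctr <- tryCatch(sidechain_center(chain$residues[[i]], fallback = sc_fallback),
                    error = function(e) NULL)
    if (!is.null(ctr)) sc[i, ] <- ctr
  }
  d <- as.matrix(stats::dist(sc))
  diag(d) <- NA_real_
  out <- list(id = id, n = n, aa = aa, domains = domains, sc = sc, dist = d,
              fallback_label = domain_table$fallback_label)
  class(out) <- "protein_descriptor"
  out
}

#' @export
print.protein_descriptor <- function(x, ...) {
  cat(sprintf("protein_descriptor: %s, %d residues, %d torsion-defined, %d side-chain centers\n",
              x$id, x$n, sum(x$domains != x$fallback_label),
              sum(!is.na(x$sc[, 1]))))
  invisible(x)
}
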