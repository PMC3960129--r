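# Reading protein chains from PDB files into the package's residue-level
# container. Parsing is delegated to bio3d; this layer selects one chain,
# keeps standard residues only, resolves alternate locations and
# multi-model files deterministically, and groups atoms per residue.

#' Residue container
#'
#' @param aa one-letter amino-acid code.
#' @param backbone named list with optional numeric length-3 elements
#'   `N`, `CA`, `C` (Angstrom); a missing atom is `NULL`.
#' @param sidechain numeric matrix (k x 3) of heavy side-chain atom
#'   coordinates; zero rows allowed (glycine or incomplete residues).
#' @return object of class `residue_atoms`.
#' @export
residue_atoms <- function(aa, backbone = list(N = NULL, CA = NULL, C = NULL),
                          sidechain = matrix(numeric(0), ncol = 3)) {
  stopifnot(aa %in% AA1)
  sidechain <- matrix(as.numeric(sidechain), ncol = 3)
  if (nrow(sidechain) > 0 && any(!is.finite(sidechain))) {
    stop("residue_atoms: non-finite side-chain coordinates")
  }
  for (nm in c("N", "CA", "C")) {
    if (!is.null(backbone[[nm]]) && any(!is.finite(backbone[[nm]]))) {
      stop("residue_atoms: non-finite backbone coordinates")
    }
  }
  structure(list(aa = aa, backbone = backbone, sidechain = sidechain),
            class = "residue_atoms")
}

#' Chain container
#'
#' @param chain_id author chain identifier.
#' @param residues list of [residue_atoms], in sequence order.
#' @param source_id identifier of the source structure (file stem).
#' @return object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, residues, source_id = "") {
  stopifnot(length(residues) >= 1,
            all(vapply(residues, inherits, TRUE, "residue_atoms")))
  structure(list(chain_id = chain_id, residues = residues,
                 source_id = source_id),
            class = "chain_structure")
}

#' @export
length.chain_structure <- function(x) length(x$residues)

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("chain_structure: %s chain %s, %d residues\n",
              x$source_id, x$chain_id, length(x$residues)))
  invisible(x)
}

#' Sequence of a chain
#'
#' @param chain a [chain_structure].
#' @return character vector of one-letter codes.
#' @export
chain_sequence <- function(chain) {
  vapply(chain$residues, `[[`, "", "aa")
}

#' Read one protein chain from a PDB file
#'
#' Keeps `ATOM` records of the 20 standard amino acids only; `HETATM`
#' records and non-standard residues are skipped (their count is
#' reported via a message). Only the first model of a multi-model file
#' is used; alternate locations are resolved by highest occupancy, then
#' first occurrence.
#'
#' @param path PDB file.
#' @param chain_id author chain identifier (default: first chain in the
#'   file).
#' @param quiet suppress the skipped-record message.
#' @return a [chain_structure].
#' @export
read_chain <- function(path, chain_id = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("read_chain: file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  n_het <- sum(at$type == "HETATM")
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain_id)) chain_id <- at$chain[1]
  if (!chain_id %in% at$chain) {
    stop("read_chain: chain '", chain_id, "' not present in ", path)
  }
  at <- at[at$chain == chain_id, , drop = FALSE]
  aa1 <- aa_three_to_one(at$resid)
  n_nonstd <- length(unique(at$resno[is.na(aa1)]))
  at <- at[!is.na(aa1), , drop = FALSE]
  if (nrow(at) == 0) {
    stop("read_chain: no standard amino-acid residues in chain '",
         chain_id, "' of ", path)
  }
  # resolve alternate locations: highest occupancy, then first seen
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, at$elety)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
  at <- at[order(at$resno, seq_len(nrow(at))), , drop = FALSE]

  resno <- unique(at$resno)
  residues <- vector("list", length(resno))
  for (k in seq_along(resno)) {
    ra <- at[at$resno == resno[k], , drop = FALSE]
    aa <- aa_three_to_one(ra$resid[1])
    bb <- list(N = NULL, CA = NULL, C = NULL)
    for (nm in c("N", "CA", "C")) {
      i <- match(nm, ra$elety)
      if (!is.na(i)) bb[[nm]] <- c(ra$x[i], ra$y[i], ra$z[i])
    }
    sc <- ra[!(ra$elety %in% BACKBONE_ATOMS) &
               substr(ra$elety, 1, 1) != "H", , drop = FALSE]
    residues[[k]] <- residue_atoms(aa, bb,
                                   cbind(sc$x, sc$y, sc$z))
  }
  if (!quiet && (n_het > 0 || n_nonstd > 0)) {
    message(sprintf("read_chain: skipped %d HETATM atoms, %d non-standard residues (%s)",
                    n_het, n_nonstd, basename(path)))
  }
  chain_structure(chain_id, residues,
                  source_id = sub("\\.(pdb|ent)$", "", basename(path)))
}

#' Geometric center of the heavy side-chain atoms
#'
#' Arithmetic mean of the heavy side-chain atom coordinates. Glycine has
#' no heavy side-chain atoms; by convention its CA position is used.
#' A non-glycine residue with an empty side chain is incomplete: with
#' `fallback = TRUE` its CA is used, otherwise an error is raised.
#'
#' @param res a [residue_atoms].
#' @param fallback use CA for incomplete non-glycine residues instead of
#'   raising an error.
#' @return numeric length-3 coordinate (Angstrom).
#' @export
sidechain_center <- function(res, fallback = FALSE) {
  stopifnot(inherits(res, "residue_atoms"))
  if (nrow(res$sidechain) > 0) {
    return(colMeans(res$sidechain))
  }
  if (res$aa == "G" || fallback) {
    if (is.null(res$backbone$CA)) {
      stop("sidechain_center: no side-chain atoms and no CA for residue ", res$aa)
    }
    return(res$backbone$CA)
  }
  stop("sidechain_center: residue ", res$aa,
       " has no heavy side-chain atoms (incomplete side chain)")
}
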