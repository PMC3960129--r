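# Fixtures built in code: toy chains, hand-written PDB text, and random
# protein descriptors for counting tests.

AA20 <- thermpot:::AA1

# descriptor assembled directly from its fields (bypasses structure IO)
make_descriptor <- function(aa, domains, sc, id = "toy") {
  d <- as.matrix(stats::dist(sc))
  diag(d) <- NA_real_
  structure(list(id = id, n = length(aa), aa = aa, domains = domains,
                 sc = sc, dist = d, fallback_label = "-"),
            class = "protein_descriptor")
}

# random descriptor: random sequence, random domain labels with some
# undefined, random side-chain centers in a box with some missing
random_descriptor <- function(n, id = "rnd", p_undef = 0.15, p_nosc = 0.1,
                              box = 10) {
  labels <- default_domain_table()$labels
  aa <- sample(AA20, n, replace = TRUE)
  domains <- sample(labels, n, replace = TRUE)
  domains[stats::runif(n) < p_undef] <- "-"
  sc <- matrix(stats::runif(3 * n, 0, box), n, 3)
  sc[stats::runif(n) < p_nosc, ] <- NA_real_
  make_descriptor(aa, domains, sc, id = id)
}

# ideal helix chain built by forward kinematics; all-alanine by default
make_helix_chain <- function(n = 8, phi = -57, psi = -47,
                             seq = rep("A", n), id = "helix") {
  bb <- build_backbone(rep(phi, n), rep(psi, n))
  residues <- lapply(seq_len(n), function(i) {
    sc <- if (seq[i] == "G") matrix(numeric(0), ncol = 3) else
      matrix(place_atom(bb[[i]]$C, bb[[i]]$N, bb[[i]]$CA,
                        1.53, 110.1, 122.5), ncol = 3)
    residue_atoms(seq[i], bb[[i]], sc)
  })
  chain_structure("A", residues, source_id = id)
}

# minimal hand-written PDB text: 3 standard residues on chain A with an
# optional HEM heteroatom group
write_toy_pdb <- function(path, with_hetatm = FALSE) {
  atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                        record = "ATOM") {
    sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            record, serial, name, resn, chain, resno, x, y, z)
  }
  lines <- c(
    atom_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0),
    atom_line(2, "CA", "ALA", "A", 1, 1.458, 0.0, 0.0),
    atom_line(3, "C",  "ALA", "A", 1, 2.0, 1.4, 0.0),
    atom_line(4, "CB", "ALA", "A", 1, 1.9, -1.2, 0.9),
    atom_line(5, "N",  "GLY", "A", 2, 3.3, 1.5, 0.0),
    atom_line(6, "CA", "GLY", "A", 2, 4.2, 2.6, 0.2),
    atom_line(7, "C",  "GLY", "A", 2, 5.6, 2.1, 0.4),
    atom_line(8, "N",  "ASP", "A", 3, 6.5, 3.1, 0.5),
    atom_line(9, "CA", "ASP", "A", 3, 7.9, 2.8, 0.7),
    atom_line(10, "C", "ASP", "A", 3, 8.7, 4.1, 0.8),
    atom_line(11, "CB", "ASP", "A", 3, 8.4, 2.0, -0.5),
    atom_line(12, "OD1", "ASP", "A", 3, 9.5, 1.3, -0.4),
    atom_line(13, "OD2", "ASP", "A", 3, 7.8, 2.1, -1.6))
  if (with_hetatm) {
    lines <- c(lines,
               atom_line(14, "FE", "HEM", "A", 101, 3.0, 8.0, 3.0,
                         record = "HETATM"),
               atom_line(15, "NA", "HEM", "A", 101, 4.1, 8.8, 3.2,
                         record = "HETATM"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# records table for datasets tests
make_records <- function(id, tm = NA_real_, tenv = NA_real_,
                         family = "F1", tm_source = NA_character_,
                         sequence = NA_character_) {
  data.frame(id = id, family = family, tm = tm, tenv = tenv,
             tm_source = tm_source, sequence = sequence,
             structure_path = NA_character_, stringsAsFactors = FALSE)
}
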