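# Independent oracles, deliberately written as naive loops / exhaustive
# enumeration, never sharing code with the implementation they check.

# brute-force motif recount: plain double loops over residues
oracle_count <- function(desc, kind, window = 8, min_sep = 2,
                         binning = distance_binning(),
                         domain_labels = default_domain_table()$labels,
                         tor2_domain = "first") {
  ml <- thermpot:::motif_levels(kind, window)
  sl <- thermpot:::struct_levels(kind, binning, domain_labels)
  m <- matrix(0, length(ml), length(sl), dimnames = list(ml, sl))
  n <- desc$n
  if (kind == "tor1") {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      k <- j - i
      if (abs(k) > window) next
      if (!desc$domains[j] %in% domain_labels) next
      m[paste0(desc$aa[i], "@", k), desc$domains[j]] <-
        m[paste0(desc$aa[i], "@", k), desc$domains[j]] + 1
    }
  } else if (kind == "tor2") {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j - i < 1 || j - i > window) next
      t_res <- if (tor2_domain == "first") i else j
      if (!desc$domains[t_res] %in% domain_labels) next
      mot <- paste0(desc$aa[i], desc$aa[j])
      m[mot, desc$domains[t_res]] <- m[mot, desc$domains[t_res]] + 1
    }
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j - i < min_sep) next
      d <- desc$dist[i, j]
      if (is.na(d)) next
      b <- as.character(bin_distance(d, binning))
      if (kind == "dist2") {
        mot <- paste0(min(desc$aa[i], desc$aa[j]),
                      max(desc$aa[i], desc$aa[j]))
        m[mot, b] <- m[mot, b] + 1
      } else {
        m[desc$aa[i], b] <- m[desc$aa[i], b] + 1
        m[desc$aa[j], b] <- m[desc$aa[j], b] + 1
      }
    }
  }
  m
}

# direct evaluation of the Boltzmann inversion with shrinkage, cell by
# cell from first principles
oracle_boltzmann <- function(counts, sigma) {
  n_tot <- sum(counts)
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (ci in seq_len(nrow(counts))) {
    m_c <- sum(counts[ci, ])
    for (si in seq_len(ncol(counts))) {
      f_s <- sum(counts[, si]) / n_tot
      if (f_s == 0 || m_c == 0) next
      f_sc <- counts[ci, si] / m_c
      ftilde <- (sigma * f_s + m_c * f_sc) / (sigma + m_c)
      if (ftilde == 0) next
      out[ci, si] <- -log(ftilde / f_s)
    }
  }
  out
}

# exhaustive global alignment: enumerates every alignment of a and b
# under affine-gap scoring (gap run of length L costs open + L * ext)
# and returns the identities (matches / alignment length) of all
# optimal-score alignments
oracle_align_identities <- function(a, b, submat, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$idents <- numeric(0)
  rec <- function(i, j, score, matches, len, last) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$idents <- matches / len
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <- unique(c(best$idents, matches / len))
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, score + submat[a[i], b[j]],
          matches + (a[i] == b[j]), len + 1, "m")
    }
    if (i <= length(a)) {
      cost <- ext + if (last == "d") 0 else open
      rec(i + 1, j, score - cost, matches, len + 1, "d")
    }
    if (j <= length(b)) {
      cost <- ext + if (last == "i") 0 else open
      rec(i, j + 1, score - cost, matches, len + 1, "i")
    }
  }
  rec(1, 1, 0, 0, 0, "m")
  list(score = best$score, identities = best$idents)
}

blosum62_matrix <- function() thermpot:::blosum62()
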