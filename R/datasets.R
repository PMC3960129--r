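# Protein metadata management: Tm/Tenv tables, the three Tm-estimation
# rules (global regression, per-family regression, sequence-identity
# transfer), and the split of a dataset into mesostable / thermostable /
# average subsets with redundancy culling.

#' Read a protein metadata table
#'
#' Tab-separated table with columns `id`, `family`, `tm_measured`
#' (degrees C, empty when not experimentally characterized), `tenv`
#' (host environmental temperature, degrees C), and `structure_path`.
#' Sequences are taken from a FASTA file whose record names match `id`.
#'
#' @param path TSV file.
#' @param fasta optional FASTA file of amino-acid sequences.
#' @param base_dir directory against which relative `structure_path`
#'   entries are resolved (default: the TSV's directory).
#' @return data.frame of protein records with columns `id`, `family`,
#'   `tm`, `tenv`, `tm_source` (`"measured"` or `NA`), `sequence`,
#'   `structure_path`.
#' @export
read_protein_table <- function(path, fasta = NULL, base_dir = dirname(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "family", "tm_measured", "tenv")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("read_protein_table: missing columns: ",
                         paste(miss, collapse = ", "))
  rec <- data.frame(id = as.character(tab$id),
                    family = as.character(tab$family),
                    tm = as.numeric(tab$tm_measured),
                    tenv = as.numeric(tab$tenv),
                    tm_source = ifelse(is.na(tab$tm_measured), NA_character_,
                                       "measured"),
                    sequence = NA_character_,
                    structure_path = if ("structure_path" %in% names(tab)) {
                      ifelse(grepl("^/", tab$structure_path),
                             tab$structure_path,
                             file.path(base_dir, tab$structure_path))
                    } else NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    seqs <- Biostrings::readAAStringSet(fasta)
    nm <- sub("\\s.*$", "", names(seqs))
    rec$sequence <- as.character(seqs)[match(rec$id, nm)]
  }
  if (anyDuplicated(rec$id)) stop("read_protein_table: duplicated ids")
  rec
}

#' Write a protein metadata table
#'
#' @param records protein record data.frame.
#' @param path output TSV path.
#' @export
write_protein_table <- function(records, path) {
  out <- data.frame(id = records$id, family = records$family,
                    tm_measured = ifelse(records$tm_source %in% "measured",
                                         records$tm, NA_real_),
                    tenv = records$tenv,
                    structure_path = records$structure_path,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Tm-vs-Tenv regression line
#'
#' Ordinary least squares of melting temperature on host environmental
#' temperature, over records holding both values.
#'
#' @param records protein record data.frame; rows without measured `tm`
#'   or without `tenv` are dropped.
#' @return object of class `tm_regression`: `slope`, `intercept`,
#'   `r` (Pearson correlation), `n`.
#' @export
fit_tm_tenv_regression <- function(records) {
  keep <- records$tm_source %in% "measured" &
    !is.na(records$tm) & !is.na(records$tenv)
  x <- records$tenv[keep]
  y <- records$tm[keep]
  if (length(x) < 2) {
    stop("fit_tm_tenv_regression: need at least 2 records with measured tm and tenv")
  }
  if (stats::var(x) == 0) {
    stop("fit_tm_tenv_regression: tenv has zero variance")
  }
  fit <- stats::lm(y ~ x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, n = length(x)),
            class = "tm_regression")
}

#' @export
print.tm_regression <- function(x, ...) {
  cat(sprintf("tm_regression: Tm = %.3f * Tenv + %.3f  (r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 scoring and affine
#' gaps (open 11, extend 1); identity is the number of identical aligned
#' positions divided by the alignment length, gap positions included in
#' the denominator.
#'
#' @param a,b amino-acid sequences (single strings).
#' @param gap_opening,gap_extension affine gap penalties (positive).
#' @param substitution substitution matrix; defaults to BLOSUM62.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, gap_opening = 11, gap_extension = 1,
                              substitution = NULL) {
  if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    stop("pairwise_identity: empty sequence")
  }
  if (is.null(substitution)) substitution <- blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution,
    gapOpening = gap_opening, gapExtension = gap_extension)
  unname(alignment_identity(aln, nchar(a), nchar(b)))
}

# Identical positions over the full alignment length, every gap column
# counted. Each aligned residue pair merges one character of each
# sequence into a single column, so the column count is
# len_a + len_b - nmatch - nmismatch; this avoids materializing the
# aligned strings, which dominates the alignment cost.
alignment_identity <- function(aln, len_a, len_b) {
  m <- Biostrings::nmatch(aln)
  m / (len_a + len_b - m - Biostrings::nmismatch(aln))
}

# BLOSUM62 loaded once per session
.pkg_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' All-against-all identity matrix
#'
#' @param seqs character vector of sequences, names used as dimnames.
#' @param ... passed to [pairwise_identity]'s scoring.
#' @return symmetric numeric matrix of identity fractions, diagonal 1.
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n < 2) return(m)
  ss <- Biostrings::AAStringSet(seqs)
  for (j in 2:n) {
    aln <- Biostrings::pairwiseAlignment(
      ss[seq_len(j - 1)], ss[[j]], type = "global",
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
    m[seq_len(j - 1), j] <- m[j, seq_len(j - 1)] <-
      alignment_identity(aln, nchar(seqs[seq_len(j - 1)]), nchar(seqs[j]))
  }
  m
}

#' Estimate the melting temperature of one protein
#'
#' Three rules, used when a protein has no measured Tm:
#' \describe{
#'   \item{`est_global_regression`}{apply the global Tm-vs-Tenv
#'     regression line to the protein's `tenv`.}
#'   \item{`est_family_regression`}{apply a regression line fitted on
#'     the measured members of the protein's own family.}
#'   \item{`est_seq_identity`}{transfer the Tm of the measured family
#'     member with the highest sequence identity (ties broken by higher
#'     identity, then lexicographic id).}
#' }
#'
#' @param record single protein record (1-row data.frame or list) with
#'   `tenv`, `family`, `sequence` as required by the method.
#' @param method one of the three rule names above.
#' @param family_records records of the same family (used by the family
#'   regression and identity rules); measured members only are consulted.
#' @param global_line a `tm_regression` (required by the global rule).
#' @param idm optional precomputed identity matrix (dimnames = ids) used
#'   by the identity rule instead of aligning on the fly.
#' @return list with `tm` (degrees C) and `tm_source` (the method name).
#' @export
estimate_tm <- function(record,
                        method = c("est_global_regression",
                                   "est_family_regression",
                                   "est_seq_identity"),
                        family_records = NULL, global_line = NULL,
                        idm = NULL) {
  method <- match.arg(method)
  if (method == "est_global_regression") {
    if (is.null(global_line)) {
      stop("estimate_tm: global regression line required")
    }
    if (is.na(record$tenv)) stop("estimate_tm: record has no tenv")
    tm <- global_line$slope * record$tenv + global_line$intercept
  } else if (method == "est_family_regression") {
    if (is.null(family_records)) {
      stop("estimate_tm: family records required")
    }
    meas <- family_records[family_records$tm_source %in% "measured" &
                             !is.na(family_records$tenv), , drop = FALSE]
    if (nrow(meas) < 2) {
      stop("estimate_tm: family regression needs >= 2 measured family ",
           "members with tenv (family '", record$family, "')")
    }
    line <- fit_tm_tenv_regression(meas)
    if (is.na(record$tenv)) stop("estimate_tm: record has no tenv")
    tm <- line$slope * record$tenv + line$intercept
  } else {
    if (is.null(family_records)) {
      stop("estimate_tm: family records required")
    }
    cand <- family_records[family_records$tm_source %in% "measured" &
                             !is.na(family_records$sequence) &
                             family_records$id != record$id, , drop = FALSE]
    if (nrow(cand) < 1) {
      stop("estimate_tm: identity transfer needs >= 1 measured family ",
           "member with a sequence (family '", record$family, "')")
    }
    if (is.na(record$sequence)) stop("estimate_tm: record has no sequence")
    idn <- if (!is.null(idm) && record$id %in% rownames(idm) &&
               all(cand$id %in% colnames(idm))) {
      idm[record$id, cand$id]
    } else {
      vapply(cand$sequence, function(s)
        pairwise_identity(record$sequence, s), 0.0, USE.NAMES = FALSE)
    }
    ord <- order(-idn, cand$id)
    tm <- cand$tm[ord[1]]
  }
  list(tm = tm, tm_source = method)
}

#' Fill in estimated Tm for all unmeasured records
#'
#' Applies one estimation rule to every record without a measured Tm;
#' measured records are passed through untouched.
#'
#' @param records protein record data.frame.
#' @param method estimation rule, see [estimate_tm].
#' @param idm optional precomputed identity matrix, see [estimate_tm].
#' @return the records with `tm` and `tm_source` completed.
#' @export
estimate_tm_all <- function(records, method, idm = NULL) {
  global_line <- NULL
  if (method == "est_global_regression") {
    global_line <- fit_tm_tenv_regression(records)
  }
  for (i in seq_len(nrow(records))) {
    if (records$tm_source[i] %in% "measured") next
    fam <- records[records$family == records$family[i], , drop = FALSE]
    est <- estimate_tm(records[i, ], method,
                       family_records = fam, global_line = global_line,
                       idm = idm)
    records$tm[i] <- est$tm
    records$tm_source[i] <- est$tm_source
  }
  records
}

# Greedy redundancy culling of one subset. Conflicting pairs (identity
# above the cutoff) are resolved one at a time: mixed measured/estimated
# pairs first (the estimated member is always the one removed), then
# same-provenance pairs; within each class the highest-identity pair is
# resolved first, ties broken by lexicographic ids. Removal among
# same-provenance pairs keeps the higher Tm in the thermostable set, the
# lower Tm in the mesostable set, and the Tm closest to the pre-culling
# mean in the average set. Resolving mixed pairs first guarantees that a
# measured-Tm protein is never removed while a conflicting estimated-Tm
# partner remains.
cull_subset <- function(df, cutoff, idm, rule, ref_mean = NULL) {
  if (is.null(ref_mean)) ref_mean <- mean(df$tm)
  repeat {
    if (nrow(df) < 2) break
    sub <- idm[df$id, df$id, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- -Inf
    hits <- which(sub > cutoff, arr.ind = TRUE)
    if (nrow(hits) == 0) break
    meas <- df$tm_source %in% "measured"
    mixed <- xor(meas[hits[, 1]], meas[hits[, 2]])
    if (any(mixed)) hits <- hits[mixed, , drop = FALSE]
    idn <- sub[hits]
    key <- paste(pmin(df$id[hits[, 1]], df$id[hits[, 2]]),
                 pmax(df$id[hits[, 1]], df$id[hits[, 2]]))
    h <- hits[order(-idn, key)[1], ]
    a <- df[h[1], ]; b <- df[h[2], ]
    a_meas <- a$tm_source %in% "measured"
    b_meas <- b$tm_source %in% "measured"
    drop_id <- if (a_meas && !b_meas) {
      b$id
    } else if (b_meas && !a_meas) {
      a$id
    } else {
      score <- switch(rule,
                      thermo = c(a$tm, b$tm),          # keep highest Tm
                      meso = -c(a$tm, b$tm),           # keep lowest Tm
                      average = -abs(c(a$tm, b$tm) - ref_mean))
      if (score[1] > score[2]) b$id
      else if (score[2] > score[1]) a$id
      else max(a$id, b$id)                              # tie: drop larger id
    }
    df <- df[df$id != drop_id, , drop = FALSE]
  }
  df
}

#' Split a dataset into mesostable / thermostable / average subsets
#'
#' The records are split into two equal halves at the median melting
#' temperature `tm0` (mesostable: Tm below `tm0`; thermostable: Tm at or
#' above; with an odd count the median protein goes to the thermostable
#' half). Each half, and the full set (the "average" set), is then
#' culled so that no remaining pair exceeds the sequence-identity
#' cutoff; see [cull_subset] rules. The representative temperature of
#' each subset is the mean Tm of its members after culling.
#'
#' @param records protein record data.frame; every row must have `tm`.
#' @param identity_cutoff maximum allowed pairwise identity (default
#'   0.25).
#' @param idm optional precomputed identity matrix (dimnames = ids);
#'   computed from `sequence` when absent.
#' @return object of class `dataset_triple`: `meso`, `thermo`, `average`
#'   (record data.frames), `t_meso`, `t_thermo`, `t_avg`, `tm0`.
#' @export
split_and_cull <- function(records, identity_cutoff = 0.25, idm = NULL) {
  if (nrow(records) < 4) stop("split_and_cull: need at least 4 records")
  if (any(is.na(records$tm))) stop("split_and_cull: all records need tm")
  if (is.null(idm)) {
    idm <- identity_matrix(stats::setNames(records$sequence, records$id))
  }
  ord <- order(records$tm, records$id)
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)
  n_meso <- floor(n / 2)
  meso <- records[seq_len(n_meso), , drop = FALSE]
  thermo <- records[(n_meso + 1):n, , drop = FALSE]
  tm0 <- min(thermo$tm)
  pre_mean <- mean(records$tm)
  meso <- cull_subset(meso, identity_cutoff, idm, "meso")
  thermo <- cull_subset(thermo, identity_cutoff, idm, "thermo")
  average <- cull_subset(records, identity_cutoff, idm, "average",
                         ref_mean = pre_mean)
  structure(list(meso = meso, thermo = thermo, average = average,
                 t_meso = mean(meso$tm), t_thermo = mean(thermo$tm),
                 t_avg = mean(average$tm), tm0 = tm0),
            class = "dataset_triple")
}

#' @export
print.dataset_triple <- function(x, ...) {
  cat(sprintf(paste0("dataset_triple: tm0 = %.1f C\n",
                     "  meso:    %3d proteins, T = %.1f C\n",
                     "  thermo:  %3d proteins, T = %.1f C\n",
                     "  average: %3d proteins, T = %.1f C\n"),
              x$tm0, nrow(x$meso), x$t_meso,
              nrow(x$thermo), x$t_thermo, nrow(x$average), x$t_avg))
  invisible(x)
}
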