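# Synthetic alignment generator with planted per-column identity and
# conservative-substitution targets.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Generate an alignment with planted column conservation
#'
#' Row 1 is the reference. For every other sequence and column a category
#' is drawn -- identical (probability = identity target), conservative
#' (letters with positive BLOSUM62 score against the reference), or other
#' (non-positive-scoring letters, occasionally a gap) -- so realized column
#' statistics converge on the targets.
#'
#' @param n_sequences total rows including the reference (>= 2).
#' @param identity_pct per-column identity targets (percent), recycled to
#'   the reference length.
#' @param conservative_pct per-column conservative targets (percent);
#'   `identity_pct + conservative_pct` must not exceed 100.
#' @param reference reference sequence (string); default: random.
#' @param n_columns reference length when `reference` is NULL.
#' @param groups named integer vector of group sizes (e.g.
#'   `c(bacteria = 100, animals = 100)`), recycled over non-reference rows;
#'   default: single group "all".
#' @param gap_frac fraction of the "other" category written as gaps.
#' @param seed RNG seed.
#' @return List: `msa` (an `msa` object; reference in group "reference"
#'   plus its own group), `truth` (data.frame of per-column targets).
#' @export
generate_msa <- function(n_sequences, identity_pct = 90,
                         conservative_pct = 5, reference = NULL,
                         n_columns = NULL, groups = NULL, gap_frac = 0.2,
                         seed = 1) {
  if (n_sequences < 2) stopf("need at least 2 sequences")
  set.seed(seed)
  if (is.null(reference)) {
    n_columns <- n_columns %||% 50
    ## letters with no positive-scoring partner (e.g. P, C, G in BLOSUM62)
    ## cannot host conservative substitutions; keep them out of random
    ## references when a conservative target is requested
    pool <- AA20
    if (any(conservative_pct > 0))
      pool <- pool[vapply(pool, function(a) length(conservative_letters(a)) > 0,
                          logical(1))]
    reference <- paste(sample(pool, n_columns, replace = TRUE), collapse = "")
  }
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  idt <- rep_len(identity_pct, L)
  cst <- rep_len(conservative_pct, L)
  if (any(idt + cst > 100)) stopf("identity + conservative target exceeds 100")
  if (any(idt < 0 | cst < 0)) stopf("negative target")
  nseq <- n_sequences - 1L
  if (is.null(groups)) groups <- c(all = nseq)
  glab <- rep(rep(names(groups), groups), length.out = nseq)
  mat <- matrix("", n_sequences, L)
  mat[1, ] <- ref
  for (j in seq_len(L)) {
    cons <- conservative_letters(ref[j])
    if (cst[j] > 0 && length(cons) == 0)
      stopf("column %d: no conservative letter exists for '%s'", j, ref[j])
    other <- setdiff(AA20, c(ref[j], cons))
    ## fixed category counts, random placement: realized percentages sit
    ## within rounding of the targets at any n
    n_id <- round(idt[j] / 100 * nseq)
    n_cv <- round(cst[j] / 100 * nseq)
    if (n_id + n_cv > nseq) n_cv <- nseq - n_id
    lab <- sample(rep.int(1:3, c(n_id, n_cv, nseq - n_id - n_cv)))
    pick <- character(nseq)
    pick[lab == 1] <- ref[j]
    if (any(lab == 2)) pick[lab == 2] <- sample(cons, sum(lab == 2), TRUE)
    if (any(lab == 3)) {
      ot <- which(lab == 3)
      gap <- stats::runif(length(ot)) < gap_frac
      pick[ot[!gap]] <- sample(other, sum(!gap), TRUE)
      pick[ot[gap]] <- "-"
    }
    mat[2:n_sequences, j] <- pick
  }
  ids <- c("reference", sprintf("seq%04d", seq_len(nseq)))
  rownames(mat) <- ids
  msa <- msa_object(mat, ids, groups = stats::setNames(
    c(glab[1] %||% "all", glab), ids))
  ## reference is counted in no group's stats (column_stats drops row 1)
  truth <- data.frame(column = seq_len(L), residue = seq_len(L),
                      reference = ref, identity_target = idt,
                      conservative_target = cst)
  list(msa = msa, truth = truth)
}

#' Write an `msa` as aligned FASTA (with a sidecar group table)
#'
#' @param msa an `msa`.
#' @param path FASTA output path.
#' @param groups_path optional TSV (`id`, `group`) sidecar path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, groups_path = NULL) {
  seqs <- apply(msa$seqs, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- msa$ids
  Biostrings::writeXStringSet(ss, path)
  if (!is.null(groups_path))
    utils::write.table(data.frame(id = msa$ids, group = msa$groups),
                       groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
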