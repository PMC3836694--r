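# MSA column conservation: per-column identity and conservative-substitution
# percentages by taxon group, mapped to reference residue numbering.
# "Conservative" means a non-identical letter with positive BLOSUM62 score
# against the reference letter (the closest reconstructable analogue of
# BLASTP "positives"); gaps and X count as plain mismatches.

.hs_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.hs_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .hs_env$blosum62 <- e$BLOSUM62
  }
  .hs_env$blosum62
}

## letters scoring > 0 against ref (excluding ref itself), standard AAs only
conservative_letters <- function(ref) {
  B <- blosum62()
  aa <- intersect(rownames(B), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  if (!ref %in% aa) return(character(0))
  setdiff(aa[B[ref, aa] > 0], ref)
}

#' Read an aligned FASTA with taxon-group labels
#'
#' Row 1 is the reference sequence. All rows must have equal length;
#' letters are upper-cased. Groups come from a sidecar table (`id`,
#' `group`) or a named character vector keyed by the first token of each
#' FASTA header.
#'
#' @param path aligned FASTA file.
#' @param groups data.frame with columns `id` and `group`, or a named
#'   character vector; `NULL` puts every sequence in group "all".
#' @return An `msa` object: list with `seqs` (character matrix `n x L`),
#'   `ids`, `groups` (character vector per sequence).
#' @export
read_alignment <- function(path, groups = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stopf("%s: empty alignment", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1)
    stopf("%s: ragged alignment (row lengths %s)", path,
          paste(unique(w), collapse = ", "))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  mat <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(mat) <- ids
  msa_object(mat, ids, groups)
}

msa_object <- function(mat, ids, groups = NULL) {
  grp <- if (is.null(groups)) {
    rep("all", length(ids))
  } else if (is.data.frame(groups)) {
    g <- groups$group[match(ids, groups$id)]
    if (anyNA(g)) stopf("no group label for sequence(s): %s",
                        paste(ids[is.na(g)], collapse = ", "))
    as.character(g)
  } else {
    g <- unname(groups[ids])
    if (anyNA(g)) stopf("no group label for sequence(s): %s",
                        paste(ids[is.na(g)], collapse = ", "))
    g
  }
  structure(list(seqs = mat, ids = ids, groups = grp), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns; groups: %s\n",
              nrow(x$seqs), ncol(x$seqs),
              paste(sprintf("%s (%d)", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Map alignment columns to reference residue numbers
#'
#' Non-gap positions of the reference row are numbered 1..L in order; gap
#' columns are unmapped (NA).
#'
#' @param msa an `msa`.
#' @return Integer vector, one entry per column (NA where the reference has
#'   a gap).
#' @export
map_columns <- function(msa) {
  ref <- msa$seqs[1, ]
  nongap <- ref != "-" & ref != "."
  if (!any(nongap)) warnf("reference row is all gaps")
  m <- rep(NA_integer_, length(ref))
  m[nongap] <- seq_len(sum(nongap))
  m
}

#' Identity and conservative-substitution percentages of one column
#'
#' Identity is the percentage of group sequences matching the reference
#' letter; conservative is the percentage that differ but score > 0 in
#' BLOSUM62 against it. Gaps and X count in the denominator as plain
#' mismatches, so identity + conservative <= 100.
#'
#' @param msa an `msa`.
#' @param column alignment column index.
#' @param group taxon group label (must be non-empty in the alignment).
#' @param exclude_reference drop row 1 from the tally (default TRUE).
#' @return Named numeric: `identity_pct`, `conservative_pct`, `n`.
#' @export
column_stats <- function(msa, column, group, exclude_reference = TRUE) {
  ref <- msa$seqs[1, column]
  if (ref %in% c("-", ".")) stopf("reference has a gap at column %d", column)
  rows <- which(msa$groups == group)
  if (exclude_reference) rows <- setdiff(rows, 1L)
  if (length(rows) == 0) stopf("group '%s' is empty", group)
  col <- msa$seqs[rows, column]
  ident <- mean(col == ref)
  cons <- mean(col %in% conservative_letters(ref))
  c(identity_pct = 100 * ident, conservative_pct = 100 * cons,
    n = length(rows))
}

#' Conservation profile over all reference residues and groups
#'
#' @param msa an `msa`.
#' @param groups group labels to profile (default: all present).
#' @return A `conservation_profile` data.frame: `residue`, `column`,
#'   `group`, `n`, `identity_pct`, `conservative_pct`, `combined_pct`.
#' @export
conservation_profile <- function(msa, groups = NULL) {
  groups <- groups %||% unique(msa$groups)
  cmap <- map_columns(msa)
  cols <- which(!is.na(cmap))
  out <- do.call(rbind, lapply(groups, function(g) {
    st <- vapply(cols, function(j) column_stats(msa, j, g), numeric(3))
    data.frame(residue = cmap[cols], column = cols, group = g,
               n = st[3, ], identity_pct = st[1, ],
               conservative_pct = st[2, ],
               combined_pct = st[1, ] + st[2, ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Flag residues conserved across required taxon groups
#'
#' In `"identity"` mode a residue passes when its identity percentage
#' reaches `identity_min` in every required group; `"combined"` mode uses
#' identity + conservative substitutions. Thresholds are non-strict (a
#' residue printed at exactly the threshold passes, matching how published
#' conservation tables highlight their rows).
#'
#' @param profile a `conservation_profile` (any data.frame with columns
#'   `residue`, `group`, `identity_pct`, `conservative_pct` works, so
#'   printed literature tables can be fed directly).
#' @param identity_min threshold, percent.
#' @param groups_required groups that must all pass.
#' @param mode `"identity"` or `"combined"`.
#' @return Sorted integer residue numbers.
#' @export
flag_conserved <- function(profile, identity_min = 90,
                           groups_required = c("bacteria", "animals"),
                           mode = c("identity", "combined")) {
  mode <- match.arg(mode)
  miss <- setdiff(groups_required, unique(profile$group))
  if (length(miss)) stopf("profile lacks group(s): %s", paste(miss, collapse = ", "))
  if (is.null(profile$combined_pct))
    profile$combined_pct <- profile$identity_pct + profile$conservative_pct
  val <- if (mode == "identity") profile$identity_pct else profile$combined_pct
  keep <- profile$group %in% groups_required
  pass <- tapply(val[keep] >= identity_min, profile$residue[keep], all)
  sort(as.integer(names(pass)[pass]))
}
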