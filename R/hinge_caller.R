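# Combine torsion multimodality, state shifts, nucleotide-correlation
# tallies, conservation and ligand proximity into a ranked hinge report.

#' Build a per-residue hinge evidence report
#'
#' Evidence tiers: A = multimodal, state-shifted and tally-significant;
#' B = multimodal plus one of the two; C = multimodal only; "none"
#' otherwise. Adding evidence can only raise a tier.
#'
#' @param multimodal integer residues with >= 2 phi/psi modes (union over
#'   states), or a named list of per-state residue sets.
#' @param shifts data.frame from [compare_states()] (or a named list of
#'   them, one per state pair; a residue is shifted if shifted in any
#'   pair).
#' @param tally a [tally_runs()] result (may be NULL).
#' @param conservation a [conservation_profile()] (may be NULL).
#' @param distances a [distance_to_ligand()] result (may be NULL).
#' @param universe residue numbers the report covers; default: union of
#'   the inputs.
#' @param identity_min conservation threshold passed to [flag_conserved()].
#' @param groups_required conservation groups that must pass.
#' @return A `hinge_report`: list with `table` (one row per residue) and
#'   `params`.
#' @export
build_report <- function(multimodal, shifts = NULL, tally = NULL,
                         conservation = NULL, distances = NULL,
                         universe = NULL, identity_min = 90,
                         groups_required = c("bacteria", "animals")) {
  if (is.list(multimodal) && !is.data.frame(multimodal))
    multimodal <- sort(unique(unlist(multimodal)))
  shift_tab <- NULL
  if (!is.null(shifts)) {
    if (is.data.frame(shifts)) shifts <- list(shifts)
    shift_tab <- do.call(rbind, lapply(names(shifts) %||% seq_along(shifts),
      function(nm) cbind(shifts[[nm]], pair = as.character(nm))))
  }
  universe <- universe %||% sort(unique(c(
    multimodal, shift_tab$residue, tally$residue,
    conservation$residue, distances$resno)))
  tab <- data.frame(residue = universe)
  tab$multimodal <- tab$residue %in% multimodal
  if (!is.null(shift_tab)) {
    sh <- shift_tab[shift_tab$shifted, , drop = FALSE]
    tab$state_shifted <- tab$residue %in% sh$residue
    tab$shift_pairs <- vapply(tab$residue, function(r)
      paste(unique(sh$pair[sh$residue == r]), collapse = ";"), character(1))
  } else {
    tab$state_shifted <- FALSE
    tab$shift_pairs <- ""
  }
  if (!is.null(tally)) {
    i <- match(tab$residue, tally$residue)
    tab$tally <- ifelse(is.na(i), 0L, tally$count[i])
    tab$tally_significant <- !is.na(i) & tally$significant[i]
  } else {
    tab$tally <- NA_integer_
    tab$tally_significant <- FALSE
  }
  cons_note <- "not evaluated"
  tab$conserved_identity <- NA
  tab$conserved_combined <- NA
  if (!is.null(conservation)) {
    cons_note <- sprintf(">= %g%% in %s", identity_min,
                         paste(groups_required, collapse = " & "))
    id_set <- flag_conserved(conservation, identity_min, groups_required,
                             mode = "identity")
    cb_set <- flag_conserved(conservation, identity_min, groups_required,
                             mode = "combined")
    known <- unique(conservation$residue)
    tab$conserved_identity <- ifelse(tab$residue %in% known,
                                     tab$residue %in% id_set, NA)
    tab$conserved_combined <- ifelse(tab$residue %in% known,
                                     tab$residue %in% cb_set, NA)
  }
  if (!is.null(distances)) {
    i <- match(tab$residue, distances$resno)
    tab$ligand_distance <- distances$distance[i]
    tab$near_ligand <- distances$near[i]
  } else {
    tab$ligand_distance <- NA_real_
    tab$near_ligand <- NA
  }
  tab$tier <- with(tab, ifelse(
    multimodal & state_shifted & tally_significant, "A",
    ifelse(multimodal & (state_shifted | tally_significant), "B",
           ifelse(multimodal, "C", "none"))))
  structure(list(table = tab,
                 params = list(identity_min = identity_min,
                               groups_required = groups_required,
                               conservation = cons_note)),
            class = "hinge_report")
}

#' @export
print.hinge_report <- function(x, ...) {
  t <- x$table
  cat(sprintf("hinge report: %d residues; tiers A/B/C: %d/%d/%d; conservation rule: %s\n",
              nrow(t), sum(t$tier == "A"), sum(t$tier == "B"),
              sum(t$tier == "C"), x$params$conservation))
  invisible(x)
}

#' Select hinge-mutation candidates from a report
#'
#' Keeps residues that are multimodal (unless disabled) and pass the
#' requested conservation rule, sorted by evidence tier then residue
#' number. The rule text is attached to the result so reports stay
#' self-describing.
#'
#' @param report a `hinge_report` built with a conservation profile.
#' @param rule `"identity"` or `"combined"` conservation mode.
#' @param require_multimodal require >= 2 phi/psi modes (default TRUE).
#' @return data.frame `residue`, `tier`; attribute `"rule"` echoes the
#'   selection rule.
#' @export
select_candidates <- function(report, rule = c("identity", "combined"),
                              require_multimodal = TRUE) {
  rule <- match.arg(rule)
  t <- report$table
  col <- paste0("conserved_", rule)
  keep <- !is.na(t[[col]]) & t[[col]]
  if (require_multimodal) keep <- keep & t$multimodal
  out <- t[keep, c("residue", "tier")]
  out <- out[order(out$tier, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rule") <- sprintf(
    "conservation %s (%s), require_multimodal=%s",
    rule, report$params$conservation, require_multimodal)
  out
}

#' Split candidates by nucleotide-correlation significance
#'
#' @param report a `hinge_report`.
#' @param candidates residue numbers (or a [select_candidates()] result).
#' @return List with `correlated` and `uncorrelated` residue vectors.
#' @export
group_candidates <- function(report, candidates) {
  if (is.data.frame(candidates)) candidates <- candidates$residue
  bad <- setdiff(candidates, report$table$residue)
  if (length(bad)) stopf("candidate(s) outside the report universe: %s",
                         paste(bad, collapse = ", "))
  sig <- report$table$residue[report$table$tally_significant]
  list(correlated = sort(intersect(candidates, sig)),
       uncorrelated = sort(setdiff(candidates, sig)))
}
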