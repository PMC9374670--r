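#' Define a design target region
#'
#' A target region is a stretch of (usually disordered) protein sequence
#' against which peptides are designed.  `numbering_offset` is the
#' biological residue number of the first character, so that reported
#' complementary windows use the numbering of the full-length protein.
#'
#' @param sequence One-letter amino-acid string (canonical residues only).
#' @param identifier Free-text identifier.
#' @param numbering_offset Residue number of the first character (1-based).
#' @return An object of class `target_region`.
#' @export
target_region <- function(sequence, identifier = "target",
                          numbering_offset = 1L) {
  residues <- split_residues(sequence, context = identifier)
  if (length(residues) == 0L) stop("empty target sequence", call. = FALSE)
  structure(list(identifier = identifier,
                 sequence = paste(residues, collapse = ""),
                 residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  n <- length(x$residues)
  cat(sprintf("Target region '%s': %d residues (%d-%d)\n", x$identifier, n,
              x$numbering_offset, x$numbering_offset + n - 1L))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Design-run parameters
#'
#' @param peptide_length Number of residues in the designed peptide
#'   (commonly 10 or 16).
#' @param mode `"OO"` (score each peptide residue against the single
#'   aligned target residue) or `"OT"` (against the aligned residue plus
#'   its two sequence neighbours).
#' @param gly_to_ala If `TRUE` (default), glycine is removed from the
#'   candidate set so that alanine is emitted wherever the bare score would
#'   pick either; appropriate for side-chain-derived energy tables whose G
#'   entries reflect a near-absent side chain.  With `FALSE` both are
#'   candidates and exact A/G ties still resolve to A via alphabet order.
#' @param max_single_residue_fraction Optional composition cap in (0, 1]:
#'   the most frequent residue of the selected peptide may not exceed this
#'   fraction.  `NULL` (default) disables the cap and reproduces the raw
#'   minimum-energy design.
#' @param delta_e Energy tolerance (kcal/mol, >= 0) defining the
#'   near-minimum set searched when the composition cap is active.
#' @param top_k Number of candidates included in selection reports.
#' @param ot_edge `"margin"` (default) restricts OT windows so every
#'   aligned target residue has both neighbours; `"truncate"` admits edge
#'   windows and simply drops the missing neighbour term.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(peptide_length = 10L,
                        mode = c("OO", "OT"),
                        gly_to_ala = TRUE,
                        max_single_residue_fraction = NULL,
                        delta_e = 0,
                        top_k = 5L,
                        ot_edge = c("margin", "truncate")) {
  mode <- match.arg(mode)
  ot_edge <- match.arg(ot_edge)
  peptide_length <- as.integer(peptide_length)
  if (peptide_length < 1L) stop("peptide_length must be >= 1", call. = FALSE)
  if (delta_e < 0) stop("delta_e must be >= 0", call. = FALSE)
  if (!is.null(max_single_residue_fraction)) {
    f <- max_single_residue_fraction
    if (!(f > 0 && f <= 1)) {
      stop("max_single_residue_fraction must be in (0, 1]", call. = FALSE)
    }
  }
  structure(list(peptide_length = peptide_length, mode = mode,
                 gly_to_ala = gly_to_ala,
                 max_single_residue_fraction = max_single_residue_fraction,
                 delta_e = delta_e, top_k = as.integer(top_k),
                 ot_edge = ot_edge),
            class = "design_spec")
}

# internal: candidate residues under a spec (G dropped when gly_to_ala)
candidate_residues <- function(spec) {
  ab <- aa_alphabet()
  if (isTRUE(spec$gly_to_ala)) ab[ab != "G"] else ab
}

# internal: admissible window starts (sequence coordinates, 1-based)
admissible_starts <- function(target, spec) {
  n <- length(target$residues)
  L <- spec$peptide_length
  if (spec$mode == "OT" && spec$ot_edge == "margin") {
    lo <- 2L; hi <- n - L  # window end <= n - 1
  } else {
    lo <- 1L; hi <- n - L + 1L
  }
  if (hi < lo) {
    stop(sprintf("target '%s' (%d residues) admits no window of length %d in %s mode",
                 target$identifier, n, L, spec$mode), call. = FALSE)
  }
  lo:hi
}

#' Score one candidate residue at one peptide position
#'
#' In OO mode the score of placing `candidate` at peptide position
#' `peptide_pos` in the window starting at `window_start` is the relative
#' contact energy against the aligned target residue
#' `t[window_start + peptide_pos - 1]`.  In OT mode the energies against
#' that residue's two sequence neighbours are added.  The peptide is
#' aligned parallel to the target (N to C).
#'
#' @param rel A `relative_energy_table`.
#' @param target A `target_region`.
#' @param window_start Window start in target sequence coordinates.
#' @param peptide_pos Position within the peptide (1..length).
#' @param candidate Candidate residue (one-letter code).
#' @param mode `"OO"` or `"OT"`.
#' @param ot_edge See [design_spec()].
#' @return Score in kcal/mol (lower = more favourable).
#' @export
position_score <- function(rel, target, window_start, peptide_pos, candidate,
                           mode = c("OO", "OT"), ot_edge = c("margin", "truncate")) {
  mode <- match.arg(mode)
  ot_edge <- match.arg(ot_edge)
  assert_residues(candidate, "candidate")
  n <- length(target$residues)
  i <- window_start + peptide_pos - 1L
  if (i < 1L || i > n) stop("window out of range", call. = FALSE)
  e <- rel$energies
  ti <- target$residues[i]
  if (mode == "OO") return(e[ti, candidate])
  idx <- c(i - 1L, i, i + 1L)
  if (ot_edge == "margin") {
    if (i == 1L || i == n) {
      stop("OT window touches a sequence end (use ot_edge = \"truncate\" to allow)",
           call. = FALSE)
    }
  } else {
    idx <- idx[idx >= 1L & idx <= n]
  }
  sum(e[target$residues[idx], candidate])
}

#' Design the minimum-energy peptide for one target window
#'
#' Each peptide position is optimised independently: the candidate residue
#' minimising [position_score()] is chosen, with exact ties broken by
#' alphabet order (so A is preferred over G when both are candidates).
#' Because positions do not interact, this greedy per-position argmin is
#' the exact optimum over all sequences of the window.
#'
#' @param rel A `relative_energy_table`.
#' @param target A `target_region`.
#' @param window_start Window start (target sequence coordinates).
#' @param spec A `design_spec`.
#' @return A `design_result`: `peptide`, `target_start`/`target_end`
#'   (biological numbering), `per_position` data frame (position, target
#'   residue, chosen residue, energy), `total_energy`, `constrained`.
#' @export
design_window <- function(rel, target, window_start, spec = design_spec()) {
  starts <- admissible_starts(target, spec)
  if (!(window_start %in% starts)) {
    stop(sprintf("window start %d does not fit target '%s' (admissible: %d-%d)",
                 window_start, target$identifier, min(starts), max(starts)),
         call. = FALSE)
  }
  cands <- candidate_residues(spec)
  e <- rel$energies
  n <- length(target$residues)
  L <- spec$peptide_length
  chosen <- character(L)
  energy <- numeric(L)
  tres <- character(L)
  for (p in seq_len(L)) {
    i <- window_start + p - 1L
    if (spec$mode == "OO") {
      scores <- e[target$residues[i], cands]
    } else {
      idx <- c(i - 1L, i, i + 1L)
      idx <- idx[idx >= 1L & idx <= n]
      scores <- colSums(e[target$residues[idx], cands, drop = FALSE])
    }
    best <- which.min(scores)  # first minimum = alphabetical tie-break
    chosen[p] <- cands[best]
    energy[p] <- scores[best]
    tres[p] <- target$residues[i]
  }
  off <- target$numbering_offset
  structure(list(
    peptide = paste(chosen, collapse = ""),
    window_start = as.integer(window_start),
    target_start = off + window_start - 1L,
    target_end = off + window_start + L - 2L,
    per_position = data.frame(position = seq_len(L), target_residue = tres,
                              residue = chosen, energy = energy,
                              stringsAsFactors = FALSE),
    total_energy = sum(energy),
    mode = spec$mode,
    constrained = FALSE),
    class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("%s design %s vs target %d-%d: total %.3f kcal/mol%s\n",
              x$mode, x$peptide, x$target_start, x$target_end,
              x$total_energy,
              if (isTRUE(x$constrained)) " [composition-constrained]" else ""))
  invisible(x)
}

#' Scan all registers of a target and design each
#'
#' Designs one peptide per admissible window start and returns the results
#' sorted by ascending total energy (ties: smaller start first).
#'
#' @inheritParams design_window
#' @return List of `design_result`, best first.
#' @export
scan_designs <- function(rel, target, spec = design_spec()) {
  starts <- admissible_starts(target, spec)
  results <- lapply(starts, function(s) design_window(rel, target, s, spec))
  energies <- vapply(results, `[[`, numeric(1), "total_energy")
  results[order(energies, starts)]
}

# internal: fraction of the most frequent residue in a peptide
max_residue_fraction <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  max(table(chars)) / length(chars)
}

#' Select a design, optionally enforcing residue diversity
#'
#' Minimum-contact-energy designs over charge-biased IDRs can collapse to
#' homopolymers (e.g. all-arginine), which trades specificity for raw
#' affinity.  With a composition cap set, the lowest-energy scanned design
#' within `delta_e` of the global minimum whose most frequent residue does
#' not exceed `max_single_residue_fraction` is selected instead, and
#' flagged `constrained`.
#'
#' @param results List of `design_result` from [scan_designs()].
#' @param spec The `design_spec` used (supplies the cap, `delta_e`,
#'   `top_k`).
#' @return The selected `design_result`, with attribute `"report"`: a data
#'   frame of the `top_k` lowest-energy candidates (peptide, window,
#'   total energy, max residue fraction, most frequent residue).
#' @export
select_candidate <- function(results, spec = design_spec()) {
  if (length(results) == 0L) stop("no design results to select from", call. = FALSE)
  energies <- vapply(results, `[[`, numeric(1), "total_energy")
  ord <- order(energies)
  results <- results[ord]; energies <- energies[ord]
  fracs <- vapply(results, function(r) max_residue_fraction(r$peptide), numeric(1))
  modal <- vapply(results, function(r) {
    tab <- table(strsplit(r$peptide, "", fixed = TRUE)[[1L]])
    names(tab)[which.max(tab)]
  }, character(1))
  k <- min(spec$top_k, length(results))
  report <- data.frame(
    peptide = vapply(results[seq_len(k)], `[[`, character(1), "peptide"),
    target_start = vapply(results[seq_len(k)], `[[`, integer(1), "target_start"),
    target_end = vapply(results[seq_len(k)], `[[`, integer(1), "target_end"),
    total_energy = energies[seq_len(k)],
    max_residue_fraction = fracs[seq_len(k)],
    modal_residue = modal[seq_len(k)],
    stringsAsFactors = FALSE)

  cap <- spec$max_single_residue_fraction
  if (is.null(cap)) {
    sel <- results[[1L]]
  } else {
    near <- which(energies <= energies[1L] + spec$delta_e)
    ok <- near[fracs[near] <= cap]
    if (length(ok) == 0L) {
      best_miss <- near[which.min(fracs[near])]
      stop(sprintf(
        paste0("no design within delta_e = %g kcal/mol satisfies max residue ",
               "fraction <= %g (nearest miss: %s, fraction %.2f, %.3f kcal/mol ",
               "above minimum)"),
        spec$delta_e, cap, results[[best_miss]]$peptide, fracs[best_miss],
        energies[best_miss] - energies[1L]), call. = FALSE)
    }
    sel <- results[[ok[1L]]]
    sel$constrained <- TRUE
  }
  attr(sel, "report") <- report
  sel
}

#' Biological residue-number range a design is complementary to
#'
#' @param result A `design_result`.
#' @return Integer vector `c(start, end)` in biological numbering.
#' @export
complementary_window <- function(result) {
  stopifnot(inherits(result, "design_result"))
  c(start = result$target_start, end = result$target_end)
}
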