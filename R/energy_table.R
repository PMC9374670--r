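#' Construct a residue-pair contact-energy table
#'
#' A contact-energy table holds the effective pairwise contact free energy
#' `e_ij` (kcal/mol) for every unordered pair of the 20 amino-acid types
#' (210 pairs, stored as a symmetric 20x20 matrix in alphabet order).
#'
#' @param energies Symmetric 20x20 numeric matrix with dimnames equal to
#'   [aa_alphabet()] in order; all values finite.  Small asymmetries (below
#'   `tol`) are averaged away; larger ones are an error.
#' @param source_tag Provenance class of the energies: `"md_side_chain"`,
#'   `"md_whole"`, `"structure_3d"` or `"user"`.
#' @param label Free-text provenance note.
#' @param tol Largest tolerated `|e_ij - e_ji|` before erroring.
#' @return An object of class `contact_energy_table` with elements
#'   `energies`, `source_tag`, `label`.
#' @seealso [load_energy_table()], [mean_energies()], [relative_energy_table()]
#' @export
contact_energy_table <- function(energies,
                                 source_tag = c("user", "md_side_chain",
                                                "md_whole", "structure_3d"),
                                 label = "",
                                 tol = 1e-8) {
  source_tag <- match.arg(source_tag)
  ab <- aa_alphabet()
  if (!is.matrix(energies) || !is.numeric(energies) ||
      nrow(energies) != 20L || ncol(energies) != 20L) {
    stop("'energies' must be a numeric 20x20 matrix", call. = FALSE)
  }
  if (is.null(dimnames(energies))) {
    dimnames(energies) <- list(ab, ab)
  }
  assert_residues(rownames(energies), "row")
  assert_residues(colnames(energies), "column")
  if (anyDuplicated(rownames(energies)) || anyDuplicated(colnames(energies))) {
    stop("duplicated residue codes in table dimnames", call. = FALSE)
  }
  energies <- energies[ab, ab]
  nonfin <- which(!is.finite(energies), arr.ind = TRUE)
  if (nrow(nonfin) > 0L) {
    stop(sprintf("non-finite energy for pair (%s, %s)",
                 ab[nonfin[1L, 1L]], ab[nonfin[1L, 2L]]), call. = FALSE)
  }
  asym <- abs(energies - t(energies))
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "asymmetric table: |e(%s,%s) - e(%s,%s)| = %.3g exceeds tolerance %g",
      ab[idx[1L]], ab[idx[2L]], ab[idx[2L]], ab[idx[1L]],
      max(asym), tol), call. = FALSE)
  }
  energies <- (energies + t(energies)) / 2
  structure(list(energies = energies, source_tag = source_tag, label = label),
            class = "contact_energy_table")
}

#' @export
print.contact_energy_table <- function(x, ...) {
  cat(sprintf("Contact-energy table [%s] %s\n", x$source_tag,
              if (nzchar(x$label)) x$label else ""))
  cat(sprintf("  210 unordered pairs, kcal/mol; range [%.3f, %.3f]\n",
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Read a contact-energy table from a TSV file
#'
#' The dialect is: optional `#`-prefixed metadata lines (recognised keys:
#' `units:` with value `kcal/mol`, `kJ/mol` or `RT`; anything else is kept
#' as the label), a header row of one-letter codes, then one row per
#' residue (first column the code, remaining columns tab-separated numeric
#' cells).  Both full square matrices and triangular ones (lower or upper;
#' missing cells empty or `NA`) are accepted; triangular input is mirrored.
#' `kJ/mol` values are divided by 4.184 and `RT` values multiplied by
#' 0.593 (kT at 298 K) so that tables are always held in kcal/mol.
#'
#' @param path File path.
#' @param source_tag Provenance tag, see [contact_energy_table()].
#' @param tol Asymmetry tolerance for square input.
#' @return A `contact_energy_table`.
#' @export
load_energy_table <- function(path, source_tag = "user", tol = 1e-8) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("energy table file has no data rows", call. = FALSE)

  units <- "kcal/mol"
  label <- ""
  for (m in meta) {
    m2 <- trimws(sub("^#+", "", m))
    if (grepl("^units:", m2)) units <- trimws(sub("^units:", "", m2))
    if (grepl("^source:", m2)) label <- trimws(sub("^source:", "", m2))
  }
  factor <- switch(units,
                   "kcal/mol" = 1,
                   "kJ/mol"   = 1 / 4.184,
                   "RT"       = 0.593,
                   stop(sprintf("unsupported units '%s'", units), call. = FALSE))

  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  header <- trimws(header[nzchar(trimws(header))])
  assert_residues(header, "header")
  n <- length(header)

  ab <- aa_alphabet()
  acc <- matrix(NA_real_, 20L, 20L, dimnames = list(ab, ab))
  for (row in body[-1L]) {
    cells <- strsplit(row, "\t", fixed = TRUE)[[1L]]
    code <- trimws(cells[1L])
    assert_residues(code, "row")
    vals <- trimws(cells[-1L])
    for (k in seq_along(vals)) {
      if (k > n) stop(sprintf("row %s has more cells than header columns", code),
                      call. = FALSE)
      v <- vals[k]
      if (!nzchar(v) || toupper(v) == "NA") next
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) {
        stop(sprintf("non-numeric cell '%s' at row %s, column %s",
                     v, code, header[k]), call. = FALSE)
      }
      acc[code, header[k]] <- num * factor
    }
  }

  # mirror triangular input; detect asymmetric square input
  for (i in seq_len(20L)) {
    for (j in seq_len(20L)) {
      a <- acc[i, j]; b <- acc[j, i]
      if (is.na(a) && !is.na(b)) acc[i, j] <- b
    }
  }
  missing <- which(is.na(acc), arr.ind = TRUE)
  if (nrow(missing) > 0L) {
    pair <- sort(c(ab[missing[1L, 1L]], ab[missing[1L, 2L]]))
    stop(sprintf("missing energy for pair (%s, %s)", pair[1L], pair[2L]),
         call. = FALSE)
  }
  contact_energy_table(acc, source_tag = source_tag, label = label, tol = tol)
}

#' Write a contact-energy table to TSV
#'
#' Emits the full square matrix in the dialect read by
#' [load_energy_table()], always in kcal/mol, with full `%.17g` precision
#' so that a save/load round trip is bit-identical.
#'
#' @param table A `contact_energy_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_energy_table <- function(table, path) {
  stopifnot(inherits(table, "contact_energy_table"))
  ab <- aa_alphabet()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: kcal/mol",
               sprintf("# source: %s", table$label),
               sprintf("# source_tag: %s", table$source_tag)), con)
  writeLines(paste(c("", ab), collapse = "\t"), con)
  for (i in ab) {
    writeLines(paste(c(i, sprintf("%.17g", table$energies[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Mean contact energies against the average residue
#'
#' For a complete table, the mean energy of residue `i` against the
#' "average residue" r is `e_ir = sum_j e_ij / 20` (the self pair counted
#' once, like any other partner) and the global mean is
#' `e_rr = sum_i e_ir / 20`.  For 3D structure-derived tables these
#' reference values are usually taken from the original publication rather
#' than recomputed; supply them through `per_residue` / `global` in that
#' case and the mode is recorded as `"externally_supplied"`.
#'
#' @param table A `contact_energy_table`.
#' @param per_residue Optional named numeric vector of 20 externally
#'   supplied `e_ir` values (names = one-letter codes).
#' @param global Optional externally supplied `e_rr`; required when
#'   `per_residue` is given.
#' @return An object of class `mean_energies` with elements `per_residue`
#'   (named 20-vector, kcal/mol), `global` (kcal/mol) and `mode`.
#' @export
mean_energies <- function(table, per_residue = NULL, global = NULL) {
  stopifnot(inherits(table, "contact_energy_table"))
  ab <- aa_alphabet()
  if (is.null(per_residue)) {
    e_ir <- rowMeans(table$energies)
    e_rr <- mean(e_ir)
    mode <- "computed_from_table"
  } else {
    if (is.null(global)) {
      stop("'global' (e_rr) must be supplied along with 'per_residue'",
           call. = FALSE)
    }
    assert_residues(names(per_residue), "per_residue name")
    if (length(per_residue) != 20L) {
      stop("'per_residue' must hold all 20 residues", call. = FALSE)
    }
    e_ir <- per_residue[ab]
    e_rr <- as.numeric(global)
    mode <- "externally_supplied"
  }
  structure(list(per_residue = e_ir, global = e_rr, mode = mode),
            class = "mean_energies")
}

#' Relative contact energies referenced to the average residue
#'
#' Transforms a raw contact-energy table into relative energies
#' `e~_ij = e_ij + e_rr - e_ir - e_jr`, which subtract out the additive
#' per-residue ("stickiness") component so that only genuinely pair-specific
#' preferences remain.  When the means were computed from the table itself,
#' the 400 ordered entries of the result average to exactly zero.
#'
#' @param table A `contact_energy_table`.
#' @param means A `mean_energies` object, by default computed from `table`.
#' @return An object of class `relative_energy_table` with elements
#'   `energies` (symmetric 20x20 matrix, kcal/mol), `source_tag`, `label`
#'   and `means_mode`.
#' @export
relative_energy_table <- function(table, means = mean_energies(table)) {
  stopifnot(inherits(table, "contact_energy_table"),
            inherits(means, "mean_energies"))
  ab <- aa_alphabet()
  if (!identical(names(means$per_residue), ab)) {
    stop("alphabet mismatch between table and mean energies", call. = FALSE)
  }
  e_ir <- means$per_residue
  rel <- table$energies + means$global - outer(e_ir, rep(1, 20L)) -
    outer(rep(1, 20L), e_ir)
  dimnames(rel) <- list(ab, ab)
  structure(list(energies = rel, source_tag = table$source_tag,
                 label = table$label, means_mode = means$mode),
            class = "relative_energy_table")
}

#' @export
print.relative_energy_table <- function(x, ...) {
  cat(sprintf("Relative contact-energy table [%s] (means %s)\n",
              x$source_tag, x$means_mode))
  cat(sprintf("  range [%.3f, %.3f] kcal/mol\n",
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Pearson correlation between two energy tables
#'
#' Correlates the entries of two (typically relative) energy tables over
#' the same alphabet.  By default only the 210 unique unordered-pair
#' entries enter the correlation; `entries = "full"` uses all 400 ordered
#' entries instead (which double-counts off-diagonal pairs but leaves the
#' coefficient almost unchanged for symmetric tables).
#'
#' @param a,b Objects with a 20x20 `$energies` matrix
#'   (`contact_energy_table` or `relative_energy_table`).
#' @param entries `"unique"` (210 unordered pairs, default) or `"full"`
#'   (400 ordered entries).
#' @return Pearson correlation coefficient (scalar).
#' @export
table_correlation <- function(a, b, entries = c("unique", "full")) {
  entries <- match.arg(entries)
  ea <- a$energies; eb <- b$energies
  stopifnot(is.matrix(ea), is.matrix(eb),
            identical(dimnames(ea), dimnames(eb)))
  if (entries == "unique") {
    keep <- upper.tri(ea, diag = TRUE)
    va <- ea[keep]; vb <- eb[keep]
  } else {
    va <- as.vector(ea); vb <- as.vector(eb)
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance in at least one table; correlation undefined",
         call. = FALSE)
  }
  stats::cor(va, vb)
}
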