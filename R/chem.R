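# Monoisotopic mass arithmetic for peptides: residue masses from empirical
# formulas, neutral peptide masses, precursor m/z at z = 2 or 3, and singly
# charged b-/y-ion series.

# Empirical formula of each residue (amino acid minus one water), as element
# counts over C, H, N, O, S.
.residue_formulas <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

#' Chemical reference table for peptide mass computation
#'
#' Builds the table of elemental monoisotopic masses and residue empirical
#' formulas that all m/z arithmetic in the package draws from. Residue masses
#' are derived from the formulas at construction time (formula counts dotted
#' with the element masses), never stored independently, so the table is
#' internally consistent by construction.
#'
#' The element masses are monoisotopic: C 12.00000000, H 1.00782503,
#' N 14.00307401, O 15.99491462, plus S 31.97207117 so that masses remain
#' computable for cysteine/methionine peptides upstream of any composition
#' filter. The charge carrier is the proton (1.00727646 Da), i.e. the hydrogen
#' atom mass minus the electron mass; `proton_mass` is the single place to
#' change if the hydrogen-atom convention is wanted instead.
#'
#' @return An object of class `chem_table`: a list with `element_masses`
#'   (named numeric, Da), `residue_formulas` (named list of C/H/N/O/S counts),
#'   `residue_masses` (named numeric, Da, one per standard residue),
#'   `water_mass` and `proton_mass` (Da).
#' @examples
#' ct <- chem_table()
#' ct$residue_masses[["G"]]  # glycine residue, 57.02146372 Da
#' @export
chem_table <- function() {
  elements <- c(
    C = 12.00000000,
    H = 1.00782503,
    N = 14.00307401,
    O = 15.99491462,
    S = 31.97207117
  )
  residues <- vapply(
    .residue_formulas,
    function(f) sum(f * elements[names(f)]),
    numeric(1)
  )
  structure(
    list(
      element_masses   = elements,
      residue_formulas = .residue_formulas,
      residue_masses   = residues,
      water_mass       = 2 * elements[["H"]] + elements[["O"]],
      proton_mass      = 1.00727646
    ),
    class = "chem_table"
  )
}

#' @export
print.chem_table <- function(x, ...) {
  cat("<chem_table>\n")
  cat("  elements:", paste(names(x$element_masses), collapse = " "), "\n")
  cat("  residues:", length(x$residue_masses), "standard amino acids\n")
  cat(sprintf("  water %.8f Da, proton %.8f Da\n", x$water_mass, x$proton_mass))
  invisible(x)
}

# Split a peptide string into residue characters, rejecting anything outside
# the 20-letter alphabet (B, Z, X, U, O, '*', lower case already upper-cased
# at I/O time).
.residue_chars <- function(sequence, chem, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("`", what, "` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(chem$residue_masses))
  if (length(bad) > 0L) {
    stop(
      "unknown residue code(s) in ", what, ": ",
      paste0("'", bad, "'", collapse = ", "),
      call. = FALSE
    )
  }
  chars
}

#' Monoisotopic mass of a single residue
#'
#' @param residue One-letter code of a standard amino acid.
#' @param chem A [chem_table()].
#' @return Residue mass in Da (amino acid minus water).
#' @examples
#' residue_mass("G")  # 57.02146372
#' @export
residue_mass <- function(residue, chem = chem_table()) {
  chars <- .residue_chars(residue, chem, what = "residue")
  if (length(chars) != 1L) {
    stop("`residue` must be a single one-letter code", call. = FALSE)
  }
  unname(chem$residue_masses[chars])
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue masses plus one water.
#'
#' @param sequence Peptide sequence (one-letter codes). Vectorised.
#' @param chem A [chem_table()].
#' @return Numeric vector of neutral masses in Da.
#' @examples
#' peptide_neutral_mass("GAGAGAR")  # 558.28740820
#' @export
peptide_neutral_mass <- function(sequence, chem = chem_table()) {
  vapply(sequence, function(s) {
    chars <- .residue_chars(s, chem)
    sum(chem$residue_masses[chars]) + chem$water_mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Precursor ion m/z for a peptide
#'
#' Peptides selected for MS/MS on a triple quadrupole are doubly or triply
#' charged; only z = 2 and z = 3 are supported.
#'
#' @param sequence Peptide sequence(s).
#' @param charge Precursor charge state, 2 (default) or 3.
#' @param chem A [chem_table()].
#' @return A tibble with one row per peptide: `peptide_sequence`, `charge`,
#'   `neutral_mass`, `mz`.
#' @examples
#' precursor_mz("GAGAGAR", charge = 2)
#' @export
precursor_mz <- function(sequence, charge = 2L, chem = chem_table()) {
  if (length(charge) != 1L || !charge %in% c(2L, 3L)) {
    stop("`charge` must be 2 or 3", call. = FALSE)
  }
  charge <- as.integer(charge)
  neutral <- peptide_neutral_mass(sequence, chem)
  tibble::tibble(
    peptide_sequence = sequence,
    charge = charge,
    neutral_mass = neutral,
    mz = (neutral + charge * chem$proton_mass) / charge
  )
}

#' Singly charged b- and y-ion series of a peptide
#'
#' Amide-bond fragments: b-ions retain the N-terminus (prefix residue sums
#' plus a proton), y-ions retain the C-terminus (suffix residue sums plus
#' water plus a proton). For a peptide of length n the series runs b1..b(n-1)
#' and y1..y(n-1); the full-length b_n/y_n "fragments" are not ions of a
#' backbone cleavage and are not emitted. All product ions are singly charged.
#'
#' @param sequence Peptide sequence of length >= 2.
#' @param chem A [chem_table()].
#' @return A tibble with `2 * (n - 1)` rows: `series` ("b" or "y"), `index`,
#'   `charge` (always 1), `mz`, sorted b before y, then by index.
#' @examples
#' ion_series("GAGAGAR")
#' @export
ion_series <- function(sequence, chem = chem_table()) {
  chars <- .residue_chars(sequence, chem)
  n <- length(chars)
  if (n < 2L) {
    stop("`sequence` must have at least 2 residues to fragment", call. = FALSE)
  }
  masses <- unname(chem$residue_masses[chars])
  prefix <- cumsum(masses)[seq_len(n - 1L)]
  suffix <- cumsum(rev(masses))[seq_len(n - 1L)]
  tibble::tibble(
    series = rep(c("b", "y"), each = n - 1L),
    index = rep(seq_len(n - 1L), times = 2L),
    charge = 1L,
    mz = c(
      prefix + chem$proton_mass,
      suffix + chem$water_mass + chem$proton_mass
    )
  )
}
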