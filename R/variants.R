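# Variant-bearing peptide discovery: apply one single-residue substitution at
# a time, re-digest the mutant sequence, and keep only the peptides whose
# span covers the substituted position. A substitution can create or destroy
# cleavage sites (gaining a K/R, losing one, or introducing a proline after
# one), so the mutant is always digested from scratch rather than patching
# the wild-type peptide list.

#' Read a variant table (TSV)
#'
#' Loads single-residue substitutions from a tab-separated file with a header
#' row and columns `protein_id`, `position` (1-based), `wt`, `alt`, and
#' optionally `label`. Missing labels are filled as `"<wt><position><alt>"`
#' (e.g. `"P6L"`). When `proteins` is supplied every record is validated
#' against the sequences (see [validate_variants()]).
#'
#' @param path Path to the TSV file.
#' @param proteins Optional protein table to validate against.
#' @return A tibble with columns `protein_id`, `position`, `wt`, `alt`,
#'   `label`.
#' @export
read_variants <- function(path, proteins = NULL) {
  variants <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      position = readr::col_integer(),
      wt = readr::col_character(),
      alt = readr::col_character(),
      .default = readr::col_character()
    )
  )
  required <- c("protein_id", "position", "wt", "alt")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0L) {
    stop("variant table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(variants)) {
    variants$label <- NA_character_
  }
  variants$label <- dplyr::coalesce(
    variants$label,
    sprintf("%s%d%s", variants$wt, variants$position, variants$alt)
  )
  variants <- dplyr::select(variants, "protein_id", "position", "wt", "alt",
                            "label")
  if (!is.null(proteins)) {
    validate_variants(variants, proteins)
  }
  variants
}

#' Validate a variant table against protein sequences
#'
#' Checks that each record names a loaded protein, that `position` is within
#' the sequence, that the stated wild-type residue matches the sequence at
#' that position, that `wt != alt`, and that both residues are single
#' standard amino acids -- multi-residue values (insertions, deletions,
#' frameshifts) are rejected: only substitutions are supported.
#'
#' @param variants A tibble as returned by [read_variants()].
#' @param proteins A protein table (`protein_id`, `sequence`).
#' @param chem A [chem_table()], for the residue alphabet.
#' @return `variants`, invisibly, if all records pass.
#' @export
validate_variants <- function(variants, proteins, chem = chem_table()) {
  proteins <- .as_protein_tbl(proteins)
  unknown <- setdiff(unique(variants$protein_id), proteins$protein_id)
  if (length(unknown) > 0L) {
    stop("variant table references unknown protein id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  alphabet <- names(chem$residue_masses)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (nchar(v$wt) != 1L || nchar(v$alt) != 1L ||
        !v$wt %in% alphabet || !v$alt %in% alphabet) {
      stop("variant '", v$label, "': only single-residue substitutions are ",
           "supported (wt='", v$wt, "', alt='", v$alt, "')", call. = FALSE)
    }
    if (v$wt == v$alt) {
      stop("variant '", v$label, "': wt and alt residues are identical",
           call. = FALSE)
    }
    seq <- proteins$sequence[match(v$protein_id, proteins$protein_id)]
    if (v$position < 1L || v$position > nchar(seq)) {
      stop("variant '", v$label, "': position ", v$position,
           " outside protein '", v$protein_id, "' (length ", nchar(seq), ")",
           call. = FALSE)
    }
    found <- substr(seq, v$position, v$position)
    if (found != v$wt) {
      stop("variant '", v$label, "': expected wild-type '", v$wt,
           "' at position ", v$position, " of '", v$protein_id,
           "' but sequence has '", found, "'", call. = FALSE)
    }
  }
  invisible(variants)
}

#' Apply a single-residue substitution to a sequence
#'
#' @param sequence Protein sequence.
#' @param position 1-based position of the substitution.
#' @param wt Stated wild-type residue; must match `sequence` at `position`.
#' @param alt Replacement residue.
#' @return The mutant sequence (same length, differing at exactly one
#'   position).
#' @examples
#' apply_variant("AAAAKPAAAAAAR", 6, "P", "L")
#' @export
apply_variant <- function(sequence, position, wt, alt) {
  position <- as.integer(position)
  if (position < 1L || position > nchar(sequence)) {
    stop("position ", position, " outside the sequence (length ",
         nchar(sequence), ")", call. = FALSE)
  }
  found <- substr(sequence, position, position)
  if (found != wt) {
    stop("expected wild-type '", wt, "' at position ", position,
         " but sequence has '", found, "'", call. = FALSE)
  }
  if (wt == alt) {
    stop("wt and alt residues are identical ('", wt, "')", call. = FALSE)
  }
  substr(sequence, position, position) <- alt
  sequence
}

#' Variant-bearing peptides and their transitions
#'
#' For each variant independently (substitutions are never combined), the
#' mutant sequence is built, digested from scratch, restricted to peptides
#' whose span covers the variant position, passed through the standard
#' length/composition filter, and turned into transitions with the standard
#' product-ion threshold. Coordinates in the output are on the mutant
#' sequence; `variant_offset` marks the substituted residue within the
#' peptide (1-based).
#'
#' A variant may yield no peptide at all: the covering peptide can fail the
#' length filter, or the substitution itself can introduce a residue (C/M)
#' that the composition filter removes.
#'
#' @param proteins Protein table (`protein_id`, `sequence`) or named
#'   character vector.
#' @param variants Variant tibble (`protein_id`, `position`, `wt`, `alt`,
#'   optional `label`), e.g. from [read_variants()].
#' @inheritParams design_transitions
#' @return A tibble of class `mrm_transitions` with the transition columns of
#'   [build_transitions()] plus `variant_label` and `variant_offset`.
#' @examples
#' variant_peptides(
#'   c(p = "AAAAKPAAAAAAR"),
#'   tibble::tibble(protein_id = "p", position = 6, wt = "P", alt = "L")
#' )
#' @export
variant_peptides <- function(proteins, variants, enzyme = "trypsin",
                             charge = 2L, min_len = 7L, max_len = 25L,
                             exclude = c("M", "C"), missed_cleavages = 0L,
                             chem = chem_table()) {
  proteins <- .as_protein_tbl(proteins)
  variants <- tibble::as_tibble(variants)
  if (!"label" %in% names(variants)) {
    variants$label <- sprintf("%s%d%s", variants$wt, variants$position,
                              variants$alt)
  }
  validate_variants(variants, proteins, chem = chem)
  out <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    wt_seq <- proteins$sequence[match(v$protein_id, proteins$protein_id)]
    mut_seq <- apply_variant(wt_seq, v$position, v$wt, v$alt)
    peps <- digest_peptides(
      tibble::tibble(protein_id = v$protein_id, sequence = mut_seq),
      enzyme = enzyme, missed_cleavages = missed_cleavages, chem = chem
    )
    covering <- peps[peps$start <= v$position & peps$end >= v$position, ,
                     drop = FALSE]
    kept <- filter_peptides(covering, min_len = min_len, max_len = max_len,
                            exclude = exclude)
    if (nrow(kept) == 0L) {
      return(NULL)
    }
    trans <- build_transitions(kept, charge = charge, chem = chem)
    trans$variant_label <- v$label
    trans$variant_offset <- v$position - trans$start + 1L
    trans
  })
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble::tibble(
      protein_id = character(0), peptide_sequence = character(0),
      start = integer(0), end = integer(0), missed_cleavages = integer(0),
      precursor_charge = integer(0), precursor_mz = numeric(0),
      product_series = character(0), product_index = integer(0),
      product_mz = numeric(0), n_products = integer(0),
      variant_label = character(0), variant_offset = integer(0)
    )
  }
  structure(
    out,
    class = c("mrm_transitions", class(tibble::as_tibble(out))),
    enzyme = enzyme_rule(enzyme)$name,
    charge = as.integer(charge),
    filter = list(min_len = min_len, max_len = max_len, exclude = exclude),
    counts = list(
      proteins = nrow(proteins),
      peptides_digested = NA_integer_,
      peptides_selected = dplyr::n_distinct(
        out[c("variant_label", "peptide_sequence", "start")]
      )
    )
  )
}
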