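# Proteotypic uniqueness by exact substring scan against a background
# proteome. A peptide is proteotypic when its sequence occurs in exactly one
# background protein, making it a valid quantitative surrogate for that
# protein. For exact 7-25-mer peptides, substring identity is the relevant
# criterion; near-identical homolog peptides with mismatches are out of scope
# (and indistinguishable peptides in mass space -- same residues, different
# order -- are undetectable by any sequence scan).

# All occurrence start positions of `pattern` in `subject`, overlapping
# included (gregexpr with fixed = TRUE skips overlaps, a lookahead does not;
# peptide strings contain no regex metacharacters).
.find_starts <- function(pattern, subject) {
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

.collapse_il <- function(x) chartr("L", "I", x)

#' All exact occurrences of one peptide in a background proteome
#'
#' @param peptide Peptide sequence (one string).
#' @param proteome A data frame with `protein_id` and `sequence` columns
#'   (e.g. [read_fasta()]), or a named character vector.
#' @param il_equivalent Treat isoleucine and leucine as the same residue
#'   (they are isobaric, so indistinguishable in mass space). Default `FALSE`.
#' @return A tibble with one row per occurrence: `protein_id`, `match_start`
#'   (1-based position in the background protein).
#' @examples
#' peptide_hits("GAGAGAR", c(bg = "AAGAGAGARKK"))
#' @export
peptide_hits <- function(peptide, proteome, il_equivalent = FALSE) {
  proteome <- .as_protein_tbl(proteome)
  if (nrow(proteome) == 0L) {
    stop("no background provided: the proteome is empty", call. = FALSE)
  }
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop("`peptide` must be a single non-empty string", call. = FALSE)
  }
  pat <- if (il_equivalent) .collapse_il(peptide) else peptide
  subj <- if (il_equivalent) .collapse_il(proteome$sequence) else proteome$sequence
  hits <- purrr::map2_dfr(proteome$protein_id, subj, function(id, s) {
    starts <- .find_starts(pat, s)
    tibble::tibble(protein_id = rep(id, length(starts)), match_start = starts)
  })
  hits
}

#' Scan peptides for proteotypic uniqueness against a background proteome
#'
#' Every distinct peptide is searched (exactly, substring-wise) against every
#' background sequence; a peptide is proteotypic when its hits fall in exactly
#' one distinct background protein. Zero hits also mean not proteotypic: the
#' background then carries no evidence the peptide identifies anything.
#' Repeated peptides are scanned once.
#'
#' @param peptides A character vector of peptide sequences, or any data frame
#'   with a `peptide_sequence` column (e.g. an `mrm_transitions` object).
#' @inheritParams peptide_hits
#' @param top_hits Cap on the number of hits listed in `hit_ids` (default 10,
#'   mirroring a top-ten report). The proteotypic decision always uses the
#'   full hit set; `hit_count` is never truncated.
#' @return A tibble with one row per distinct peptide: `peptide_sequence`,
#'   `hit_count` (all occurrences), `n_proteins` (distinct proteins hit),
#'   `is_proteotypic`, `hit_ids` (up to `top_hits` entries
#'   `"protein_id@start"`, semicolon-separated; `""` when no match).
#' @examples
#' proteotypic_scan("GAGAGAR", c(a = "AAGAGAGARK", b = "GAGAGARPPP"))
#' @export
proteotypic_scan <- function(peptides, proteome, il_equivalent = FALSE,
                             top_hits = 10L) {
  if (is.data.frame(peptides)) {
    peptides <- peptides$peptide_sequence
  }
  peptides <- unique(as.character(peptides))
  proteome <- .as_protein_tbl(proteome)
  if (nrow(proteome) == 0L) {
    stop("no background provided: the proteome is empty", call. = FALSE)
  }
  purrr::map_dfr(peptides, function(pep) {
    hits <- peptide_hits(pep, proteome, il_equivalent = il_equivalent)
    shown <- utils::head(hits, top_hits)
    tibble::tibble(
      peptide_sequence = pep,
      hit_count = nrow(hits),
      n_proteins = dplyr::n_distinct(hits$protein_id),
      is_proteotypic = dplyr::n_distinct(hits$protein_id) == 1L,
      hit_ids = paste(
        sprintf("%s@%d", shown$protein_id, shown$match_start),
        collapse = ";"
      )
    )
  })
}

#' Annotate transitions with proteotypic scan results
#'
#' Runs [proteotypic_scan()] on the distinct peptides of a transition table
#' and joins `hit_count`, `is_proteotypic` and `hit_ids` onto every row.
#'
#' @param transitions A transition tibble from [design_transitions()] or
#'   [build_transitions()].
#' @inheritParams proteotypic_scan
#' @return The input with three proteotypic columns appended.
#' @export
annotate_proteotypic <- function(transitions, proteome, il_equivalent = FALSE,
                                 top_hits = 10L) {
  report <- proteotypic_scan(transitions, proteome,
                             il_equivalent = il_equivalent,
                             top_hits = top_hits)
  dplyr::left_join(
    tibble::as_tibble(transitions),
    dplyr::select(report, "peptide_sequence", "hit_count", "is_proteotypic",
                  "hit_ids"),
    by = "peptide_sequence"
  )
}
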