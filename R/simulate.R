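# Seeded synthetic proteome generator with a ground-truth manifest.
#
# Proteins are assembled from tryptic fragments whose interiors contain no
# K/R (so the tryptic digest at 0 missed cleavages recovers exactly the
# planted fragments), no fragment starts with proline (so no planted site is
# suppressed), and planted "qualifying" fragments are 7-25 residues with no
# M/C -- i.e. each one survives the full filter cascade and yields exactly
# one transition. Decoy fragments are disqualified by construction (too
# short, too long, or M/C-bearing). The manifest records the planted truth
# so pipeline output can be checked against an independent expectation.

# Residues legal inside a planted fragment: no K/R (would add cleavage
# sites), no M/C (would trip the composition filter for qualifying ones).
.SIM_INTERIOR <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P", "Q",
                   "S", "T", "V", "W", "Y")

.sim_fragment <- function(len, terminal = TRUE, with_mc = FALSE) {
  first <- sample(setdiff(.SIM_INTERIOR, "P"), 1L)
  n_mid <- len - 1L - as.integer(terminal)
  mid <- if (n_mid > 0L) {
    sample(.SIM_INTERIOR, n_mid, replace = TRUE)
  } else {
    character(0)
  }
  chars <- c(first, mid, if (terminal) sample(c("K", "R"), 1L))
  if (with_mc && len >= 3L) {
    chars[sample(2:(len - 1L), 1L)] <- sample(c("M", "C"), 1L)
  }
  paste(chars, collapse = "")
}

# Analytic expectation for a variant: which mutant digest peptides cover the
# variant position and pass the filter. Derived by hand-application of the
# cleavage and filter rules to the planted construction, independently of
# digest_peptides().
.sim_variant_expectation <- function(kind, frag, offset) {
  len <- nchar(frag)
  if (kind == "interior") {
    list(n = 1L, sequence = NULL) # same span, one substituted residue
  } else if (kind == "to_cys") {
    list(n = 0L, sequence = NULL) # composition filter removes the peptide
  } else if (kind == "gain_site") {
    # new K at `offset` splits the fragment; only the left piece (length
    # `offset`, ending at the new K) covers the variant, and 7 <= offset <= 25
    # is guaranteed at planting time
    left <- paste0(substr(frag, 1L, offset - 1L), "K")
    list(n = 1L, sequence = left)
  } else {
    stop("unknown variant kind: ", kind)
  }
}

#' Generate a seeded synthetic proteome with known ground truth
#'
#' Builds `n_proteins` pseudo-random proteins by concatenating tryptic
#' fragments: per protein, `qualifying_per_protein` fragments that survive
#' the default filter cascade (7-25 residues, no M/C), plus decoy fragments
#' that fail it (short, long, or M/C-bearing) and a short non-tryptic tail.
#' Optionally plants one qualifying peptide shared verbatim between the
#' first two proteins (for proteotypic tests) and a set of single-residue
#' variants with analytically known consequences:
#'
#' * `interior` — a benign substitution inside a qualifying peptide; exactly
#'   one mutant peptide is expected.
#' * `to_cys` — substitution to cysteine; the composition filter removes the
#'   covering peptide, so zero mutant peptides are expected.
#' * `gain_site` — substitution to lysine inside a qualifying peptide,
#'   creating a cleavage site; the left cleavage product (which ends at the
#'   new K and covers the variant) is expected.
#'
#' The same seed always reproduces the same proteins, variants and manifest.
#'
#' @param n_proteins Number of proteins (>= 2 when `share_peptide` is TRUE).
#' @param qualifying_per_protein Planted filter-surviving peptides per
#'   protein (before the optional shared peptide).
#' @param decoys_per_protein Planted filter-failing fragments per protein.
#' @param share_peptide Plant one qualifying peptide in both protein 1 and
#'   protein 2 (default TRUE).
#' @param n_variants Number of planted variants, cycling through the three
#'   kinds above (default 3).
#' @param seed Integer seed; required, for reproducibility.
#' @return A list of class `mrm_fixture`:
#'   * `proteins` — tibble (`protein_id`, `description`, `sequence`)
#'   * `variants` — tibble (`protein_id`, `position`, `wt`, `alt`, `label`)
#'   * `manifest` — ground truth: `qualifying` (planted surviving peptides
#'     with coordinates), `per_protein` (expected transition count per
#'     protein), `shared` (the duplicated peptide and its hosts), and
#'     `variant_truth` (expected mutant peptide count, and sequence where
#'     determined, per variant).
#' @examples
#' fx <- simulate_proteome(seed = 42)
#' glance(design_transitions(fx$proteins))
#' @export
simulate_proteome <- function(n_proteins = 4L,
                              qualifying_per_protein = 3L,
                              decoys_per_protein = 3L,
                              share_peptide = TRUE,
                              n_variants = 3L,
                              seed) {
  if (missing(seed)) {
    stop("`seed` is required for a reproducible fixture", call. = FALSE)
  }
  stopifnot(n_proteins >= 1L, qualifying_per_protein >= 1L)
  if (share_peptide && n_proteins < 2L) {
    stop("`share_peptide` needs at least 2 proteins", call. = FALSE)
  }
  withr::local_seed(seed)

  # qualifying fragments, unique across the whole proteome
  n_qual <- n_proteins * qualifying_per_protein
  qual <- character(0)
  while (length(qual) < n_qual) {
    frag <- .sim_fragment(sample(7:25, 1L), terminal = TRUE)
    if (!frag %in% qual) qual <- c(qual, frag)
  }
  qual_by_protein <- split(qual, rep(seq_len(n_proteins),
                                     each = qualifying_per_protein))

  shared <- if (share_peptide) .sim_fragment(sample(8:20, 1L), terminal = TRUE)

  proteins <- vector("list", n_proteins)
  qual_rows <- vector("list", n_proteins)
  decoy_kinds <- c("short", "with_mc", "long")
  for (p in seq_len(n_proteins)) {
    frags <- qual_by_protein[[p]]
    if (share_peptide && p <= 2L) frags <- c(frags, shared)
    for (d in seq_len(decoys_per_protein)) {
      kind <- decoy_kinds[(d - 1L) %% 3L + 1L]
      frags <- c(frags, switch(
        kind,
        short = .sim_fragment(sample(3:6, 1L), terminal = TRUE),
        with_mc = .sim_fragment(sample(7:25, 1L), terminal = TRUE,
                                with_mc = TRUE),
        long = .sim_fragment(sample(26:30, 1L), terminal = TRUE)
      ))
    }
    frags <- sample(frags) # shuffle fragment order within the protein
    frags <- c(frags, .sim_fragment(sample(4:5, 1L), terminal = FALSE))
    starts <- cumsum(c(1L, utils::head(nchar(frags), -1L)))
    id <- sprintf("SYN%03d", p)
    proteins[[p]] <- tibble::tibble(
      protein_id = id,
      description = "synthetic protein",
      sequence = paste(frags, collapse = "")
    )
    is_qual <- frags %in% c(qual_by_protein[[p]],
                            if (share_peptide && p <= 2L) shared)
    qual_rows[[p]] <- tibble::tibble(
      protein_id = id,
      peptide_sequence = frags[is_qual],
      start = starts[is_qual],
      end = starts[is_qual] + nchar(frags[is_qual]) - 1L
    )
  }
  proteins <- dplyr::bind_rows(proteins)
  qualifying <- dplyr::bind_rows(qual_rows)

  # variants planted on non-shared qualifying fragments, one per fragment
  variant_kinds <- c("interior", "to_cys", "gain_site")
  pool <- qualifying[!qualifying$peptide_sequence %in% shared, , drop = FALSE]
  pool <- pool[sample(nrow(pool)), , drop = FALSE]
  variants <- NULL
  truth <- NULL
  if (n_variants > 0L) {
    if (n_variants > nrow(pool)) {
      stop("not enough planted peptides to host ", n_variants, " variants",
           call. = FALSE)
    }
    vrows <- vector("list", n_variants)
    trows <- vector("list", n_variants)
    for (i in seq_len(n_variants)) {
      kind <- variant_kinds[(i - 1L) %% 3L + 1L]
      host <- pool[i, ]
      frag <- host$peptide_sequence
      len <- nchar(frag)
      if (kind == "gain_site") {
        # need a split offset giving a 7..25-residue left piece, with no
        # proline after the new K, and strictly inside the fragment
        cand <- if (len - 2L >= 7L) 7:min(len - 2L, 25L) else integer(0)
        if (length(cand) > 0L) {
          cand <- cand[substring(frag, cand + 1L, cand + 1L) != "P"]
        }
        if (length(cand) == 0L) kind <- "interior"
      }
      offset <- switch(
        kind,
        gain_site = if (length(cand) == 1L) cand else sample(cand, 1L),
        sample(2:(len - 2L), 1L)
      )
      wt <- substr(frag, offset, offset)
      alt <- switch(
        kind,
        interior = sample(setdiff(.SIM_INTERIOR, c(wt, "P")), 1L),
        to_cys = "C",
        gain_site = "K"
      )
      position <- host$start + offset - 1L
      label <- sprintf("%s%d%s", wt, position, alt)
      vrows[[i]] <- tibble::tibble(
        protein_id = host$protein_id, position = position,
        wt = wt, alt = alt, label = label
      )
      exp <- .sim_variant_expectation(kind, frag, offset)
      trows[[i]] <- tibble::tibble(
        label = label, kind = kind,
        expected_peptides = exp$n,
        expected_sequence = exp$sequence %||%
          if (kind == "interior") {
            paste0(substr(frag, 1L, offset - 1L), alt,
                   substr(frag, offset + 1L, len))
          } else {
            NA_character_
          }
      )
    }
    variants <- dplyr::bind_rows(vrows)
    truth <- dplyr::bind_rows(trows)
  }

  structure(
    list(
      proteins = proteins,
      variants = variants %||% tibble::tibble(
        protein_id = character(0), position = integer(0), wt = character(0),
        alt = character(0), label = character(0)
      ),
      manifest = list(
        qualifying = qualifying,
        per_protein = dplyr::count(qualifying, .data$protein_id,
                                   name = "n_expected_transitions"),
        shared = if (share_peptide) {
          tibble::tibble(
            peptide_sequence = shared,
            protein_ids = paste(proteins$protein_id[1:2], collapse = ";")
          )
        } else {
          tibble::tibble(peptide_sequence = character(0),
                         protein_ids = character(0))
        },
        variant_truth = truth %||% tibble::tibble(
          label = character(0), kind = character(0),
          expected_peptides = integer(0), expected_sequence = character(0)
        )
      ),
      seed = seed
    ),
    class = "mrm_fixture"
  )
}

#' @export
print.mrm_fixture <- function(x, ...) {
  cat(sprintf(
    "<mrm_fixture> seed %d: %d proteins, %d planted qualifying peptides, %d variants\n",
    x$seed, nrow(x$proteins), nrow(x$manifest$qualifying), nrow(x$variants)
  ))
  invisible(x)
}
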