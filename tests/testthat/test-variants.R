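test_that("apply_variant substitutes exactly one residue and checks wt", {
  expect_equal(apply_variant("AAAAKPAAAAAAR", 6, "P", "L"), "AAAAKLAAAAAAR")
  # stated wild type must match the sequence
  expect_error(apply_variant("AAEAA", 3, "D", "G"), "expected wild-type 'D'")
  expect_error(apply_variant("AAEAA", 3, "D", "G"), "position 3")
  expect_error(apply_variant("AAEAA", 9, "E", "G"), "outside")
  expect_error(apply_variant("AAEAA", 3, "E", "E"), "identical")
  # involution: applying then reverting returns the original
  mut <- apply_variant("AAAAKPAAAAAAR", 6, "P", "L")
  expect_equal(apply_variant(mut, 6, "L", "P"), "AAAAKPAAAAAAR")
})

test_that("a variant destroying proline suppression unmasks a cleavage site", {
  # wild type AAAAKPAAAAAAR digests whole (K5 blocked by P6); P6L unblocks
  # K5, so the mutant digests to AAAAK (filtered, 5 residues) + LAAAAAAR
  vp <- variant_peptides(
    c(p = "AAAAKPAAAAAAR"),
    tibble::tibble(protein_id = "p", position = 6, wt = "P", alt = "L")
  )
  peps <- dplyr::distinct(tidy(vp), peptide_sequence, start, end,
                          variant_offset)
  expect_equal(peps$peptide_sequence, "LAAAAAAR")
  expect_equal(peps$start, 6L)
  expect_equal(peps$variant_offset, 1L)
})

test_that("variants to filtered residues or oversized peptides yield nothing", {
  # substitution to C inside the only covering peptide: composition filter
  vp1 <- variant_peptides(
    c(p = "GAGAGARAAAAAAAK"),
    tibble::tibble(protein_id = "p", position = 3, wt = "G", alt = "C")
  )
  expect_equal(nrow(vp1), 0L)
  # covering peptide longer than 25 residues with no new site: length filter
  long <- paste(rep("A", 30), collapse = "")
  vp2 <- variant_peptides(
    c(p = long),
    tibble::tibble(protein_id = "p", position = 10, wt = "A", alt = "G")
  )
  expect_equal(nrow(vp2), 0L)
})

test_that("every reported peptide covers its variant and shows the alt residue", {
  fx <- simulate_proteome(seed = 123, n_variants = 3)
  vp <- variant_peptides(fx$proteins, fx$variants)
  rows <- dplyr::distinct(tidy(vp), peptide_sequence, start, end,
                          variant_label, variant_offset)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    v <- fx$variants[fx$variants$label == r$variant_label, ]
    expect_true(r$start <= v$position && v$position <= r$end)
    expect_equal(substr(r$peptide_sequence, r$variant_offset,
                        r$variant_offset), v$alt)
    # wild-type exclusion: the reported peptide differs from the wild-type
    # subsequence over the same span
    wt_seq <- fx$proteins$sequence[fx$proteins$protein_id == v$protein_id]
    expect_false(r$peptide_sequence == substr(wt_seq, r$start, r$end))
  }
})

test_that("mutant peptide sets match the planted expectation and a full re-digest", {
  for (seed in c(123, 456)) {
    fx <- simulate_proteome(seed = seed, n_variants = 3)
    vp <- variant_peptides(fx$proteins, fx$variants)
    counts <- dplyr::count(
      dplyr::distinct(tidy(vp), variant_label, peptide_sequence, start),
      variant_label
    )
    truth <- fx$manifest$variant_truth
    for (i in seq_len(nrow(truth))) {
      got <- counts$n[counts$variant_label == truth$label[i]]
      expect_equal(if (length(got) == 0) 0L else got,
                   truth$expected_peptides[i], info = truth$label[i])
      if (!is.na(truth$expected_sequence[i]) &&
          truth$expected_peptides[i] > 0) {
        expect_true(truth$expected_sequence[i] %in%
                      vp$peptide_sequence[vp$variant_label == truth$label[i]])
      }
    }
    # oracle: digest the mutant from scratch with the naive scanner and
    # apply the filter rules by hand
    for (i in seq_len(nrow(fx$variants))) {
      v <- fx$variants[i, ]
      wt_seq <- fx$proteins$sequence[fx$proteins$protein_id == v$protein_id]
      mut_seq <- apply_variant(wt_seq, v$position, v$wt, v$alt)
      frags <- oracle_digest(mut_seq, "trypsin")
      ends <- cumsum(nchar(frags))
      starts <- ends - nchar(frags) + 1
      covering <- frags[starts <= v$position & ends >= v$position]
      expected <- covering[nchar(covering) >= 7 & nchar(covering) <= 25 &
                             !grepl("[MC]", covering)]
      got <- unique(vp$peptide_sequence[vp$variant_label == v$label])
      expect_setequal(got, expected)
    }
  }
})

test_that("variant tables are validated against the loaded proteins", {
  prot <- tibble::tibble(protein_id = "p", sequence = "GAGAGARAAAAAAAK")
  good <- tibble::tibble(protein_id = "p", position = 2L, wt = "A",
                         alt = "V", label = "A2V")
  expect_silent(validate_variants(good, prot))
  expect_error(
    validate_variants(dplyr::mutate(good, protein_id = "ghost"), prot),
    "ghost"
  )
  expect_error(
    validate_variants(dplyr::mutate(good, wt = "G"), prot),
    "sequence has 'A'"
  )
  expect_error(
    validate_variants(dplyr::mutate(good, position = 99L), prot),
    "outside"
  )
  # insertions/deletions (multi-residue values) are rejected as unsupported
  expect_error(
    validate_variants(dplyr::mutate(good, alt = "VV"), prot),
    "single-residue"
  )
  # empty table and per-variant independence
  expect_equal(nrow(variant_peptides(prot, good[0, ])), 0L)
  three <- dplyr::bind_rows(
    tibble::tibble(protein_id = "p", position = 2L, wt = "A", alt = "V"),
    tibble::tibble(protein_id = "p", position = 4L, wt = "A", alt = "S"),
    tibble::tibble(protein_id = "p", position = 6L, wt = "A", alt = "T")
  )
  vp <- variant_peptides(prot, three)
  labs <- unique(vp$variant_label)
  expect_equal(length(labs), 3L)
  # each analysis is independent: no peptide carries two substitutions
  for (lab in labs) {
    peps <- unique(vp$peptide_sequence[vp$variant_label == lab])
    for (pep in peps) {
      diffs <- sum(strsplit(pep, "")[[1]] !=
                     strsplit(substr("GAGAGAR", 1, nchar(pep)), "")[[1]])
      expect_equal(diffs, 1L)
    }
  }
})

test_that("variants TSV round-trips through read_variants with validation", {
  fx <- simulate_proteome(seed = 321)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(fx$variants, path)
  loaded <- read_variants(path, fx$proteins)
  expect_equal(loaded, fx$variants, ignore_attr = TRUE)
  # labels are synthesised when absent
  readr::write_tsv(dplyr::select(fx$variants, -label), path)
  relabelled <- read_variants(path, fx$proteins)
  expect_equal(relabelled$label, fx$variants$label)
  # a corrupted wt residue is caught at load
  bad <- fx$variants
  bad$wt[1] <- setdiff(c("A", "G", "V"), bad$wt[1])[1]
  readr::write_tsv(bad, path)
  expect_error(read_variants(path, fx$proteins), "wild-type")
})
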