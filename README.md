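# mrmkit

Targeted proteomics on a triple-quadrupole mass spectrometer quantifies a
protein through a *transition*: a peptide precursor ion selected in Q1 paired
with one of its sequence-specific product ions selected in Q3. `mrmkit` is an
offline toolkit that turns protein sequences into candidate MRM/SRM
transition lists, for biologists and mass spectrometrists designing
multiple-reaction-monitoring assays:

1. **In silico digestion** with six protease rule sets — trypsin (C-terminal
   to K/R, suppressed before proline), chymotrypsin (F/Y/W), AspN
   (N-terminal to D), GluC (D/E), LysC (K), ArgC (R) — with optional missed
   cleavages and 1-based peptide coordinates.
2. **Filtering** to peptides of 7–25 residues containing neither methionine
   nor cysteine (oxidation-prone during sample handling).
3. **Mass computation.** Monoisotopic neutral masses from residue empirical
   formulas with elemental masses C = 12.00000000, H = 1.00782503,
   N = 14.00307401, O = 15.99491462 (and S = 31.97207117); precursor m/z at
   z = 2 or 3 with proton mass 1.00727646 Da; singly charged b/y series

       b_i = Σ_{j≤i} m_res(j) + m_H+        y_i = Σ_{j>n−i} m_res(j) + m_H2O + m_H+

   Retained products are those with m/z strictly above the precursor m/z, so
   a singly charged interferent at the precursor m/z cannot produce them.
4. **Proteotypic check**: exact (optionally I/L-equivalent) substring scan of
   each peptide against a background proteome FASTA; a peptide is
   proteotypic when it occurs in exactly one background protein.
5. **Variant peptides**: apply single-residue substitutions from a TSV table
   (UniProt-style 1-based positions, validated against the sequence),
   re-digest the mutant from scratch — substitutions can create or destroy
   cleavage sites — and report only the mutation-bearing peptides with their
   transitions.

A seeded synthetic proteome generator (`simulate_proteome()`) plants
qualifying peptides, shared peptides and variants with analytically known
outcomes, and returns a ground-truth manifest the test suite checks the
pipeline against.

## Worked example

```r
library(mrmkit)

tr <- design_transitions(c(ENO1 = "GAGAGARKPAAAKAVEHINLGIYKDWSEVR"))
glance(tr)
#> # A tibble: 1 × 8
#>   n_proteins n_peptides_digested n_peptides_selected n_transitions n_product_ions
#>        <int>               <int>               <int>         <int>          <int>
#> 1          1                   4                   2             2             16
```

The tryptic digest yields four peptides (`GAGAGAR`, `KPAAAK`, `AVEHINLGIYK`,
`DWSEVR`; the K before proline does not cleave). The two 6-mers fall below
the 7-residue floor, leaving two transitions. For `GAGAGAR` the neutral mass
is 558.28741 Da and the doubly charged precursor sits at m/z 280.15098; of
its twelve b/y ions, six (b4–b6, y4–y6, e.g. y6 = 502.2732, b6 = 385.1830)
lie above the precursor and are retained as products, while e.g. y1
(175.1190) is excluded. `tidy(tr)` gives the row-per-product-ion table,
`autoplot(tr)` draws the transition map, and `write_transitions_csv()`
writes a deterministic RFC-4180 CSV with m/z at 4 decimal places.

Variant discovery works the same way:

```r
variant_peptides(
  c(p = "AAAAKPAAAAAAR"),
  tibble::tibble(protein_id = "p", position = 6, wt = "P", alt = "L")
)
```

Here P6L removes the proline that suppressed cleavage after K5, so the
mutant digests into `AAAAK` (filtered out, 5 residues) and the reported
mutation-bearing peptide `LAAAAAAR` with `variant_offset = 1`.

## Command line

```sh
Rscript inst/cli/mrm-designer.R transitions \
  --fasta proteins.fasta --enzyme trypsin --charge 2 \
  --background proteome.fasta --out transitions.csv
```

Subcommands: `digest`, `transitions`, `proteotypic`, `mutations`, `fixture`.

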