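# compcode

Protein and peptide identification from **residue composition codes**.

Most single-molecule protein identification schemes read a fingerprint of a
protein rather than its full sequence. One practical fingerprint is the
relative abundance of the residue types that can be chemically labeled —
Cys, Lys, Met, Asp/Glu, Tyr, Arg, His, Trp and Ser — for example by
attaching an amplifiable DNA barcode to each residue type and counting the
barcodes by qPCR. The vector of per-channel counts (or relative ratios) is
the protein's *composition code*, and a protein is identified by searching
its measured code against a code library computed from a proteome or
secretome database.

`compcode` implements the computational side of that workflow for R users:

- **Code libraries** — parse FASTA proteomes or UniProt-style annotation
  (flat text or TSV), extract secreted mature chains/active peptides grouped
  under their precursor entries, and convert sequences into composition
  codes over configurable residue-channel panels (with optional terminus
  counts matching the labeling chemistry).
- **Search** — rank library entries by cosine similarity,

  `similarity(u, v) = (u · v) / (‖u‖ ‖v‖)`,

  which is scale-invariant, so raw counts and measured relative ratios are
  directly comparable; report top-N candidates with deterministic
  tie-breaking; collapse processed chains of one precursor into a single
  database entry.
- **Coverage evaluation** — noise-free self-search coverage across panel
  sizes 2–9 (top-1 / top-5), the code-uniqueness fraction, and Monte Carlo
  coverage under per-element Gaussian relative measurement error
  (σ = RSD · μ), averaged over independent replicates.
- **qPCR analysis** — fit Ct-vs-log10(copies) standard curves, convert Ct
  values (including "Undetermined") to copy numbers,
  fluorescence-calibrate aliquots, and assemble measured composition codes
  from replicate wells and independent runs.
- **Synthetic data** — seeded generators for proteomes with human-like
  residue frequencies, secretome-like chain sets with shared precursors,
  and simulated qPCR runs, so the full pipeline is testable from code alone.

## Worked example

The URP peptide (`ACFWKYCV`, entry UTS2B) has two Cys, one Lys, no Met and a
C-terminal carboxylate. On the assay-matched C/K/M/D+E panel (the D/E
channel also counts the C-terminus) its theoretical code is `(2, 1, 0, 1)`:

```r
library(compcode)

panel <- canonical_panel(4, "assay-matched")
compute_code("ACFWKYCV", panel)
#> <composition_code> [C,K,M,D/E] C=2 K=1 M=0 D/E=1

lib <- build_library(
  protein_records(id = c("UTS2B", "ELA", "D1"),
                  sequence = c("ACFWKYCV", "CCKKMMG", "KG")),
  panel)

# a measured code (relative ratios from qPCR, Lys channel = 1)
identify_protein(c(2.04, 1, 0.00, 0.95), lib, n = 3)
#>   rank record_id group_id entry_name similarity
#> 1    1     UTS2B    UTS2B      UTS2B      1.000
#> 2    2       ELA      ELA        ELA      0.792
#> 3    3        D1       D1         D1      0.560
```

The measured code ranks its true entry first with similarity 1.000 (rounded
to 3 decimals; the exact value is 0.9997), well separated from the decoys.

Identification coverage on a seeded synthetic proteome grows with the number
of labeled residue channels and with the allowed candidate depth:

```r
recs <- generate_proteome(proteome_spec(n_proteins = 500, seed = 7))
panel_sweep(recs, sizes = c(3, 4, 9), top_ns = c(1, 5))
#>   panel_size top_n coverage
#> 1          3     1    0.670
#> 2          3     5    0.988
#> 3          4     1    0.984
#> 4          4     5    1.000
#> 5          9     1    1.000
#> 6          9     5    1.000
```

`coverage` is the fraction of entries whose own code, searched against the
whole library, returns their precursor group within the top N (ties counted
conservatively). Adding the fourth channel (Asp/Glu) lifts top-1 coverage
from 67% to 98% on this fixture.

A command-line wrapper over the same functions is installed at
`inst/cli/compcode` with subcommands `synth`, `build-library`, `identify`,
`coverage`, `simulate-error` and `qpcr-to-code`; see `?run_cli`.

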