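# isomirpair

Most miRNAs are annotated as one canonical mature sequence, but small-RNA
sequencing shows each miRNA as a cloud of length and sequence variants
(isomiRs). Variants at the 3' end leave the seed untouched and are largely
redundant; a shift at the **5' end moves the seed** (positions 2–8 of the
mature sequence) and therefore redirects the miRNA to a different target
spectrum. `isomirpair` is an R package for finding and analyzing such
**canonical miRNA / 5'isomiR pairs** in small-RNA-seq data, with the
breast-cancer pair hsa-miR-140-3p / 5'isomiR-140-3p as its worked example.

It is written for computational biologists who want a small, fully tested,
end-to-end path from reads to cohort statistics:

1. **isomiR quantification** — adapter trimming, exact-match placement of
   reads on miRNA precursors (no mismatches), offset classification in the
   `d5|d3` notation (e.g. `0|0`, `+1|+2`), collapsing of 3' variants
   (18–24 nt) into 5'-end groups, and reads-per-million normalization.
2. **Pair detection** — a miRNA/5'isomiR pair is called *highly expressed*
   when the canonical form averages ≥ 100 rpm across samples and the
   isomiR:canonical ratio of means is ≥ 1:5.
3. **Seed-shift target analysis** — seed extraction, reverse-complement
   7-mer site scanning of 3'UTRs, and a one-sided Fisher exact test for
   seed-site enrichment among downregulated genes, with the
   strictly-less-than 65 % expression / corrected p < 0.05 downregulation
   filter and two-condition Venn partition.
4. **Cohort statistics** — isoform–isoform Pearson correlation, unpaired
   Student's t comparisons across ER/metastasis groups, and quartile-based
   Kaplan–Meier survival with a two-group log-rank test
   (upper quartile = "high", lower quartile = "low").
5. **Synthetic data** — a deterministic generator for every input above
   (references, reads, DE tables, patient cohorts) with recorded ground
   truth, so each stage is testable against planted parameters.

## Worked example

The package ships a 12-isoform × 8-cell-line rpm matrix of six
miRNA/5'isomiR pairs from a public breast cell-line small-RNA-seq panel
(ArrayExpress E-MTAB-4539):

```r
library(isomirpair)

pairs <- detect_pairs(cellline_panel_rpm(), pair_criteria())
pairs
#>    mirna_name canonical_mean_rpm isomir_mean_rpm     ratio passes
#> 1  miR-10a-5p           2959.237       1333.2250 0.4505299   TRUE
#> 2 miR-1307-3p           1258.925        457.8375 0.3636734   TRUE
#> 3  miR-140-3p            208.325        383.0750 1.8388336   TRUE
#> 4  miR-183-5p            986.400        808.2750 0.8194191   TRUE
#> 5  miR-203-3p           1759.675        875.4625 0.4975137   TRUE
#> 6  miR-30a-3p            346.550        103.2875 0.2980450   TRUE
```

All six pairs pass both criteria. miR-140-3p stands out: its 5'isomiR
*out-expresses* the canonical form (ratio 1.84, and in every one of the
eight cell lines). The one-nucleotide 5' shift changes the seed:

```r
seed_of(mir140_pair()[["canonical"]])   # "ACCACAG"
seed_of(mir140_pair()[["isomir"]])      # "CCACAGG"
target_site_of("CCACAGG")               # "CCTGTGG" - the site scanned in 3'UTRs
```

so the two isoforms recognize different 7-mer sites in 3'UTRs
(`scan_utr`, `enrichment_test`).

A shell pipeline over the same functions is available through the thin
wrapper in `inst/scripts/isomir`:

```sh
isomir simulate --config config.yaml --out-dir sim/
isomir quantify --reads S1=sim/S1.fastq --precursors sim/precursors.fa \
       --matures sim/matures.gff3 --adapter TGGAATTCTCGGGTGCCAAGG --out matrix.tsv
isomir pairs --matrix matrix.tsv --out pairs.tsv
```

Every subcommand writes a JSON run manifest (version, parameters, input
checksums, seed) next to its output.

## Limitations

Mapping is exact-match against precursor sequences (not a genome aligner);
multi-locus miRNA families are resolved by fractional counting, not by
genomic context. The synthetic cohort's expression dispersion is milder
than real tumor rpm data — see the methods vignette
(`vignettes/isomir-pipeline.Rmd`) for what the recovery tests do and do
not demonstrate.
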