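# bcellsplice

Alternative splicing and co-expression analysis of B-cell differentiation
RNA-seq, rebuilt as a tested R pipeline that runs entirely on synthetic data.

## The problem

During a T-cell-dependent immune response, activated B cells differentiate
into antibody-secreting plasmablasts/plasma cells (PB/PC) and resting memory
B cells (MBC). Antibody secretion demands a massive expansion of the early
secretory pathway — in particular the COPII machinery (SEC23/24 inner coat,
SEC13/31 outer coat, KLHL12/CUL3 regulators) that exports cargo from the ER.
Two RNA-level mechanisms tune this machinery between subtypes: differential
gene expression, and alternative splicing — including poison isoforms that
introduce a premature termination codon (PTC) and route the transcript into
nonsense-mediated decay (AS-NMD), and frame-preserving variants that remodel
protein domains instead.

`bcellsplice` packages that analysis for anyone who wants to run, test or
extend it without the original sequencing data:

- **expression** — median-of-ratios normalization, a Welch-t differential
  test on `log2(normalized+1)` at the study cut-offs (padj < 0.001,
  |log2FC| > 0.5), BH adjustment, hypergeometric gene-set enrichment
  (FDR < 0.05), directional gene-set summaries, sample PCA.
- **splicing** — percent spliced in from junction reads with
  effective-length normalization, `PSI = (inc/len_inc) / (inc/len_inc +
  skip/len_skip)`; differential splicing (p < 0.001, |ΔPSI| > 0.4);
  SE/RI/A5SS/A3SS breakdowns; direction summaries; isoform fractions for a
  two-choice isoform grid.
- **consequence** — event application on transcript models, reading-frame
  status (Δlength mod 3), ORF scan, NMD prediction by the 50-nt
  last-junction rule, domain truncation, and a four-way consequence
  classification.
- **tf_screen** — a two-stage Pearson screen (r > 0.9 gate against three
  COPII target genes, all-target intersection, 17-tissue validation by
  averaged r/p, ranking).
- **synthetic_data** — a negative-binomial generator for the 4-condition ×
  3-replicate design with planted DE genes, a planted TF→target module, a
  tissue panel, junction counts at configurable true PSI, and a toy
  annotation reproducing the exemplar loci (116-nt, 296-nt, 99+187-nt,
  50-nt and frame-preserving cassettes; six kelch-repeat domains).

## Worked example

```r
library(bcellsplice)

# the two canonical PSI readings
100 * compute_psi(50, 0, len_inc = 2, len_skip = 1)    # 100 (% included)
100 * compute_psi(100, 50, len_inc = 2, len_skip = 1)  # 50

# a frameshifting exon skip on the SEC24C-like fixture
ann <- build_toy_annotation()
ev  <- ann$events[ann$events$event_id == "SE_SEC24C_E11", ]
v   <- apply_event(ann$transcripts$SEC24C_like, ev, inclusion = FALSE)
classify_consequence(v)[, c("delta_length", "category")]
#>   delta_length category
#> 1         -116 frameshift-NMD

# end-to-end on synthetic data
summary <- run_pipeline(list(outdir = "results/pipeline", seed = 3))
summary$n_de            # 88 differential genes (MBC vs PC)
summary$top_tf          # "ELF2" — the planted regulator, rank 1
```

Skipping the 116-nt exon shifts the reading frame (−116 is not divisible by
3), the scanner finds a premature stop well over 50 nt upstream of the last
exon–exon junction, and the isoform is classified as NMD-inducing — the
AS-NMD mechanism that lowers SEC24C abundance in memory B cells. The
pipeline run recovers the planted differential genes, finds the planted
gene set enriched, and ranks the planted TF first after tissue validation.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` … `05_tf_screen.R`), writing tables under
`results/`; `vignettes/bcell-splicing-methods.Rmd` documents the models,
parameter choices and limitations.

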