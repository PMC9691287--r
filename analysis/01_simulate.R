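#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the study design: four B-cell differentiation stages (prePB, PB,
# PC, MBC) in triplicate with planted differential expression in MBC, a
# planted TF -> target co-regulation structure (ELF2 -> SEC24B/CUL3/CSNK1D
# stand-ins among 200 decoy TFs), a 17-tissue validation panel, a 200-event
# splice panel with planted PSI shifts, and the toy exemplar annotation.
# Everything downstream reads only the files written here.

suppressPackageStartupMessages(library(bcellsplice))

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 20221110L)

sim <- generate_counts(cfg)
tissue <- generate_tissue_panel(cfg, sim$truth)
ev_truth <- simulate_event_truth(cfg)
junctions <- generate_junction_counts(cfg, ev_truth$events,
                                      ev_truth$true_psi)
genesets <- c(toy_gene_sets(sim$truth), toy_tf_genesets(sim$truth))

write_counts_tsv(sim$counts, file.path(outdir, "counts.tsv"),
                 file.path(outdir, "samples.tsv"))
write_counts_tsv(tissue, file.path(outdir, "tissue_counts.tsv"),
                 file.path(outdir, "tissue_samples.tsv"))
write_events_tsv(ev_truth$events, file.path(outdir, "events.tsv"))
write_junctions_tsv(junctions, file.path(outdir, "junctions.tsv"))
write_gene_sets_tsv(genesets, file.path(outdir, "gene_sets.tsv"))
write_annotation(build_toy_annotation(), file.path(outdir, "annotation"))

truth_out <- sim$truth[c("de", "de_condition", "planted_tf",
                         "planted_targets")]
truth_out$differential_events <- ev_truth$differential
jsonlite::write_json(truth_out, file.path(outdir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d genes x %d B-cell samples (+%d-tissue panel)\n",
            nrow(sim$counts$counts), ncol(sim$counts$counts),
            ncol(tissue$counts)))
cat(sprintf("planted: %d DE genes in %s, TF %s -> %s, %d/%d shifted events\n",
            nrow(sim$truth$de), sim$truth$de_condition, sim$truth$planted_tf,
            paste(sim$truth$planted_targets, collapse = "/"),
            length(ev_truth$differential), nrow(ev_truth$events)))
cat("inputs written under", outdir, "\n")
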