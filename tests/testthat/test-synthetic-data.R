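test_that("count generation is deterministic and respects the design", {
  cfg <- sim_config(seed = 5L)
  sim1 <- generate_counts(cfg)
  sim2 <- generate_counts(cfg)
  expect_identical(sim1$counts$counts, sim2$counts$counts)
  expect_identical(sim1$truth$de, sim2$truth$de)

  cm <- sim1$counts
  expect_equal(dim(cm$counts), c(1000L, 12L))
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == floor(cm$counts)))
  expect_equal(sort(unique(unname(cm$condition))),
               sort(c("prePB", "PB", "PC", "MBC")))
  expect_equal(sum(cm$condition == "MBC"), 3L)

  # column sums track the drawn library sizes (the planted effects and NB
  # noise perturb them by at most a modest factor)
  rng <- sim_config()$library_size_range
  expect_true(all(colSums(cm$counts) > rng[1] * 0.8))
  expect_true(all(colSums(cm$counts) < rng[2] * 1.35))

  # every planted id exists in the generated matrix
  truth <- sim1$truth
  expect_true(all(c(truth$planted_tf, truth$planted_targets,
                    truth$decoy_tfs, truth$de$gene_id)
                  %in% rownames(cm$counts)))
})

test_that("degenerate and invalid configurations are rejected or empty", {
  sim <- generate_counts(sim_config(n_genes = 0L))
  expect_equal(nrow(sim$counts$counts), 0L)
  expect_equal(nrow(sim$truth$de), 0L)
  expect_error(sim_config(n_genes = -5), "sizing")
  expect_error(sim_config(junction_depth = 0), "sizing")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(library_size_range = c(100, 10)),
               "library_size_range")
})

test_that("a planted log2FC of 2 gives a ~4x ratio of group means", {
  sim <- generate_counts(sim_config(seed = 8L))
  x <- sweep(sim$counts$counts, 2, size_factors(sim$counts), "/")
  grp <- sim$counts$condition
  up <- sim$truth$de$gene_id[sim$truth$de$log2fc > 0]
  ratio <- rowMeans(x[up, grp == "MBC"]) / rowMeans(x[up, grp == "PC"])
  expect_true(all(abs(log2(ratio) - 2) < 0.35))
  dn <- sim$truth$de$gene_id[sim$truth$de$log2fc < 0]
  ratio_dn <- rowMeans(x[dn, grp == "MBC"]) / rowMeans(x[dn, grp == "PC"])
  expect_true(all(abs(log2(ratio_dn) + 2) < 0.35))
})

test_that("junction counts invert the PSI estimator in expectation", {
  cfg <- sim_config(seed = 3L, junction_depth = 1000L)
  events <- rbind(splice_event("se", "g1", "SE", c(100, 200)),
                  splice_event("ri", "g2", "RI", c(100, 200)),
                  splice_event("a5", "g3", "A5SS", c(100, 130)),
                  splice_event("a3", "g4", "A3SS", c(100, 130)))
  # exact inverse on expected counts, all event types
  for (i in seq_len(nrow(events))) {
    for (psi in c(0, 0.15, 0.5, 0.8, 1)) {
      q <- psi * events$len_inc[i] /
        (psi * events$len_inc[i] + (1 - psi) * events$len_skip[i])
      expect_equal(compute_psi(q * 1000, (1 - q) * 1000,
                               events$len_inc[i], events$len_skip[i]),
                   psi, tolerance = 1e-12)
    }
  }

  # boundary: true PSI 1 -> zero skipping reads in every sample
  tp <- matrix(1, nrow(events), 4,
               dimnames = list(events$event_id, cfg$conditions))
  j <- generate_junction_counts(cfg, events, tp)
  expect_true(all(j$skip_reads == 0))

  # SE at PSI 0.5: expected inclusion reads are twice the skipping reads
  tp05 <- matrix(0.5, 1, 4, dimnames = list("se", cfg$conditions))
  j05 <- generate_junction_counts(cfg, events[1, ], tp05)
  expect_equal(sum(j05$inc_reads) / sum(j05$skip_reads), 2, tolerance = 0.1)

  expect_error(generate_junction_counts(cfg, events,
                                        tp * 1.5), "PSI")
  # determinism
  expect_identical(generate_junction_counts(cfg, events, tp),
                   generate_junction_counts(cfg, events, tp))
})

test_that("tissue panel has the designed size and co-regulation limit", {
  cfg <- sim_config(seed = 10L)
  sim <- generate_counts(cfg)
  tissue <- generate_tissue_panel(cfg, sim$truth)
  expect_equal(ncol(tissue$counts), 17L)

  # zero co-regulation noise: planted TF and targets correlate near 1
  cfg0 <- sim_config(seed = 10L, coregulation_noise_sd = 0)
  sim0 <- generate_counts(cfg0)
  tissue0 <- generate_tissue_panel(cfg0, sim0$truth)
  x <- log_expr(tissue0)
  for (tg in sim0$truth$planted_targets)
    expect_gt(cor(x[sim0$truth$planted_tf, ], x[tg, ]), 0.99)

  expect_identical(generate_tissue_panel(cfg, sim$truth)$counts,
                   tissue$counts)
})

test_that("toy annotation carries the exemplar exon lengths and domains", {
  ann <- build_toy_annotation()
  lens <- function(tx) tx$exons[, 2] - tx$exons[, 1]

  expect_equal(lens(ann$transcripts$SEC24C_like)[11], 116)
  expect_equal(lens(ann$transcripts$KLHL12_like)[10], 99)
  expect_equal(lens(ann$transcripts$KLHL12_like)[11], 187)
  ev <- ann$events
  expect_equal(ev$seg_end[ev$event_id == "SE_SEC24D_poison"] -
                 ev$seg_start[ev$event_id == "SE_SEC24D_poison"], 296)
  expect_equal(ev$seg_end[ev$event_id == "SE_SEC31A_E3b"] -
                 ev$seg_start[ev$event_id == "SE_SEC31A_E3b"], 50)
  expect_equal(lens(ann$transcripts$PICALM_like)[c(13, 17)] %% 3, c(0, 0))

  # CDS lies within the spliced transcript and ends at a stop codon
  for (tx in ann$transcripts) {
    s <- bcellsplice:::transcript_seq(tx)
    expect_lte(tx$cds_end + 3, nchar(s))
    expect_equal((tx$cds_end - tx$cds_start) %% 3, 0)
    expect_equal(substr(s, tx$cds_start + 1, tx$cds_start + 3), "ATG")
    expect_true(substr(s, tx$cds_end + 1, tx$cds_end + 3) %in%
                  c("TAA", "TAG", "TGA"))
  }

  # six kelch repeats, three downstream of the 99/187-nt cassette pair
  kel <- ann$domains[ann$domains$transcript_id == "KLHL12_like", ]
  expect_equal(nrow(kel), 6L)
  cassette_end <- sum(lens(ann$transcripts$KLHL12_like)[1:11])
  expect_equal(sum(kel$start >= cassette_end), 3L)

  # deterministic fixture
  ann2 <- build_toy_annotation()
  expect_identical(ann$transcripts$KLHL12_like$genome_seq,
                   ann2$transcripts$KLHL12_like$genome_seq)
})
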