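ann <- build_toy_annotation()
txs <- ann$transcripts
get_ev <- function(id) ann$events[ann$events$event_id == id, ]

test_that("frame status follows length change mod 3", {
  expect_false(frame_status(-116))
  expect_true(frame_status(-99))
  expect_false(frame_status(-187))
  expect_false(frame_status(-296))
  expect_true(frame_status(0))
  expect_false(frame_status(50))
  expect_true(frame_status(-286 - 2))  # -288 = -286 joint minus 2
})

test_that("apply_event recomputes structure, sequence and delta", {
  # skipping the 116-nt cassette
  v <- apply_event(txs$SEC24C_like, get_ev("SE_SEC24C_E11"), FALSE)
  expect_equal(v$delta_length, -116L)
  expect_equal(nrow(v$exons), nrow(txs$SEC24C_like$exons) - 1)

  # inclusion of an already-present exon is the identity
  v_id <- apply_event(txs$SEC24C_like, get_ev("SE_SEC24C_E11"), TRUE)
  expect_equal(v_id$delta_length, 0L)
  expect_identical(v_id$seq, v_id$ref_seq)

  # joint skipping of the 99 + 187 nt pair
  v10 <- apply_event(txs$KLHL12_like, get_ev("SE_KLHL12_E10"), FALSE)
  v1011 <- apply_event(v10, get_ev("SE_KLHL12_E11"), FALSE)
  expect_equal(v1011$delta_length, -286L)

  # poison-exon inclusion adds its length
  vp <- apply_event(txs$SEC24D_like, get_ev("SE_SEC24D_poison"), TRUE)
  expect_equal(vp$delta_length, 296L)

  # involution: complementary flag on the reference returns the reference
  for (eid in c("SE_SEC24C_E11", "SE_KLHL12_E10", "SE_PICALM_E13",
                "A3SS_NERF_E7")) {
    ev <- get_ev(eid)
    tx <- txs[[ev$transcript_id]]
    expect_identical(apply_event(tx, ev, TRUE)$seq,
                     bcellsplice:::transcript_seq(tx))
  }

  # structural mismatch: cassette overlapping no exon boundary
  bad <- splice_event("bad", "g", "SE", c(5, 20), chrom = "chr_SEC24C")
  expect_error(apply_event(txs$SEC24C_like, bad, FALSE),
               "structural mismatch")
})

test_that("ORF scan agrees with annotation and the translation oracle", {
  for (tx in txs) {
    orf <- scan_orf(reference_variant(tx))
    expect_equal(orf$stop_pos, tx$cds_end)
    expect_false(orf$alt_start)
  }

  # frameshift variant stop found by the brute-force translation oracle
  v <- apply_event(txs$SEC24C_like, get_ev("SE_SEC24C_E11"), FALSE)
  orf <- scan_orf(v)
  expect_equal(orf$stop_pos, oracle_first_stop(v$seq, orf$start_pos))

  # sequence with no stop after the start: none
  no_stop <- transcript_model("t", "g", "c", "+",
                              cbind(0L, 90L), 0L, 90L,
                              paste(c("ATG", rep("GCA", 40)), collapse = ""))
  v0 <- reference_variant(no_stop)
  v0$base$cds_start <- 0L
  expect_true(is.na(scan_orf(v0)$stop_pos))
})

test_that("ORF scan matches the translation oracle on random transcripts", {
  set.seed(77)
  checked <- 0
  for (i in 1:200) {
    tx <- random_toy_transcript(sprintf("rt%03d", i))
    # random internal cassette skip (never touches exon 1, so the start
    # survives)
    k <- sample(2:(nrow(tx$exons) - 1), 1)
    ev <- splice_event(paste0("ev", i), tx$gene_id, "SE", tx$exons[k, ])
    v <- apply_event(tx, ev, FALSE)
    expect_equal(frame_status(v$delta_length),
                 (nchar(v$seq) - nchar(v$ref_seq)) %% 3 == 0)
    orf <- scan_orf(v)
    expected <- oracle_first_stop(v$seq, tx$cds_start)
    if (!orf$alt_start) {
      expect_equal(orf$stop_pos, expected)
    } else {
      # the scanner fell back to an alternative start: the annotated frame
      # must indeed be stop-free, and the alt ORF must check out
      expect_true(is.na(expected))
      expect_equal(orf$stop_pos, oracle_first_stop(v$seq, orf$start_pos))
    }
    checked <- checked + 1
  }
  expect_equal(checked, 200)
})

test_that("NMD prediction implements the 50-nt last-junction rule", {
  # two exons of 500 nt: last junction at 500
  tx <- transcript_model("t", "g", "c", "+",
                         rbind(c(0L, 500L), c(600L, 1100L)), 0L, 900L,
                         paste(rep("A", 1100), collapse = ""))
  v <- reference_variant(tx)
  # stop 100 nt upstream of the junction: NMD
  expect_equal(nmd_predict(v, 400L),
               list(nmd_predicted = TRUE, stop_in_last_exon = FALSE))
  # stop exactly 50 nt upstream: still NMD (>= 50)
  expect_true(nmd_predict(v, 450L)$nmd_predicted)
  # stop 10 nt upstream: too close, escapes, but not in the last exon
  expect_equal(nmd_predict(v, 490L),
               list(nmd_predicted = FALSE, stop_in_last_exon = FALSE))
  # stop in the final exon: escape
  expect_equal(nmd_predict(v, 700L),
               list(nmd_predicted = FALSE, stop_in_last_exon = TRUE))
  # single-exon variant escapes by definition
  tx1 <- transcript_model("t1", "g", "c", "+", cbind(0L, 600L), 0L, 300L,
                          paste(rep("A", 600), collapse = ""))
  expect_equal(nmd_predict(reference_variant(tx1), 100L),
               list(nmd_predicted = FALSE, stop_in_last_exon = TRUE))

  # monotonicity: moving the PTC upstream never turns NMD off
  calls <- vapply(seq(0, 497, by = 7), function(p)
    nmd_predict(v, as.integer(p))$nmd_predicted, logical(1))
  expect_true(all(diff(as.integer(calls)) <= 0))

  expect_error(nmd_predict(v, NA_integer_), "valid")
})

test_that("domain truncation reproduces the kelch-repeat exemplar", {
  dom <- ann$domains[ann$domains$transcript_id == "KLHL12_like", ]

  # reference isoform loses nothing
  st_ref <- domain_truncation(reference_variant(txs$KLHL12_like), dom)
  expect_true(all(st_ref$status == "retained"))

  # joint skip loses exactly the three repeats downstream of the pair
  v10 <- apply_event(txs$KLHL12_like, get_ev("SE_KLHL12_E10"), FALSE)
  v1011 <- apply_event(v10, get_ev("SE_KLHL12_E11"), FALSE)
  st <- domain_truncation(v1011, dom)
  expect_equal(st$domain_id[st$status == "lost"],
               c("kelch4", "kelch5", "kelch6"))
  expect_equal(sum(st$status == "retained"), 3L)

  # the frame-preserving single skip (-99 nt) deletes no repeat: downstream
  # domains stay in frame and upstream of the stop
  st10 <- domain_truncation(v10, dom)
  expect_true(all(st10$status == "retained"))

  # a variant whose stop precedes all domains loses all of them
  early <- v1011
  st_all <- domain_truncation(early, dom,
                              orf = list(start_pos = 30L, stop_pos = 60L,
                                         alt_start = FALSE, status = "ok"))
  expect_true(all(st_all$status == "lost"))

  bad <- tibble::tibble(domain_id = "x", start = 0L, end = 33L)
  expect_error(domain_truncation(reference_variant(txs$KLHL12_like), bad),
               "outside")
})

test_that("consequence categories reproduce every printed exemplar", {
  calls <- consequence_table(ann)
  by_ev <- function(id) calls[calls$event_id == id, ]

  # SEC24C exon-11 skip: frameshift + PTC -> NMD
  expect_equal(by_ev("SE_SEC24C_E11")$category, "frameshift-NMD")
  expect_equal(by_ev("SE_SEC24C_E11")$delta_length, -116L)

  # SEC24D poison inclusion: frameshift -> NMD
  expect_equal(by_ev("SE_SEC24D_poison")$category, "frameshift-NMD")

  # KLHL12 joint skip: frameshift, stop in last exon, NMD escape, 3/6 lost
  v10 <- apply_event(txs$KLHL12_like, get_ev("SE_KLHL12_E10"), FALSE)
  v1011 <- apply_event(v10, get_ev("SE_KLHL12_E11"), FALSE)
  cc <- classify_consequence(v1011,
                             ann$domains[ann$domains$transcript_id ==
                                           "KLHL12_like", ])
  expect_equal(cc$category, "frameshift-escape-alt-terminus")
  expect_true(cc$stop_in_last_exon)
  expect_false(cc$nmd_predicted)
  expect_equal(cc$n_lost_domains, 3L)

  # PICALM Delta13 / Delta17: both frame-preserving, distinct C-termini
  d13 <- by_ev("SE_PICALM_E13"); d17 <- by_ev("SE_PICALM_E17")
  expect_equal(d13$category, "frame-preserving")
  expect_equal(d17$category, "frame-preserving")
  expect_false(d13$delta_length == d17$delta_length)

  # SEC31A 50-nt inclusion: alternative-start call, flagged low-confidence
  s31 <- by_ev("SE_SEC31A_E3b")
  expect_true(s31$alt_start)
  expect_equal(s31$lost_domains, "WD40_1")

  # categories are mutually exclusive and exhaustive over the fixtures
  expect_true(all(calls$category %in%
                    c("frame-preserving", "frameshift-NMD",
                      "frameshift-escape-alt-terminus", "no-ORF")))
  expect_equal(calls$frame_preserving, calls$delta_length %% 3 == 0)
  # nmd_predicted implies a found stop outside the last exon
  expect_true(all(!calls$nmd_predicted |
                    (!is.na(calls$stop_pos) & !calls$stop_in_last_exon)))
})
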