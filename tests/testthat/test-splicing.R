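test_that("compute_psi matches the worked junction examples", {
  # zero skipping reads: fully included
  expect_equal(compute_psi(50, 0, 2, 1), 1)
  # length-normalized: 100 inclusion / 50 skipping reads on SE geometry
  expect_equal(compute_psi(100, 50, 2, 1), 0.5)
  # no coverage: missing
  expect_true(is.na(compute_psi(0, 0, 2, 1)))
  expect_error(compute_psi(-1, 5), "non-negative")
  expect_error(compute_psi(1, 5, 0, 1), "positive")

  # invariant to common scaling of both counts
  set.seed(4)
  for (i in 1:50) {
    inc <- sample(0:500, 1); skip <- sample(0:500, 1)
    if (inc + skip == 0) next
    k <- sample(1:20, 1)
    expect_equal(compute_psi(inc, skip, 2, 1),
                 compute_psi(k * inc, k * skip, 2, 1))
  }
})

test_that("psi_matrix assembles per-event PSI with event-specific lengths", {
  events <- rbind(splice_event("se", "g1", "SE", c(100, 200)),
                  splice_event("ri", "g2", "RI", c(100, 200)))
  j <- tibble::tibble(event_id = c("se", "se", "ri", "ri"),
                      sample = c("s1", "s2", "s1", "s2"),
                      inc_reads = c(100L, 0L, 30L, 0L),
                      skip_reads = c(50L, 0L, 30L, 0L))
  psi <- psi_matrix(j, events)
  expect_equal(psi["se", "s1"], 0.5)
  expect_equal(psi["ri", "s1"], 0.5)
  expect_true(is.na(psi["se", "s2"]))
  expect_error(psi_matrix(tibble::tibble(event_id = "zz", sample = "s1",
                                         inc_reads = 1L, skip_reads = 1L),
                          events), "unknown")
})

test_that("differential PSI applies the significance gate and coverage rule", {
  cond <- setNames(rep(c("A", "B"), each = 3), sprintf("s%d", 1:6))

  # identical groups: dpsi 0, not significant
  psi <- matrix(rep(c(0.4, 0.5, 0.6), 2), 1, byrow = TRUE,
                dimnames = list("e1", names(cond)))
  r <- differential_psi(psi, cond, "A", "B")
  expect_equal(r$dpsi, 0)
  expect_false(r$significant)

  # |dpsi| below the gate is never significant, however small the p
  psi2 <- matrix(c(0.80, 0.801, 0.799, 0.65, 0.651, 0.649), 1,
                 dimnames = list("e1", names(cond)))
  r2 <- differential_psi(psi2, cond, "A", "B")
  expect_lt(r2$pvalue, 0.001)
  expect_false(r2$significant)

  # events with < 2 covered replicates per group are untested, not p = 1
  psi3 <- matrix(c(0.8, NA, NA, 0.2, 0.25, 0.22), 1,
                 dimnames = list("e1", names(cond)))
  r3 <- differential_psi(psi3, cond, "A", "B")
  expect_false(r3$tested)
  expect_true(is.na(r3$pvalue))
  expect_false(r3$significant)

  expect_error(differential_psi(psi, cond, "A", "Z"), "unknown condition")
})

test_that("a planted PSI 1.0 vs 0.5 change is detected with dpsi ~ -0.5", {
  hits <- 0
  for (s in 1:100) {
    cfg <- sim_config(conditions = c("PC", "MBC"), seed = s)
    ev <- splice_event("e1", "g1", "SE", c(100, 200))
    tp <- matrix(c(1, 0.5), 1, 2, dimnames = list("e1", c("PC", "MBC")))
    j <- generate_junction_counts(cfg, ev, tp)
    psi <- psi_matrix(j, ev)
    r <- differential_psi(psi, setNames(j$condition, j$sample), "PC", "MBC")
    if (r$significant && abs(r$dpsi + 0.5) < 0.1) hits <- hits + 1
  }
  # with one group at PSI exactly 1.0 the Welch df collapses to 2, so the
  # realized p sits near the 0.001 gate; ~90% detection is the honest level
  # at depth 1000 (see the methods vignette)
  expect_gte(hits / 100, 0.85)
})

test_that("event breakdown counts significant events by type", {
  events <- do.call(rbind, c(
    lapply(1:8, function(i) splice_event(paste0("se", i), "g", "SE", c(1, 2))),
    lapply(1:2, function(i) splice_event(paste0("ri", i), "g", "RI", c(1, 2))),
    list(splice_event("a5", "g", "A5SS", c(1, 2)))))
  res <- tibble::tibble(event_id = events$event_id,
                        significant = c(rep(TRUE, 10), FALSE))
  bd <- event_breakdown(res, events)
  expect_equal(bd$n[bd$etype == "SE"], 8L)
  expect_equal(bd$pct[bd$etype == "SE"], 80)
  expect_equal(bd$pct[bd$etype == "RI"], 20)
  expect_equal(sum(bd$n), sum(res$significant))
  expect_equal(sum(bd$pct), 100)

  none <- event_breakdown(tibble::tibble(event_id = character(0),
                                         significant = logical(0)), events)
  expect_true(all(none$n == 0))
})

test_that("direction summary mirrors the lower-inclusion fraction", {
  res <- tibble::tibble(event_id = sprintf("e%d", 1:5),
                        dpsi = c(-0.5, -0.6, -0.7, 0.5, -0.1),
                        significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  attr(res, "group_a") <- "PC"; attr(res, "group_b") <- "MBC"
  # 3 of 4 significant events have lower PSI in MBC
  expect_equal(direction_summary(res, "MBC"), 0.75)
  expect_equal(direction_summary(res, "PC"), 0.25)
  expect_error(direction_summary(res, "PB"), "focal_group")

  res$significant <- FALSE
  expect_true(is.na(direction_summary(res, "MBC")))
})

test_that("isoform fractions follow the independence product rule", {
  f <- isoform_fractions_from_junctions(90, 10, 50, 50)
  expect_equal(unname(f), c(0.45, 0.45, 0.05, 0.05))
  expect_equal(sum(f), 1)
  expect_equal(names(f), c("NERF-1a", "NERF-1b", "NERF-2a", "NERF-2b"))

  expect_equal(unname(isoform_fractions_from_junctions(10, 0, 10, 0)),
               c(1, 0, 0, 0))
  expect_equal(unname(isoform_fractions_from_junctions(5, 5, 5, 5)),
               rep(0.25, 4))
  expect_error(isoform_fractions_from_junctions(0, 0, 5, 5), "estimation")
  expect_error(isoform_fractions_from_junctions(5, 5, -1, 5),
               "non-negative")
})
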