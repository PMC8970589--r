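test_that("generated genomes respect length, composition and determinism", {
  g0 <- simulate_genome(10, 0, seed = 1)
  expect_equal(nchar(g0[[1]]), 10)
  expect_true(grepl("^[AT]+$", g0[[1]]))

  g <- simulate_genome(100000, 0.5, seed = 7)
  gc <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C"))
  # binomial CI oracle: 3 SDs of Binom(1e5, 0.5)
  expect_lt(abs(gc - 50000), 3 * sqrt(100000 * 0.25))

  expect_identical(simulate_genome(500, 0.4, seed = 3),
                   simulate_genome(500, 0.4, seed = 3))
  expect_error(simulate_genome(0, 0.5), "positive")
  expect_error(simulate_genome(10, 1.5), "\\[0,1\\]")
})

test_that("planted sites match their motif, strand and spacing", {
  g <- simulate_genome(5000, 0.5, seed = 2)
  pl <- plant_sites(g, "TTACCC", 3, c(1, 2, 3), min_gap = 50, seed = 9)
  for (i in 1:3) {
    s <- pl$sites[i, ]
    ref <- substr(pl$genome[[1]], s$start + 1, s$end)
    on_motif <- if (s$strand == "-") oracle_revcomp(ref) else ref
    expect_identical(on_motif, "TTACCC")
    expect_identical(s$motif_seq, "TTACCC")
  }

  pl2 <- plant_sites(g, "CGTNNNNNRNKA", 5, rep(1, 5), min_gap = 50, seed = 4)
  for (i in 1:5) {
    expect_true(oracle_matches_motif(pl2$sites$motif_seq[i], "CGTNNNNNRNKA"))
    ref <- substr(pl2$genome[[1]], pl2$sites$start[i] + 1, pl2$sites$end[i])
    on_motif <- if (pl2$sites$strand[i] == "-") oracle_revcomp(ref) else ref
    expect_identical(on_motif, pl2$sites$motif_seq[i])
  }
  gaps <- with(pl2$sites, start[-1] - end[-5])
  expect_true(all(gaps >= 50))

  pl0 <- plant_sites(g, "TTACCC", 0, numeric(0))
  expect_identical(pl0$genome, g)
  expect_equal(nrow(pl0$sites), 0)

  expect_error(plant_sites(g, "TTACCC", 200, rep(1, 200), min_gap = 50),
               "cannot place")
})

test_that("lesion fields follow the planted base-dependent Poisson rates", {
  # no-footprint null: suppression/hotspot absent => cellular and naked
  # expected counts coincide position-wise (identical truth rates)
  s <- small_sim(seed = 11, suppression_profile = NULL)
  expect_equal(s$field$truth$p_cellular, s$field$truth$p_naked)

  # zero rates for C/T => lesions only at purine-on-lesion-strand positions
  s2 <- small_sim(seed = 12,
                  base_damage_rate = c(A = 4, C = 0, G = 20, T = 0))
  expect_true(all(s2$field$cellular$base %in% c("A", "G")))
  expect_true(all(s2$field$naked$base %in% c("A", "G")))

  # planted core suppression recovered from raw counts within 3 SDs
  s3 <- small_sim(seed = 13, n_sites = 30L, genome_length = 100000L,
                  depth = 1e6, occupancy_values = rep(20, 30),
                  suppression_profile = rect_profile(6, 0.3))
  tr <- s3$field
  core_pos <- unlist(lapply(seq_len(nrow(s3$sites)), function(i) {
    s3$sites$midpoint[i] + (-6:6)
  }))
  cell_core <- sum(tr$cellular$count[tr$cellular$pos %in% core_pos])
  naked_core <- sum(tr$naked$count[tr$naked$pos %in% core_pos])
  # Poisson-ratio oracle: expected core ratio after depth alignment
  lam_c <- sum(tr$truth$lambda_cellular$plus[core_pos + 1],
               tr$truth$lambda_cellular$minus[core_pos + 1])
  lam_n <- sum(tr$truth$lambda_naked$plus[core_pos + 1],
               tr$truth$lambda_naked$minus[core_pos + 1])
  ratio <- (cell_core / naked_core) / (lam_c / lam_n) * 0.3
  se <- 0.3 * sqrt(1 / lam_c + 1 / lam_n)
  expect_lt(abs(ratio - 0.3), 3 * se)

  # determinism: identical config and seed => identical tracks
  s4a <- small_sim(seed = 21)
  s4b <- small_sim(seed = 21)
  expect_identical(track_df(s4a$field$cellular), track_df(s4b$field$cellular))
  expect_identical(track_df(s4a$field$naked), track_df(s4b$field$naked))
})

test_that("repair thinning follows first-order survival", {
  s <- small_sim(seed = 31, n_sites = 0L, occupancy_values = numeric(0),
                 genome_length = 50000L, depth = 5e5,
                 nucleosome_dyad_inhibition = 1)
  f <- s$field

  expect_identical(simulate_repair_timepoint(f$cellular, f$truth, 0, seed = 1),
                   f$cellular)

  # uniform k: genome-wide remaining fraction ~ exp(-k t), binomial oracle
  t2 <- simulate_repair_timepoint(f$cellular, f$truth, 2, seed = 2)
  n0 <- sum(f$cellular$count)
  p <- exp(-s$cfg$repair_rate_background * 2)
  expect_lt(abs(sum(t2$count) / n0 - p), 3 * sqrt(p * (1 - p) / n0))

  # zero repair rate inside the motif => counts unchanged there, exactly
  s5 <- small_sim(seed = 32, n_sites = 10L,
                  occupancy_values = rep(20, 10), depth = 5e5,
                  repair_inhibition_profile = rect_profile(3, 0),
                  nucleosome_dyad_inhibition = 1)
  core_pos <- unlist(lapply(s5$sites$midpoint, function(m) m + (-3:3)))
  t2b <- simulate_repair_timepoint(s5$field$cellular, s5$field$truth, 2,
                                   seed = 3)
  a <- s5$field$cellular[s5$field$cellular$pos %in% core_pos, ]
  b <- t2b[t2b$pos %in% core_pos, ]
  expect_identical(track_df(a), track_df(b))

  # monotonicity along the time course (same seed chain)
  t1 <- simulate_repair_timepoint(f$cellular, f$truth, 1, seed = 5)
  j <- dplyr::left_join(t1, f$cellular, by = c("chrom", "pos", "strand"),
                        suffix = c("_t", "_0"))
  expect_true(all(j$count_t <= j$count_0))
  expect_error(simulate_repair_timepoint(f$cellular, f$truth, -1), "non-negative")
})

test_that("read emission is the exact inverse of lesion inference", {
  g <- c(chrZ = "ACGTACGTAC")
  # single interior + strand lesion -> one minus-strand read, hand-traced
  one <- toy_track(4, "+", 1, chrom = "chrZ", base = "A")
  r <- emit_reads(one, g)
  expect_equal(nrow(r), 1)
  expect_equal(r$pos, 3L)
  expect_equal(r$strand, "-")
  back <- infer_lesions(r, g)
  expect_equal(back$pos, 4L)
  expect_equal(back$strand, "+")

  # empty table -> empty read set
  r0 <- emit_reads(toy_track(integer(), character(), integer(), chrom = character()), g)
  expect_equal(nrow(r0), 0)

  # conservation incl. edge drops: lesion at + strand pos 0 has no
  # upstream read position
  edge <- toy_track(c(0, 5), c("+", "+"), c(2, 3), chrom = "chrZ")
  re <- emit_reads(edge, g)
  expect_equal(attr(re, "dropped_lesions"), 2L)
  expect_equal(sum(re$count) + attr(re, "dropped_lesions"), 5L)

  # round trip on a full simulated field
  s <- small_sim(seed = 41)
  reads <- emit_reads(s$field$cellular, s$genome)
  inf <- infer_lesions(reads, s$genome)
  L <- nchar(s$genome[[1]])
  retained <- dplyr::filter(s$field$cellular,
                            !(strand == "+" & pos == 0),
                            !(strand == "-" & pos == L - 1))
  expect_identical(track_df(inf), track_df(retained))
  expect_equal(sum(reads$count) + attr(reads, "dropped_lesions"),
               sum(s$field$cellular$count))
})

test_that("nucleosome lattice avoids site windows and shapes coverage", {
  s <- small_sim(seed = 51)
  tr <- s$field$truth
  expect_true(all(vapply(tr$dyads, function(d) {
    all(abs(d - s$sites$midpoint) > s$cfg$ndr_halfwidth)
  }, logical(1))))
  cov <- simulate_nucleosome_track(tr)
  expect_equal(nrow(cov), tr$genome_length)
  expect_true(all(cov$value >= 0 & cov$value <= 1))
  expect_equal(cov$value[cov$pos %in% tr$dyads], rep(1, length(tr$dyads)))
})
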