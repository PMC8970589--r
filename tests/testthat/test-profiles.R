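# A constant-valued per-position profile over a small genome.
const_profile <- function(L, value = 1, chrom = "c") {
  tibble::tibble(chrom = chrom, pos = 0:(L - 1), value = value,
                 masked = FALSE)
}

test_that("metaprofile aggregation is exact on constructed signals", {
  L <- 2000L
  sites <- tibble::tibble(chrom = "c", midpoint = c(500L, 1400L),
                          strand = c("+", "-"))
  flat <- site_metaprofile(const_profile(L, 3.5), sites, flank = 100,
                           window = 5)
  expect_true(all(flat$value == 3.5))
  expect_equal(attr(flat, "n_features"), 2L)

  # single + strand site: profile equals the local value series
  ramp <- tibble::tibble(chrom = "c", pos = 0:(L - 1),
                         value = as.numeric(0:(L - 1)), masked = FALSE)
  one <- site_metaprofile(ramp, sites[1, ], flank = 10, window = 1)
  expect_equal(one$value, as.numeric(490:510))
  expect_equal(one$rel_pos, -10:10)

  # single - strand site: the mirror of the local series
  mone <- site_metaprofile(ramp, sites[2, ], flank = 10, window = 1)
  expect_equal(mone$value, as.numeric(1410:1390))
})

test_that("TSS profiles follow gene orientation", {
  L <- 1000L
  ramp <- tibble::tibble(chrom = "c", pos = 0:(L - 1),
                         value = as.numeric(0:(L - 1)), masked = FALSE)
  genes <- tibble::tibble(gene_id = c("f", "r"), chrom = "c",
                          tss = c(300L, 700L), strand = c("+", "-"))
  fwd <- tss_metaprofile(ramp, genes[1, ], flank = 5, window = 1)
  expect_equal(fwd$value, as.numeric(295:305))
  rev <- tss_metaprofile(ramp, genes[2, ], flank = 5, window = 1)
  expect_equal(rev$value, as.numeric(705:695))

  flat <- tss_metaprofile(const_profile(L, 2), genes, flank = 50, window = 5)
  expect_true(all(flat$value == 2))
})

test_that("mirroring the genome and features mirrors the profile exactly", {
  set.seed(66)
  L <- 500L
  vals <- tibble::tibble(chrom = "c", pos = 0:(L - 1),
                         value = runif(L), masked = FALSE)
  sites <- tibble::tibble(chrom = "c", midpoint = c(120L, 300L),
                          strand = c("+", "-"))
  p <- site_metaprofile(vals, sites, flank = 50, window = 1)
  mirror_vals <- dplyr::mutate(vals, pos = L - 1L - pos)
  mirror_sites <- dplyr::mutate(sites, midpoint = L - 1L - midpoint,
                                strand = c("-", "+"))
  pm <- site_metaprofile(mirror_vals, mirror_sites, flank = 50, window = 1)
  expect_equal(pm$value, p$value)
})

test_that("pooled-count aggregation is additive across libraries", {
  s <- small_sim(seed = 111)
  hi <- dplyr::filter(stratify_occupancy(s$sites), occupancy_class == "high")
  a <- s$field$cellular
  b <- s$field$naked
  merged <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(a, b), chrom, pos, strand, base,
                    lesion_class),
    count = sum(count), .groups = "drop")
  p_merged <- repair_metaprofile(merged, a, hi, flank = 100, window = 1)
  # pooled counts of (a + b) relative to a == 1 + pooled(b)/pooled(a)
  p_b <- repair_metaprofile(b, a, hi, flank = 100, window = 1)
  expect_equal(p_merged$value, 1 + p_b$value)
})

test_that("nucleosome overlays are scaled aggregations of coverage", {
  L <- 2000L
  sites <- tibble::tibble(chrom = "c", midpoint = c(500L, 1400L),
                          strand = c("+", "-"))
  const_cov <- tibble::tibble(chrom = "c", pos = 0:(L - 1), value = 7)
  ov <- nucleosome_overlay(const_cov, sites, flank = 100, window = 5)
  expect_true(all(ov$value == 1.0))

  # planted lattice with site-centered depletion: minimum at the origin
  s <- small_sim(seed = 121)
  cov <- simulate_nucleosome_track(s$field$truth)
  hi <- dplyr::filter(stratify_occupancy(s$sites), occupancy_class == "high")
  ov2 <- nucleosome_overlay(cov, hi, flank = 300, window = 5)
  prof <- repair_metaprofile(s$field$naked, s$field$cellular, hi,
                             flank = 300, window = 5)
  expect_equal(nrow(ov2), nrow(prof))
  core <- mean(ov2$value[abs(ov2$rel_pos) <= 50])
  distal <- mean(ov2$value[abs(ov2$rel_pos) >= 200])
  expect_lt(core, distal)
  expect_error(nucleosome_overlay(const_cov[0, ], sites), "empty")
})

test_that("gene heatmaps order rows by site-TSS distance", {
  L <- 1500L
  vals <- const_profile(L)
  genes <- tibble::tibble(gene_id = c("near", "far"), chrom = "c",
                          tss = c(450L, 1050L), strand = c("+", "-"))
  sites <- tibble::tibble(chrom = "c", midpoint = c(400L, 800L))
  links <- link_to_tss(sites, genes)
  expect_equal(sort(abs(links$distance)), c(50, 250))
  hm <- gene_heatmap(vals, links, genes, flank = 100, window = 5)
  expect_equal(levels(hm$gene_id), c("far", "near"))  # longest on top
  expect_equal(length(unique(hm$gene_id)), 2)
  # ordering equals a brute-force sort on |distance|
  ord <- links$gene_id[order(-abs(links$distance))]
  expect_equal(levels(hm$gene_id), ord)
  expect_error(gene_heatmap(vals, links[0, ], genes), "empty")
})

test_that("inhibition width reads off constructed footprints exactly", {
  mk <- function(half) {
    tibble::tibble(rel_pos = -300:300,
                   value = ifelse(abs(-300:300) <= half, 2, 1))
  }
  w30 <- inhibition_width(mk(15), baseline_span = c(100, 300),
                          threshold_frac = 0.2)
  expect_equal(w30$width, 30)
  expect_equal(c(w30$left, w30$right), c(-15, 15))
  expect_false(w30$flagged)

  w50 <- inhibition_width(mk(25), baseline_span = c(100, 300),
                          threshold_frac = 0.2)
  expect_equal(w50$width, 50)
  expect_equal(w50$width - w30$width, 20)

  flat <- inhibition_width(
    tibble::tibble(rel_pos = -300:300, value = 1),
    baseline_span = c(100, 300))
  expect_equal(flat$width, 0)
  expect_true(flat$flagged)

  # formation dips work with the reversed comparator
  dip <- tibble::tibble(rel_pos = -300:300,
                        value = ifelse(abs(-300:300) <= 10, 0.3, 1))
  wd <- inhibition_width(dip, baseline_span = c(100, 300),
                         direction = "dip")
  expect_equal(wd$width, 20)
  expect_equal(tidy(wd)$width, 20)
})

test_that("window significance separates planted differences and calibrates", {
  # identical groups: statistic 0, adjusted p ~ 1
  a <- tibble::tibble(rel_pos = rep(0:24, each = 4), value = 1)
  eq <- window_significance(a, a, w = 5)
  expect_true(all(eq$statistic == 0))
  expect_true(all(eq$p_adjusted == 1))

  # planted 0.3x suppression at the core is detected at FDR 0.05
  set.seed(77)
  n_sites <- 200
  obs <- function(mult_core) {
    tibble::tibble(
      rel_pos = rep(c(2, 52), each = n_sites),
      value = c(rpois(n_sites, 20 * mult_core), rpois(n_sites, 20)) / 20
    )
  }
  sig <- window_significance(obs(0.3), obs(1), w = 5)
  expect_lt(sig$p_adjusted[sig$rel_pos == 2], 0.05)
  expect_gt(sig$p_adjusted[sig$rel_pos == 52], 0.05)
})
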