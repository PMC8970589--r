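# Restrict a track to a region universe (tibble chrom,start,end; 0-based
# half-open). NULL means the whole track.
restrict_to_regions <- function(track, regions) {
  if (is.null(regions)) return(track)
  if (nrow(regions) == 0) abort("empty region set")
  gr_t <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$pos + 1L, width = 1L))
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
  hit <- GenomicRanges::countOverlaps(gr_t, gr_r) > 0
  track[hit, , drop = FALSE]
}

join_tracks <- function(a, b, names = c("a", "b")) {
  a <- select(a, "chrom", "pos", "strand", "count")
  b <- select(b, "chrom", "pos", "strand", "count")
  j <- full_join(a, b, by = c("chrom", "pos", "strand"),
                 suffix = c("_a", "_b"))
  j$count_a[is.na(j$count_a)] <- 0L
  j$count_b[is.na(j$count_b)] <- 0L
  stats::setNames(j, c("chrom", "pos", "strand", names))
}

#' Per-position damage-formation ratio (cellular vs naked DNA)
#'
#' Normalizes a cellular lesion track to a naked-DNA control to factor out
#' the sequence-intrinsic damage propensity, leaving the modulation caused
#' by bound proteins. Both libraries are depth-scaled by their total
#' lesion-class reads within the analysis region, the per-position ratio is
#' taken, positions with insufficient naked-DNA coverage are masked, and
#' the profile is rescaled so its mean over unmasked positions equals 1.
#'
#' @param cellular,naked Lesion tracks (same genome, same lesion class).
#' @param regions Optional analysis region tibble (chrom, start, end;
#'   0-based half-open); `NULL` uses all positions present in either track.
#' @param min_naked Mask positions whose naked count is below this floor
#'   (default 1; no pseudocount smoothing is applied).
#' @return Per-position profile tibble (chrom, pos, strand, cellular,
#'   naked, value, masked) with mean(value[!masked]) == 1.
#' @export
damage_ratio <- function(cellular, naked, regions = NULL, min_naked = 1L) {
  if (min_naked < 1) abort("min_naked must be >= 1")
  cellular <- restrict_to_regions(cellular, regions)
  naked <- restrict_to_regions(naked, regions)
  j <- join_tracks(cellular, naked, c("cellular", "naked"))
  if (nrow(j) == 0) abort("tracks are disjoint or empty in the region")
  tot_c <- sum(j$cellular)
  tot_n <- sum(j$naked)
  j$masked <- j$naked < min_naked
  # a naked library with no usable coverage masks everything, error-free
  j$value <- if_else(j$masked | tot_c == 0 | tot_n == 0, NA_real_,
                     (j$cellular / tot_c) / (j$naked / max(tot_n, 1)))
  usable <- !j$masked & !is.na(j$value)
  if (any(usable) && mean(j$value[usable]) > 0) {
    j$value <- j$value / mean(j$value[usable])
  }
  as_tibble(j)
}

#' Spike-in depth-correction factor
#'
#' Ratio of spike-in (e.g. damaged plasmid) lesion reads at time 0 over
#' time `t`; multiplying a remaining-damage ratio by this factor corrects
#' for library-depth differences between the two time points.
#'
#' @param spike_reads_0,spike_reads_t Spike-in read totals at 0 hr and at
#'   the repair time point.
#' @return A positive scalar.
#' @export
spike_factor <- function(spike_reads_0, spike_reads_t) {
  if (spike_reads_0 <= 0 || spike_reads_t <= 0) {
    abort("spike-in read totals must be positive")
  }
  spike_reads_0 / spike_reads_t
}

#' Per-position fraction of remaining damage
#'
#' Divides depth-scaled lesion counts at a repair time point by the initial
#' (0 hr) counts. High values indicate slow repair. With a spike-in factor
#' the raw count ratio is multiplied by it instead of relying on total-count
#' depth scaling alone. Values above 1 can arise from noise and are
#' reported as-is (flagged via the `over_one` column, never clipped).
#'
#' @param track_t Lesion track after repair time `t`.
#' @param track_0 Lesion track at 0 hr (must have signal in the region).
#' @param spike Optional spike-in factor from [spike_factor()], the
#'   preferred depth correction; overrides `scale`.
#' @param regions Optional analysis region tibble as in [damage_ratio()].
#' @param min_t0 Mask positions whose 0 hr count is below this floor.
#' @param scale `"none"` (default) takes the raw count ratio — correct
#'   whenever the two tracks are already on a common scale (spike-in
#'   corrected upstream, or survivors of the same initial field);
#'   `"total"` depth-matches by total lesion-class reads in the region,
#'   for independently sequenced libraries without a spike-in.
#' @return Per-position profile tibble (chrom, pos, strand, count_t,
#'   count_0, value, masked, over_one).
#' @export
remaining_fraction <- function(track_t, track_0, spike = NULL,
                               regions = NULL, min_t0 = 1L,
                               scale = c("none", "total")) {
  scale <- match.arg(scale)
  track_t <- restrict_to_regions(track_t, regions)
  track_0 <- restrict_to_regions(track_0, regions)
  j <- join_tracks(track_t, track_0, c("count_t", "count_0"))
  if (nrow(j) == 0 || sum(j$count_0) == 0) {
    abort("no 0 hr signal in the analysis region")
  }
  scale <- if (!is.null(spike)) {
    if (spike <= 0) abort("spike factor must be positive")
    spike
  } else if (scale == "total") {
    (sum(j$count_0)) / max(sum(j$count_t), 1)
  } else {
    1
  }
  j$masked <- j$count_0 < min_t0
  j$value <- if_else(j$masked, NA_real_,
                     (j$count_t / j$count_0) * scale)
  j$over_one <- !j$masked & j$value > 1
  as_tibble(j)
}

#' Average a profile in non-overlapping windows
#'
#' Tiles the position axis with non-overlapping windows of width `w`
#' anchored at the origin (windows cover positions `0..w-1`, `w..2w-1`,
#' and mirrored on the negative side), and averages the unmasked member
#' positions of each window. Windows whose members are all masked stay
#' masked.
#'
#' @param profile Tibble with a position column (`rel_pos` if present,
#'   otherwise `pos`), a `value` column and optionally `masked`.
#' @param w Window width in bases (default 5; `w = 1` is the identity).
#' @return Tibble (rel_pos = window center, value, n, masked).
#' @export
window_average <- function(profile, w = 5L) {
  if (w < 1) abort("window width must be >= 1")
  pos_col <- if ("rel_pos" %in% names(profile)) "rel_pos" else "pos"
  p <- tibble(pos = profile[[pos_col]], value = profile$value)
  p$masked <- if ("masked" %in% names(profile)) profile$masked else is.na(p$value)
  p$win <- floor(p$pos / w)
  out <- summarise(
    group_by(p, .data$win),
    value = if (any(!.data$masked)) mean(.data$value[!.data$masked]) else NA_real_,
    n = sum(!.data$masked),
    .groups = "drop"
  )
  out <- mutate(out,
                rel_pos = .data$win * w + (w - 1) / 2,
                masked = .data$n == 0L)
  select(arrange(out, .data$rel_pos), "rel_pos", "value", "n", "masked")
}

#' Pearson correlation between replicate lesion tracks
#'
#' Bins each track (both strands pooled), depth-normalizes by library
#' totals, and computes the Pearson correlation over bins where both
#' replicates have signal — the standard reproducibility check for
#' damage-mapping libraries.
#'
#' @param track_a,track_b Lesion tracks on the same genome.
#' @param bin Bin width in bases.
#' @return Pearson correlation coefficient (scalar).
#' @export
replicate_correlation <- function(track_a, track_b, bin = 50L) {
  if (bin < 1) abort("bin must be >= 1")
  bin_track <- function(tr) {
    summarise(group_by(tr, chrom = .data$chrom, bin = .data$pos %/% bin),
              count = sum(.data$count), .groups = "drop")
  }
  a <- bin_track(track_a)
  b <- bin_track(track_b)
  j <- inner_join(a, b, by = c("chrom", "bin"), suffix = c("_a", "_b"))
  j <- filter(j, .data$count_a > 0, .data$count_b > 0)
  if (nrow(j) < 2) abort("fewer than 2 jointly nonzero bins")
  cor(j$count_a / sum(a$count), j$count_b / sum(b$count))
}
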