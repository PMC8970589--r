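# Features table used by every aggregator: chrom, origin (midpoint or
# TSS), strand. Builders accept site or gene tibbles.
as_features <- function(x) {
  if (all(c("origin", "strand") %in% names(x))) {
    tibble(chrom = x$chrom, origin = x$origin, strand = x$strand)
  } else if (all(c("midpoint", "strand") %in% names(x))) {
    tibble(chrom = x$chrom, origin = x$midpoint, strand = x$strand)
  } else if (all(c("tss", "strand") %in% names(x))) {
    tibble(chrom = x$chrom, origin = x$tss, strand = x$strand)
  } else {
    abort("features need chrom plus midpoint/strand or tss/strand columns")
  }
}

# Long table of (feature, offset, genomic position) within +/- flank.
feature_positions <- function(features, flank) {
  offs <- seq.int(-flank, flank)
  n <- nrow(features)
  tibble(
    feature = rep(seq_len(n), each = length(offs)),
    chrom = rep(features$chrom, each = length(offs)),
    rel_pos = rep(offs, times = n),
    pos = relative_to_genomic(rep(offs, times = n),
                              rep(features$origin, each = length(offs)),
                              rep(features$strand, each = length(offs)))
  )
}

new_meta_profile <- function(df, window, flank, n_features,
                             type = "signal", overlay = NULL) {
  structure(df, class = c("meta_profile", class(tibble())),
            window = window, flank = flank, n_features = n_features,
            type = type, overlay = overlay)
}

# Pool track counts (both strands) per oriented offset across features.
pool_counts <- function(track, fpos) {
  per_pos <- summarise(group_by(track, .data$chrom, .data$pos),
                       count = sum(.data$count), .groups = "drop")
  j <- inner_join(fpos, per_pos, by = c("chrom", "pos"))
  out <- summarise(group_by(j, .data$rel_pos), count = sum(.data$count),
                   .groups = "drop")
  full <- tibble(rel_pos = seq.int(min(fpos$rel_pos), max(fpos$rel_pos)))
  out <- left_join(full, out, by = "rel_pos")
  out$count[is.na(out$count)] <- 0L
  out
}

#' Metaprofile of a per-position signal around oriented features
#'
#' Maps every genomic position within `flank` of each feature origin to a
#' motif-relative offset (strand-aware, so profiles read 5'->3' along the
#' motif/gene strand), averages the unmasked per-position values per
#' offset, and window-averages the result.
#'
#' @param profile Per-position value tibble (chrom, pos, value, optional
#'   masked), e.g. from [damage_ratio()] or [remaining_fraction()].
#' @param sites Oriented site tibble (chrom, midpoint, strand).
#' @param flank Flank in bases on each side of the origin.
#' @param window Averaging window width in bases ([window_average()]).
#' @param origin_shift Optional origin shift (see [orient_relative()]).
#' @return A `meta_profile` tibble (rel_pos, value, n, masked).
#' @export
site_metaprofile <- function(profile, sites, flank = 500L, window = 5L,
                             origin_shift = 0L) {
  features <- as_features(sites)
  fpos <- feature_positions(features, flank)
  fpos$rel_pos <- fpos$rel_pos - origin_shift
  p <- profile
  if (!"masked" %in% names(p)) p$masked <- is.na(p$value)
  # strand-collapse the per-position values first
  per_pos <- summarise(
    group_by(p, .data$chrom, .data$pos),
    value = if (any(!.data$masked)) mean(.data$value[!.data$masked]) else NA_real_,
    .groups = "drop"
  )
  j <- inner_join(fpos, per_pos, by = c("chrom", "pos"))
  if (nrow(j) == 0 || all(is.na(j$value))) {
    abort("no feature overlaps usable signal")
  }
  agg <- summarise(
    group_by(j, .data$rel_pos),
    value = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  agg$masked <- agg$n == 0L
  out <- window_average(agg, w = window)
  new_meta_profile(out, window, flank, nrow(features))
}

#' @rdname site_metaprofile
#' @param genes Gene tibble (gene_id, chrom, tss, strand); upstream of the
#'   TSS is the negative side of the axis.
#' @export
tss_metaprofile <- function(profile, genes, flank = 500L, window = 5L) {
  site_metaprofile(profile, as_features(genes), flank = flank,
                   window = window)
}

#' Damage-formation metaprofile (pooled-count route)
#'
#' The canonical formation analysis: cellular and naked-DNA lesion counts
#' are pooled across features per motif-relative offset, each library is
#' depth-scaled by its pooled total, the per-offset ratio is taken, offsets
#' with insufficient naked coverage are masked, the profile is rescaled to
#' mean 1 over the plotted span, and finally window-averaged. Pooling
#' before the ratio keeps single-nucleotide resolution usable where
#' per-site counts are sparse; set `method = "mean_of_ratios"` to average
#' per-position ratios ([damage_ratio()]) instead.
#'
#' @inheritParams site_metaprofile
#' @param cellular,naked Lesion tracks of one lesion class.
#' @param min_naked Mask offsets whose pooled naked count is below this.
#' @param method `"pooled"` (default) or `"mean_of_ratios"`.
#' @return A `meta_profile` tibble (rel_pos, value, n, masked) with
#'   `type = "formation"`.
#' @export
damage_metaprofile <- function(cellular, naked, sites, flank = 500L,
                               window = 5L, min_naked = 1L,
                               origin_shift = 0L,
                               method = c("pooled", "mean_of_ratios")) {
  method <- match.arg(method)
  if (method == "mean_of_ratios") {
    regions <- feature_regions(sites, flank)
    pr <- damage_ratio(cellular, naked, regions = regions,
                       min_naked = min_naked)
    out <- site_metaprofile(pr, sites, flank, window, origin_shift)
    attr(out, "type") <- "formation"
    return(out)
  }
  features <- as_features(sites)
  fpos <- feature_positions(features, flank)
  fpos$rel_pos <- fpos$rel_pos - origin_shift
  pc <- pool_counts(cellular, fpos)
  pn <- pool_counts(naked, fpos)
  tot_c <- sum(pc$count)
  tot_n <- sum(pn$count)
  if (tot_c == 0 || tot_n == 0) abort("no feature overlaps usable signal")
  agg <- tibble(rel_pos = pc$rel_pos,
                value = (pc$count / tot_c) / (pn$count / tot_n),
                n = pn$count)
  agg$masked <- pn$count < min_naked
  agg$value[agg$masked] <- NA_real_
  agg$value <- agg$value / mean(agg$value[!agg$masked])
  out <- window_average(agg, w = window)
  new_meta_profile(out, window, flank, nrow(features), type = "formation")
}

#' Remaining-damage metaprofile (pooled-count route)
#'
#' Fraction of remaining damage around features: time-point and 0 hr
#' counts are pooled per offset, depth-scaled (by pooled totals, or by a
#' spike-in factor when supplied), and ratioed. No mean-1 rescaling is
#' applied — the fraction is meaningful on its absolute scale.
#'
#' @inheritParams damage_metaprofile
#' @inheritParams remaining_fraction
#' @param track_t,track_0 Lesion tracks at repair time `t` and at 0 hr.
#' @param features Optional pre-built feature tibble; sites or genes both
#'   work (`sites` is ignored when given).
#' @return A `meta_profile` with `type = "remaining"`.
#' @export
repair_metaprofile <- function(track_t, track_0, sites, flank = 500L,
                               window = 5L, spike = NULL, min_t0 = 1L,
                               origin_shift = 0L, features = NULL,
                               scale = c("none", "total"),
                               method = c("pooled", "mean_of_ratios")) {
  method <- match.arg(method)
  scale_mode <- match.arg(scale)
  features <- if (is.null(features)) as_features(sites) else features
  if (method == "mean_of_ratios") {
    regions <- tibble(chrom = features$chrom,
                      start = pmax(0L, features$origin - flank),
                      end = features$origin + flank + 1L)
    pr <- remaining_fraction(track_t, track_0, spike = spike,
                             regions = regions, min_t0 = min_t0,
                             scale = scale_mode)
    out <- site_metaprofile(pr, features, flank, window, origin_shift)
    attr(out, "type") <- "remaining"
    return(out)
  }
  fpos <- feature_positions(features, flank)
  fpos$rel_pos <- fpos$rel_pos - origin_shift
  pt <- pool_counts(track_t, fpos)
  p0 <- pool_counts(track_0, fpos)
  if (sum(p0$count) == 0) abort("no 0 hr signal at the features")
  scale <- if (!is.null(spike)) spike
           else if (scale_mode == "total") sum(p0$count) / max(sum(pt$count), 1)
           else 1
  agg <- tibble(rel_pos = pt$rel_pos, n = p0$count)
  agg$masked <- p0$count < min_t0
  agg$value <- if_else(agg$masked, NA_real_,
                       (pt$count / p0$count) * scale)
  out <- window_average(agg, w = window)
  new_meta_profile(out, window, flank, nrow(features), type = "remaining")
}

# Region tibble covering feature midpoints +/- flank.
feature_regions <- function(sites, flank) {
  f <- as_features(sites)
  tibble(chrom = f$chrom, start = pmax(0L, f$origin - flank),
         end = f$origin + flank + 1L)
}

#' Nucleosome-density overlay for a metaprofile
#'
#' Runs a coverage track (e.g. MNase-derived dyad density) through the
#' same feature-relative aggregation and scales the result to `[0,1]` so
#' it can be drawn as the gray background of a repair plot.
#'
#' @param coverage Tibble (chrom, pos, value), strandless coverage.
#' @param features Site or gene tibble (oriented).
#' @inheritParams site_metaprofile
#' @return A `meta_profile` with `type = "nucleosome"`, values in `[0,1]`.
#' @export
nucleosome_overlay <- function(coverage, features, flank = 500L,
                               window = 5L) {
  if (nrow(coverage) == 0) abort("empty coverage track")
  prof <- tibble(chrom = coverage$chrom, pos = coverage$pos,
                 value = coverage$value, masked = FALSE)
  out <- site_metaprofile(prof, as_features(features), flank, window)
  mx <- max(out$value, na.rm = TRUE)
  if (mx > 0) out$value <- out$value / mx
  attr(out, "type") <- "nucleosome"
  out
}

#' Attach a nucleosome overlay to a profile
#'
#' @param profile A `meta_profile`.
#' @param overlay A `meta_profile` from [nucleosome_overlay()] (same axis).
#' @return `profile` with the overlay stored for [autoplot.meta_profile()].
#' @export
with_overlay <- function(profile, overlay) {
  stopifnot(inherits(profile, "meta_profile"),
            nrow(overlay) == nrow(profile))
  attr(profile, "overlay") <- overlay$value
  profile
}

#' Per-gene remaining-damage heatmap rows, ordered by site-TSS distance
#'
#' Builds one TSS-aligned row per linked gene from a per-position profile,
#' window-averages each row, and orders rows by the absolute distance
#' between the linked binding site and the TSS, longest distance first —
#' so the bound-site signal sweeps across the heatmap.
#'
#' @param profile Per-position value tibble (chrom, pos, value).
#' @param links Link tibble from [link_to_tss()].
#' @param genes Gene tibble supplying TSS and strand per gene_id.
#' @param flank Flank in bases around the TSS.
#' @param window Window width for row averaging.
#' @return A `gene_heatmap` tibble (gene_id, distance, rel_pos, value)
#'   whose `gene_id` factor levels encode the row order.
#' @export
gene_heatmap <- function(profile, links, genes, flank = 500L, window = 5L) {
  if (nrow(links) == 0) abort("empty link set")
  g <- inner_join(links, select(genes, "gene_id", "tss", "strand"),
                  by = c("gene_id", "tss"))
  if (nrow(g) < nrow(links)) abort("every linked gene needs a TSS annotation")
  p <- profile
  if (!"masked" %in% names(p)) p$masked <- is.na(p$value)
  per_pos <- summarise(
    group_by(p, .data$chrom, .data$pos),
    value = if (any(!.data$masked)) mean(.data$value[!.data$masked]) else NA_real_,
    .groups = "drop"
  )
  rows <- purrr::map(seq_len(nrow(g)), function(i) {
    feat <- tibble(chrom = g$chrom[i], origin = g$tss[i],
                   strand = g$gene_strand[i])
    fpos <- feature_positions(feat, flank)
    j <- left_join(fpos, per_pos, by = c("chrom", "pos"))
    wa <- window_average(tibble(rel_pos = j$rel_pos, value = j$value),
                         w = window)
    tibble(gene_id = g$gene_id[i], distance = g$distance[i],
           rel_pos = wa$rel_pos, value = wa$value)
  })
  out <- bind_rows(rows)
  ord <- arrange(distinct(out, .data$gene_id, .data$distance),
                 desc(abs(.data$distance)))
  out$gene_id <- factor(out$gene_id, levels = ord$gene_id)
  structure(out, class = c("gene_heatmap", class(tibble())),
            window = window, flank = flank)
}

#' Width of the repair-inhibition (or formation-suppression) footprint
#'
#' Descriptive width estimator for the central bump of a remaining-damage
#' metaprofile (or the central dip of a formation profile): the baseline
#' is the mean over a distal flank span, and the footprint is the longest
#' contiguous run of offsets containing the origin whose values exceed
#' `baseline * (1 + threshold_frac)` (fall below `baseline *
#' (1 - threshold_frac)` for dips). Width is `right - left` in bp.
#'
#' @param profile A `meta_profile` (or tibble with rel_pos/value).
#' @param baseline_span Two absolute offsets, `c(lo, hi)`; positions with
#'   `lo <= abs(rel_pos) <= hi` define the baseline.
#' @param threshold_frac Fractional excursion over (under) baseline that
#'   counts as inside the footprint.
#' @param direction `"peak"` for remaining-damage bumps, `"dip"` for
#'   formation suppression.
#' @return An `inhibition_width` object: list(left, right, width,
#'   baseline, threshold, flagged); `flagged = TRUE` with width 0 when the
#'   origin never crosses the threshold.
#' @export
inhibition_width <- function(profile, baseline_span = c(200, 500),
                             threshold_frac = 0.2,
                             direction = c("peak", "dip")) {
  direction <- match.arg(direction)
  p <- filter(as_tibble(profile), !is.na(.data$value))
  p <- arrange(p, .data$rel_pos)
  base_idx <- abs(p$rel_pos) >= baseline_span[1] &
    abs(p$rel_pos) <= baseline_span[2]
  if (!any(base_idx)) abort("baseline span contains no usable offsets")
  baseline <- mean(p$value[base_idx])
  thr <- if (direction == "peak") baseline * (1 + threshold_frac)
         else baseline * (1 - threshold_frac)
  inside <- if (direction == "peak") p$value >= thr else p$value <= thr
  io <- which.min(abs(p$rel_pos))  # grid point nearest the origin
  res <- list(left = 0, right = 0, width = 0, baseline = baseline,
              threshold = thr, flagged = TRUE)
  if (inside[io]) {
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    r <- which(starts <= io & ends >= io)
    res$left <- p$rel_pos[starts[r]]
    res$right <- p$rel_pos[ends[r]]
    res$width <- res$right - res$left
    res$flagged <- FALSE
  }
  structure(res, class = "inhibition_width")
}

#' @export
print.inhibition_width <- function(x, ...) {
  cat("Inhibition footprint: [", x$left, ", ", x$right, "] width ",
      x$width, " bp", if (x$flagged) " (no footprint detected)" else "",
      "\n  baseline ", signif(x$baseline, 4), ", threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Per-window significance of a signal difference between two conditions
#'
#' Groups feature-level observations into non-overlapping windows on the
#' relative-position axis, runs a Welch two-sample t-test per window, and
#' adjusts p-values across windows by Benjamini-Hochberg. Windows where
#' both groups are constant and equal get statistic 0 and p 1.
#'
#' @param values_a,values_b Tibbles of observations (rel_pos, value), one
#'   row per feature per position (e.g. per-site window means of a ratio).
#' @param w Window width in bases.
#' @return Tibble (rel_pos = window center, statistic, p_value,
#'   p_adjusted, n_a, n_b); windows with fewer than 2 observations in
#'   either group are dropped.
#' @export
window_significance <- function(values_a, values_b, w = 5L) {
  assign_win <- function(x) {
    mutate(filter(x, !is.na(.data$value)), win = floor(.data$rel_pos / w))
  }
  a <- assign_win(values_a)
  b <- assign_win(values_b)
  wins <- sort(intersect(unique(a$win), unique(b$win)))
  rows <- purrr::map(wins, function(wi) {
    va <- a$value[a$win == wi]
    vb <- b$value[b$win == wi]
    if (length(va) < 2 || length(vb) < 2) return(NULL)
    if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      stat <- if (mean(va) == mean(vb)) 0 else Inf
      p <- if (mean(va) == mean(vb)) 1 else 0
    } else {
      tt <- t.test(va, vb)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble(rel_pos = wi * w + (w - 1) / 2, statistic = stat,
           p_value = p, n_a = length(va), n_b = length(vb))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("insufficient observations in every window")
  mutate(out, p_adjusted = p.adjust(.data$p_value, method = "BH"))
}

#' Per-site window observations of a damage or repair ratio
#'
#' Builds the feature-level observations [window_significance()] consumes:
#' for each site and each window on the motif-relative axis, the mean of
#' the unmasked per-position profile values falling in that window at that
#' site.
#'
#' @param profile Per-position value tibble (chrom, pos, value, masked).
#' @param sites Oriented site tibble.
#' @param flank Flank in bases.
#' @param w Window width.
#' @return Tibble (feature, rel_pos = window center, value).
#' @export
site_window_values <- function(profile, sites, flank = 500L, w = 5L) {
  features <- as_features(sites)
  fpos <- feature_positions(features, flank)
  p <- profile
  if (!"masked" %in% names(p)) p$masked <- is.na(p$value)
  per_pos <- summarise(
    group_by(p, .data$chrom, .data$pos),
    value = if (any(!.data$masked)) mean(.data$value[!.data$masked]) else NA_real_,
    .groups = "drop"
  )
  j <- inner_join(fpos, per_pos, by = c("chrom", "pos"))
  j$win <- floor(j$rel_pos / w)
  out <- summarise(
    group_by(j, .data$feature, .data$win),
    value = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
    .groups = "drop"
  )
  out <- filter(out, !is.na(.data$value))
  transmute_win <- mutate(out, rel_pos = .data$win * w + (w - 1) / 2)
  select(transmute_win, "feature", "rel_pos", "value")
}
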