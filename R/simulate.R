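#' Rectangular site-relative multiplier profile
#'
#' Convenience constructor for the site-relative multiplier maps used by
#' [sim_config()]: a named numeric vector whose names are integer offsets
#' relative to the site midpoint and whose values multiply the background
#' rate at those offsets. Offsets absent from the map are implicitly 1.
#'
#' @param halfwidth Integer; offsets `-halfwidth..halfwidth` are covered.
#' @param value Multiplier applied inside the window.
#' @return Named numeric vector (names = offsets).
#' @export
#' @examples
#' rect_profile(2, 0.3)
rect_profile <- function(halfwidth, value) {
  stopifnot(halfwidth >= 0, is.finite(value), value >= 0)
  offs <- seq.int(-halfwidth, halfwidth)
  stats::setNames(rep(value, length(offs)), offs)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic damage-and-repair generator. The
#' generator emulates an alkylation-damage mapping experiment: methylation
#' lesions form with strongly base-dependent rates (G >> A >> C ~ T),
#' formation is suppressed where a bound transcription factor shields its
#' motif (with optional position-specific hotspots), and first-order repair
#' is slowed inside occupied sites +/- a flank and near nucleosome dyads.
#'
#' @param genome_length Genome size in bases.
#' @param gc_content GC fraction of the random background sequence.
#' @param n_sites Number of binding sites to plant.
#' @param motif IUPAC motif planted at each site.
#' @param occupancy_values Occupancy score per site; sites with occupancy
#'   strictly above `occupancy_threshold` are treated as protein-bound.
#' @param occupancy_threshold Boundary between bound ("high") and unbound
#'   ("low") sites; the boundary value itself is low.
#' @param base_damage_rate Named relative lesion-formation rate per base
#'   (per-strand, strand-aware). Scaled internally so one library's
#'   expected read total equals `depth`.
#' @param suppression_profile Named multiplier map (offsets relative to the
#'   site midpoint, values in `[0,1]`) applied at occupied sites only.
#' @param hotspot_profile Optional named multiplier map (values >= 1) for
#'   position-specific damage hotspots at occupied sites; `NULL` for none.
#' @param repair_rate_background Background repair rate, per hour.
#' @param repair_inhibition_profile Named multiplier map in `[0,1]` applied
#'   to the repair rate inside occupied sites and their flanks. Default
#'   covers the motif plus 15 bp on each side at multiplier 0.1.
#' @param nucleosome_spacing Dyad-to-dyad lattice spacing in bases.
#' @param nucleosome_dyad_inhibition Repair-rate multiplier within
#'   `dyad_halfwidth` of a nucleosome dyad.
#' @param dyad_halfwidth Half-width of dyad influence on repair, bases.
#' @param ndr_halfwidth Half-width of the nucleosome-depleted window kept
#'   free of dyads around each site midpoint.
#' @param timepoints Repair time course, hours (must start at 0).
#' @param depth Expected reads per library.
#' @param site_min_gap Minimum gap between planted sites, bases.
#' @param seed Integer seed; identical configs give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L,
                       gc_content = 0.38,
                       n_sites = 60L,
                       motif = "TTACCC",
                       occupancy_values = rep(c(20, 5), length.out = n_sites),
                       occupancy_threshold = 10,
                       base_damage_rate = c(A = 4, C = 1, G = 20, T = 0.5),
                       suppression_profile = rect_profile(6, 0.3),
                       hotspot_profile = NULL,
                       repair_rate_background = 0.5,
                       repair_inhibition_profile =
                         rect_profile(nchar(motif) %/% 2 + 15, 0.1),
                       nucleosome_spacing = 165L,
                       nucleosome_dyad_inhibition = 0.5,
                       dyad_halfwidth = 30L,
                       ndr_halfwidth = 150L,
                       timepoints = c(0, 1, 2),
                       depth = 2e5,
                       site_min_gap = 1000L,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    n_sites = as.integer(n_sites), motif = toupper(motif),
    occupancy_values = occupancy_values,
    occupancy_threshold = occupancy_threshold,
    base_damage_rate = base_damage_rate,
    suppression_profile = suppression_profile,
    hotspot_profile = hotspot_profile,
    repair_rate_background = repair_rate_background,
    repair_inhibition_profile = repair_inhibition_profile,
    nucleosome_spacing = as.integer(nucleosome_spacing),
    nucleosome_dyad_inhibition = nucleosome_dyad_inhibition,
    dyad_halfwidth = as.integer(dyad_halfwidth),
    ndr_halfwidth = as.integer(ndr_halfwidth),
    timepoints = timepoints, depth = depth,
    site_min_gap = as.integer(site_min_gap), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` object to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$genome_length <= 0) abort("genome_length must be positive")
  if (cfg$gc_content < 0 || cfg$gc_content > 1) abort("gc_content must be in [0,1]")
  iupac_regex(cfg$motif)  # errors on invalid IUPAC
  if (length(cfg$occupancy_values) != cfg$n_sites) {
    abort("occupancy_values must have length n_sites")
  }
  if (any(cfg$occupancy_values < 0)) abort("occupancy values must be non-negative")
  if (!all(c("A", "C", "G", "T") %in% names(cfg$base_damage_rate))) {
    abort("base_damage_rate must name all of A, C, G, T")
  }
  rates <- cfg$base_damage_rate
  if (any(!is.finite(rates)) || any(rates < 0)) abort("damage rates must be finite and >= 0")
  chk_mult <- function(p, lo, hi, what) {
    if (is.null(p)) return(invisible())
    if (any(!is.finite(p)) || any(p < lo) || any(p > hi)) {
      abort(paste0(what, " multipliers must be finite and in [", lo, ",", hi, "]"))
    }
    if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p))))) {
      abort(paste0(what, " must be named by integer offsets"))
    }
  }
  chk_mult(cfg$suppression_profile, 0, 1, "suppression_profile")
  chk_mult(cfg$hotspot_profile, 1, Inf, "hotspot_profile")
  chk_mult(cfg$repair_inhibition_profile, 0, 1, "repair_inhibition_profile")
  if (cfg$nucleosome_dyad_inhibition < 0 || cfg$nucleosome_dyad_inhibition > 1) {
    abort("nucleosome_dyad_inhibition must be in [0,1]")
  }
  if (any(cfg$timepoints < 0) || cfg$timepoints[1] != 0) {
    abort("timepoints must be non-negative and start at 0")
  }
  if (cfg$depth <= 0) abort("depth must be positive")
  cfg
}

#' Generate a random genome sequence
#'
#' @param length Sequence length in bases.
#' @param gc Target GC fraction in `[0,1]`.
#' @param seed Integer seed.
#' @param chrom Chromosome name for the single synthetic contig.
#' @return Named character vector of length one (a genome as used
#'   throughout the package: names are chromosomes, 0-based coordinates).
#' @export
#' @examples
#' g <- simulate_genome(50, 0.5, seed = 1)
#' nchar(g)
simulate_genome <- function(length, gc, seed = 1L, chrom = "chrS") {
  if (length <= 0) abort("length must be positive")
  if (gc < 0 || gc > 1) abort("gc must be in [0,1]")
  set.seed(seed)
  at <- (1 - gc) / 2
  bases <- sample(c("A", "T", "G", "C"), size = length, replace = TRUE,
                  prob = c(at, at, gc / 2, gc / 2))
  stats::setNames(paste0(bases, collapse = ""), chrom)
}

#' Plant motif instances into a genome
#'
#' Places `n` non-overlapping concrete instances of an IUPAC motif, each on
#' a random strand, and writes them into the sequence. Placement uses equal
#' slots with random jitter so the minimum gap is guaranteed by
#' construction.
#'
#' @param genome Named character vector (see [simulate_genome()]).
#' @param motif IUPAC motif string.
#' @param n Number of sites.
#' @param occupancies Numeric occupancy score per site (length `n`).
#' @param min_gap Minimum distance between consecutive site intervals.
#' @param seed Integer seed.
#' @return List with `genome` (edited sequence) and `sites`, a tibble with
#'   columns chrom, start, end (0-based half-open), midpoint, strand,
#'   occupancy, motif_seq (the concrete instance on the motif strand).
#' @export
plant_sites <- function(genome, motif, n, occupancies,
                        min_gap = 20L, seed = 1L) {
  stopifnot(length(genome) == 1)
  motif <- toupper(motif)
  len <- nchar(motif)
  L <- unname(nchar(genome))
  if (n == 0) {
    return(list(genome = genome, sites = tibble(
      chrom = character(), start = integer(), end = integer(),
      midpoint = integer(), strand = character(),
      occupancy = numeric(), motif_seq = character()
    )))
  }
  if (length(occupancies) != n) abort("occupancies must have length n")
  if (n * (len + min_gap) > L) {
    abort("cannot place n sites of this motif respecting min_gap")
  }
  set.seed(seed)
  slot <- L %/% n
  jitter_max <- slot - len - min_gap
  starts <- (seq_len(n) - 1L) * slot +
    vapply(seq_len(n), function(i) sample.int(jitter_max + 1L, 1L) - 1L, integer(1))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  letters <- strsplit(motif, "")[[1]]
  concrete <- vapply(seq_len(n), function(i) {
    paste0(vapply(letters, function(l) sample(iupac_letters(l), 1L), character(1)),
           collapse = "")
  }, character(1))
  seq_chr <- genome[[1]]
  for (i in seq_len(n)) {
    ins <- if (strands[i] == "-") revcomp(concrete[i]) else concrete[i]
    substr(seq_chr, starts[i] + 1L, starts[i] + len) <- ins
  }
  out <- genome
  out[[1]] <- seq_chr
  sites <- tibble(
    chrom = names(genome), start = as.integer(starts),
    end = as.integer(starts + len),
    midpoint = as.integer(starts + (len - 1L) %/% 2L),
    strand = strands, occupancy = as.numeric(occupancies),
    motif_seq = concrete
  )
  list(genome = out, sites = sites)
}

# Site-relative offset -> genomic position on a site's motif strand.
site_offset_positions <- function(site_mid, site_strand, offsets) {
  if (site_strand == "+") site_mid + offsets else site_mid - offsets
}

# Apply a named multiplier map around occupied site midpoints to a
# per-position multiplier vector (1-based indexing into the vector).
apply_site_profile <- function(mult, sites_occ, profile, L) {
  if (is.null(profile) || nrow(sites_occ) == 0) return(mult)
  offs <- as.integer(names(profile))
  for (i in seq_len(nrow(sites_occ))) {
    pos <- site_offset_positions(sites_occ$midpoint[i], sites_occ$strand[i], offs)
    ok <- pos >= 0 & pos < L
    mult[pos[ok] + 1L] <- mult[pos[ok] + 1L] * unname(profile)[ok]
  }
  mult
}

# Dense per-strand vectors -> sparse lesion-track tibble.
dense_to_track <- function(chrom, counts_plus, counts_minus, bases_plus) {
  ip <- which(counts_plus > 0L)
  im <- which(counts_minus > 0L)
  bp <- bases_plus[ip]
  bm <- comp_base(bases_plus[im])
  tr <- tibble(
    chrom = chrom,
    pos = c(ip, im) - 1L,
    strand = c(rep("+", length(ip)), rep("-", length(im))),
    base = c(bp, bm),
    count = c(counts_plus[ip], counts_minus[im])
  )
  tr$lesion_class <- tr$base
  arrange(tr, .data$pos, .data$strand)
}

#' Simulate lesion formation in cellular and naked DNA
#'
#' Draws per-position, per-strand lesion counts at time 0 from independent
#' Poisson distributions. The cellular library's rate at each position is
#' `base_damage_rate[base] * suppression * hotspot` (the latter two only at
#' occupied sites); the naked-DNA library uses the base rate alone. Rates
#' are scaled so each library's expected total equals `config$depth`.
#'
#' @param genome Named character vector (single contig).
#' @param sites Site tibble from [plant_sites()].
#' @param config A [sim_config()].
#' @param seed Seed for the Poisson draws (defaults to `config$seed`).
#' @return List with `cellular` and `naked` lesion-track tibbles (chrom,
#'   pos, strand, base, count, lesion_class) and `truth`, a `sim_truth`
#'   object recording the exact per-position rates, repair rates, occupied
#'   flags and nucleosome dyads.
#' @export
simulate_lesion_field <- function(genome, sites, config,
                                  seed = config$seed) {
  validate_sim_config(config)
  stopifnot(length(genome) == 1)
  chrom <- names(genome)
  L <- unname(nchar(genome))
  if (nrow(sites) > 0 && any(sites$start < 0 | sites$end > L)) {
    abort("sites fall outside genome bounds")
  }
  bases_plus <- strsplit(genome[[1]], "")[[1]]
  rate_plus <- unname(config$base_damage_rate[bases_plus])
  rate_minus <- unname(config$base_damage_rate[comp_base(bases_plus)])

  occupied <- sites$occupancy > config$occupancy_threshold
  sites_occ <- sites[occupied, , drop = FALSE]
  mult <- rep(1, L)
  mult <- apply_site_profile(mult, sites_occ, config$suppression_profile, L)
  mult <- apply_site_profile(mult, sites_occ, config$hotspot_profile, L)

  p_cell_plus <- rate_plus * mult
  p_cell_minus <- rate_minus * mult

  lam <- function(p_plus, p_minus) {
    tot <- sum(p_plus) + sum(p_minus)
    list(plus = config$depth * p_plus / tot,
         minus = config$depth * p_minus / tot)
  }
  lam_cell <- lam(p_cell_plus, p_cell_minus)
  lam_naked <- lam(rate_plus, rate_minus)

  set.seed(seed)
  cell_plus <- rpois(L, lam_cell$plus)
  cell_minus <- rpois(L, lam_cell$minus)
  naked_plus <- rpois(L, lam_naked$plus)
  naked_minus <- rpois(L, lam_naked$minus)

  # Repair-rate field: background, slowed inside occupied sites +/- flank
  # and near nucleosome dyads (dyads on a lattice avoiding site NDRs).
  k <- rep(config$repair_rate_background, L)
  k <- apply_site_profile(k / config$repair_rate_background, sites_occ,
                          config$repair_inhibition_profile, L) *
    config$repair_rate_background
  dyads <- seq.int(config$nucleosome_spacing %/% 2L, L - 1L,
                   by = config$nucleosome_spacing)
  if (nrow(sites) > 0) {
    near_site <- vapply(dyads, function(d) {
      any(abs(d - sites$midpoint) <= config$ndr_halfwidth)
    }, logical(1))
    dyads <- dyads[!near_site]
  }
  if (length(dyads) > 0 && config$nucleosome_dyad_inhibition < 1) {
    pos0 <- seq.int(0L, L - 1L)
    idx <- findInterval(pos0, dyads)
    d_right <- ifelse(idx < length(dyads), dyads[pmin(idx + 1L, length(dyads))] - pos0, Inf)
    d_left <- ifelse(idx >= 1L, pos0 - dyads[pmax(idx, 1L)], Inf)
    near_dyad <- pmin(d_left, d_right) <= config$dyad_halfwidth
    k[near_dyad] <- k[near_dyad] * config$nucleosome_dyad_inhibition
  }

  truth <- structure(list(
    chrom = chrom, genome_length = L,
    p_cellular = list(plus = p_cell_plus, minus = p_cell_minus),
    p_naked = list(plus = rate_plus, minus = rate_minus),
    lambda_cellular = lam_cell, lambda_naked = lam_naked,
    repair_rate = k,
    sites = mutate(sites, occupied = .env$occupied),
    dyads = dyads, depth = config$depth
  ), class = "sim_truth")

  list(
    cellular = dense_to_track(chrom, cell_plus, cell_minus, bases_plus),
    naked = dense_to_track(chrom, naked_plus, naked_minus, bases_plus),
    truth = truth
  )
}

#' Thin a lesion field through first-order repair
#'
#' Each lesion at position `i` survives to time `t` independently with
#' probability `exp(-k_i * t)`, where `k_i` is the planted per-position
#' repair rate (background x site inhibition x dyad inhibition).
#'
#' @param track_t0 Lesion track at time 0.
#' @param truth `sim_truth` from [simulate_lesion_field()].
#' @param t Repair time in hours (>= 0).
#' @param seed Integer seed for the binomial thinning.
#' @return Lesion track at time `t`; per-position counts never exceed the
#'   input. Zero-count positions are dropped (sparse convention).
#' @export
simulate_repair_timepoint <- function(track_t0, truth, t, seed = 1L) {
  if (t < 0) abort("t must be non-negative")
  stopifnot(inherits(truth, "sim_truth"))
  if (t == 0) return(track_t0)
  set.seed(seed)
  k <- truth$repair_rate[track_t0$pos + 1L]
  surv <- exp(-k * t)
  out <- track_t0
  out$count <- rbinom(nrow(out), size = track_t0$count, prob = surv)
  filter(out, .data$count > 0L)
}

#' Emit sequencing reads from a lesion field
#'
#' Deterministic inverse of the 5'-end lesion-inference rule: a lesion at
#' position `p` on the + strand yields a read on the - strand with its 5'
#' end at `p - 1`; a lesion on the - strand yields a + strand read with 5'
#' end at `p + 1`. Lesions whose paired read start would fall outside the
#' chromosome are dropped and counted (attribute `dropped_lesions`), so
#' [infer_lesions()] recovers exactly the retained set.
#'
#' @param track Lesion track tibble (chrom, pos, strand, count).
#' @param genome Named character vector, for chromosome bounds.
#' @return Read tibble (chrom, pos = 0-based 5' end, strand, count) with
#'   attribute `dropped_lesions`.
#' @export
emit_reads <- function(track, genome) {
  check_strand(track$strand)
  lens <- genome_lengths(genome)
  read_pos <- if_else(track$strand == "+", track$pos - 1L, track$pos + 1L)
  read_strand <- if_else(track$strand == "+", "-", "+")
  ok <- read_pos >= 0L & read_pos < lens[track$chrom]
  dropped <- sum(track$count[!ok])
  reads <- tibble(
    chrom = track$chrom[ok], pos = read_pos[ok],
    strand = read_strand[ok], count = track$count[ok]
  )
  reads <- arrange(reads, .data$chrom, .data$pos, .data$strand)
  attr(reads, "dropped_lesions") <- dropped
  reads
}

#' Synthetic nucleosome-coverage track
#'
#' Triangular coverage peaking at each planted dyad and falling to zero at
#' `halfwidth`, emulating an MNase-style dyad-density signal for overlay
#' plots.
#'
#' @param truth `sim_truth` object (provides dyads and genome length).
#' @param halfwidth Footprint half-width in bases.
#' @return Tibble (chrom, pos, value), one row per position.
#' @export
simulate_nucleosome_track <- function(truth, halfwidth = 73L) {
  stopifnot(inherits(truth, "sim_truth"))
  pos0 <- seq.int(0L, truth$genome_length - 1L)
  dyads <- truth$dyads
  if (length(dyads) == 0) {
    return(tibble(chrom = truth$chrom, pos = pos0, value = 0))
  }
  idx <- findInterval(pos0, dyads)
  d_right <- ifelse(idx < length(dyads), dyads[pmin(idx + 1L, length(dyads))] - pos0, Inf)
  d_left <- ifelse(idx >= 1L, pos0 - dyads[pmax(idx, 1L)], Inf)
  d <- pmin(d_left, d_right)
  tibble(chrom = truth$chrom, pos = pos0,
         value = pmax(0, 1 - d / halfwidth))
}
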