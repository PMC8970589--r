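#' Run the full synthetic end-to-end demonstration
#'
#' Simulates a genome with bound (high-occupancy) and unbound
#' (low-occupancy) binding sites, a naked-DNA control, and a repair time
#' course; emits and re-infers reads; and runs the formation and
#' remaining-damage metaprofile analyses for both occupancy classes. All
#' stage outputs are written as plain interchange files (FASTA, BED6+1,
#' strand-split bedGraph, TSV) plus a JSON run manifest with input
#' checksums and per-stage row/drop counters, so any stage can be re-run
#' against real data in the same formats.
#'
#' @param outdir Writable output directory (created if absent).
#' @param config A [sim_config()].
#' @param seed Integer seed overriding `config$seed`.
#' @return Invisibly, a list with the manifest, site table, lesion
#'   tracks, and the four metaprofiles (formation/remaining x high/low).
#' @export
run_demo <- function(outdir, config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort("cannot create output directory")
  }
  if (file.access(outdir, mode = 2) != 0) abort("output directory not writable")

  genome0 <- simulate_genome(config$genome_length, config$gc_content,
                             seed = seed)
  planted <- plant_sites(genome0, config$motif, config$n_sites,
                         config$occupancy_values,
                         min_gap = config$site_min_gap, seed = seed + 1L)
  genome <- planted$genome
  sites <- stratify_occupancy(planted$sites, config$occupancy_threshold)

  field <- simulate_lesion_field(genome, planted$sites, config,
                                 seed = seed + 2L)
  t_last <- max(config$timepoints)
  track_t <- simulate_repair_timepoint(field$cellular, field$truth,
                                       t = t_last, seed = seed + 3L)

  # sequencing round trip: lesions -> reads -> inferred lesions
  reads0 <- emit_reads(field$cellular, genome)
  inferred0 <- infer_lesions(reads0, genome, mode = "nmp")

  g0 <- select_class(inferred0, "G")
  g_naked <- select_class(field$naked, "G")
  g_t <- select_class(track_t, "G")

  high <- filter(sites, .data$occupancy_class == "high")
  low <- filter(sites, .data$occupancy_class == "low")
  flank <- 500L
  prof <- list(
    formation_high = damage_metaprofile(g0, g_naked, high, flank = flank),
    formation_low = damage_metaprofile(g0, g_naked, low, flank = flank),
    remaining_high = repair_metaprofile(g_t, g0, high, flank = flank),
    remaining_low = repair_metaprofile(g_t, g0, low, flank = flank)
  )

  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    sites = file.path(outdir, "sites.bed"),
    reads = file.path(outdir, "reads_0hr.bed"),
    cellular = file.path(outdir, "lesions_0hr"),
    naked = file.path(outdir, "lesions_naked"),
    timepoint = file.path(outdir, sprintf("lesions_%ghr", t_last))
  )
  write_genome_fasta(genome, paths$genome)
  write_sites_bed(planted$sites, paths$sites)
  write_reads_bed(reads0, paths$reads)
  track_files <- c(write_track_bedgraph(field$cellular, paths$cellular),
                   write_track_bedgraph(field$naked, paths$naked),
                   write_track_bedgraph(track_t, paths$timepoint))
  prof_files <- purrr::imap_chr(prof, function(p, nm) {
    write_profile_tsv(p, file.path(outdir, paste0("profile_", nm, ".tsv")))
  })

  all_files <- c(unlist(paths[c("genome", "sites", "reads")]),
                 track_files, unname(prof_files))
  manifest <- list(
    tool = "tfrepair", version = as.character(packageVersion("tfrepair")),
    seed = seed,
    config = unclass(config),
    counts = list(
      n_sites = nrow(planted$sites),
      n_sites_high = nrow(high), n_sites_low = nrow(low),
      lesions_0hr = sum(field$cellular$count),
      lesions_naked = sum(field$naked$count),
      lesions_t = sum(track_t$count),
      reads_emitted = sum(reads0$count),
      lesions_edge_dropped = attr(reads0, "dropped_lesions"),
      reads_edge_dropped = attr(inferred0, "dropped_reads")
    ),
    files = lapply(stats::setNames(all_files, basename(all_files)),
                   function(f) unname(tools::md5sum(f)))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, sites = sites,
                 tracks = list(cellular = field$cellular,
                               naked = field$naked, timepoint = track_t),
                 truth = field$truth, profiles = prof,
                 outdir = outdir))
}
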