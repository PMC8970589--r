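# All genomic coordinates are 0-based half-open internally and in BED /
# bedGraph files; conversion to the 1-based GRanges convention happens
# only here.

#' Read and write genomes as FASTA
#'
#' @param path File path.
#' @return `read_genome_fasta()` returns a named character vector of
#'   chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

tib_to_granges <- function(x, width = 1L, score = NULL) {
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(start = x$pos + 1L, width = width),
    strand = if ("strand" %in% names(x)) x$strand else "*"
  )
  if (!is.null(score)) gr$score <- score
  gr
}

#' Read and write read 5'-end records as BED6
#'
#' Each BED record is a 1 bp interval at the read's 5' end; the score
#' column carries the read multiplicity (collapsed duplicates), name is
#' unused. With `five_prime = TRUE`, full-interval BED input is reduced to
#' the strand-aware 5' end (interval start for + reads, end - 1 for -).
#'
#' @param path File path.
#' @param five_prime Reduce full intervals to their 5' ends.
#' @return Read tibble (chrom, pos, strand, count).
#' @export
read_reads_bed <- function(path, five_prime = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) abort("reads BED must carry strand in column 6")
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)  # half-open
  pos <- if (five_prime) if_else(st == "+", start0, end0 - 1L) else start0
  cnt <- if (!is.null(gr$score) && !all(is.na(gr$score))) {
    as.integer(gr$score)
  } else {
    rep(1L, length(gr))
  }
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         pos = pos, strand = st, count = cnt)
}

#' @rdname read_reads_bed
#' @param reads Read tibble.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- tib_to_granges(reads, score = reads$count)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write strand-split lesion tracks as bedGraph pairs
#'
#' A lesion track is stored as two bedGraph files (plus/minus strand),
#' counts in the score column. Reading needs the genome to restore the
#' lesion base at each position.
#'
#' @param prefix Output path prefix; files are `<prefix>_plus.bedGraph`
#'   and `<prefix>_minus.bedGraph`.
#' @param track Lesion track tibble.
#' @return `write_track_bedgraph()` returns the two paths invisibly.
#' @export
write_track_bedgraph <- function(track, prefix) {
  paths <- paste0(prefix, c("_plus.bedGraph", "_minus.bedGraph"))
  for (i in 1:2) {
    s <- c("+", "-")[i]
    sub <- filter(track, .data$strand == s)
    gr <- GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(start = sub$pos + 1L, width = 1L),
      score = sub$count)
    rtracklayer::export(gr, paths[i], format = "bedGraph")
  }
  invisible(paths)
}

#' @rdname write_track_bedgraph
#' @param genome Named character vector (for base annotation); `NULL`
#'   leaves base/lesion_class as `NA`.
#' @export
read_track_bedgraph <- function(prefix, genome = NULL) {
  paths <- paste0(prefix, c("_plus.bedGraph", "_minus.bedGraph"))
  parts <- purrr::map2(paths, c("+", "-"), function(p, s) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    if (length(gr) == 0) {
      return(tibble(chrom = character(), pos = integer(),
                    strand = character(), count = integer()))
    }
    # expand runs back to single positions
    starts <- BiocGenerics::start(gr) - 1L
    widths <- BiocGenerics::width(gr)
    tibble(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), widths),
      pos = unlist(purrr::map2(starts, widths, function(a, w) a + seq_len(w) - 1L)),
      strand = s,
      count = rep(as.integer(gr$score), widths)
    )
  })
  tr <- bind_rows(parts)
  tr$base <- if (is.null(genome)) NA_character_ else {
    genome_base(genome, tr$chrom, tr$pos, tr$strand)
  }
  tr$lesion_class <- tr$base
  arrange(tr, .data$chrom, .data$pos, .data$strand)
}

#' Read and write binding-site tables as BED6+1
#'
#' Column 7 carries the occupancy score; the BED score column is unused.
#'
#' @param path File path.
#' @return Site tibble (chrom, start, end, midpoint, strand, occupancy).
#' @export
read_sites_bed <- function(path) {
  df <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "name", "score",
                        "strand", "occupancy"),
    col_types = "ciicdcd", progress = FALSE)
  tibble(chrom = df$chrom, start = df$start, end = df$end,
         midpoint = df$start + (df$end - df$start - 1L) %/% 2L,
         strand = df$strand, occupancy = df$occupancy)
}

#' @rdname read_sites_bed
#' @param sites Site tibble.
#' @export
write_sites_bed <- function(sites, path) {
  df <- tibble(chrom = sites$chrom, start = sites$start, end = sites$end,
               name = if ("motif_seq" %in% names(sites)) sites$motif_seq else ".",
               score = 0L, strand = sites$strand,
               occupancy = sites$occupancy)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a TSV with columns gene_id, chrom, tss (0-based coordinate)
#' and strand.
#'
#' @param path File path.
#' @return Gene tibble.
#' @export
read_genes_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_integer(), strand = readr::col_character()
  ), progress = FALSE)
}

#' Write a profile or metaprofile as TSV
#'
#' @param profile Any profile tibble (per-position or relative-axis).
#' @param path File path.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path, progress = FALSE)
  invisible(path)
}
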