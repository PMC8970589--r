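#' Filter binding sites by a canonical IUPAC motif
#'
#' Retains only sites whose genomic interval (optionally widened by
#' `slop` bases on each side) contains a match to the motif on either
#' strand, and re-anchors each retained site on its matched motif
#' instance: start/end/midpoint are the matched interval, strand is the
#' motif strand, and `motif_seq` is the matched sequence read on that
#' strand. Sites without a match are excluded. The midpoint of an
#' even-length motif is the left-of-center base.
#'
#' @param sites Tibble with chrom, start, end (0-based half-open) and any
#'   additional columns (e.g. occupancy), which are carried through.
#' @param genome Named character vector of chromosome sequences.
#' @param motif IUPAC motif string (e.g. `"CGTNNNNNRNKA"` or `"TTACCC"`).
#' @param slop Extra bases searched on each side of the interval.
#' @return Filtered site tibble with start, end, midpoint, strand and
#'   motif_seq replaced by the match; a + strand match is preferred when
#'   both strands match.
#' @export
filter_by_motif <- function(sites, genome, motif, slop = 0L) {
  motif <- toupper(motif)
  iupac_regex(motif)  # validate letters
  len <- nchar(motif)
  lens <- genome_lengths(genome)
  pat <- Biostrings::DNAString(motif)
  rows <- purrr::map(seq_len(nrow(sites)), function(i) {
    chrom <- sites$chrom[i]
    lo <- max(0L, sites$start[i] - slop)
    hi <- min(unname(lens[chrom]), sites$end[i] + slop)
    if (hi - lo < len) return(NULL)
    subseq <- substr(genome[[chrom]], lo + 1L, hi)
    dna <- Biostrings::DNAString(subseq)
    m_plus <- Biostrings::matchPattern(pat, dna, fixed = FALSE)
    hit <- NULL
    if (length(m_plus) > 0) {
      s <- lo + BiocGenerics::start(m_plus)[1] - 1L
      hit <- list(start = s, strand = "+",
                  seq = as.character(m_plus[[1]]))
    } else {
      m_minus <- Biostrings::matchPattern(pat,
                                          Biostrings::reverseComplement(dna),
                                          fixed = FALSE)
      if (length(m_minus) > 0) {
        # coordinates of the revcomp match back on the + reference
        s_rc <- BiocGenerics::start(m_minus)[1]
        s <- lo + (nchar(subseq) - (s_rc + len - 1L))
        hit <- list(start = s, strand = "-",
                    seq = as.character(m_minus[[1]]))
      }
    }
    if (is.null(hit)) return(NULL)
    row <- sites[i, , drop = FALSE]
    row$start <- as.integer(hit$start)
    row$end <- as.integer(hit$start + len)
    row$midpoint <- as.integer(hit$start + (len - 1L) %/% 2L)
    row$strand <- hit$strand
    row$motif_seq <- hit$seq
    row
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- mutate(sites[0, , drop = FALSE], midpoint = integer(),
                  strand = character(), motif_seq = character())
  }
  out
}

#' Stratify sites by occupancy
#'
#' Splits sites into bound ("high", occupancy strictly above the
#' threshold) and weakly bound ("low", occupancy at or below it) classes.
#'
#' @param sites Site tibble with an `occupancy` column.
#' @param threshold Occupancy boundary (default 10; the boundary value is
#'   classed low).
#' @return The input with an added `occupancy_class` factor
#'   (`"high"`/`"low"`); the two classes partition the input exactly.
#' @export
stratify_occupancy <- function(sites, threshold = 10) {
  if (!"occupancy" %in% names(sites) || anyNA(sites$occupancy)) {
    abort("all sites need an occupancy value")
  }
  mutate(sites, occupancy_class = factor(
    if_else(.data$occupancy > threshold, "high", "low"),
    levels = c("high", "low")
  ))
}

#' Link binding sites to putative target genes by TSS proximity
#'
#' For each site, finds the nearest transcription start site; a gene is
#' linked when that TSS lies within `max_dist` of the site midpoint. A
#' site flanked by two divergently transcribed genes (nearest TSS on the
#' left belonging to a leftward, - strand gene and nearest on the right to
#' a rightward, + strand gene, both within range) links both genes. Two
#' equidistant nearest TSSs are both linked. Each gene appears at most
#' once in the result (closest site kept).
#'
#' @param sites Site tibble with chrom, midpoint (and optionally an id).
#' @param genes Gene tibble (gene_id, chrom, tss, strand).
#' @param max_dist Maximum midpoint-to-TSS distance in bases.
#' @return Link tibble (site_idx, gene_id, chrom, midpoint, tss,
#'   gene_strand, distance) where `distance` is TSS minus midpoint, sign
#'   flipped for - strand genes so positive means the site lies upstream
#'   of the gene.
#' @export
link_to_tss <- function(sites, genes, max_dist = 300L) {
  if (nrow(genes) == 0) abort("empty gene set")
  if (anyDuplicated(genes$gene_id)) abort("gene_id values must be unique")
  links <- purrr::map(seq_len(nrow(sites)), function(i) {
    g <- genes[genes$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    mid <- sites$midpoint[i]
    d <- g$tss - mid
    sel <- integer()
    left <- which(d < 0)
    right <- which(d > 0)
    nl <- if (length(left)) left[which.max(d[left])] else NA_integer_
    nr <- if (length(right)) right[which.min(d[right])] else NA_integer_
    divergent <- !is.na(nl) && !is.na(nr) &&
      g$strand[nl] == "-" && g$strand[nr] == "+" &&
      abs(d[nl]) <= max_dist && abs(d[nr]) <= max_dist
    if (divergent) {
      sel <- c(nl, nr)
    } else {
      nearest <- which(abs(d) == min(abs(d)))
      sel <- nearest[abs(d[nearest]) <= max_dist]
    }
    if (length(sel) == 0) return(NULL)
    tibble(
      site_idx = i, gene_id = g$gene_id[sel], chrom = sites$chrom[i],
      midpoint = mid, tss = g$tss[sel], gene_strand = g$strand[sel],
      distance = if_else(g$strand[sel] == "-", -(g$tss[sel] - mid),
                         g$tss[sel] - mid)
    )
  })
  out <- bind_rows(links)
  if (nrow(out) == 0) {
    return(tibble(site_idx = integer(), gene_id = character(),
                  chrom = character(), midpoint = integer(),
                  tss = integer(), gene_strand = character(),
                  distance = integer()))
  }
  # one row per gene: keep the closest site
  out <- slice_min(group_by(out, .data$gene_id), abs(.data$distance),
                   n = 1, with_ties = FALSE)
  arrange(ungroup(out), .data$chrom, .data$midpoint)
}

#' Map genomic coordinates to motif-relative offsets (and back)
#'
#' Offsets are signed distances from the site midpoint, read 5'->3' along
#' the motif strand: for a - strand site the sign is flipped so profiles
#' from sites on either strand align. An optional origin shift moves
#' position 0 (e.g. onto the first G of a GGGTAA core on the G-rich
#' strand, the conventional numbering for that motif).
#'
#' @param position Genomic coordinate vector (0-based).
#' @param midpoint Site midpoint(s), recycled.
#' @param strand Site motif strand(s), recycled.
#' @param origin_shift Offset subtracted after orientation (default 0).
#' @return Integer vector of motif-relative offsets.
#' @export
orient_relative <- function(position, midpoint, strand, origin_shift = 0L) {
  check_strand(strand)
  n <- max(length(position), length(midpoint), length(strand))
  raw <- rep_len(position, n) - rep_len(midpoint, n)
  flip <- rep_len(strand, n) == "-"
  as.integer(ifelse(flip, -raw, raw) - origin_shift)
}

#' @rdname orient_relative
#' @param offset Motif-relative offset vector.
#' @return `relative_to_genomic()` returns genomic coordinates; it is the
#'   exact inverse of `orient_relative()`.
#' @export
relative_to_genomic <- function(offset, midpoint, strand, origin_shift = 0L) {
  check_strand(strand)
  n <- max(length(offset), length(midpoint), length(strand))
  shifted <- rep_len(offset, n) + origin_shift
  flip <- rep_len(strand, n) == "-"
  as.integer(rep_len(midpoint, n) + ifelse(flip, -shifted, shifted))
}

#' Motif offsets that cannot form a given lesion class
#'
#' Motif columns restricted to A/T on both strands (IUPAC letters A, T or
#' W) contain no G:C pair and can never carry a G-class (or C-class)
#' lesion; single-nucleotide profiles mask such positions rather than
#' plotting structural zeros.
#'
#' @param motif IUPAC motif string.
#' @param lesion_base Lesion base class the profile shows (`"G"`, `"C"`,
#'   `"A"` or `"T"`).
#' @return Integer offsets (relative to the motif midpoint) to mask.
#' @export
nonlesion_offsets <- function(motif, lesion_base = "G") {
  motif <- toupper(motif)
  letters <- strsplit(motif, "")[[1]]
  mid <- (nchar(motif) - 1L) %/% 2L
  at_only <- vapply(letters, function(l) {
    all(iupac_letters(l) %in% c("A", "T"))
  }, logical(1))
  gc_only <- vapply(letters, function(l) {
    all(iupac_letters(l) %in% c("G", "C"))
  }, logical(1))
  dead <- if (toupper(lesion_base) %in% c("G", "C")) at_only else gc_only
  unname(which(dead)) - 1L - mid
}
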