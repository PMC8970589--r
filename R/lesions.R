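#' Infer single-nucleotide lesion positions from read 5' ends
#'
#' Lesion-tagged libraries place the sequencing read so that the damaged
#' base lies immediately upstream of the read's 5' end, on the opposing
#' strand. In `nmp` mode a + strand read with 5' end at `x` therefore
#' implies a lesion at `x - 1` on the - strand, and a - strand read with
#' 5' end at `y` a lesion at `y + 1` on the + strand; the lesion base is
#' read from the lesion strand. In `cpd` mode the two upstream nucleotides
#' on the opposing strand form a putative dinucleotide lesion, keyed by its
#' 5'-most base on the lesion strand. Reads whose upstream position(s)
#' fall outside the chromosome are dropped and counted.
#'
#' @param reads Read tibble: chrom, pos (0-based 5' end), strand, and an
#'   optional count column (absent = one read per row).
#' @param genome Named character vector of chromosome sequences.
#' @param mode `"nmp"` (single-base lesion) or `"cpd"` (dinucleotide).
#' @return Lesion track tibble (chrom, pos, strand, base, count,
#'   lesion_class) with attribute `dropped_reads`.
#' @export
#' @examples
#' g <- c(chr1 = "ACGTA")
#' reads <- tibble::tibble(chrom = "chr1", pos = 3L, strand = "+")
#' infer_lesions(reads, g)
infer_lesions <- function(reads, genome, mode = c("nmp", "cpd")) {
  mode <- match.arg(mode)
  check_strand(reads$strand)
  if (!all(reads$chrom %in% names(genome))) {
    abort("reads reference chromosomes absent from the genome")
  }
  if (!"count" %in% names(reads)) reads$count <- 1L
  lens <- genome_lengths(genome)
  plus_read <- reads$strand == "+"
  span <- if (mode == "nmp") 1L else 2L
  # Lesion coordinate = key position of the (di)nucleotide on the lesion
  # strand; for cpd the key is its 5'-most base on that strand.
  lpos <- if_else(plus_read, reads$pos - 1L, reads$pos + 1L)
  lstrand <- if_else(plus_read, "-", "+")
  far <- if_else(plus_read, reads$pos - span, reads$pos + span)
  ok <- far >= 0L & far < lens[reads$chrom]
  dropped <- sum(reads$count[!ok])

  kept <- reads[ok, , drop = FALSE]
  lpos <- lpos[ok]
  lstrand <- lstrand[ok]
  if (mode == "nmp") {
    base <- genome_base(genome, kept$chrom, lpos, lstrand)
    cls <- base
  } else {
    # 5'->3' dinucleotide on the lesion strand: key base then the next
    # base 3' of it (genomically +1 on the + strand, -1 on the - strand).
    nxt <- if_else(lstrand == "+", lpos + 1L, lpos - 1L)
    base <- genome_base(genome, kept$chrom, lpos, lstrand)
    base2 <- genome_base(genome, kept$chrom, nxt, lstrand)
    cls <- paste0(base, base2)
  }
  track <- tibble(chrom = kept$chrom, pos = lpos, strand = lstrand,
                  base = base, lesion_class = cls, count = kept$count)
  track <- summarise(
    group_by(track, .data$chrom, .data$pos, .data$strand, .data$base,
             .data$lesion_class),
    count = sum(.data$count), .groups = "drop"
  )
  track <- select(arrange(track, .data$chrom, .data$pos, .data$strand),
                  "chrom", "pos", "strand", "base", "count", "lesion_class")
  attr(track, "dropped_reads") <- dropped
  track
}

#' Base composition of a lesion library
#'
#' Counts the reads assigned to each lesion base, the standard first look
#' at a methylation-damage library (G reads dominate, then A, reflecting
#' 7meG >> 3meA formation).
#'
#' @param track Lesion track from [infer_lesions()].
#' @return Tibble (base, reads, fraction), fractions summing to 1.
#' @export
base_composition <- function(track) {
  if (nrow(track) == 0 || sum(track$count) == 0) {
    abort("empty lesion track: no reads to summarise")
  }
  out <- summarise(group_by(track, base = .data$base),
                   reads = sum(.data$count), .groups = "drop")
  out <- mutate(arrange(out, .data$base),
                fraction = .data$reads / sum(.data$reads))
  out
}

#' Restrict a lesion track to one lesion class
#'
#' Extracts the sub-track for a base class (G for putative 7meG, A for
#' putative 3meA) or, for dinucleotide tracks, a set of dinucleotides
#' (e.g. the dipyrimidines `c("TT","TC","CT","CC")`).
#'
#' @param track Lesion track.
#' @param class Character vector of class labels to retain.
#' @return The track restricted to matching positions, counts unchanged.
#' @export
select_class <- function(track, class) {
  class <- toupper(class)
  valid <- unique(c("A", "C", "G", "T",
                    as.vector(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0))))
  if (!all(class %in% valid)) {
    abort(paste0("unknown lesion class label(s): ",
                 paste(setdiff(class, valid), collapse = ", ")))
  }
  filter(track, .data$lesion_class %in% class)
}
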