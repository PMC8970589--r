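# Independent oracles, written directly from first principles and kept
# free of the package's own helpers wherever the package path is the
# thing under test.

oracle_comp <- function(b) chartr("ACGTN", "TGCAN", b)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Brute-force single-base lesion inference: one read at a time, applying
# the rule "the single nucleotide immediately upstream of the 5' end, on
# the opposing strand" literally. Returns rows (pos, strand, base) or
# NULL when the upstream base falls off the chromosome.
oracle_infer_one <- function(seq, pos, strand) {
  L <- nchar(seq)
  if (strand == "+") {
    up <- pos - 1
    if (up < 0) return(NULL)
    list(pos = up, strand = "-",
         base = oracle_comp(substr(seq, up + 1, up + 1)))
  } else {
    up <- pos + 1
    if (up >= L) return(NULL)
    list(pos = up, strand = "+", base = substr(seq, up + 1, up + 1))
  }
}

oracle_infer_nmp <- function(reads, seq) {
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    r <- oracle_infer_one(seq, reads$pos[i], reads$strand[i])
    if (is.null(r)) next
    key <- paste(r$pos, r$strand)
    cnt <- if (!is.null(rows[[key]])) rows[[key]]$count else 0L
    n_i <- if ("count" %in% names(reads)) reads$count[i] else 1L
    rows[[key]] <- list(pos = r$pos, strand = r$strand, base = r$base,
                        count = cnt + n_i)
  }
  if (length(rows) == 0) {
    return(data.frame(pos = integer(), strand = character(),
                      base = character(), count = integer()))
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  # locale-independent ordering: "+" before "-" at the same position
  df <- df[order(df$pos, match(df$strand, c("+", "-"))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# IUPAC regex oracle (own degeneracy table, not the package's).
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]", S = "[CG]",
  W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

oracle_motif_regex <- function(motif) {
  paste(unlist(ORACLE_IUPAC[strsplit(motif, "")[[1]]]), collapse = "")
}

oracle_matches_motif <- function(seq, motif) {
  grepl(paste0("^", oracle_motif_regex(motif), "$"), seq)
}

# Does the interval sequence (either strand) contain a motif match?
oracle_interval_has_motif <- function(seq, motif) {
  re <- oracle_motif_regex(motif)
  grepl(re, seq) || grepl(re, oracle_revcomp(seq))
}

# Brute-force TSS linkage: nearest TSS per site, divergent rule, ties
# both, each gene once at its closest site.
oracle_link_tss <- function(sites, genes, max_dist = 300) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    g <- genes[genes$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- g$tss - sites$midpoint[i]
    left <- which(d < 0); right <- which(d > 0)
    nl <- if (length(left)) left[which.max(d[left])] else NA
    nr <- if (length(right)) right[which.min(d[right])] else NA
    pick <- integer()
    if (!is.na(nl) && !is.na(nr) && g$strand[nl] == "-" &&
        g$strand[nr] == "+" && abs(d[nl]) <= max_dist &&
        abs(d[nr]) <= max_dist) {
      pick <- c(nl, nr)
    } else {
      nearest <- which(abs(d) == min(abs(d)))
      pick <- nearest[abs(d[nearest]) <= max_dist]
    }
    for (k in pick) {
      out[[length(out) + 1L]] <- data.frame(
        site_idx = i, gene_id = g$gene_id[k],
        dist_abs = abs(d[k]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(site_idx = integer(), gene_id = character()))
  }
  df <- do.call(rbind, out)
  # one row per gene, closest site
  df <- df[order(df$gene_id, df$dist_abs), , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df[order(df$site_idx, df$gene_id), c("site_idx", "gene_id")]
}

# Small-fixture builders -----------------------------------------------

toy_track <- function(pos, strand, count, chrom = "chr1",
                      base = "G") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 base = base, count = as.integer(count),
                 lesion_class = base)
}

# Strip order/attribute differences before comparing two lesion tracks.
track_df <- function(tr) {
  df <- data.frame(chrom = as.character(tr$chrom), pos = as.integer(tr$pos),
                   strand = as.character(tr$strand),
                   base = as.character(tr$base),
                   count = as.integer(tr$count))
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Default-ish small simulation used by several tests.
small_sim <- function(seed = 1, n_sites = 20L, genome_length = 60000L,
                      depth = 2e5, ...) {
  cfg <- sim_config(genome_length = genome_length, n_sites = n_sites,
                    depth = depth, seed = seed, ...)
  g <- simulate_genome(cfg$genome_length, cfg$gc_content, seed = seed)
  pl <- plant_sites(g, cfg$motif, cfg$n_sites, cfg$occupancy_values,
                    min_gap = cfg$site_min_gap, seed = seed + 1L)
  field <- simulate_lesion_field(pl$genome, pl$sites, cfg, seed = seed + 2L)
  list(cfg = cfg, genome = pl$genome, sites = pl$sites, field = field)
}
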