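# Shared fixtures and independent oracles.  The cohort fixture is built
# once per test run and cached; oracles avoid the package's pileup
# machinery entirely (plain per-read text scans).

.fixture_cache <- new.env(parent = emptyenv())

# Small paperlike cohort used by several test files.
fix_cohort <- function() {
  if (!is.null(.fixture_cache$cohort)) return(.fixture_cache$cohort)
  gen <- build_genome(genome_spec(n_chromosomes = 2L, chrom_length = 30000L,
                                  repeat_count = 20L, repeat_length = 200L,
                                  seed = 101L))
  catalog <- make_site_catalog(gen, n_background = 12L, seed = 102L)
  editomes <- make_cell_editomes(catalog, "paperlike", seed = 103L)
  .fixture_cache$cohort <- list(gen = gen, catalog = catalog,
                                editomes = editomes)
  .fixture_cache$cohort
}

# Hand-written SAM: reads described as (chrom, pos, seq, phred vector).
write_toy_sam <- function(reads, chrom_lengths, path,
                          nh = rep(1L, length(reads))) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      chrom_lengths))
  body <- vapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    paste(sprintf("toy%03d", i), 0L, r$chrom, r$pos, 255L,
          paste0(nchar(r$seq), "M"), "*", 0L, 0L, r$seq,
          rawToChar(as.raw(r$phred + 33L)),
          sprintf("NH:i:%d", nh[i]), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Brute-force oracle: per-read scan of a SAM text file, counting bases at
# one genomic position with a strict phred filter.  Ungapped reads only.
oracle_bases_at <- function(sam_path, chrom, pos, min_phred = 25L,
                            unique_only = TRUE) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (f[3] != chrom) next
    if (unique_only) {
      nh_f <- grep("^NH:i:", f[-(1:11)], value = TRUE)
      if (length(nh_f) && as.integer(sub("NH:i:", "", nh_f[1])) > 1) next
    }
    start <- as.integer(f[4])
    len <- nchar(f[10])
    if (pos < start || pos > start + len - 1) next
    off <- pos - start + 1
    b <- substr(f[10], off, off)
    q <- utf8ToInt(substr(f[11], off, off)) - 33L
    if (q > min_phred && b != "N") out <- c(out, b)
  }
  out
}

# Oracle site counts (strand-aware) from the per-read scan.
oracle_site_counts <- function(sam_path, chrom, pos, strand,
                               min_phred = 25L, unique_only = TRUE) {
  b <- oracle_bases_at(sam_path, chrom, pos, min_phred, unique_only)
  if (strand == "-") b <- chartr("ACGT", "TGCA", b)
  c(n_A = sum(b == "A"), n_G = sum(b == "G"),
    n_other = sum(b %in% c("C", "T")))
}

# Oracle mismatch counts over repeat positions: full per-read, per-base
# scan, independent of the pileup path.
oracle_repeat_tab <- function(sam_path, genome, repeats, min_phred = 25L) {
  tab <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  rep_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(repeats)),
                       start = GenomicRanges::start(repeats),
                       end = GenomicRanges::end(repeats),
                       strand = as.character(GenomicRanges::strand(repeats)))
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    start <- as.integer(f[4]); len <- nchar(f[10])
    chrom <- f[3]
    refseq <- as.character(Biostrings::subseq(genome[[chrom]], start,
                                              start + len - 1))
    for (k in which(rep_df$chrom == chrom & rep_df$start <= start + len - 1 &
                      rep_df$end >= start)) {
      a <- max(rep_df$start[k], start); z <- min(rep_df$end[k], start + len - 1)
      for (p in a:z) {
        off <- p - start + 1
        rb <- substr(refseq, off, off)
        ob <- substr(f[10], off, off)
        q <- utf8ToInt(substr(f[11], off, off)) - 33L
        if (q <= min_phred || ob == "N" || rb == "N") next
        if (rep_df$strand[k] == "-") {
          rb <- chartr("ACGT", "TGCA", rb); ob <- chartr("ACGT", "TGCA", ob)
        }
        tab[rb, ob] <- tab[rb, ob] + 1L
      }
    }
  }
  tab
}

# Exact two-sided Mann-Whitney by full enumeration of all rank splits.
oracle_mw_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- combn(n + m, n)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
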