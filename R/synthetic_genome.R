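# Synthetic genome + repeat annotation generator.
#
# Stands in for a mammalian reference with RepeatMasker SINE annotation
# (three repeat families, mixed orientation, per-copy divergence) so the
# repeat editing index and hyper-editing rescue can run at desk scale with
# exact ground truth.

#' Specification for a synthetic genome
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bases.
#' @param repeat_count total number of repeat copies planted across the
#'   genome.
#' @param repeat_length length of each repeat family consensus in bases.
#' @param repeat_divergence per-copy substitution fraction relative to the
#'   family consensus, in `[0, 0.3]`.
#' @param gc_content GC fraction of the background sequence, in `(0, 1)`.
#' @param families character vector of repeat family names.
#' @param inverted_fraction fraction of repeat copies planted in inverted
#'   (minus-strand) orientation.
#' @param seed integer seed; the whole genome is deterministic given it.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(n_chromosomes = 2L, chrom_length = 50000L,
                        repeat_count = 30L, repeat_length = 200L,
                        repeat_divergence = 0.1, gc_content = 0.42,
                        families = c("B1", "B2", "B4"),
                        inverted_fraction = 0.3, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 1, repeat_count >= 0,
            repeat_length >= 1)
  if (repeat_divergence < 0 || repeat_divergence > 0.3)
    stop("repeat_divergence must lie in [0, 0.3]")
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie in (0, 1)")
  if (as.numeric(chrom_length) * n_chromosomes <
      as.numeric(repeat_count) * repeat_length)
    stop("impossible packing: repeats exceed total chromosome length")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 repeat_count = as.integer(repeat_count),
                 repeat_length = as.integer(repeat_length),
                 repeat_divergence = repeat_divergence,
                 gc_content = gc_content, families = families,
                 inverted_fraction = inverted_fraction,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# Mutate a consensus copy: each base substituted to a uniformly chosen
# different base with probability `div`.
mutate_copy <- function(consensus, div) {
  if (div <= 0) return(consensus)
  b <- strsplit(consensus, "")[[1]]
  hit <- runif(length(b)) < div
  if (any(hit)) {
    alts <- c("A", "C", "G", "T")
    b[hit] <- vapply(b[hit],
                     function(x) sample(setdiff(alts, x), 1L), character(1))
  }
  paste(b, collapse = "")
}

#' Build a synthetic genome with planted repeat copies
#'
#' Generates random chromosomes and plants mutated descendants of
#' per-family consensus sequences at non-overlapping positions, a fraction
#' of them inverted.  Family consensi are drawn independently, so their
#' mutual identity is near the random baseline (~25%), keeping placement
#' unambiguous.
#'
#' @param spec a [genome_spec()].
#' @return a list with `genome` (named [Biostrings::DNAStringSet]),
#'   `repeats` ([GenomicRanges::GRanges] with `name` = family and strand),
#'   and `consensus` (named character vector of family consensi).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    consensus <- setNames(
      vapply(spec$families, function(f)
        random_dna(spec$repeat_length, spec$gc_content), character(1)),
      spec$families)
    per_chrom <- ceiling(spec$repeat_count / spec$n_chromosomes)
    chroms <- character(spec$n_chromosomes)
    rep_rows <- list()
    placed <- 0L
    for (ci in seq_len(spec$n_chromosomes)) {
      seqc <- random_dna(spec$chrom_length, spec$gc_content)
      n_here <- min(per_chrom, spec$repeat_count - placed)
      if (n_here > 0) {
        # greedy non-overlapping placement with a 2 bp guard gap
        slots <- integer(0)
        tries <- 0L
        while (length(slots) < n_here && tries < 20000L) {
          cand <- sample.int(spec$chrom_length - spec$repeat_length + 1L, 1L)
          if (!any(abs(cand - slots) < spec$repeat_length + 2L))
            slots <- c(slots, cand)
          tries <- tries + 1L
        }
        if (length(slots) < n_here)
          stop("impossible packing: could not place repeat copies")
        slots <- sort(slots)
        for (s in slots) {
          fam <- sample(spec$families, 1L)
          copy <- mutate_copy(consensus[[fam]], spec$repeat_divergence)
          inv <- runif(1) < spec$inverted_fraction
          ins <- if (inv) revcomp_chr(copy) else copy
          substr(seqc, s, s + spec$repeat_length - 1L) <- ins
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            chrom = paste0("chr", ci), start = s,
            end = s + spec$repeat_length - 1L,
            name = fam, strand = if (inv) "-" else "+",
            stringsAsFactors = FALSE)
        }
        placed <- placed + n_here
      }
      chroms[ci] <- seqc
    }
    genome <- DNAStringSet(chroms)
    names(genome) <- paste0("chr", seq_len(spec$n_chromosomes))
    rep_df <- do.call(rbind, rep_rows)
    repeats <- if (is.null(rep_df)) GRanges() else
      GRanges(rep_df$chrom, IRanges(rep_df$start, rep_df$end),
              strand = rep_df$strand, name = rep_df$name)
    list(genome = genome, repeats = repeats, consensus = consensus,
         spec = spec)
  })
}

#' Write genome FASTA (+ .fai) and repeat BED
#'
#' BED is 6-column, 0-based half-open, `name` = repeat family, column 6 =
#' strand.
#'
#' @param gen result of [build_genome()].
#' @param dir output directory (created if absent).
#' @return named character vector of paths (`fasta`, `fai`, `bed`).
#' @export
write_genome_files <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "genome.fa")
  writeXStringSet(gen$genome, fasta)
  Rsamtools::indexFa(fasta)
  bed <- file.path(dir, "repeats.bed")
  df <- data.frame(chrom = as.character(seqnames(gen$repeats)),
                   start = start(gen$repeats) - 1L,
                   end = end(gen$repeats),
                   name = mcols(gen$repeats)$name,
                   score = 0L,
                   strand = as.character(strand(gen$repeats)))
  utils::write.table(df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  c(fasta = fasta, fai = paste0(fasta, ".fai"), bed = bed)
}

# Named recoding-site panels.  Levels are fractions; the printed in-vitro
# neuron/astrocyte control values back the six measured sites, and the two
# remaining neuron-high sites of the injury panel carry plausible values in
# the same range (see the methods vignette).
panel_sites <- function(panel = c("paperlike", "table2")) {
  panel <- match.arg(panel)
  t2 <- data.frame(
    gene = c("FLNA_QR", "TMEM63B_QR", "GRIK2_IV", "GRIK2_QR",
             "COPA_IV", "COG3_IV"),
    neuron = c(0.0726, 0.3160, 0.3874, 0.6935, 0.0310, 0.2469),
    astrocyte = c(0.0196, 0.0126, 0.0376, 0.0468, 0.1835, 0.8856),
    stringsAsFactors = FALSE)
  if (panel == "table2") return(t2)
  extra <- data.frame(
    gene = c("CACNA1D_IM", "BLCAP_YC"),
    neuron = c(0.35, 0.25),
    astrocyte = c(0.08, 0.10),
    stringsAsFactors = FALSE)
  rbind(t2[1:4, ], extra, t2[5:6, ])
}

#' Build a synthetic editing-site catalog
#'
#' Sites are adenosines on their annotated strand (a minus-strand site is a
#' plus-strand thymidine).  A named recoding panel is planted first, then
#' background sites are sampled outside annotated repeats.
#'
#' @param gen result of [build_genome()].
#' @param n_background number of background (generic) sites.
#' @param panel `"paperlike"` (8 named recoding sites), `"table2"` (the 6
#'   measured in-vitro sites) or `"none"`.
#' @param frac_minus fraction of sites placed on the minus strand.
#' @param frac_conserved_background fraction of background sites flagged
#'   conserved.
#' @param seed integer seed.
#' @return data.frame with columns `site_id, chrom, pos` (1-based),
#'   `strand, gene, conserved`.
#' @export
make_site_catalog <- function(gen, n_background = 20L,
                              panel = c("paperlike", "table2", "none"),
                              frac_minus = 0.3,
                              frac_conserved_background = 0.8,
                              seed = 1L) {
  panel <- match.arg(panel)
  genes <- if (panel == "none") character(0) else panel_sites(panel)$gene
  n_total <- length(genes) + n_background
  with_seed(seed, {
    rows <- list()
    used <- list()
    chrom_names <- names(gen$genome)
    for (i in seq_len(n_total)) {
      on_minus <- runif(1) < frac_minus
      want <- if (on_minus) "T" else "A"  # sense-strand adenosine
      repeat {
        ch <- sample(chrom_names, 1L)
        L <- length(gen$genome[[ch]])
        p <- sample.int(L - 200L, 1L) + 100L
        key <- paste(ch, p)
        in_repeat <- length(gen$repeats) > 0 &&
          any(as.character(seqnames(gen$repeats)) == ch &
              start(gen$repeats) <= p & end(gen$repeats) >= p)
        base <- as.character(subseq(gen$genome[[ch]], p, p))
        if (!in_repeat && is.null(used[[key]]) && base == want) {
          used[[key]] <- TRUE
          break
        }
      }
      gene <- if (i <= length(genes)) genes[i] else sprintf("GENE%03d", i)
      conserved <- if (i <= length(genes)) 1L else
        as.integer(runif(1) < frac_conserved_background)
      rows[[i]] <- data.frame(site_id = sprintf("site%03d", i), chrom = ch,
                              pos = p, strand = if (on_minus) "-" else "+",
                              gene = gene, conserved = conserved,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Write a site catalog TSV
#' @param catalog data.frame from [make_site_catalog()].
#' @param path output path.
#' @param seed seed recorded in the file header.
#' @return the path, invisibly.
#' @export
write_site_catalog <- function(catalog, path, seed = NULL) {
  write_tsv(catalog, path, seed = seed)
}

#' Read a site catalog TSV
#' @param path file written by [write_site_catalog()] (or any TSV with the
#'   same columns; `#` lines are skipped).
#' @return the catalog data.frame.
#' @export
read_site_catalog <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom", "pos", "strand", "gene", "conserved")
  if (!all(need %in% names(df)))
    stop("catalog lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!("site_id" %in% names(df)))
    df$site_id <- sprintf("site%03d", seq_len(nrow(df)))
  dup <- duplicated(df[c("chrom", "pos", "strand")])
  if (any(dup)) {
    warning(sum(dup), " duplicate catalog rows collapsed")
    df <- df[!dup, ]
  }
  df
}
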