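# Per-site editing quantification: filtered base counts at catalogued
# sites, editing levels with coverage filtering, the conserved-editing
# index (CEI), and the expression-dominance QC rule.

#' Quantification filter configuration
#'
#' @param min_phred base-quality cutoff; bases with phred <= `min_phred`
#'   are excluded entirely (strict `>` comparison; default 25).
#' @param min_coverage minimum filtered reads for a level to be reported
#'   (default 15).
#' @param min_groups number of sample groups that must meet
#'   `min_coverage` for a site to be kept at all (default 2).
#' @param unique_only drop alignments whose `NH` tag exceeds 1 (default
#'   `TRUE`; switch off for amplicon input).
#' @return a `quant_config` list.
#' @export
quant_config <- function(min_phred = 25L, min_coverage = 15L,
                         min_groups = 2L, unique_only = TRUE) {
  stopifnot(min_phred >= 0, min_coverage >= 1, min_groups >= 1)
  structure(list(min_phred = as.integer(min_phred),
                 min_coverage = as.integer(min_coverage),
                 min_groups = as.integer(min_groups),
                 unique_only = isTRUE(unique_only)),
            class = "quant_config")
}

# Pile read bases and their phred values at width-1 positions.
# Returns per-position character vectors of bases and integer phreds.
pile_at_positions <- function(gal, at) {
  GenomeInfoDb::seqlevels(at) <- GenomeInfoDb::seqlevels(gal)
  seqs <- mcols(gal)$seq
  quals <- as(mcols(gal)$qual, "BStringSet")
  piled_b <- GenomicAlignments::pileLettersAt(
    seqs, seqnames(gal), start(gal), cigar(gal), at)
  piled_q <- GenomicAlignments::pileLettersAt(
    quals, seqnames(gal), start(gal), cigar(gal), at)
  b <- strsplit(as.character(piled_b), "")
  q <- lapply(strsplit(as.character(piled_q), ""),
              function(x) if (length(x)) utf8ToInt(paste(x, collapse = "")) - 33L
              else integer(0))
  list(bases = b, phred = q)
}

filter_unique <- function(gal, config) {
  if (!config$unique_only) return(gal)
  nh <- mcols(gal)$NH
  if (is.null(nh)) return(gal)
  gal[is.na(nh) | nh == 1L]
}

#' Count filtered bases at catalogued editing sites
#'
#' Bases with phred <= `min_phred` are excluded from numerator and
#' denominator alike.  Minus-strand sites are counted in complemented
#' space: a plus-strand `T` pileup is reported as `n_A`, a `C` as `n_G`,
#' so `n_G` always measures sense-strand A-to-G.
#'
#' @param alignments path to a SAM or BAM file.
#' @param catalog site catalog data.frame (`chrom, pos, strand, ...`).
#' @param config a [quant_config()].
#' @param sample_id identifier recorded in the output (default: file base
#'   name).
#' @return data.frame: one row per site with `n_A, n_G, n_other, n_total`
#'   (post-filter).
#' @export
count_site_bases <- function(alignments, catalog, config = quant_config(),
                             sample_id = NULL) {
  catalog <- check_catalog(catalog)
  sample_id <- sample_id %||%
    sub("\\.(sam|bam)$", "", basename(alignments), ignore.case = TRUE)
  bam <- ensure_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_chrom <- setdiff(unique(catalog$chrom), names(hdr))
  if (length(missing_chrom))
    stop("catalog chromosome(s) absent from alignment header: ",
         paste(missing_chrom, collapse = ", "))
  at <- GRanges(catalog$chrom, IRanges(catalog$pos, width = 1L))
  # read the whole file once: desk-scale inputs, and region queries would
  # return a read twice when it spans two query ranges
  gal <- read_alignments(bam)
  gal <- filter_unique(gal, config)
  out <- data.frame(site_id = catalog$site_id, chrom = catalog$chrom,
                    pos = catalog$pos, strand = catalog$strand,
                    gene = catalog$gene, conserved = catalog$conserved,
                    sample = sample_id, n_A = 0L, n_G = 0L, n_other = 0L,
                    n_total = 0L, stringsAsFactors = FALSE)
  if (length(gal) == 0) {
    warning("no alignments overlap the catalog; returning zero counts")
    return(out)
  }
  piled <- pile_at_positions(gal, at)
  for (i in seq_len(nrow(catalog))) {
    b <- piled$bases[[i]]; q <- piled$phred[[i]]
    keep <- q > config$min_phred & b != "N"
    b <- b[keep]
    if (catalog$strand[i] == "-") b <- comp_base(b)
    out$n_A[i] <- sum(b == "A")
    out$n_G[i] <- sum(b == "G")
    out$n_other[i] <- sum(b == "C" | b == "T")
    out$n_total[i] <- out$n_A[i] + out$n_G[i] + out$n_other[i]
  }
  out
}

check_catalog <- function(catalog) {
  need <- c("chrom", "pos", "strand")
  stopifnot(all(need %in% names(catalog)))
  if (!("site_id" %in% names(catalog)))
    catalog$site_id <- sprintf("site%03d", seq_len(nrow(catalog)))
  if (!("gene" %in% names(catalog))) catalog$gene <- catalog$site_id
  if (!("conserved" %in% names(catalog))) catalog$conserved <- 1L
  dup <- duplicated(catalog[c("chrom", "pos", "strand")])
  if (any(dup)) {
    warning(sum(dup), " duplicate catalog rows collapsed")
    catalog <- catalog[!dup, ]
  }
  catalog
}

#' Per-site editing levels with coverage filtering
#'
#' The level is `n_G / (n_A + n_G)`.  A site-sample cell with filtered
#' coverage below `min_coverage` is reported missing with a reason; a site
#' that meets coverage in fewer than `min_groups` groups is dropped from
#' the table entirely.
#'
#' @param counts row-bound output of [count_site_bases()] over one or more
#'   samples.
#' @param config a [quant_config()].
#' @param groups optional named vector mapping sample id to group (e.g.
#'   cell type); defaults to each sample being its own group.  A group
#'   meets coverage at a site if at least one of its samples does.
#' @return data.frame `site_id, sample, level, coverage, missing_reason`;
#'   dropped sites in `attr(, "dropped_sites")`.
#' @export
editing_levels <- function(counts, config = quant_config(), groups = NULL) {
  samples <- unique(counts$sample)
  groups <- groups %||% setNames(samples, samples)
  counts$group <- unname(groups[counts$sample])
  ok <- counts$n_total >= config$min_coverage
  n_groups_ok <- tapply(counts$group[ok], counts$site_id[ok],
                        function(g) length(unique(g)))
  keep_sites <- names(n_groups_ok)[n_groups_ok >= config$min_groups]
  dropped <- setdiff(unique(counts$site_id), keep_sites)
  counts <- counts[counts$site_id %in% keep_sites, ]
  lv <- ifelse(counts$n_A + counts$n_G > 0,
               counts$n_G / (counts$n_A + counts$n_G), NA_real_)
  reason <- rep(NA_character_, nrow(counts))
  low <- counts$n_total < config$min_coverage
  reason[low] <- ifelse(counts$n_total[low] == 0, "not covered",
                        "low coverage")
  lv[low] <- NA_real_
  reason[!low & is.na(lv)] <- "no A/G bases"
  out <- data.frame(site_id = counts$site_id, sample = counts$sample,
                    gene = counts$gene, conserved = counts$conserved,
                    level = lv, coverage = counts$n_total,
                    missing_reason = reason, stringsAsFactors = FALSE)
  attr(out, "dropped_sites") <- dropped
  out
}

#' Editing-level matrix (sites x samples)
#' @param levels output of [editing_levels()].
#' @return numeric matrix, rownames = site ids, colnames = samples.
#' @export
level_matrix <- function(levels) {
  sites <- unique(levels$site_id)
  samples <- unique(levels$sample)
  m <- matrix(NA_real_, length(sites), length(samples),
              dimnames = list(sites, samples))
  m[cbind(match(levels$site_id, sites), match(levels$sample, samples))] <-
    levels$level
  m
}

#' Conserved-editing index (CEI)
#'
#' Coverage-weighted aggregate editing over conserved sites: summed
#' A-to-G mismatch bases divided by summed filtered bases over all
#' conserved sites, with no per-site coverage cutoff — deeper sites weigh
#' more.
#'
#' @param counts output of [count_site_bases()] (one or more samples);
#'   only rows with `conserved == 1` contribute.
#' @return data.frame `sample, numerator, denominator, cei`.
#' @export
compute_cei <- function(counts) {
  cons <- counts[counts$conserved == 1, ]
  if (nrow(cons) == 0) stop("no conserved sites in counts")
  agg_n <- tapply(cons$n_G, cons$sample, sum)
  agg_d <- tapply(cons$n_total, cons$sample, sum)
  if (any(agg_d == 0))
    stop("zero total coverage over conserved sites for sample(s): ",
         paste(names(agg_d)[agg_d == 0], collapse = ", "))
  data.frame(sample = names(agg_n), numerator = as.integer(agg_n),
             denominator = as.integer(agg_d),
             cei = as.numeric(agg_n / agg_d),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression-dominance QC check
#'
#' Flags a sample in which a single host gene dominates the summed
#' expression of all genes carrying catalogued sites (share strictly above
#' `threshold`); such samples distort the depth-weighted CEI and are
#' excluded from CEI summaries by the pipeline.
#'
#' @param fpkm named numeric vector of per-host-gene FPKM for one sample.
#' @param threshold dominance share (default 0.7).
#' @return list `flagged` (logical), `dominant` (gene name), `share`.
#' @export
expression_dominance_check <- function(fpkm, threshold = 0.7) {
  if (length(fpkm) == 0 || any(!is.finite(fpkm)))
    stop("fpkm must be a non-empty vector of finite values")
  if (sum(fpkm) <= 0) stop("all-zero FPKM: dominance share undefined")
  share <- max(fpkm) / sum(fpkm)
  list(flagged = share > threshold,
       dominant = names(fpkm)[which.max(fpkm)] %||% NA_character_,
       share = share)
}
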