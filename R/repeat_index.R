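# Global repeat (SINE) editing index: the weighted mismatch rate over all
# adenosines inside annotated repeats, computed for all 12 substitution
# types.  The A->G entry is the editing signal; the other 11 are the noise
# floor.

#' Build a repeat base map from genome + repeat annotation
#'
#' Same-strand overlapping intervals are merged; regions where repeats of
#' opposite strand overlap are dropped (ambiguous adenosine strand), with
#' the dropped base count recorded.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param repeats a [GenomicRanges::GRanges] (1-based, with strand and
#'   `name` = family) or a 6-column BED path (0-based half-open).
#' @param families optional character vector; keep only these families.
#' @return a `repeat_map` list: `intervals` (GRanges), `genome`,
#'   `n_conflict_bases`.
#' @export
build_repeat_map <- function(genome, repeats, families = NULL) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(repeats)) repeats <- read_bed(repeats)
  if (!is.null(families)) {
    if (is.null(mcols(repeats)$name))
      stop("repeat annotation has no family names to filter on")
    repeats <- repeats[mcols(repeats)$name %in% families]
  }
  bad <- setdiff(unique(as.character(seqnames(repeats))), names(genome))
  if (length(bad))
    stop("repeat chromosome(s) absent from genome: ",
         paste(bad, collapse = ", "))
  plus <- reduce(repeats[strand(repeats) == "+"], ignore.strand = TRUE)
  minus <- reduce(repeats[strand(repeats) == "-"], ignore.strand = TRUE)
  conflict <- GenomicRanges::intersect(plus, minus, ignore.strand = TRUE)
  n_conflict <- sum(width(conflict))
  if (n_conflict > 0) {
    plus <- GenomicRanges::setdiff(plus, conflict, ignore.strand = TRUE)
    minus <- GenomicRanges::setdiff(minus, conflict, ignore.strand = TRUE)
    message("dropped ", n_conflict,
            " bases where opposite-strand repeats overlap")
  }
  strand(plus) <- "+"; strand(minus) <- "-"
  iv <- sort(c(plus, minus), ignore.strand = TRUE)
  structure(list(intervals = iv, genome = genome,
                 n_conflict_bases = n_conflict),
            class = "repeat_map")
}

# Minimal BED6 reader via rtracklayer (0-based half-open -> 1-based GRanges).
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED file '", path, "': ",
                        conditionMessage(e)))
  gr
}

#' Reference bases at positions inside a repeat map
#' @param map a `repeat_map`.
#' @return list: `pos` (GRanges width 1, with strand of the hosting
#'   repeat) and `base` (plus-strand reference base per position).
#' @export
repeat_positions <- function(map) {
  iv <- map$intervals
  if (length(iv) == 0) stop("empty repeat map")
  pos <- unlist(lapply(seq_along(iv), function(i) start(iv)[i]:end(iv)[i]))
  chrom <- rep(as.character(seqnames(iv)), width(iv))
  strd <- rep(as.character(strand(iv)), width(iv))
  base <- character(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    base[sel] <- as.character(Biostrings::extractAt(
      map$genome[[ch]], IRanges(pos[sel], width = 1L)))
  }
  list(gr = GRanges(chrom, IRanges(pos, width = 1L), strand = strd),
       base = base)
}

#' Compute the 12-way mismatch index table over repeat positions
#'
#' Every filtered read base overlapping a repeat position with reference
#' base `X` increments `denominator(X)` and, when the read base is
#' `Y != X`, `numerator(X->Y)`.  Minus-strand repeat intervals are counted
#' in complemented space, so the A->G entry always measures sense-strand
#' A-to-G — the SINE editing index.
#'
#' @param alignments SAM/BAM path.
#' @param map a `repeat_map` from [build_repeat_map()].
#' @param config a [quant_config()] (phred and unique-mapping filters).
#' @param rescued optional SAM/BAM of hyper-editing-rescued reads, counted
#'   identically and pooled in.
#' @param sample_id identifier for the output rows.
#' @return data.frame of class `mismatch_index_table`: `sample, ref, alt,
#'   numerator, denominator, index`; the A->G row is the SINE editing
#'   index (also in `attr(, "sine_editing_index")`).
#' @export
compute_editing_index <- function(alignments, map,
                                  config = quant_config(),
                                  rescued = NULL, sample_id = NULL) {
  stopifnot(inherits(map, "repeat_map"))
  sample_id <- sample_id %||%
    sub("\\.(sam|bam)$", "", basename(alignments), ignore.case = TRUE)
  rp <- repeat_positions(map)
  tab <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  accumulate <- function(path) {
    gal <- filter_unique(read_alignments(path), config)
    if (length(gal) == 0) return(invisible(NULL))
    piled <- pile_at_positions(gal, rp$gr)
    n_per <- lengths(piled$bases)
    b <- unlist(piled$bases, use.names = FALSE)
    q <- unlist(piled$phred, use.names = FALSE)
    idx <- rep(seq_along(n_per), n_per)
    keep <- q > config$min_phred & b != "N"
    b <- b[keep]; idx <- idx[keep]
    refb <- rp$base[idx]
    minus <- as.character(strand(rp$gr))[idx] == "-"
    b[minus] <- comp_base(b[minus])
    refb[minus] <- comp_base(refb[minus])
    ok <- refb != "N"
    t2 <- table(factor(refb[ok], levels = rownames(tab)),
                factor(b[ok], levels = colnames(tab)))
    tab <<- tab + as.matrix(t2)
    invisible(NULL)
  }
  accumulate(alignments)
  if (!is.null(rescued)) accumulate(rescued)
  denom <- rowSums(tab)
  if (all(denom == 0))
    stop("no filtered read bases overlap the repeat map")
  rows <- expand.grid(ref = rownames(tab), alt = colnames(tab),
                      stringsAsFactors = FALSE)
  rows <- rows[rows$ref != rows$alt, ]
  rows <- rows[order(rows$ref, rows$alt), ]
  out <- data.frame(sample = sample_id, ref = rows$ref, alt = rows$alt,
                    numerator = tab[cbind(rows$ref, rows$alt)],
                    denominator = denom[rows$ref],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$index <- ifelse(out$denominator > 0,
                      out$numerator / out$denominator, NA_real_)
  attr(out, "sine_editing_index") <-
    out$index[out$ref == "A" & out$alt == "G"]
  class(out) <- c("mismatch_index_table", class(out))
  out
}

#' Extract the SINE editing index from a mismatch index table
#' @param table output of [compute_editing_index()].
#' @param percent report on the x100 ("%") scale (default `FALSE`).
#' @return numeric scalar.
#' @export
sine_editing_index <- function(table, percent = FALSE) {
  v <- table$index[table$ref == "A" & table$alt == "G"]
  if (percent) 100 * v else v
}

#' Per-sample index report with signal-to-noise
#'
#' Signal-to-noise is the A->G index divided by the median of the other
#' 11 indices; `Inf` is reported when the noise median is 0.
#'
#' @param tables a `mismatch_index_table` or list of them (one per
#'   sample).
#' @return list: `long` (row-bound table, sorted by sample, with both
#'   fraction and percent scales) and `summary` (per sample: A->G index,
#'   noise median, signal-to-noise).
#' @export
index_report <- function(tables) {
  if (inherits(tables, "mismatch_index_table")) tables <- list(tables)
  long <- do.call(rbind, lapply(tables, as.data.frame))
  long <- long[order(long$sample, long$ref, long$alt), ]
  long$index_percent <- 100 * long$index
  summ <- do.call(rbind, lapply(split(long, long$sample), function(d) {
    ag <- d$index[d$ref == "A" & d$alt == "G"]
    noise <- median(d$index[!(d$ref == "A" & d$alt == "G")], na.rm = TRUE)
    data.frame(sample = d$sample[1], ag_index = ag, noise_median = noise,
               signal_to_noise = if (is.na(noise) || noise == 0) Inf
               else ag / noise,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(long = long[order(long$sample), ], summary = summ)
}
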