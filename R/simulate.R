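# Read-level simulator: emits aligned reads (SAM) from a mixture of
# cell-type editomes, hyper-edited reads (FASTQ, unmapped by construction),
# and a full ground-truth table.
#
# Reads are always written on the plus strand; site/repeat strand is carried
# by the annotation, so a minus-strand edit appears as T->C on the plus
# strand and downstream counting complements accordingly.

#' Design of one simulated sample
#'
#' @param id sample identifier.
#' @param mixture named numeric vector of cell-type fractions summing to 1.
#' @param depth reads emitted per catalogued site.
#' @param read_length read length in bases.
#' @param error_rate per-base miscall probability, in `[0, 0.1)`.
#' @param phred_high phred of ordinary bases (default 35).
#' @param phred_low phred of the low-quality fraction (default 20, below
#'   the default `>25` filter).
#' @param low_qual_fraction fraction of bases emitted at `phred_low`.
#' @param repeat_depth target mean coverage of repeat bases (0 = no repeat
#'   reads).
#' @param hyper_fraction fraction of aligned reads additionally emitted as
#'   heavily edited unmapped reads, in `[0, 0.05]`.
#' @param hyper_edit_range range of planted edits per hyper read (default
#'   6–10, beyond a standard aligner's mismatch budget).
#' @param seed integer seed.
#' @return a `sample_design` list.
#' @export
sample_design <- function(id, mixture, depth = 100L, read_length = 75L,
                          error_rate = 0.001, phred_high = 35L,
                          phred_low = 20L, low_qual_fraction = 0,
                          repeat_depth = 0, hyper_fraction = 0,
                          hyper_edit_range = c(6L, 10L), seed = 1L) {
  mixture <- validate_mixture(mixture)
  stopifnot(depth > 0, read_length >= 20)
  if (error_rate < 0 || error_rate >= 0.1)
    stop("error_rate must lie in [0, 0.1)")
  if (hyper_fraction < 0 || hyper_fraction > 0.05)
    stop("hyper_fraction must lie in [0, 0.05]")
  structure(list(id = id, mixture = mixture, depth = as.integer(depth),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, phred_high = as.integer(phred_high),
                 phred_low = as.integer(phred_low),
                 low_qual_fraction = low_qual_fraction,
                 repeat_depth = repeat_depth,
                 hyper_fraction = hyper_fraction,
                 hyper_edit_range = as.integer(hyper_edit_range),
                 seed = as.integer(seed)),
            class = "sample_design")
}

validate_mixture <- function(mixture) {
  if (length(mixture) == 0 || is.null(names(mixture)))
    stop("mixture must be a non-empty named numeric vector")
  if (any(mixture < 0)) stop("mixture fractions must be non-negative")
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture fractions must sum to 1 (got ", sum(mixture), ")")
  mixture
}

apply_errors <- function(seq_chars, error_rate) {
  if (error_rate <= 0) return(seq_chars)
  hit <- which(runif(length(seq_chars)) < error_rate)
  if (length(hit)) {
    alts <- c("A", "C", "G", "T")
    seq_chars[hit] <- vapply(seq_chars[hit], function(x)
      sample(setdiff(alts, x), 1L), character(1))
  }
  seq_chars
}

#' Simulate one sample: aligned SAM + hyper-edited FASTQ + ground truth
#'
#' Each aligned read is drawn from a cell type with probability proportional
#' to fraction x expression weight of its locus; every catalogued site and
#' every repeat adenosine the read covers is edited with that cell type's
#' rate; per-base miscalls and quality values are then applied.  Hyper reads
#' carry 6–10 planted A-to-G edits (sense space) and are written only to
#' FASTQ.
#'
#' @param gen genome build ([build_genome()]).
#' @param catalog site catalog ([make_site_catalog()]).
#' @param editomes ground-truth editomes ([make_cell_editomes()]).
#' @param design a [sample_design()].
#' @param out_dir output directory for `<id>.sam`, `<id>_unmapped.fastq`
#'   and truth TSVs.
#' @return a `sim_sample` list: paths, `n_aligned`, and `truth`
#'   (`site_counts`, `repeat_counts`, `hyper`).
#' @export
simulate_sample <- function(gen, catalog, editomes, design, out_dir) {
  stopifnot(inherits(design, "sample_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mixture <- design$mixture
  types <- names(mixture)
  miss <- setdiff(types, colnames(editomes$levels))
  if (length(miss)) stop("no editome for cell type(s): ",
                         paste(miss, collapse = ", "))
  chrom_seq <- vapply(names(gen$genome), function(n)
    as.character(gen$genome[[n]]), character(1))
  chrom_len <- nchar(chrom_seq)
  for (i in seq_len(nrow(catalog)))
    if (catalog$pos[i] > chrom_len[[catalog$chrom[i]]])
      stop("catalog site beyond chromosome end: ", catalog$site_id[i])
  rl <- design$read_length
  rep_df <- if (length(gen$repeats)) data.frame(
    chrom = as.character(seqnames(gen$repeats)),
    start = start(gen$repeats), end = end(gen$repeats),
    strand = as.character(strand(gen$repeats)),
    stringsAsFactors = FALSE) else NULL

  with_seed(design$seed, {
    sam <- character(0)
    site_cov <- setNames(integer(nrow(catalog)), catalog$site_id)
    site_edit <- site_cov
    rep_a_cov <- 0L; rep_a_edit <- 0L
    read_records <- list()
    n_read <- 0L

    emit_read <- function(chrom, start, ct) {
      end <- start + rl - 1L
      s <- substr(chrom_seq[[chrom]], start, end)
      b <- strsplit(s, "")[[1]]
      # plant edits at catalogued sites covered by the read
      covered <- which(catalog$chrom == chrom & catalog$pos >= start &
                         catalog$pos <= end)
      for (k in covered) {
        off <- catalog$pos[k] - start + 1L
        site_cov[catalog$site_id[k]] <<- site_cov[catalog$site_id[k]] + 1L
        if (runif(1) < editomes$levels[catalog$site_id[k], ct]) {
          b[off] <- if (catalog$strand[k] == "+") "G" else "C"
          site_edit[catalog$site_id[k]] <<- site_edit[catalog$site_id[k]] + 1L
        }
      }
      # plant edits at repeat adenosines covered by the read
      if (!is.null(rep_df)) {
        ov <- which(rep_df$chrom == chrom & rep_df$start <= end &
                      rep_df$end >= start)
        for (k in ov) {
          a <- max(rep_df$start[k], start); z <- min(rep_df$end[k], end)
          offs <- (a:z) - start + 1L
          want <- if (rep_df$strand[k] == "+") "A" else "T"
          apos <- offs[b[offs] == want]
          # skip catalogued sites inside repeats (none by construction)
          if (length(apos)) {
            rep_a_cov <<- rep_a_cov + length(apos)
            hit <- apos[runif(length(apos)) < editomes$p_repeat[[ct]]]
            if (length(hit)) {
              b[hit] <- if (rep_df$strand[k] == "+") "G" else "C"
              rep_a_edit <<- rep_a_edit + length(hit)
            }
          }
        }
      }
      b <- apply_errors(b, design$error_rate)
      q <- rep(design$phred_high, rl)
      if (design$low_qual_fraction > 0) {
        lo <- runif(rl) < design$low_qual_fraction
        q[lo] <- design$phred_low
      }
      n_read <<- n_read + 1L
      sam[[length(sam) + 1L]] <<- paste(
        sprintf("read%06d", n_read), 0L, chrom, start, 255L,
        paste0(rl, "M"), "*", 0L, 0L, paste(b, collapse = ""),
        phred_to_qualstring(q), "NH:i:1", sep = "\t")
      invisible(NULL)
    }

    # site-targeted reads
    for (i in seq_len(nrow(catalog))) {
      ch <- catalog$chrom[i]; pos <- catalog$pos[i]
      w <- editomes$expression[catalog$gene[i], types]
      pr <- mixture * w
      if (sum(pr) <= 0) stop("all-zero mixture x expression weight at site ",
                             catalog$site_id[i])
      cts <- sample(types, design$depth, replace = TRUE, prob = pr)
      for (ct in cts) {
        lo <- max(1L, pos - rl + 1L)
        hi <- min(pos, chrom_len[[ch]] - rl + 1L)
        start <- if (hi <= lo) lo else sample(lo:hi, 1L)
        emit_read(ch, start, ct)
      }
    }
    # repeat-covering reads
    if (design$repeat_depth > 0 && !is.null(rep_df)) {
      total_rep_bases <- sum(rep_df$end - rep_df$start + 1L)
      n_rep_reads <- round(design$repeat_depth * total_rep_bases / rl)
      if (n_rep_reads > 0) {
        widths <- rep_df$end - rep_df$start + 1L
        ivs <- sample.int(nrow(rep_df), n_rep_reads, replace = TRUE,
                          prob = widths)
        cts <- sample(types, n_rep_reads, replace = TRUE, prob = mixture)
        for (j in seq_len(n_rep_reads)) {
          k <- ivs[j]; ch <- rep_df$chrom[k]
          lo <- max(1L, rep_df$start[k] - rl + 1L)
          hi <- min(rep_df$end[k], chrom_len[[ch]] - rl + 1L)
          start <- if (hi <= lo) lo else sample(lo:hi, 1L)
          emit_read(ch, start, cts[j])
        }
      }
    }
    # hyper-edited unmapped reads
    fastq <- character(0)
    hyper_rows <- list()
    n_hyper <- round(design$hyper_fraction * n_read)
    if (n_hyper > 0) {
      for (j in seq_len(n_hyper)) {
        ok <- FALSE
        for (try in 1:200) {
          sense <- sample(c("+", "-"), 1L)
          ch <- sample(names(chrom_seq), 1L)
          start <- sample.int(chrom_len[[ch]] - rl + 1L, 1L)
          s <- substr(chrom_seq[[ch]], start, start + rl - 1L)
          b <- strsplit(s, "")[[1]]
          want <- if (sense == "+") "A" else "T"
          apos <- which(b == want)
          n_edits <- sample(design$hyper_edit_range[1]:design$hyper_edit_range[2], 1L)
          if (length(apos) >= n_edits) {
            pick <- sort(sample(apos, n_edits))
            b[pick] <- if (sense == "+") "G" else "C"
            b <- apply_errors(b, design$error_rate)
            id <- sprintf("hyper%04d", j)
            fastq <- c(fastq, paste0("@", id), paste(b, collapse = ""), "+",
                       phred_to_qualstring(rep(design$phred_high, rl)))
            hyper_rows[[j]] <- data.frame(
              read_id = id, chrom = ch, start = start, sense = sense,
              n_edits = n_edits,
              positions = paste(start + pick - 1L, collapse = ","),
              stringsAsFactors = FALSE)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place a hyper read with enough adenosines")
      }
    }

    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_seq), chrom_len),
                sprintf("@PG\tID:editomix\tPN:editomix\tVN:%s",
                        as.character(utils::packageVersion("editomix"))))
    sam_path <- file.path(out_dir, paste0(design$id, ".sam"))
    writeLines(c(header, sam), sam_path)
    fastq_path <- file.path(out_dir, paste0(design$id, "_unmapped.fastq"))
    writeLines(fastq, fastq_path)

    truth <- list(
      site_counts = data.frame(site_id = catalog$site_id,
                               covered = as.integer(site_cov),
                               edited = as.integer(site_edit),
                               stringsAsFactors = FALSE),
      repeat_counts = data.frame(a_positions_covered = rep_a_cov,
                                 a_edited = rep_a_edit),
      hyper = if (length(hyper_rows)) do.call(rbind, hyper_rows) else
        data.frame(read_id = character(0), chrom = character(0),
                   start = integer(0), sense = character(0),
                   n_edits = integer(0), positions = character(0)))
    for (nm in names(truth))
      write_tsv(truth[[nm]], file.path(out_dir,
                paste0(design$id, "_truth_", nm, ".tsv")),
                seed = design$seed)
    structure(list(sam = sam_path, fastq = fastq_path, truth = truth,
                   n_aligned = n_read, design = design),
              class = "sim_sample")
  })
}

#' Simulate per-site base counts directly (count-level shortcut)
#'
#' Draws each site's edited-read count from the binomial law the read-level
#' simulator realises (`n_G ~ Binom(depth, mixed level)`), skipping SAM
#' emission.  Used for replicated statistical experiments where only the
#' site counts matter.
#'
#' @param editomes `cell_editomes` ground truth.
#' @param mixture named cell-type fraction vector summing to 1.
#' @param depth reads per site.
#' @param seed integer seed.
#' @param weights optional genes x types expression weight matrix
#'   (default: the editomes' own, uniform unless changed).
#' @return data.frame: `site_id, n_A, n_G, n_other, n_total`.
#' @export
simulate_site_counts <- function(editomes, mixture, depth, seed = 1L,
                                 weights = NULL) {
  mixture <- validate_mixture(mixture)
  catalog <- editomes$catalog
  w <- weights %||% editomes$expression
  p <- mixed_site_levels(editomes, mixture, w)
  with_seed(seed, {
    k <- rbinom(length(p), depth, p)
    data.frame(site_id = catalog$site_id, n_A = depth - k, n_G = k,
               n_other = 0L, n_total = depth, stringsAsFactors = FALSE)
  })
}

# Expected (noise-free) mixed level per site:
#   level(s) = sum_c f_c w_c(g(s)) L_c(s) / sum_c f_c w_c(g(s))
mixed_site_levels <- function(editomes, mixture, weights) {
  types <- names(mixture)
  catalog <- editomes$catalog
  vapply(seq_len(nrow(catalog)), function(i) {
    wc <- weights[catalog$gene[i], types]
    den <- sum(mixture * wc)
    if (den <= 0) return(NA_real_)
    sum(mixture * wc * editomes$levels[catalog$site_id[i], types]) / den
  }, numeric(1))
}
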