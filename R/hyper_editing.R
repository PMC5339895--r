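# Hyper-editing rescue: heavily A-to-G edited reads defeat standard
# alignment (too many mismatches).  They are recovered by collapsing the
# editing-affected letter: transform A->G in both reads and genome,
# realign in the reduced three-letter space, then back-transform and call
# the mismatches.  Antisense editing (T->C on the plus strand) is handled
# by a second transformed index rather than by reverse-complementing
# reads; the sense is recorded per hit.

#' Hyper-editing rescue configuration
#'
#' The printed thresholds follow the standard rescue scheme: an accepted
#' read needs at least `min_edits_per_read` A-to-G edits, an A-to-G share
#' of all mismatches of at least `min_ag_fraction`, and at most
#' `max_other_mismatches` non-A-to-G mismatches.
#'
#' @param min_edits_per_read minimum planted A-to-G edits (default 5).
#' @param min_ag_fraction minimum A-to-G share of all mismatches after
#'   back-transform (default 0.6).
#' @param max_other_mismatches maximum non-A-to-G mismatches (default 1).
#' @param min_phred_at_edit base-quality cutoff at edit positions,
#'   strict `>` (default 25).
#' @param seed_length exact-match seed length of the internal aligner
#'   (default 16).
#' @param max_transformed_mismatches mismatch budget in transformed space
#'   (default 2).
#' @return a `hyper_config` list.
#' @export
hyper_config <- function(min_edits_per_read = 5L, min_ag_fraction = 0.6,
                         max_other_mismatches = 1L, min_phred_at_edit = 25L,
                         seed_length = 16L,
                         max_transformed_mismatches = 2L) {
  stopifnot(min_edits_per_read >= 2, min_ag_fraction > 0,
            min_ag_fraction <= 1, seed_length >= 8)
  structure(list(min_edits_per_read = as.integer(min_edits_per_read),
                 min_ag_fraction = min_ag_fraction,
                 max_other_mismatches = as.integer(max_other_mismatches),
                 min_phred_at_edit = as.integer(min_phred_at_edit),
                 seed_length = as.integer(seed_length),
                 max_transformed_mismatches =
                   as.integer(max_transformed_mismatches)),
            class = "hyper_config")
}

#' Three-letter transform of a nucleotide sequence
#'
#' Replaces every `from_base` by `to_base`; all other symbols (including
#' `N`) pass through unchanged.  Idempotent: transforming an
#' already-transformed sequence is a no-op.
#'
#' @param sequence character vector (or XStringSet coerced via
#'   `as.character`) over `{A,C,G,T,N}`.
#' @param from_base,to_base single bases (default A -> G).
#' @return transformed character vector, same lengths.
#' @export
three_letter_transform <- function(sequence, from_base = "A",
                                   to_base = "G") {
  chartr(from_base, to_base, as.character(sequence))
}

#' Build the transformed genome index for hyper-editing rescue
#'
#' Two collapsed genomes are kept: A->G for sense editing and T->C for
#' antisense editing (edits on the minus-strand transcript seen as T->C on
#' the plus strand).
#'
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param seed_length exact seed length used at alignment time.
#' @return a `transformed_index` list.
#' @export
build_transformed_index <- function(genome, seed_length = 16L) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  orig <- vapply(names(genome), function(n) as.character(genome[[n]]),
                 character(1))
  structure(list(
    original = orig,
    sense = vapply(orig, three_letter_transform, character(1),
                   from_base = "A", to_base = "G"),
    antisense = vapply(orig, three_letter_transform, character(1),
                       from_base = "T", to_base = "C"),
    seed_length = as.integer(seed_length)),
    class = "transformed_index")
}

# Candidate loci for one transformed read against one transformed genome:
# exact seeds tried at read start, middle and end.
seed_candidates <- function(tread, tgenome, seed_length) {
  L <- nchar(tread)
  offs <- unique(c(1L, max(1L, (L - seed_length) %/% 2L + 1L),
                   L - seed_length + 1L))
  out <- list()
  for (chrom in names(tgenome)) {
    subject <- tgenome[[chrom]]
    for (o in offs) {
      seedseq <- substr(tread, o, o + seed_length - 1L)
      hits <- matchPattern(seedseq, Biostrings::BString(subject))
      if (length(hits)) {
        locus <- start(hits) - o + 1L
        locus <- locus[locus >= 1 & locus + L - 1L <= nchar(subject)]
        for (l in locus)
          out[[paste(chrom, l)]] <- list(chrom = chrom, start = l)
      }
    }
  }
  out
}

count_mismatches <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  sum(x != y)
}

#' Align one read in transformed space
#'
#' Tries both transformed genomes (sense A->G, antisense T->C) with exact
#' seeds at the read start, middle and end, extends candidates ungapped,
#' and keeps a hit only when the best locus is unique and its
#' transformed-space mismatch count is within budget.  A sense/antisense
#' tie at equal mismatches is discarded as ambiguous.
#'
#' @param read read sequence (character).
#' @param index a `transformed_index`.
#' @param config a [hyper_config()].
#' @return list `chrom, start` (1-based), `sense` (`"+"`/`"-"`),
#'   `mismatches`, or `NULL` when there is no acceptable unique hit.
#' @export
align_transformed <- function(read, index, config = hyper_config()) {
  L <- nchar(read)
  if (L < config$seed_length) return(NULL)
  cands <- list()
  for (sense in c("+", "-")) {
    tread <- if (sense == "+")
      three_letter_transform(read, "A", "G") else
        three_letter_transform(read, "T", "C")
    tg <- if (sense == "+") index$sense else index$antisense
    for (cand in seed_candidates(tread, tg, config$seed_length)) {
      gsub_seq <- substr(tg[[cand$chrom]], cand$start, cand$start + L - 1L)
      mm <- count_mismatches(tread, gsub_seq)
      if (mm <= config$max_transformed_mismatches)
        cands[[paste(sense, cand$chrom, cand$start)]] <-
          list(chrom = cand$chrom, start = cand$start, sense = sense,
               mismatches = mm)
    }
  }
  if (length(cands) == 0) return(NULL)
  mms <- vapply(cands, `[[`, numeric(1), "mismatches")
  best <- which(mms == min(mms))
  if (length(best) > 1) return(NULL)  # ambiguous, discarded
  cands[[best]]
}

#' Back-transform a hit and call the edit cluster
#'
#' Compares the original read to the original genome at the hit locus.
#' For a sense hit the editing type is A->G; for an antisense hit it is
#' T->C on the plus strand, reported in sense space as A->G.  Editing-type
#' mismatches with phred above `min_phred_at_edit` count as edits
#' (low-quality ones are ignored); every other mismatch counts as
#' `n_other`.  The verdict applies the acceptance rules in order and
#' records the first failing one.
#'
#' @param read original read sequence (character).
#' @param phred integer vector of per-base phred values.
#' @param index a `transformed_index` (carries the original genome).
#' @param hit result of [align_transformed()].
#' @param config a [hyper_config()].
#' @param read_id identifier for the output.
#' @return an `edit_cluster` list: coordinates, `edits` data.frame
#'   (`pos, ref, alt, phred`, plus-strand space), `n_ag`, `n_other`,
#'   `verdict`, `reason`.
#' @export
back_transform_call <- function(read, phred, index, hit,
                                config = hyper_config(),
                                read_id = "read") {
  L <- nchar(read)
  gseq <- index$original[[hit$chrom]]
  if (hit$start + L - 1L > nchar(gseq))
    stop("hit extends beyond chromosome end")
  ref <- strsplit(substr(gseq, hit$start, hit$start + L - 1L), "")[[1]]
  obs <- strsplit(read, "")[[1]]
  mm <- which(ref != obs & obs != "N" & ref != "N")
  edit_ref <- if (hit$sense == "+") "A" else "T"
  edit_alt <- if (hit$sense == "+") "G" else "C"
  is_edit_type <- ref[mm] == edit_ref & obs[mm] == edit_alt
  hi_qual <- phred[mm] > config$min_phred_at_edit
  n_ag <- sum(is_edit_type & hi_qual)
  n_other <- sum(!is_edit_type)
  keep <- is_edit_type & hi_qual | !is_edit_type
  edits <- data.frame(pos = hit$start + mm[keep] - 1L, ref = ref[mm[keep]],
                      alt = obs[mm[keep]], phred = phred[mm[keep]],
                      is_edit = is_edit_type[keep] & hi_qual[keep],
                      stringsAsFactors = FALSE)
  verdict <- "accepted"; reason <- NA_character_
  if (n_ag < config$min_edits_per_read) {
    verdict <- "rejected"; reason <- "too few edits"
  } else if (n_ag / (n_ag + n_other) < config$min_ag_fraction) {
    verdict <- "rejected"; reason <- "low A-to-G fraction"
  } else if (n_other > config$max_other_mismatches) {
    verdict <- "rejected"; reason <- "other mismatches"
  }
  structure(list(read_id = read_id, chrom = hit$chrom,
                 start = hit$start, sense = hit$sense, edits = edits,
                 n_ag = n_ag, n_other = n_other, verdict = verdict,
                 reason = reason, read = read, phred = phred),
            class = "edit_cluster")
}

#' Rescue hyper-edited reads from a FASTQ of unmapped reads
#'
#' Full rescue pipeline: transformed alignment, back-transform, cluster
#' filtering.  Accepted reads are exported as plus-strand SAM alignments
#' (original sequence) so they can be pooled into the repeat editing
#' index.
#'
#' @param fastq path to FASTQ (phred+33) of unmapped reads.
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param config a [hyper_config()].
#' @param sam_out optional path; when given, accepted reads are written
#'   there as SAM.
#' @return list: `clusters` (one row per aligned read: locus, counts,
#'   verdict, reason), `edits` (accepted edit sites: `read_id, chrom, pos,
#'   sense, phred`), `n_reads`, `n_aligned`, `n_accepted`,
#'   `mismatch_spectrum` (pooled sense-space mismatch counts over accepted
#'   clusters, named `"X>Y"`), `sam_path`.
#' @export
rescue_hyper_edited <- function(fastq, genome, config = hyper_config(),
                                sam_out = NULL) {
  index <- if (inherits(genome, "transformed_index")) genome else
    build_transformed_index(genome, config$seed_length)
  reads <- readDNAStringSet(fastq, format = "fastq", with.qualities = TRUE)
  quals <- qualstring_to_phred(as.character(mcols(reads)$qualities))
  rows <- list(); edit_rows <- list(); sam_lines <- character(0)
  spectrum <- integer(0)  # pooled sense-space mismatch counts, "X>Y"
  for (i in seq_along(reads)) {
    id <- sub("\\s.*", "", names(reads)[i])
    rd <- as.character(reads[[i]])
    hit <- align_transformed(rd, index, config)
    if (is.null(hit)) next
    cl <- back_transform_call(rd, quals[[i]], index, hit, config, id)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = id, chrom = cl$chrom, start = cl$start, sense = cl$sense,
      n_ag = cl$n_ag, n_other = cl$n_other, verdict = cl$verdict,
      reason = cl$reason %||% NA_character_, stringsAsFactors = FALSE)
    if (cl$verdict == "accepted") {
      mm <- cl$edits
      if (nrow(mm)) {
        ref_s <- mm$ref; alt_s <- mm$alt
        if (cl$sense == "-") {
          ref_s <- comp_base(ref_s); alt_s <- comp_base(alt_s)
        }
        key <- paste0(ref_s, ">", alt_s)
        for (k in key)
          spectrum[k] <- (if (k %in% names(spectrum)) spectrum[[k]] else 0L) + 1L
      }
      ed <- cl$edits[cl$edits$is_edit, , drop = FALSE]
      if (nrow(ed))
        edit_rows[[length(edit_rows) + 1L]] <- data.frame(
          read_id = id, chrom = cl$chrom, pos = ed$pos, sense = cl$sense,
          phred = ed$phred, stringsAsFactors = FALSE)
      sam_lines <- c(sam_lines, paste(
        id, 0L, cl$chrom, cl$start, 255L, paste0(nchar(rd), "M"), "*",
        0L, 0L, rd, phred_to_qualstring(quals[[i]]),
        "NH:i:1", sep = "\t"))
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), chrom = character(0),
               start = integer(0), sense = character(0), n_ag = integer(0),
               n_other = integer(0), verdict = character(0),
               reason = character(0))
  edits <- if (length(edit_rows)) do.call(rbind, edit_rows) else
    data.frame(read_id = character(0), chrom = character(0),
               pos = integer(0), sense = character(0), phred = integer(0))
  sam_path <- NULL
  if (!is.null(sam_out)) {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(index$original),
                        nchar(index$original)))
    writeLines(c(header, sam_lines), sam_out)
    sam_path <- sam_out
  }
  list(clusters = clusters, edits = edits, n_reads = length(reads),
       n_aligned = nrow(clusters),
       n_accepted = sum(clusters$verdict == "accepted"),
       mismatch_spectrum = sort(spectrum, decreasing = TRUE),
       sam_path = sam_path)
}

# Sense-space flanking bases of a plus-strand position: for an antisense
# site the sense-space upstream neighbor is the complement of the
# plus-strand downstream base, and vice versa.
sense_flanks <- function(genome_chr, pos, sense) {
  up_pos <- ifelse(sense == "+", pos - 1L, pos + 1L)
  dn_pos <- ifelse(sense == "+", pos + 1L, pos - 1L)
  n <- nchar(genome_chr)
  ok <- up_pos >= 1 & up_pos <= n & dn_pos >= 1 & dn_pos <= n
  up <- substring(genome_chr, up_pos[ok], up_pos[ok])
  dn <- substring(genome_chr, dn_pos[ok], dn_pos[ok])
  minus <- sense[ok] == "-"
  up[minus] <- comp_base(up[minus])
  dn[minus] <- comp_base(dn[minus])
  list(up = up, down = dn, n_skipped = sum(!ok))
}

#' ADAR neighbor-signature profile of accepted edit sites
#'
#' Bona fide ADAR sites show G depletion at the nucleotide immediately
#' upstream of the edited adenosine and G excess immediately downstream.
#' Frequencies at accepted sites are compared with the background over all
#' genomic adenosines (both strands, sense space).
#'
#' @param edits accepted edit sites ([rescue_hyper_edited()]`$edits`).
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @return list: `site_up`, `site_down`, `bg_up`, `bg_down` (base
#'   frequency vectors summing to 1), `depletion_ratio_upstream_G`,
#'   `enrichment_ratio_downstream_G`, `n_sites`, `n_skipped`.
#' @export
signature_profile <- function(edits, genome) {
  if (nrow(edits) == 0) stop("no accepted edit sites")
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  chrs <- vapply(names(genome), function(n) as.character(genome[[n]]),
                 character(1))
  bases <- c("A", "C", "G", "T")
  freq <- function(x) {
    f <- table(factor(x, levels = bases))
    as.numeric(f) / sum(f)
  }
  up <- character(0); dn <- character(0); skipped <- 0L
  for (ch in unique(edits$chrom)) {
    sel <- edits$chrom == ch
    fl <- sense_flanks(chrs[[ch]], edits$pos[sel], edits$sense[sel])
    up <- c(up, fl$up); dn <- c(dn, fl$down); skipped <- skipped + fl$n_skipped
  }
  bg_up <- character(0); bg_dn <- character(0)
  for (ch in names(chrs)) {
    b <- strsplit(chrs[[ch]], "")[[1]]
    for (sense in c("+", "-")) {
      apos <- which(b == (if (sense == "+") "A" else "T"))
      fl <- sense_flanks(chrs[[ch]], apos, rep(sense, length(apos)))
      bg_up <- c(bg_up, fl$up); bg_dn <- c(bg_dn, fl$down)
    }
  }
  su <- setNames(freq(up), bases); sd_ <- setNames(freq(dn), bases)
  bu <- setNames(freq(bg_up), bases); bd <- setNames(freq(bg_dn), bases)
  list(site_up = su, site_down = sd_, bg_up = bu, bg_down = bd,
       depletion_ratio_upstream_G = su[["G"]] / bu[["G"]],
       enrichment_ratio_downstream_G = sd_[["G"]] / bd[["G"]],
       n_sites = length(up), n_skipped = skipped)
}

#' Hyper-editing rate per million mapped reads
#' @param accepted_reads number of accepted (rescued) reads.
#' @param mapped_reads number of normally mapped reads (> 0).
#' @return list `accepted_reads, mapped_reads, rate`.
#' @export
hyper_rate <- function(accepted_reads, mapped_reads) {
  if (mapped_reads <= 0) stop("mapped_reads must be positive")
  list(accepted_reads = accepted_reads, mapped_reads = mapped_reads,
       rate = accepted_reads * 1e6 / mapped_reads)
}
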