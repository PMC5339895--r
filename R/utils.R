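# Internal helpers: seeded RNG scope, phred codecs, base complement, TSV I/O.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483562L
}

phred_to_qualstring <- function(q) {
  rawToChar(as.raw(q + 33L))
}

qualstring_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV writers carry a comment header (tool version, seed, parameter digest)
# so every artifact is self-describing.
write_tsv <- function(df, path, seed = NULL, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- sprintf("# editomix %s", as.character(utils::packageVersion("editomix")))
  if (!is.null(seed)) hdr <- paste0(hdr, sprintf(" seed=%s", seed))
  if (!is.null(params)) {
    pstr <- paste(names(params), unlist(params), sep = "=", collapse = ";")
    hdr <- paste0(hdr, " params_digest=", substr(digest_string(pstr), 1, 12))
  }
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# Small stable string digest (FNV-1a over bytes, hex) — used only for
# parameter fingerprints in file headers, not for security.
digest_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x%04x", as.integer(h), length(bytes) %% 65536)
}

# Convert a SAM file to a sorted, indexed BAM in tempdir; BAM passes through.
ensure_bam <- function(path) {
  stopifnot(file.exists(path))
  if (tolower(tools::file_ext(path)) == "bam") return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
}

# Read alignments (SAM or BAM) with sequence, quality and the NH tag.
read_alignments <- function(path, which = NULL) {
  bam <- ensure_bam(path)
  p <- if (is.null(which)) {
    Rsamtools::ScanBamParam(what = c("seq", "qual"), tag = "NH")
  } else {
    Rsamtools::ScanBamParam(what = c("seq", "qual"), tag = "NH", which = which)
  }
  GenomicAlignments::readGAlignments(bam, param = p)
}
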