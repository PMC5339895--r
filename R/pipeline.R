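# Orchestration: configuration, stage scheduling, input validation and a
# run manifest.  Stages: simulate -> quant -> hyper -> sine_index ->
# compose; partial subsets are allowed when upstream outputs already
# exist on disk.

#' Bundled demonstration configuration
#'
#' A two-condition cohort emulating the study design: control tissue with
#' a high neuronal fraction, and injured tissue with the neuronal
#' fraction reduced by 20\% plus an immune-cell influx, both simulated
#' from the `"paperlike"` cell-type editomes.
#'
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @param depth reads per site per sample.
#' @param replicates replicates per condition.
#' @return a `run_config` list accepted by [run_pipeline()].
#' @export
paperlike_config <- function(out_dir, seed = 1L, depth = 120L,
                             replicates = 2L) {
  control <- c(neuron = 0.5, astrocyte = 0.2, opc = 0.05,
               new_oligo = 0.05, myel_oligo = 0.1, microglia = 0.05,
               endothelial = 0.05)
  # injury: neuronal fraction down 20%, immune influx, others renormalized
  injured <- c(neuron = 0.4, immune = 0.06,
               0.54 * control[setdiff(names(control), "neuron")] /
                 sum(control[setdiff(names(control), "neuron")]))
  names(injured)[-(1:2)] <- setdiff(names(control), "neuron")
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    genome = list(n_chromosomes = 2L, chrom_length = 30000L,
                  repeat_count = 24L, repeat_length = 200L,
                  repeat_divergence = 0.1, gc_content = 0.42),
    catalog = list(n_background = 16L, panel = "paperlike"),
    editomes = list(profile = "paperlike",
                    cell_types = c(brain_cell_types(), "immune")),
    quant = list(min_phred = 25L, min_coverage = 15L, min_groups = 2L),
    hyper = list(),
    conditions = list(
      control = list(mixture = c(control, immune = 0),
                     group = "control"),
      injured = list(mixture = injured, group = "injured")),
    sample = list(depth = as.integer(depth), read_length = 75L,
                  error_rate = 0.001, repeat_depth = 1.5,
                  hyper_fraction = 0.01, low_qual_fraction = 0.02),
    replicates = as.integer(replicates)),
    class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [paperlike_config()].
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (cn in names(cfg$conditions))
    cfg$conditions[[cn]]$mixture <- unlist(cfg$conditions[[cn]]$mixture)
  structure(cfg, class = "run_config")
}

stage_order <- c("simulate", "quant", "hyper", "sine_index", "compose")

#' Run the pipeline
#'
#' Executes the requested stages in dependency order and writes a JSON
#' manifest recording, per stage, inputs (with content hashes),
#' parameters, outputs and wall-clock times.  Requesting a downstream
#' stage whose upstream outputs are missing raises a dependency error
#' naming the stage.
#'
#' @param config a `run_config` ([paperlike_config()] /
#'   [read_run_config()]).
#' @param stages subset of `c("simulate","quant","hyper","sine_index",
#'   "compose")`; default all.
#' @return list of per-stage outputs, invisibly; manifest at
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, stages = stage_order) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  stages <- stage_order[stage_order %in% stages]
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  seed <- config$seed

  log_line <- function(stage, level, msg) {
    message(sprintf("%s\t%s\t%s\t%s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                    level, msg))
  }
  record <- function(stage, inputs, params, outputs, t0) {
    manifest[[stage]] <<- list(
      inputs = lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
      parameters = params,
      outputs = lapply(outputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
      tool_version = as.character(utils::packageVersion("editomix")),
      seed = seed,
      start = t0, end = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
  }
  need <- function(stage, paths) {
    miss <- paths[!file.exists(paths)]
    if (length(miss))
      stop("dependency error at stage '", stage, "': missing upstream ",
           "output(s): ", paste(miss, collapse = ", "))
  }
  sample_ids <- unlist(lapply(names(config$conditions), function(cn)
    sprintf("%s_r%d", cn, seq_len(config$replicates))))
  sam_path <- function(id) file.path(out_dir, paste0(id, ".sam"))
  fq_path <- function(id) file.path(out_dir, paste0(id, "_unmapped.fastq"))

  if ("simulate" %in% stages) {
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
    log_line("simulate", "INFO", "building genome and cohort")
    spec <- do.call(genome_spec, c(config$genome, list(seed = seed)))
    gen <- build_genome(spec)
    paths <- write_genome_files(gen, out_dir)
    catalog <- do.call(make_site_catalog,
                       c(list(gen = gen), config$catalog,
                         list(seed = derive_seed(seed, "catalog"))))
    cat_path <- file.path(out_dir, "sites.tsv")
    write_site_catalog(catalog, cat_path, seed = seed)
    eds <- make_cell_editomes(catalog,
                              profile = config$editomes$profile %||% "paperlike",
                              cell_types = config$editomes$cell_types %||%
                                brain_cell_types(),
                              seed = derive_seed(seed, "editomes"))
    ed_path <- file.path(out_dir, "editome_truth.tsv")
    write_tsv(data.frame(site_id = rownames(eds$levels), eds$levels,
                         check.names = FALSE), ed_path, seed = seed)
    outs <- character(0)
    for (cn in names(config$conditions)) {
      for (r in seq_len(config$replicates)) {
        id <- sprintf("%s_r%d", cn, r)
        des <- do.call(sample_design, c(
          list(id = id, mixture = config$conditions[[cn]]$mixture),
          config$sample, list(seed = derive_seed(seed, id))))
        sim <- simulate_sample(gen, catalog, eds, des, out_dir)
        results$simulate[[id]] <- sim
        outs <- c(outs, sim$sam, sim$fastq)
      }
    }
    results$gen <- gen; results$catalog <- catalog; results$editomes <- eds
    record("simulate", character(0),
           c(config$genome, config$catalog, list(seed = seed)),
           c(paths[["fasta"]], paths[["bed"]], cat_path, ed_path, outs), t0)
  } else {
    results$catalog <- if (file.exists(file.path(out_dir, "sites.tsv")))
      read_site_catalog(file.path(out_dir, "sites.tsv")) else NULL
  }

  if ("quant" %in% stages) {
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
    need("quant", c(file.path(out_dir, "sites.tsv"),
                    vapply(sample_ids, sam_path, character(1))))
    catalog <- results$catalog %||%
      read_site_catalog(file.path(out_dir, "sites.tsv"))
    qc <- do.call(quant_config, config$quant %||% list())
    counts <- do.call(rbind, lapply(sample_ids, function(id)
      count_site_bases(sam_path(id), catalog, qc, sample_id = id)))
    groups <- setNames(sub("_r\\d+$", "", sample_ids), sample_ids)
    lv <- editing_levels(counts, qc, groups = groups)
    cei <- compute_cei(counts)
    cpath <- file.path(out_dir, "site_counts.tsv")
    lpath <- file.path(out_dir, "editing_levels.tsv")
    kpath <- file.path(out_dir, "cei.tsv")
    write_tsv(counts, cpath, seed = seed, params = unclass(qc))
    write_tsv(lv, lpath, seed = seed, params = unclass(qc))
    write_tsv(cei, kpath, seed = seed, params = unclass(qc))
    results$quant <- list(counts = counts, levels = lv, cei = cei)
    record("quant", c(file.path(out_dir, "sites.tsv"),
                      vapply(sample_ids, sam_path, character(1))),
           unclass(qc), c(cpath, lpath, kpath), t0)
  }

  if ("hyper" %in% stages) {
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
    need("hyper", c(file.path(out_dir, "genome.fa"),
                    vapply(sample_ids, fq_path, character(1))))
    hc <- do.call(hyper_config, config$hyper %||% list())
    index <- build_transformed_index(file.path(out_dir, "genome.fa"),
                                     hc$seed_length)
    outs <- character(0); rates <- list()
    for (id in sample_ids) {
      rs <- rescue_hyper_edited(fq_path(id), index, hc,
                                sam_out = file.path(out_dir,
                                  paste0(id, "_rescued.sam")))
      mapped <- results$simulate[[id]]$n_aligned %||%
        count_sam_records(sam_path(id))
      hr <- hyper_rate(max(rs$n_accepted, 0), mapped)
      rates[[id]] <- data.frame(sample = id,
                                accepted_reads = rs$n_accepted,
                                mapped_reads = mapped, rate = hr$rate)
      results$hyper[[id]] <- rs
      outs <- c(outs, rs$sam_path)
    }
    rate_df <- do.call(rbind, rates); rownames(rate_df) <- NULL
    rpath <- file.path(out_dir, "hyper_rates.tsv")
    write_tsv(rate_df, rpath, seed = seed, params = unclass(hc))
    results$hyper_rates <- rate_df
    record("hyper", vapply(sample_ids, fq_path, character(1)),
           unclass(hc), c(outs, rpath), t0)
  }

  if ("sine_index" %in% stages) {
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
    need("sine_index", c(file.path(out_dir, "genome.fa"),
                         file.path(out_dir, "repeats.bed"),
                         vapply(sample_ids, sam_path, character(1))))
    qc <- do.call(quant_config, config$quant %||% list())
    map <- build_repeat_map(file.path(out_dir, "genome.fa"),
                            file.path(out_dir, "repeats.bed"))
    tabs <- lapply(sample_ids, function(id) {
      rescued <- file.path(out_dir, paste0(id, "_rescued.sam"))
      compute_editing_index(sam_path(id), map, qc,
                            rescued = if (file.exists(rescued) &&
                                          count_sam_records(rescued) > 0)
                              rescued else NULL,
                            sample_id = id)
    })
    rep_report <- index_report(tabs)
    ipath <- file.path(out_dir, "mismatch_indices.tsv")
    spath <- file.path(out_dir, "sine_index_summary.tsv")
    write_tsv(rep_report$long, ipath, seed = seed)
    write_tsv(rep_report$summary, spath, seed = seed)
    results$sine_index <- rep_report
    record("sine_index", vapply(sample_ids, sam_path, character(1)),
           unclass(qc), c(ipath, spath), t0)
  }

  if ("compose" %in% stages) {
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
    need("compose", c(file.path(out_dir, "editing_levels.tsv"),
                      file.path(out_dir, "editome_truth.tsv")))
    lv <- results$quant$levels %||%
      read_tsv(file.path(out_dir, "editing_levels.tsv"))
    mat <- level_matrix(lv)
    conds <- names(config$conditions)
    grp <- sub("_r\\d+$", "", colnames(mat))
    a_cols <- grp == conds[1]; b_cols <- grp == conds[2]
    diff <- differential_editing(mat[, a_cols, drop = FALSE],
                                 mat[, b_cols, drop = FALSE])
    ed_truth <- read_tsv(file.path(out_dir, "editome_truth.tsv"))
    truth_mat <- as.matrix(ed_truth[, -1]); rownames(truth_mat) <- ed_truth$site_id
    cell_a <- truth_mat[, "neuron"]; cell_b <- truth_mat[, "astrocyte"]
    cond_means <- function(cols) rowMeans(mat[, cols, drop = FALSE],
                                          na.rm = TRUE)
    rep_deltas <- NULL
    if (!is.null(results$sine_index)) {
      s <- results$sine_index$summary
      ix <- setNames(s$ag_index, s$sample)
      rep_deltas <- c(cell = NA, condition =
                        mean(ix[grp == conds[2]]) - mean(ix[grp == conds[1]]))
      rep_deltas[1] <- diff_repeat_truth(config)
    }
    corr <- editome_correlation(cell_a, cell_b,
                                setNames(cond_means(a_cols), rownames(mat)),
                                setNames(cond_means(b_cols), rownames(mat)),
                                repeat_deltas = rep_deltas)
    clus <- tryCatch(cluster_editomes(mat), error = function(e) NULL)
    frac <- estimate_fraction_change(
      setNames(cond_means(a_cols), rownames(mat)),
      setNames(cond_means(b_cols), rownames(mat)),
      truth_mat[rownames(mat), intersect(colnames(truth_mat),
        names(config$conditions[[1]]$mixture)), drop = FALSE])
    dpath <- file.path(out_dir, "differential.tsv")
    ppath <- file.path(out_dir, "correlation_points.tsv")
    fpath <- file.path(out_dir, "fraction_change.tsv")
    write_tsv(diff, dpath, seed = seed)
    write_tsv(corr$points, ppath, seed = seed)
    write_tsv(data.frame(t(c(f_pre_neuron = frac$f_pre[["neuron"]],
                             f_post_neuron = frac$f_post[["neuron"]],
                             neuron_delta = frac$neuron_delta,
                             r = corr$r, r_squared = corr$r_squared))),
              fpath, seed = seed)
    outs <- c(dpath, ppath, fpath)
    if (!is.null(clus)) {
      tpath <- file.path(out_dir, "editome_tree.nwk")
      write_tree_newick(clus, tpath)
      outs <- c(outs, tpath)
    }
    results$compose <- list(differential = diff, correlation = corr,
                            clustering = clus, fraction = frac)
    record("compose", c(file.path(out_dir, "editing_levels.tsv")),
           list(), outs, t0)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# True repeat-rate difference (neuron - astrocyte) for the correlation's
# repeat-index point, computed from the preset repeat rates.
diff_repeat_truth <- function(config) {
  eds <- make_cell_editomes(
    data.frame(site_id = "s1", chrom = "chr1", pos = 1, strand = "+",
               gene = "g", conserved = 1L),
    profile = config$editomes$profile %||% "paperlike",
    cell_types = config$editomes$cell_types %||% brain_cell_types(),
    seed = 1L)
  eds$p_repeat[["neuron"]] - eds$p_repeat[["astrocyte"]]
}

count_sam_records <- function(path) {
  sum(!startsWith(readLines(path), "@"))
}

#' Validate pipeline input files
#'
#' Parse and coordinate checks for FASTA, BED, site catalog and SAM
#' inputs; report-only (never throws for content problems).
#'
#' @param fasta,bed,catalog,sam optional paths; omitted inputs are
#'   skipped.
#' @return data.frame `file, line, problem` (zero rows when clean).
#' @export
validate_inputs <- function(fasta = NULL, bed = NULL, catalog = NULL,
                            sam = NULL) {
  probs <- list()
  add <- function(file, line, problem)
    probs[[length(probs) + 1L]] <<- data.frame(
      file = file, line = line, problem = problem, stringsAsFactors = FALSE)
  genome <- NULL
  if (!is.null(fasta)) {
    genome <- tryCatch(readDNAStringSet(fasta), error = function(e) {
      add(fasta, NA_integer_, paste("unparseable FASTA:",
                                    conditionMessage(e)))
      NULL
    })
    if (!is.null(genome)) names(genome) <- sub("\\s.*", "", names(genome))
  }
  if (!is.null(bed)) {
    lines <- readLines(bed)
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) < 3) { add(bed, i, "fewer than 3 BED columns"); next }
      s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e)) add(bed, i, "non-integer BED coordinates")
      else if (e <= s) add(bed, i, "BED end <= start")
      else if (!is.null(genome)) {
        if (!(f[1] %in% names(genome)))
          add(bed, i, paste("chromosome not in genome:", f[1]))
        else if (e > length(genome[[f[1]]]))
          add(bed, i, "interval beyond chromosome end")
      }
      if (length(f) >= 6 && !(f[6] %in% c("+", "-", ".")))
        add(bed, i, paste("invalid strand:", f[6]))
    }
  }
  if (!is.null(catalog)) {
    df <- tryCatch(read_site_catalog(catalog), error = function(e) {
      add(catalog, NA_integer_, conditionMessage(e)); NULL
    })
    if (!is.null(df)) {
      for (i in seq_len(nrow(df))) {
        if (!(df$strand[i] %in% c("+", "-")))
          add(catalog, i, paste("invalid strand:", df$strand[i]))
        if (!is.null(genome)) {
          if (!(df$chrom[i] %in% names(genome)))
            add(catalog, i, paste("chromosome not in genome:", df$chrom[i]))
          else if (df$pos[i] > length(genome[[df$chrom[i]]]) || df$pos[i] < 1)
            add(catalog, i, "site beyond chromosome length")
        }
      }
    }
  }
  if (!is.null(sam)) {
    lines <- readLines(sam)
    if (!any(startsWith(lines, "@SQ")))
      add(sam, NA_integer_, "SAM header lacks @SQ lines")
    body <- which(!startsWith(lines, "@"))
    for (i in head(body, 1000)) {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) < 11) add(sam, i, "fewer than 11 SAM fields")
    }
  }
  if (length(probs) == 0)
    return(data.frame(file = character(0), line = integer(0),
                      problem = character(0)))
  do.call(rbind, probs)
}
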