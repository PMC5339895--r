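# Cell-composition analysis: forward mixing of cell-type editomes,
# neuronal-density change, differential-editing statistics, editome
# correlation and clustering, and inverse estimation of the neuronal
# fraction change.
#
# The forward model: a bulk sample's level at site s is the read-weighted
# average over cell types,
#   level(s) = sum_c f_c w_c(g(s)) L_c(s) / sum_c f_c w_c(g(s)),
# where f_c are cell fractions, w_c expression weights of the host gene
# and L_c(s) the cell-type editing levels.  With uniform weights this is
# the plain convex combination sum_c f_c L_c(s).

#' Validate a cell-type mixture
#' @param ... named fractions, or a single named numeric vector.
#' @return named numeric vector summing to 1.
#' @export
mixture_spec <- function(...) {
  args <- list(...)
  m <- if (length(args) == 1 && is.numeric(args[[1]]) &&
           !is.null(names(args[[1]]))) args[[1]] else unlist(args)
  validate_mixture(m)
}

#' Mix cell-type editomes into a predicted tissue editome
#'
#' @param editomes a `cell_editomes` object, or a sites x types numeric
#'   matrix of measured levels.
#' @param mixture named fraction vector summing to 1.
#' @param weights optional genes x types expression weight matrix; uniform
#'   when `NULL`.
#' @param p_repeat optional named per-type repeat editing rate (taken from
#'   `editomes` when available); the repeat index mixes with read-output
#'   weights, uniform by default.
#' @return a `tissue_editome` list: `levels` (named per-site vector),
#'   `repeat_index`, `mixture`, `provenance`.
#' @export
mix_editomes <- function(editomes, mixture, weights = NULL,
                         p_repeat = NULL) {
  mixture <- validate_mixture(mixture)
  types <- names(mixture)
  if (inherits(editomes, "cell_editomes")) {
    miss <- setdiff(types, colnames(editomes$levels))
    if (length(miss)) stop("no editome for cell type(s): ",
                           paste(miss, collapse = ", "))
    w <- weights %||% editomes$expression
    lv <- mixed_site_levels(editomes, mixture, w)
    names(lv) <- editomes$catalog$site_id
    pr <- p_repeat %||% editomes$p_repeat
  } else {
    lev <- as.matrix(editomes)
    miss <- setdiff(types, colnames(lev))
    if (length(miss)) stop("no editome for cell type(s): ",
                           paste(miss, collapse = ", "))
    if (is.null(weights)) {
      lv <- as.numeric(lev[, types, drop = FALSE] %*% mixture)
    } else {
      lv <- vapply(seq_len(nrow(lev)), function(i) {
        wc <- weights[i, types]
        den <- sum(mixture * wc)
        if (den <= 0) return(NA_real_)
        sum(mixture * wc * lev[i, types]) / den
      }, numeric(1))
    }
    names(lv) <- rownames(lev)
    pr <- p_repeat
  }
  rep_ix <- if (is.null(pr)) NA_real_ else sum(mixture * pr[types])
  structure(list(levels = lv, repeat_index = rep_ix, mixture = mixture,
                 provenance = list(weights = !is.null(weights))),
            class = "tissue_editome")
}

#' Scale the neuronal fraction and renormalize a mixture
#'
#' The neuronal fraction is multiplied by `1 + neuron_delta`; the removed
#' (or added) mass is redistributed over the other cell types in
#' proportion to their base fractions, so the result still sums to 1.
#'
#' @param base named mixture summing to 1.
#' @param neuron_delta relative change of the neuronal fraction (e.g.
#'   `-0.2` for a 20\% reduction).
#' @param neuron_type name of the neuronal component (default
#'   `"neuron"`).
#' @return the new mixture.
#' @export
simulate_density_change <- function(base, neuron_delta,
                                    neuron_type = "neuron") {
  base <- validate_mixture(base)
  if (!(neuron_type %in% names(base)))
    stop("mixture has no '", neuron_type, "' component")
  fn <- base[[neuron_type]] * (1 + neuron_delta)
  if (fn < 0 || fn > 1)
    stop("neuron_delta pushes the neuronal fraction outside [0, 1]")
  others <- setdiff(names(base), neuron_type)
  out <- base
  out[neuron_type] <- fn
  rest <- sum(base[others])
  if (rest > 0) out[others] <- base[others] * (1 - fn) / rest
  validate_mixture(out)
}

#' Per-site differential editing between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) per site: exact by full
#' enumeration when the smaller group has at most 8 replicates and there
#' are no ties, normal approximation with tie correction otherwise.
#' P-values are corrected across tested sites (Benjamini-Hochberg by
#' default).  Deltas are reported in percentage points (levels are
#' fractions in `[0,1]`).
#'
#' @param levels_a,levels_b sites x replicates numeric matrices (shared
#'   rownames = site ids); `NA`s allowed.
#' @param alpha significance level used for the `significant` flag.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return data.frame per tested site: `mean_a, mean_b, delta` (B - A,
#'   percentage points), `p, q, direction, significant`; skipped sites in
#'   `attr(, "skipped")`.
#' @export
differential_editing <- function(levels_a, levels_b, alpha = 0.05,
                                 adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  sites <- intersect(rownames(levels_a), rownames(levels_b))
  rows <- list(); skipped <- list()
  for (s in sites) {
    a <- levels_a[s, ]; b <- levels_b[s, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      skipped[[s]] <- "fewer than 2 replicates in a group"
      next
    }
    p <- mann_whitney_p(a, b)
    rows[[s]] <- data.frame(
      site_id = s, mean_a = mean(a), mean_b = mean(b),
      delta = (mean(b) - mean(a)) * 100, p = p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(site_id = character(0), mean_a = numeric(0),
                      mean_b = numeric(0), delta = numeric(0),
                      p = numeric(0), q = numeric(0),
                      direction = character(0), significant = logical(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = if (adjust == "BH") "BH" else
    "bonferroni")
  out$direction <- ifelse(out$delta > 0, "up",
                          ifelse(out$delta < 0, "down", "none"))
  out$significant <- out$q < alpha
  attr(out, "skipped") <- skipped
  out
}

# Two-sided Mann-Whitney p-value: exact enumeration for small groups
# without ties, normal approximation with tie correction otherwise.
# Identical constant groups give p = 1 by convention.
mann_whitney_p <- function(a, b) {
  if (length(unique(c(a, b))) == 1) return(1)
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && min(length(a), length(b)) <= 8
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}

#' Correlate cell-type editing differences with condition differences
#'
#' Builds the paired per-site deltas `level(type A) - level(type B)` and
#' `level(condition 2) - level(condition 1)`, optionally appends the
#' repeat-index deltas as one extra equally weighted point, and returns
#' the Pearson correlation.  Used to ask whether a condition's editome
#' shift looks like a shift along the neuron/astrocyte axis.
#'
#' @param cell_a,cell_b named per-site level vectors for the two reference
#'   cell types (e.g. neuron, astrocyte).
#' @param cond_1,cond_2 named per-site level vectors for the two
#'   conditions (e.g. control, injured).
#' @param repeat_deltas optional numeric length-2 vector
#'   `c(cell = A - B, condition = 2 - 1)` appended as one point.
#' @return list: `points` (data.frame `site_id, delta_cell,
#'   delta_condition`), `r`, `r_squared`, `n`.
#' @export
editome_correlation <- function(cell_a, cell_b, cond_1, cond_2,
                                repeat_deltas = NULL) {
  sites <- Reduce(intersect, list(names(cell_a), names(cell_b),
                                  names(cond_1), names(cond_2)))
  d_cell <- cell_a[sites] - cell_b[sites]
  d_cond <- cond_2[sites] - cond_1[sites]
  ok <- !is.na(d_cell) & !is.na(d_cond)
  pts <- data.frame(site_id = sites[ok], delta_cell = d_cell[ok],
                    delta_condition = d_cond[ok],
                    stringsAsFactors = FALSE)
  if (!is.null(repeat_deltas))
    pts <- rbind(pts, data.frame(site_id = "repeat_index",
                                 delta_cell = repeat_deltas[[1]],
                                 delta_condition = repeat_deltas[[2]]))
  if (nrow(pts) < 3)
    stop("need at least 3 shared sites with levels in all four inputs")
  if (stats::sd(pts$delta_cell) == 0 || stats::sd(pts$delta_condition) == 0)
    stop("zero variance in a delta vector; correlation undefined")
  r <- cor(pts$delta_cell, pts$delta_condition)
  list(points = pts, r = r, r_squared = r^2, n = nrow(pts))
}

#' Cluster sample editomes by correlation distance
#'
#' Pairwise Pearson correlation over complete-pair site levels, distance
#' `1 - r`, average-linkage hierarchical clustering, and a two-group cut
#' at the tallest merge.  Samples with fewer than 3 usable sites against
#' some other sample are dropped.
#'
#' @param mat sites x samples numeric matrix of editing levels (`NA`s
#'   allowed).
#' @return list: `tree` (hclust), `groups` (named two-group assignment),
#'   `correlation` (sample correlation matrix), `dropped`.
#' @export
cluster_editomes <- function(mat) {
  stopifnot(ncol(mat) >= 3)
  samples <- colnames(mat)
  obs <- !is.na(mat)
  shared <- crossprod(obs)  # pairwise complete-pair counts
  # greedily drop the sample involved in the most deficient pairs until
  # every remaining pair shares at least 3 sites
  usable <- setNames(rep(TRUE, length(samples)), samples)
  repeat {
    idx <- which(usable)
    bad <- shared[idx, idx, drop = FALSE] < 3
    diag(bad) <- FALSE
    if (!any(bad)) break
    usable[names(which.max(rowSums(bad)))] <- FALSE
  }
  dropped <- samples[!usable]
  if (length(dropped))
    message("dropped sample(s) with < 3 shared sites: ",
            paste(dropped, collapse = ", "))
  m <- mat[, usable, drop = FALSE]
  if (ncol(m) < 3) stop("fewer than 3 usable samples")
  cm <- cor(m, use = "pairwise.complete.obs")
  d <- as.dist(1 - cm)
  tree <- hclust(d, method = "average")
  groups <- cutree(tree, k = 2)
  list(tree = tree, groups = groups, correlation = cm, dropped = dropped)
}

#' Export a cluster tree as Newick
#' @param clust result of [cluster_editomes()] (or an hclust).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tree_newick <- function(clust, path) {
  tree <- if (inherits(clust, "hclust")) clust else clust$tree
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Invert the mixing model: estimate the neuronal-fraction change
#'
#' For each condition, fits cell fractions by least squares on the mixing
#' equation over sites subject to `sum(f) = 1`:
#' `sum_c f_c w_c(g_s) (L_c(s) - y_s) = 0` for all sites s, which with
#' uniform weights reduces to ordinary constrained least squares of the
#' tissue levels on the cell editomes.  Returns the fitted neuronal
#' fractions and their relative change.
#'
#' @param tissue_pre,tissue_post named per-site level vectors for the two
#'   conditions.
#' @param editomes `cell_editomes` (or sites x types matrix with rownames
#'   matching the tissue vectors).
#' @param weights optional genes x types (for `cell_editomes`) expression
#'   weights.
#' @param neuron_type name of the neuronal component.
#' @return list: `f_pre`, `f_post` (named fitted fractions),
#'   `neuron_delta` (relative change), `residual_pre`, `residual_post`,
#'   `ill_conditioned`.
#' @export
estimate_fraction_change <- function(tissue_pre, tissue_post, editomes,
                                     weights = NULL,
                                     neuron_type = "neuron") {
  if (inherits(editomes, "cell_editomes")) {
    lev <- editomes$levels
    gene_of <- setNames(editomes$catalog$gene, editomes$catalog$site_id)
    w_of <- function(s) {
      w <- weights %||% editomes$expression
      w[gene_of[[s]], colnames(lev)]
    }
  } else {
    lev <- as.matrix(editomes)
    w_of <- function(s) setNames(rep(1, ncol(lev)), colnames(lev))
  }
  fit_one <- function(y) {
    sites <- intersect(names(y)[!is.na(y)], rownames(lev))
    B <- t(vapply(sites, function(s)
      w_of(s) * (lev[s, ] - y[[s]]), numeric(ncol(lev))))
    # minimize ||B f|| s.t. sum(f) = 1 via f = e_K + Z g
    K <- ncol(B)
    Z <- rbind(diag(K - 1), rep(-1, K - 1))
    A <- B %*% Z
    rhs <- -B[, K]
    sv <- svd(A)
    cond_bad <- length(sv$d) == 0 || max(sv$d) == 0 ||
      min(sv$d) < 1e-8 * max(sv$d)
    if (cond_bad)
      return(list(f = setNames(rep(NA_real_, K), colnames(lev)),
                  residual = NA_real_, bad = TRUE))
    g <- sv$v %*% ((t(sv$u) %*% rhs) / sv$d)
    f <- as.numeric(Z %*% g); f[K] <- f[K] + 1
    names(f) <- colnames(lev)
    list(f = f, residual = sqrt(sum((B %*% f)^2) / nrow(B)), bad = FALSE)
  }
  pre <- fit_one(tissue_pre); post <- fit_one(tissue_post)
  bad <- pre$bad || post$bad
  if (bad)
    return(list(f_pre = pre$f, f_post = post$f, neuron_delta = NA_real_,
                residual_pre = pre$residual, residual_post = post$residual,
                ill_conditioned = TRUE))
  nd <- (post$f[[neuron_type]] - pre$f[[neuron_type]]) / pre$f[[neuron_type]]
  list(f_pre = pre$f, f_post = post$f, neuron_delta = nd,
       residual_pre = pre$residual, residual_post = post$residual,
       ill_conditioned = FALSE)
}
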