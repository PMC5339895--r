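# Cell-type editome generator: per-cell-type editing levels at catalog
# sites, a per-type repeat editing rate, and per-gene expression weights.

#' Brain cell types modelled by the default editome presets
#' @return character vector of cell-type names.
#' @export
brain_cell_types <- function() {
  c("neuron", "astrocyte", "opc", "new_oligo", "myel_oligo",
    "microglia", "endothelial")
}

#' Generate ground-truth cell-type editomes
#'
#' Presets encode the canonical brain pattern: neurons carry the highest
#' editing level at most sites, oligodendrocyte precursors (OPCs) rank
#' second, and a minority of sites (the COPA/COG3 class) are edited more in
#' astrocytes/endothelium than in neurons.
#'
#' \describe{
#'   \item{`"table2"`}{the six in-vitro measured recoding sites with their
#'     printed neuron/astrocyte levels; other cell types interpolated.}
#'   \item{`"paperlike"`}{the eight-site injury panel (six neuron-high, two
#'     astrocyte-high) plus randomized background sites; neurons strictly
#'     highest at >= 80\% of sites.}
#' }
#'
#' @param catalog site catalog ([make_site_catalog()]).
#' @param profile `"paperlike"`, `"table2"`, or a numeric matrix of explicit
#'   rates (sites x cell types, values in `[0,1]`) passed through unchanged.
#' @param cell_types cell types to model (ignored when `profile` is a
#'   matrix).
#' @param seed integer seed for the randomized background levels.
#' @return object of class `cell_editomes`: list with `levels` (sites x
#'   types matrix, rownames = site_id), `p_repeat` (named per-type repeat
#'   editing rate), `expression` (genes x types weight matrix, FPKM-like),
#'   `catalog`.
#' @export
make_cell_editomes <- function(catalog, profile = "paperlike",
                               cell_types = brain_cell_types(),
                               seed = 1L) {
  stopifnot(nrow(catalog) >= 1)
  if (is.matrix(profile)) {
    if (any(profile < 0 | profile > 1))
      stop("explicit editing rates must lie in [0, 1]")
    if (nrow(profile) != nrow(catalog))
      stop("explicit rate matrix must have one row per catalog site")
    lev <- profile
    rownames(lev) <- catalog$site_id
    return(finish_editomes(lev, catalog, seed))
  }
  profile <- match.arg(profile, c("paperlike", "table2"))
  panel <- panel_sites(if (profile == "table2") "table2" else "paperlike")
  # non-neuron interpolation factors relative to the shared non-neuron
  # baseline at neuron-high sites (OPC highest among them, immune lowest)
  fac <- c(opc = 1.3, astrocyte = 1.0, new_oligo = 0.8, myel_oligo = 0.7,
           microglia = 0.4, endothelial = 0.5, immune = 0.2)
  lev <- matrix(NA_real_, nrow(catalog), length(cell_types),
                dimnames = list(catalog$site_id, cell_types))
  with_seed(seed, {
    bg <- which(!(catalog$gene %in% panel$gene))
    # designated minority class: a fixed 10% of background sites are
    # astrocyte/endothelial-high (the COPA/COG3 pattern)
    astro_high_bg <- if (length(bg)) sample(bg, floor(0.1 * length(bg)))
      else integer(0)
    for (i in seq_len(nrow(catalog))) {
      g <- catalog$gene[i]
      j <- match(g, panel$gene)
      if (!is.na(j)) {
        nv <- panel$neuron[j]; av <- panel$astrocyte[j]
        astro_high <- av > nv
        for (ct in cell_types) {
          lev[i, ct] <- if (ct == "neuron") nv
          else if (ct == "astrocyte") av
          else if (astro_high) {
            # COPA/COG3 class: glial/vascular types track the astrocyte level
            base <- if (ct %in% c("endothelial", "microglia")) av else
              nv + (av - nv) * 0.5
            clamp01(base * runif(1, 0.8, 1.1))
          } else clamp01(av * (fac[[ct]] %||% 0.5) * runif(1, 0.8, 1.2))
        }
      } else {
        astro_high <- i %in% astro_high_bg
        if (astro_high) {
          av <- runif(1, 0.3, 0.8); nv <- av * runif(1, 0.05, 0.2)
          for (ct in cell_types) {
            lev[i, ct] <- if (ct == "neuron") nv
            else if (ct %in% c("astrocyte", "endothelial")) av * runif(1, 0.9, 1.05)
            else clamp01(av * runif(1, 0.3, 0.7))
          }
        } else {
          # neuron-high site: the non-neuron types share a common low
          # baseline drawn independently of the neuron level, so neuron
          # and non-neuron editome profiles decorrelate across sites
          # while non-neuron types stay mutually correlated
          nv <- runif(1, 0.3, 0.9)
          b <- runif(1, 0.02, 0.22)
          for (ct in cell_types)
            lev[i, ct] <- if (ct == "neuron") nv else
              clamp01(b * (fac[[ct]] %||% 0.5) * runif(1, 0.85, 1.15))
        }
      }
    }
  })
  finish_editomes(lev, catalog, seed)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

finish_editomes <- function(lev, catalog, seed) {
  cell_types <- colnames(lev)
  # global repeat editing rate per type: neurons highest, tracking the
  # cross-type ranking of the SINE index
  base_rep <- c(neuron = 0.020, opc = 0.012, astrocyte = 0.008,
                new_oligo = 0.006, myel_oligo = 0.006, microglia = 0.004,
                endothelial = 0.004, immune = 0.002)
  p_repeat <- vapply(cell_types, function(ct) base_rep[[ct]] %||% 0.005,
                     numeric(1))
  genes <- unique(catalog$gene)
  expression <- matrix(1, length(genes), length(cell_types),
                       dimnames = list(genes, cell_types))
  structure(list(levels = lev, p_repeat = p_repeat,
                 expression = expression, catalog = catalog, seed = seed),
            class = "cell_editomes")
}

#' @export
print.cell_editomes <- function(x, ...) {
  cat("cell_editomes:", nrow(x$levels), "sites x", ncol(x$levels),
      "cell types\n")
  cat("  types:", paste(colnames(x$levels), collapse = ", "), "\n")
  cat("  repeat rates:",
      paste(sprintf("%s=%.3f", names(x$p_repeat), x$p_repeat),
            collapse = " "), "\n")
  invisible(x)
}

#' Fraction of sites where one cell type is strictly highest
#' @param editomes a `cell_editomes` object.
#' @param cell_type cell type to test (default `"neuron"`).
#' @return fraction in `[0,1]`.
#' @export
fraction_type_highest <- function(editomes, cell_type = "neuron") {
  lev <- editomes$levels
  other <- lev[, setdiff(colnames(lev), cell_type), drop = FALSE]
  mean(lev[, cell_type] > apply(other, 1, max))
}
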