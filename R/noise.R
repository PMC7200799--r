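#' Expressed-gene mask for the noise statistic
#'
#' Non-ERCC genes expressed (count >= 1) in at least `min_cells` cells of
#' the given cell type. This is the coordinate set on which biological
#' distances are measured.
#'
#' @param x a [umi_experiment()].
#' @param cell_type cell type name (matched against `cells$cell_type`).
#' @param min_cells minimum expressing cells (default 3).
#' @return Character vector of gene identifiers.
#' @export
expressed_gene_mask <- function(x, cell_type, min_cells = 3L) {
  stopifnot(inherits(x, "umi_experiment"))
  ci <- which(x$cells$cell_type == cell_type)
  if (length(ci) < min_cells)
    stop("cell type `", cell_type, "` has fewer than ", min_cells, " cells")
  expressed <- rowSums(x$counts[, ci, drop = FALSE] >= 1L) >= min_cells
  x$genes$gene_id[expressed & !x$genes$is_ercc]
}

#' Mean expression vector of one cell type within one monkey
#'
#' The biological reference the noise statistic measures distances against:
#' the per-gene arithmetic mean of (log-normalized) expression over one
#' monkey's cells of one type, restricted to a gene mask.
#'
#' @param x a [umi_experiment()].
#' @param cell_type,monkey group selectors.
#' @param genes gene mask (default: [expressed_gene_mask()] of the type).
#' @param scale `"lognorm"` or `"raw"`.
#' @return Named numeric vector (one mean per masked gene).
#' @export
celltype_monkey_mean <- function(x, cell_type, monkey, genes = NULL,
                                 scale = c("lognorm", "raw")) {
  scale <- match.arg(scale)
  genes <- genes %||% expressed_gene_mask(x, cell_type)
  ci <- which(x$cells$cell_type == cell_type & x$cells$monkey == monkey)
  if (length(ci) == 0) {
    warning("no cells for cell type `", cell_type, "` in monkey `", monkey, "`")
    return(NULL)
  }
  expr <- if (scale == "lognorm") {
    if (is.null(x$logcounts)) stop("run log_normalize() first")
    x$logcounts
  } else {
    x$counts
  }
  rowMeans(expr[match(genes, x$genes$gene_id), ci, drop = FALSE])
}

# same rule on ERCC rows: spike-ins detected in >= min_cells cells of the type
ercc_gene_mask <- function(x, cell_type, min_cells = 3L) {
  ci <- which(x$cells$cell_type == cell_type)
  expressed <- rowSums(x$counts[, ci, drop = FALSE] >= 1L) >= min_cells
  x$genes$gene_id[expressed & x$genes$is_ercc]
}

#' Distance-based noise for one cell against its group references
#'
#' The elementary noise computation: biological Euclidean distance of the
#' cell to its group mean, technical Euclidean distance of the cell's ERCC
#' vector to the group ERCC mean, and their ratio. A zero technical distance
#' makes the ratio undefined; the record is flagged and excluded from group
#' comparisons.
#'
#' @param cell_expr,mean_expr numeric vectors on the biological gene mask.
#' @param cell_ercc,ercc_mean numeric vectors on the ERCC mask.
#' @return List: bio_distance, tech_distance, noise_ratio, flagged.
#' @export
noise_ratio <- function(cell_expr, mean_expr, cell_ercc, ercc_mean) {
  stopifnot(length(cell_expr) == length(mean_expr),
            length(cell_ercc) == length(ercc_mean))
  bio <- sqrt(sum((cell_expr - mean_expr)^2))
  tech <- sqrt(sum((cell_ercc - ercc_mean)^2))
  list(bio_distance = bio, tech_distance = tech,
       noise_ratio = if (tech > 0) bio / tech else NA_real_,
       flagged = tech == 0)
}

#' Per-cell transcriptional noise, ERCC-calibrated
#'
#' For every cell: the Euclidean distance to the mean expression vector of
#' its cell type within its monkey (biological variation), divided by the
#' Euclidean distance of its ERCC vector to the same group's ERCC mean
#' (technical variation). Distances are computed on log-normalized
#' expression by default (`scale = "raw"` uses raw counts), restricted to
#' genes expressed in at least three cells of the cell type; the ERCC mask
#' applies the same detection rule to spike-in rows.
#'
#' @param x a [umi_experiment()]; log-normalized unless `scale = "raw"`.
#' @param scale `"lognorm"` (default) or `"raw"`.
#' @param hvg optional character vector restricting the biological mask to
#'   highly variable genes (default NULL: expressed-gene mask only).
#' @param sqrt_dim_norm divide each distance by the square root of its mask
#'   size, removing the dimension dependence of the two distances (default
#'   FALSE: the plain ratio).
#' @param min_cells detection-mask support (default 3); cell types with
#'   fewer cells error in [expressed_gene_mask()].
#' @return Tibble of class `vasc_noise`: cell_id, cell_type, monkey,
#'   age_group, bio_distance, tech_distance, noise_ratio, flagged.
#' @export
transcriptional_noise <- function(x, scale = c("lognorm", "raw"), hvg = NULL,
                                  sqrt_dim_norm = FALSE, min_cells = 3L) {
  stopifnot(inherits(x, "umi_experiment"))
  scale <- match.arg(scale)
  for (key in c("cell_type", "monkey", "age_group"))
    if (!key %in% names(x$cells)) stop("missing metadata column `", key, "`")
  expr <- if (scale == "lognorm") {
    if (is.null(x$logcounts)) stop("run log_normalize() first (or use scale = \"raw\")")
    x$logcounts
  } else {
    x$counts
  }
  res <- purrr::map_dfr(sort(unique(x$cells$cell_type)), function(ct) {
    mask <- expressed_gene_mask(x, ct, min_cells = min_cells)
    if (!is.null(hvg)) mask <- intersect(mask, hvg)
    emask <- ercc_gene_mask(x, ct, min_cells = min_cells)
    if (length(emask) < 2) {
      warning("cell type `", ct, "`: fewer than two detected ERCC rows; skipped")
      return(NULL)
    }
    gi <- match(mask, x$genes$gene_id)
    ei <- match(emask, x$genes$gene_id)
    purrr::map_dfr(unique(x$cells$monkey[x$cells$cell_type == ct]), function(mk) {
      ci <- which(x$cells$cell_type == ct & x$cells$monkey == mk)
      if (length(ci) == 0) return(NULL)
      sub <- expr[gi, ci, drop = FALSE]
      esub <- expr[ei, ci, drop = FALSE]
      mu <- rowMeans(sub)
      emu <- rowMeans(esub)
      bio <- sqrt(colSums((sub - mu)^2))
      tech <- sqrt(colSums((esub - emu)^2))
      if (sqrt_dim_norm) {
        bio <- bio / sqrt(length(gi))
        tech <- tech / sqrt(length(ei))
      }
      tibble::tibble(
        cell_id = x$cells$cell_id[ci], cell_type = ct, monkey = mk,
        age_group = x$cells$age_group[ci],
        bio_distance = bio, tech_distance = tech,
        noise_ratio = ifelse(tech > 0, bio / tech, NA_real_),
        flagged = tech == 0)
    })
  })
  structure(res, class = c("vasc_noise", class(res)), scale = scale)
}

#' Old-versus-young noise comparison per cell type
#'
#' Group medians of the noise ratio and a two-sided Wilcoxon rank-sum test
#' per cell type. Flagged records (zero technical distance) are excluded;
#' cell types lacking `min_cells` unflagged cells in either age group are
#' skipped with a warning.
#'
#' @param records a [transcriptional_noise()] table.
#' @param min_cells minimum unflagged cells per age group (default 3).
#' @return Tibble: cell_type, median_old, median_young, ratio_old_young,
#'   n_old, n_young, p_value.
#' @export
compare_noise <- function(records, min_cells = 3L) {
  records <- dplyr::filter(tibble::as_tibble(records), !.data$flagged)
  purrr::map_dfr(sort(unique(records$cell_type)), function(ct) {
    r <- records[records$cell_type == ct, ]
    old <- r$noise_ratio[r$age_group == "old"]
    young <- r$noise_ratio[r$age_group == "young"]
    if (length(old) < min_cells || length(young) < min_cells) {
      warning("cell type `", ct, "`: fewer than ", min_cells,
              " cells in one age group; skipped")
      return(NULL)
    }
    tibble::tibble(
      cell_type = ct,
      median_old = stats::median(old), median_young = stats::median(young),
      ratio_old_young = stats::median(old) / stats::median(young),
      n_old = length(old), n_young = length(young),
      p_value = wilcoxon_test(old, young))
  })
}
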