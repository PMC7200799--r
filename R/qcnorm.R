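#' Cell-level quality-control thresholds
#'
#' Two presets mirror the emulated study's pipelines. `"strt"` keeps cells
#' with 1000-10,000 detected genes (inclusive), strictly more than 3000
#' UMIs, mapping ratio strictly above 10%, and 1e4-3e6 aligned reads
#' (inclusive). `"tenx"` keeps cells with strictly more than 2000 detected
#' genes and mitochondrial fraction strictly below 0.15. Detected genes and
#' UMI totals are counted on non-ERCC rows (spike-ins are not cellular
#' transcripts).
#'
#' @param preset `"strt"` or `"tenx"`.
#' @param ... named overrides of individual thresholds (`min_genes`,
#'   `max_genes`, `min_umi`, `min_mapping_ratio`, `min_aligned`,
#'   `max_aligned`, `max_mito`).
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(preset = c("strt", "tenx"), ...) {
  preset <- match.arg(preset)
  t <- switch(preset,
    strt = list(preset = "strt", min_genes = 1000L, max_genes = 10000L,
                min_umi = 3000L, min_mapping_ratio = 0.10,
                min_aligned = 1e4, max_aligned = 3e6),
    tenx = list(preset = "tenx", min_genes = 2000L, max_genes = Inf,
                max_mito = 0.15)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(t))
  if (length(bad) > 0) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  t[names(over)] <- over
  if (t$min_genes > t$max_genes) stop("min_genes exceeds max_genes")
  structure(t, class = "qc_thresholds")
}

#' Filter cells on QC predicates
#'
#' Applies the preset's per-cell predicates and returns both the kept
#' experiment and a long-format report with every predicate's value and
#' outcome for every cell, so each failure is attributable.
#'
#' @param x a [umi_experiment()].
#' @param thresholds a [qc_thresholds()].
#' @return List: `experiment` (kept cells), `report` (tibble: cell_id,
#'   predicate, value, pass).
#' @export
filter_cells <- function(x, thresholds = qc_thresholds("strt")) {
  stopifnot(inherits(x, "umi_experiment"), inherits(thresholds, "qc_thresholds"))
  t <- thresholds
  bio <- x$counts[!x$genes$is_ercc, , drop = FALSE]
  detected <- colSums(bio >= 1L)
  umi <- colSums(bio)
  checks <- list(
    genes_min = tibble::tibble(value = as.numeric(detected), pass = detected >= t$min_genes),
    genes_max = tibble::tibble(value = as.numeric(detected), pass = detected <= t$max_genes)
  )
  if (t$preset == "strt") {
    for (fld in c("mapping_ratio", "aligned_reads"))
      if (!fld %in% names(x$cells))
        stop("STRT preset requires cell metadata column `", fld, "`")
    checks$umi <- tibble::tibble(value = as.numeric(umi), pass = umi > t$min_umi)
    checks$mapping_ratio <- tibble::tibble(
      value = x$cells$mapping_ratio, pass = x$cells$mapping_ratio > t$min_mapping_ratio)
    checks$aligned_reads <- tibble::tibble(
      value = as.numeric(x$cells$aligned_reads),
      pass = x$cells$aligned_reads >= t$min_aligned &
             x$cells$aligned_reads <= t$max_aligned)
  } else {
    if (!"is_mito" %in% names(x$genes))
      stop("10x preset requires a gene `is_mito` flag")
    mito <- colSums(x$counts[x$genes$is_mito & !x$genes$is_ercc, , drop = FALSE]) /
      pmax(umi, 1)
    checks$genes_min$pass <- detected > t$min_genes  # strictly over 2000
    checks$mito <- tibble::tibble(value = mito, pass = mito < t$max_mito)
  }
  report <- purrr::imap_dfr(checks, function(d, nm)
    tibble::tibble(cell_id = x$cells$cell_id, predicate = nm,
                   value = d$value, pass = d$pass))
  keep <- report |>
    dplyr::summarise(ok = all(.data$pass), .by = "cell_id") |>
    dplyr::filter(.data$ok) |>
    dplyr::pull("cell_id")
  list(experiment = subset_experiment(x, cells = keep), report = report)
}

#' Filter genes on detection support
#'
#' Keeps genes with more than one transcript count (count >= 2) in at least
#' three cells. ERCC rows are exempt and always retained: the noise module
#' needs them regardless of biological detection support.
#'
#' @param x a [umi_experiment()].
#' @param min_count,min_cells detection rule (defaults: count >= 2 in >= 3
#'   cells).
#' @return The filtered [umi_experiment()].
#' @export
filter_genes <- function(x, min_count = 2L, min_cells = 3L) {
  stopifnot(inherits(x, "umi_experiment"))
  support <- rowSums(x$counts >= min_count)
  keep <- support >= min_cells | x$genes$is_ercc
  subset_experiment(x, genes = x$genes$gene_id[keep])
}

#' Log-normalize UMI counts
#'
#' Per-cell global scaling: `x[g,c] = ln(count[g,c] * scale / total[c] + 1)`
#' with `total[c]` the cell's UMI total over non-ERCC genes (scale 1e5 for
#' the STRT protocol, 1e4 for 10x). ERCC rows are normalized with the same
#' per-cell factor, so spike-ins stay on the cellular scale.
#'
#' @param x a [umi_experiment()].
#' @param scale scale factor (default 1e5).
#' @return The experiment with a `logcounts` matrix filled in.
#' @export
log_normalize <- function(x, scale = 1e5) {
  stopifnot(inherits(x, "umi_experiment"))
  totals <- colSums(x$counts[!x$genes$is_ercc, , drop = FALSE])
  if (any(totals == 0))
    stop("zero-total cell(s): ",
         paste(x$cells$cell_id[totals == 0], collapse = ", "))
  x$logcounts <- log1p(sweep(x$counts, 2, scale / totals, "*"))
  x
}

#' Per-gene mean-dispersion fit
#'
#' Empirical dispersion per gene is the method-of-moments negative-binomial
#' estimate on raw counts, `(variance - mean) / mean^2`, floored at 0. The
#' fitted dispersion is a smooth trend of log dispersion against log10 mean
#' (loess), evaluated per gene. Genes with zero mean are excluded; genes
#' whose empirical dispersion is 0 get the trend value only.
#'
#' @param x a [umi_experiment()] (raw counts are used).
#' @param span loess span for the trend (default 0.3).
#' @param use_ercc include ERCC rows in the table (default FALSE).
#' @return Tibble: gene_id, mean, dispersion_empirical, dispersion_fit.
#' @export
fit_dispersion <- function(x, span = 0.3, use_ercc = FALSE) {
  stopifnot(inherits(x, "umi_experiment"))
  m <- x$counts
  if (!use_ercc) m <- m[!x$genes$is_ercc, , drop = FALSE]
  if (nrow(m) < 20) stop("dispersion fit needs at least 20 genes")
  mu <- unname(rowMeans(m))
  v <- unname(apply(m, 1, stats::var))
  tab <- tibble::tibble(
    gene_id = rownames(m), mean = mu,
    dispersion_empirical = pmax((v - mu) / mu^2, 0)
  ) |>
    dplyr::filter(.data$mean > 0)
  fitdat <- dplyr::filter(tab, .data$dispersion_empirical > 0)
  if (nrow(fitdat) < 10) stop("too few overdispersed genes to fit a trend")
  fit <- stats::loess(log(dispersion_empirical) ~ log10(mean), data = fitdat,
                      span = span, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  tab$dispersion_fit <- exp(stats::predict(fit, newdata = tab))
  tab
}

#' Select highly variable genes
#'
#' A gene is highly variable iff its empirical dispersion exceeds `factor`
#' times its fitted dispersion (default factor 3).
#'
#' @param dispersion output of [fit_dispersion()].
#' @param factor multiplier on the fitted trend (default 3).
#' @return Character vector of HVG gene identifiers.
#' @export
select_hvg <- function(dispersion, factor = 3) {
  stopifnot(all(c("gene_id", "dispersion_empirical", "dispersion_fit") %in%
                  names(dispersion)))
  dispersion$gene_id[
    !is.na(dispersion$dispersion_fit) &
      dispersion$dispersion_empirical > factor * dispersion$dispersion_fit
  ]
}
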