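#' Two-sided Wilcoxon rank-sum test
#'
#' The workhorse test of the old-versus-young comparisons. Uses the exact
#' null distribution when both groups have at most 8 observations and there
#' are no ties; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y numeric vectors for the two groups (both non-empty).
#' @return Two-sided p-value.
#' @export
wilcoxon_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U of x
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n <= 8 && m <= 8) {
    p <- if (u > n * m / 2) {
      2 * (1 - stats::pwilcox(u - 1, n, m))
    } else {
      2 * stats::pwilcox(u, n, m)
    }
    return(min(1, p))
  }
  N <- n + m
  tie_tab <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 == 0) return(1)
  z <- (abs(u - n * m / 2) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Average log fold change between groups
#'
#' Computed on log-normalized expression the way single-cell DE reports it:
#' de-log each group (`expm1`), average, re-log (`log1p`) and difference.
#' Natural log by default; `base = "log2"` reports the same quantity in log2
#' units (the DEG threshold then applies on whichever base is configured).
#'
#' @param x,y log-normalized expression for the two groups (x minus y).
#' @param base `"natural"` or `"log2"`.
#' @return Signed average log fold change.
#' @export
avg_log_fc <- function(x, y, base = c("natural", "log2")) {
  base <- match.arg(base)
  lfc <- log1p(mean(expm1(x))) - log1p(mean(expm1(y)))
  if (base == "log2") lfc / log(2) else lfc
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with `m` the number of genes tested in the cell type.
#'
#' @param p p-value(s).
#' @param m family size.
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1)
  stats::p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}

#' Old-versus-young differential expression per cell type
#'
#' Within each cell type, every gene passing the detection filter (count
#' >= 2 in >= 3 of that type's cells, ERCC excluded) is tested old vs young
#' with [wilcoxon_test()] on log-normalized expression; the Bonferroni
#' family size is the number of genes tested in that cell type. Groups with
#' fewer than `min_cells` cells yield skipped records rather than errors.
#'
#' @param x a log-normalized [umi_experiment()] with `age_group` and
#'   `cell_type` metadata.
#' @param group_key,celltype_key metadata columns holding the age group
#'   (levels `"young"`/`"old"`) and the cell type.
#' @param base log base for the fold change, see [avg_log_fc()].
#' @param min_cells minimum cells per group (default 3).
#' @return Tibble of class `vasc_deg`: gene, cell_type, avg_logFC (old minus
#'   young), p_value, p_adj, direction, n_old, n_young, skipped. The log
#'   base is recorded in attribute `lfc_base`.
#' @export
age_de_test <- function(x, group_key = "age_group", celltype_key = "cell_type",
                        base = c("natural", "log2"), min_cells = 3L) {
  stopifnot(inherits(x, "umi_experiment"))
  base <- match.arg(base)
  if (is.null(x$logcounts)) stop("run log_normalize() first")
  for (key in c(group_key, celltype_key))
    if (!key %in% names(x$cells)) stop("missing metadata column `", key, "`")
  grp <- x$cells[[group_key]]
  ctv <- x$cells[[celltype_key]]
  res <- purrr::map_dfr(sort(unique(ctv)), function(ct) {
    ci <- which(ctv == ct)
    sub_counts <- x$counts[, ci, drop = FALSE]
    testable <- !x$genes$is_ercc & rowSums(sub_counts >= 2L) >= 3L
    genes <- x$genes$gene_id[testable]
    m <- length(genes)
    oi <- ci[grp[ci] == "old"]; yi <- ci[grp[ci] == "young"]
    if (length(oi) < min_cells || length(yi) < min_cells || m == 0) {
      return(tibble::tibble(
        gene = genes, cell_type = ct, avg_logFC = NA_real_,
        p_value = NA_real_, p_adj = NA_real_, direction = NA_character_,
        n_old = length(oi), n_young = length(yi), skipped = TRUE))
    }
    lo <- x$logcounts[testable, oi, drop = FALSE]
    ly <- x$logcounts[testable, yi, drop = FALSE]
    p <- vapply(seq_len(m), function(i) wilcoxon_test(lo[i, ], ly[i, ]),
                numeric(1))
    lfc <- vapply(seq_len(m), function(i) avg_log_fc(lo[i, ], ly[i, ], base = base),
                  numeric(1))
    tibble::tibble(
      gene = genes, cell_type = ct, avg_logFC = lfc, p_value = p,
      p_adj = bonferroni_adjust(p, m),
      direction = ifelse(lfc >= 0, "up", "down"),
      n_old = length(oi), n_young = length(yi), skipped = FALSE)
  })
  structure(res, class = c("vasc_deg", class(res)), lfc_base = base)
}

#' Call differentially expressed genes at the study thresholds
#'
#' A gene is an old/young DEG iff `|avg_logFC| >= lfc_threshold` and
#' `p_adj <= alpha` (both boundaries inclusive). Relaxing either threshold
#' never removes a called gene.
#'
#' @param records a [age_de_test()] table.
#' @param lfc_threshold fold-change cutoff (default 0.5, applied on the base
#'   the records were computed in).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return The called subset, same columns, class `vasc_deg`.
#' @export
call_degs <- function(records, lfc_threshold = 0.5, alpha = 0.05) {
  out <- dplyr::filter(records, !.data$skipped,
                       abs(.data$avg_logFC) >= lfc_threshold,
                       .data$p_adj <= alpha)
  structure(out, class = c("vasc_deg", class(tibble::tibble())),
            lfc_base = attr(records, "lfc_base"))
}

#' Cross-cell-type DEG sharing summary
#'
#' Summarises how called DEGs distribute across cell types: per-type up/down
#' counts, genes shared by at least two cell types, genes unique to one
#' type, and direction-stratified pairwise intersections (up with up, down
#' with down).
#'
#' @param degs a called DEG table ([call_degs()]).
#' @return List of class `vasc_deg_summary`: `per_type`, `membership`,
#'   `shared_genes`, `unique_sets`, `shared_fraction`, `pairwise`.
#' @export
shared_deg_summary <- function(degs) {
  degs <- tibble::as_tibble(degs)
  types <- sort(unique(degs$cell_type))
  if (length(types) < 2) stop("need DEG calls from at least two cell types")
  per_type <- degs |>
    dplyr::count(.data$cell_type, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (d in c("up", "down")) if (!d %in% names(per_type)) per_type[[d]] <- 0L
  membership <- degs |>
    dplyr::distinct(.data$gene, .data$cell_type) |>
    dplyr::count(.data$gene, name = "n_types")
  shared_genes <- membership$gene[membership$n_types >= 2]
  unique_sets <- degs |>
    dplyr::filter(.data$gene %in% membership$gene[membership$n_types == 1]) |>
    dplyr::distinct(.data$gene, .data$cell_type)
  unique_sets <- split(unique_sets$gene, unique_sets$cell_type)
  pairs <- t(utils::combn(types, 2))
  pairwise <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    purrr::map_dfr(c("up", "down"), function(d) {
      a <- degs$gene[degs$cell_type == pairs[i, 1] & degs$direction == d]
      b <- degs$gene[degs$cell_type == pairs[i, 2] & degs$direction == d]
      tibble::tibble(type_a = pairs[i, 1], type_b = pairs[i, 2],
                     direction = d, n_shared = length(intersect(a, b)))
    })
  })
  structure(list(
    per_type = per_type, membership = membership,
    shared_genes = shared_genes, unique_sets = unique_sets,
    shared_fraction = length(shared_genes) / max(nrow(membership), 1L),
    pairwise = pairwise
  ), class = "vasc_deg_summary")
}

#' @export
print.vasc_deg_summary <- function(x, ...) {
  cat("<vasc_deg_summary> ", nrow(x$membership), " DEGs across ",
      nrow(x$per_type), " cell types; ", length(x$shared_genes),
      " shared by >= 2 types (", sprintf("%.1f%%", 100 * x$shared_fraction),
      ")\n", sep = "")
  print(x$per_type)
  invisible(x)
}

#' Intersect shared DEGs with a transcription-factor list
#'
#' @param shared character vector of shared DEG genes, or a called DEG table
#'   (its distinct genes are used, direction carried along).
#' @param tf_list character vector of TF gene identifiers, or a path to a
#'   text file with one identifier per line.
#' @return Tibble: gene (and direction when available) for shared genes that
#'   encode TFs. An empty TF list warns and returns an empty result.
#' @export
intersect_tf_list <- function(shared, tf_list) {
  if (length(tf_list) == 1 && file.exists(tf_list)) tf_list <- readLines(tf_list)
  tf_list <- tf_list[nzchar(tf_list)]
  if (length(tf_list) == 0) {
    warning("empty TF list; returning no genes")
    return(tibble::tibble(gene = character(0)))
  }
  if (is.data.frame(shared)) {
    dplyr::distinct(tibble::as_tibble(shared), .data$gene, .data$direction) |>
      dplyr::filter(.data$gene %in% tf_list)
  } else {
    tibble::tibble(gene = intersect(shared, tf_list))
  }
}
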