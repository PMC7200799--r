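#' Infer TF-to-target edges from expression
#'
#' A deliberately simplified network-inference step: for every candidate
#' target gene, transcription factors are ranked by the absolute Spearman
#' correlation of their expression profiles (default), or by permutation
#' importance from a random-forest regression of the target on all TFs
#' (`method = "tree_importance"`, backed by ranger), and the `top_k`
#' highest-scoring TFs become edges. Full motif-database workflows are out
#' of scope; motif support enters only through [prune_by_motif()].
#'
#' @param x a log-normalized [umi_experiment()] (or a genes x cells numeric
#'   matrix with rownames).
#' @param tf_list character vector of TF gene identifiers (must be genes of
#'   the matrix). TFs with constant expression are excluded with a warning.
#' @param method `"correlation"` or `"tree_importance"`.
#' @param top_k edges kept per target (default 1: the single best-supported
#'   regulator per target, a deliberately sparse network; raise to densify).
#' @param targets optional character vector of target genes (default: all
#'   non-TF, non-ERCC genes).
#' @param min_cells minimum number of cells (default 50).
#' @param num_trees forest size for `tree_importance`.
#' @return Tibble edge list: tf, target, importance, motif_supported
#'   (initialised FALSE).
#' @export
infer_edges <- function(x, tf_list, method = c("correlation", "tree_importance"),
                        top_k = 1L, targets = NULL, min_cells = 50L,
                        num_trees = 200L) {
  method <- match.arg(method)
  if (inherits(x, "umi_experiment")) {
    if (is.null(x$logcounts)) stop("run log_normalize() first")
    expr <- x$logcounts[!x$genes$is_ercc, , drop = FALSE]
  } else {
    expr <- as.matrix(x)
  }
  if (ncol(expr) < min_cells)
    stop("edge inference needs at least ", min_cells, " cells")
  missing_tf <- setdiff(tf_list, rownames(expr))
  if (length(missing_tf) > 0)
    stop("TFs absent from the matrix: ", paste(utils::head(missing_tf, 5), collapse = ", "))
  const <- tf_list[apply(expr[tf_list, , drop = FALSE], 1, stats::sd) == 0]
  if (length(const) > 0) {
    warning("excluding constant TF(s): ", paste(const, collapse = ", "))
    tf_list <- setdiff(tf_list, const)
  }
  if (length(tf_list) == 0) stop("no usable TFs")
  targets <- targets %||% setdiff(rownames(expr), tf_list)

  if (method == "correlation") {
    score <- abs(stats::cor(t(expr[targets, , drop = FALSE]),
                            t(expr[tf_list, , drop = FALSE]),
                            method = "spearman"))
    score[is.na(score)] <- 0
    edges <- purrr::map_dfr(seq_along(targets), function(i) {
      ord <- order(score[i, ], decreasing = TRUE)[seq_len(min(top_k, length(tf_list)))]
      tibble::tibble(tf = tf_list[ord], target = targets[i],
                     importance = score[i, ord])
    })
  } else {
    if (!requireNamespace("ranger", quietly = TRUE))
      stop("method \"tree_importance\" requires the ranger package")
    preds <- as.data.frame(t(expr[tf_list, , drop = FALSE]))
    edges <- purrr::map_dfr(targets, function(tg) {
      dat <- preds[setdiff(tf_list, tg)]
      fit <- ranger::ranger(y = expr[tg, ], x = dat,
                            num.trees = num_trees,
                            importance = "permutation", seed = 1L)
      imp <- pmax(fit$variable.importance, 0)
      imp <- imp / max(sum(imp), .Machine$double.eps)
      ord <- order(imp, decreasing = TRUE)[seq_len(min(top_k, length(imp)))]
      tibble::tibble(tf = names(imp)[ord], target = tg, importance = imp[ord])
    })
  }
  edges <- dplyr::filter(edges, .data$tf != .data$target)
  edges$motif_supported <- FALSE
  edges
}

#' Flag or filter edges by motif support
#'
#' Marks every edge whose (tf, target) pair occurs in a user-supplied motif
#' map; with `keep_supported_only = TRUE` unsupported edges are dropped.
#' Motif databases themselves are external resources and are not computed
#' here.
#'
#' @param edges an [infer_edges()] edge list.
#' @param motif_map tibble/data.frame with columns `tf` and `target`, or a
#'   TSV path. Malformed rows (missing tf or target) are dropped with a
#'   warning.
#' @param keep_supported_only drop unsupported edges (default FALSE).
#' @return The edge list with `motif_supported` set.
#' @export
prune_by_motif <- function(edges, motif_map, keep_supported_only = FALSE) {
  if (is.character(motif_map) && length(motif_map) == 1)
    motif_map <- readr::read_tsv(motif_map, show_col_types = FALSE)
  motif_map <- tibble::as_tibble(motif_map)
  if (!all(c("tf", "target") %in% names(motif_map)))
    stop("motif map needs `tf` and `target` columns")
  bad <- is.na(motif_map$tf) | is.na(motif_map$target) |
    !nzchar(motif_map$tf) | !nzchar(motif_map$target)
  if (any(bad)) {
    warning(sum(bad), " malformed motif-map row(s) dropped")
    motif_map <- motif_map[!bad, ]
  }
  key <- paste(edges$tf, edges$target, sep = "\r")
  edges$motif_supported <- key %in% paste(motif_map$tf, motif_map$target, sep = "\r")
  if (keep_supported_only) edges <- edges[edges$motif_supported, ]
  edges
}

#' Old/young gene-expression signature from DE records
#'
#' Per-gene signed score: sign of the old-versus-young change times the
#' standard-normal quantile of the two-sided p-value,
#' `sign(avg_logFC) * qnorm(1 - p/2)`, capped at +/- `cap` (p = 0 maps to
#' the cap). When records from several cell types are pooled, each gene
#' keeps its most significant record.
#'
#' @param records an [age_de_test()] table.
#' @param cell_type restrict to one cell type (default NULL = pooled).
#' @param cap score cap (default 8).
#' @return Named numeric vector of scores (names = genes).
#' @export
compute_signature <- function(records, cell_type = NULL, cap = 8) {
  records <- dplyr::filter(tibble::as_tibble(records), !.data$skipped)
  if (!is.null(cell_type))
    records <- dplyr::filter(records, .data$cell_type == !!cell_type)
  if (nrow(records) == 0) stop("no usable DE records")
  records <- records |>
    dplyr::slice_min(.data$p_value, by = "gene", n = 1, with_ties = FALSE)
  score <- sign(records$avg_logFC) * stats::qnorm(1 - records$p_value / 2)
  score <- pmin(pmax(score, -cap), cap)
  score[records$p_value >= 1] <- 0
  stats::setNames(score, records$gene)
}

#' Rank-based regulon activity against a signature
#'
#' Signature scores are ranked ascending (midranks on ties); the regulon's
#' activity is the standardised mean rank of its targets, using the exact
#' mean and variance of the mean of `n` draws without replacement from the
#' `N` ranks, with a two-sided normal p-value. The statistic is invariant
#' under any strictly monotone transform of the scores.
#'
#' @param targets character vector of the regulon's target genes (must be
#'   scored in the signature; at least `min_size`).
#' @param signature named score vector from [compute_signature()].
#' @param min_size minimum regulon size (default 5).
#' @return List: z, p, n_targets.
#' @export
regulon_activity <- function(targets, signature, min_size = 5L) {
  targets <- intersect(targets, names(signature))
  n <- length(targets)
  if (n < min_size) return(NULL)
  N <- length(signature)
  r <- rank(signature)
  mu <- (N + 1) / 2
  pop_var <- mean((r - mu)^2)
  v <- if (N > n) pop_var * (N - n) / (n * (N - 1)) else 0
  u <- mean(r[match(targets, names(signature))])
  z <- if (v > 0) (u - mu) / sqrt(v) else 0
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))), n_targets = n)
}

#' Score all regulons of an edge list
#'
#' @param edges an [infer_edges()] edge list (optionally motif-pruned); a
#'   regulon is a TF's retained out-edges.
#' @param signature named score vector from [compute_signature()].
#' @param min_size minimum regulon size; smaller regulons are skipped.
#' @return Tibble: tf, regulon_size, activity_z, p.
#' @export
score_regulons <- function(edges, signature, min_size = 5L) {
  purrr::map_dfr(split(edges$target, edges$tf), function(tg) {
    act <- regulon_activity(tg, signature, min_size = min_size)
    if (is.null(act)) return(NULL)
    tibble::tibble(regulon_size = length(unique(tg)),
                   activity_z = act$z, p = act$p, n_scored = act$n_targets)
  }, .id = "tf")
}

#' Candidate master regulators and hub ranking
#'
#' Benjamini-Hochberg FDR across the scored TFs; candidate MRs are those
#' with both p and FDR strictly below `alpha`. Hubs are ranked by the
#' number of regulon targets that are called DEGs (descending; ties broken
#' by |activity z| then TF identifier), so rank 1 is the dominant regulator
#' of the aging signature.
#'
#' @param scored output of [score_regulons()].
#' @param edges the edge list the regulons came from.
#' @param deg_genes character vector of called DEG genes (or a [call_degs()]
#'   table). NULL counts all targets instead.
#' @param alpha significance cutoff (default 0.05, strict).
#' @return Tibble of class `vasc_mr`: tf, regulon_size, n_deg_targets,
#'   activity_z, p, fdr, candidate, hub_rank.
#' @export
candidate_mrs <- function(scored, edges, deg_genes = NULL, alpha = 0.05) {
  if (nrow(scored) == 0) stop("no scored regulons")
  if (is.data.frame(deg_genes)) deg_genes <- unique(deg_genes$gene)
  res <- scored
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$candidate <- res$p < alpha & res$fdr < alpha
  reg <- split(unique(edges[c("tf", "target")]), edges$tf)
  res$n_deg_targets <- vapply(res$tf, function(f) {
    tg <- edges$target[edges$tf == f]
    if (is.null(deg_genes)) length(unique(tg))
    else length(intersect(unique(tg), deg_genes))
  }, integer(1))
  ord <- order(-res$n_deg_targets, -abs(res$activity_z), res$tf)
  res$hub_rank <- match(seq_len(nrow(res)), ord)
  res <- res[order(res$hub_rank), c("tf", "regulon_size", "n_deg_targets",
                                    "activity_z", "p", "fdr", "candidate",
                                    "hub_rank")]
  structure(res, class = c("vasc_mr", class(tibble::tibble())))
}
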