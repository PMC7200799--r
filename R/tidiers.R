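#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for pipeline results
#'
#' `tidy()` returns the per-unit table of a result (per gene, per cell, per
#' TF); `glance()` condenses it to a one-row summary.
#'
#' @param x a result object (`vasc_deg`, `vasc_noise`, `vasc_mr`,
#'   `vasc_deg_summary`).
#' @param ... unused.
#' @return A tibble.
#' @name vascaging-tidiers
NULL

#' @rdname vascaging-tidiers
#' @export
tidy.vasc_deg <- function(x, ...) tibble::as_tibble(x)

#' @rdname vascaging-tidiers
#' @export
glance.vasc_deg <- function(x, ...) {
  tested <- dplyr::filter(tibble::as_tibble(x), !.data$skipped)
  tibble::tibble(
    n_tests = nrow(tested),
    n_cell_types = dplyr::n_distinct(x$cell_type),
    n_skipped = sum(x$skipped),
    n_significant = sum(tested$p_adj <= 0.05 & abs(tested$avg_logFC) >= 0.5),
    lfc_base = attr(x, "lfc_base") %||% "natural"
  )
}

#' @rdname vascaging-tidiers
#' @export
tidy.vasc_deg_summary <- function(x, ...) {
  dplyr::mutate(x$per_type,
                n_unique = lengths(x$unique_sets)[as.character(.data$cell_type)])
}

#' @rdname vascaging-tidiers
#' @export
glance.vasc_deg_summary <- function(x, ...) {
  tibble::tibble(
    n_deg = nrow(x$membership),
    n_shared = length(x$shared_genes),
    shared_fraction = x$shared_fraction,
    n_cell_types = nrow(x$per_type)
  )
}

#' @rdname vascaging-tidiers
#' @export
tidy.vasc_noise <- function(x, ...) tibble::as_tibble(x)

#' @rdname vascaging-tidiers
#' @export
glance.vasc_noise <- function(x, ...) {
  ok <- dplyr::filter(tibble::as_tibble(x), !.data$flagged)
  tibble::tibble(
    n_cells = nrow(x),
    n_flagged = sum(x$flagged),
    median_noise_old = stats::median(ok$noise_ratio[ok$age_group == "old"]),
    median_noise_young = stats::median(ok$noise_ratio[ok$age_group == "young"]),
    scale = attr(x, "scale") %||% "lognorm"
  )
}

#' @rdname vascaging-tidiers
#' @export
tidy.vasc_mr <- function(x, ...) tibble::as_tibble(x)

#' @rdname vascaging-tidiers
#' @export
glance.vasc_mr <- function(x, ...) {
  tibble::tibble(
    n_tfs = nrow(x),
    n_candidates = sum(x$candidate),
    top_hub = x$tf[x$hub_rank == 1],
    top_hub_deg_targets = x$n_deg_targets[x$hub_rank == 1]
  )
}
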