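# shared fixture builders; everything is generated in code under fixed seeds

# a small one-type / two-type simulation config for unit tests
small_sim_config <- function(seed = 1L, n_types = 1L, cells_per_monkey = 20L,
                             n_genes = 120L, n_ercc = 10L, ...) {
  types <- if (n_types == 1L) {
    tibble::tibble(name = "EC", proportion = 1, cells_per_monkey = cells_per_monkey)
  } else {
    tibble::tibble(name = c("EC", "SMC"), proportion = c(0.5, 0.5),
                   cells_per_monkey = rep(cells_per_monkey, 2))
  }
  args <- list(seed = seed, n_monkeys_young = 2L, n_monkeys_old = 2L,
               cell_types = types, n_genes = n_genes, n_ercc = n_ercc,
               n_tfs = 0L, targets_per_tf = 0L, deg_fraction = 0,
               noise_inflation_old = 1, mr_effect = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# hand-built experiment from an explicit count matrix
toy_experiment <- function(counts, is_ercc = NULL, cells = NULL, ...) {
  counts <- as.matrix(counts)
  ng <- nrow(counts); nc <- ncol(counts)
  genes <- tibble::tibble(
    gene_id = rownames(counts) %||% sprintf("g%03d", seq_len(ng)),
    is_ercc = is_ercc %||% rep(FALSE, ng), ...)
  cells <- cells %||% tibble::tibble(cell_id = colnames(counts) %||%
                                       sprintf("c%03d", seq_len(nc)))
  umi_experiment(counts, genes, cells)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
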