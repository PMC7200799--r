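#' Configuration for the synthetic-data generator
#'
#' Defines the study design and the statistical law of the simulated UMI
#' counts. Defaults mirror the emulated study design: eight young and eight
#' old monkeys, four vascular-wall cell types (endothelial cells, smooth
#' muscle cells, adventitial fibroblasts, immune cells), 96-barcode pools and
#' an 8 nt barcode + 8 nt UMI read layout. Counts follow a negative-binomial
#' law with log-normal per-gene means; planted age effects (differential
#' genes, old-cell noise inflation, a coherently downregulated hub TF
#' regulon) are recorded as ground truth.
#'
#' @param seed integer RNG seed; everything downstream is deterministic in it.
#' @param n_monkeys_young,n_monkeys_old number of animals per age group.
#' @param cell_types tibble with columns `name`, `proportion`,
#'   `cells_per_monkey`; proportions must sum to 1 and every
#'   `cells_per_monkey` must be at least 3 (the expressed-gene mask used by
#'   the noise statistic needs three cells).
#' @param n_genes number of biological genes (transcription-factor genes
#'   included); `n_ercc` ERCC spike-in rows are added on top (at least 2 so a
#'   technical distance exists).
#' @param baseline_log_mean_mu,baseline_log_mean_sigma log-normal law for the
#'   per-gene mean count.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param bio_noise_sd standard deviation (natural-log scale) of the per-cell
#'   multiplicative biological deviation around the gene mean. This is the
#'   component the noise statistic measures; ERCC rows never receive it.
#' @param lib_size_sd log-sd of the per-cell library-size factor (not applied
#'   to ERCC rows, whose expected counts are identical across a monkey's
#'   cells).
#' @param deg_fraction fraction of biological genes planted as old/young
#'   differential genes; `deg_log2fc` is their log2 fold change and
#'   `deg_share_fraction` the fraction of them planted in two cell types
#'   rather than one (emulating partial DEG sharing across cell populations).
#' @param deg_cell_types cell types eligible for DEG planting (NULL = all).
#' @param noise_inflation_old multiplier (>= 1) on `bio_noise_sd` in old
#'   cells of `noise_cell_types` (NULL = all types).
#' @param n_tfs,targets_per_tf regulon structure; the planted hub TF receives
#'   `2 * targets_per_tf` targets so it always has the largest regulon.
#' @param tf_activity_sd log-sd of the shared per-cell activity factor that
#'   couples a TF to its targets (this is what edge inference detects).
#' @param mr_effect coherent log2 downshift applied to the hub TF and its
#'   whole regulon in old cells.
#' @param read_length,whitelist read-simulation parameters; barcodes are
#'   8 nt, UMIs 8 nt, and the default whitelist holds 96 barcodes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_monkeys_young = 8L, n_monkeys_old = 8L,
                       cell_types = default_cell_types(),
                       n_genes = 2000L, n_ercc = 92L,
                       baseline_log_mean_mu = log(20),
                       baseline_log_mean_sigma = 0.8,
                       nb_dispersion = 0.05,
                       bio_noise_sd = 0.5,
                       lib_size_sd = 0.2,
                       deg_fraction = 0.05,
                       deg_log2fc = 1.5,
                       deg_share_fraction = 0.2,
                       deg_cell_types = NULL,
                       noise_inflation_old = 1,
                       noise_cell_types = NULL,
                       n_tfs = 20L, targets_per_tf = 15L,
                       tf_activity_sd = 0.8,
                       mr_effect = 1,
                       read_length = 100L,
                       whitelist = default_whitelist()) {
  cell_types <- tibble::as_tibble(cell_types)
  cfg <- list(
    seed = as.integer(seed),
    n_monkeys_young = as.integer(n_monkeys_young),
    n_monkeys_old = as.integer(n_monkeys_old),
    cell_types = cell_types,
    n_genes = as.integer(n_genes), n_ercc = as.integer(n_ercc),
    baseline_log_mean_mu = baseline_log_mean_mu,
    baseline_log_mean_sigma = baseline_log_mean_sigma,
    nb_dispersion = nb_dispersion,
    bio_noise_sd = bio_noise_sd,
    lib_size_sd = lib_size_sd,
    deg_fraction = deg_fraction,
    deg_log2fc = deg_log2fc,
    deg_share_fraction = deg_share_fraction,
    deg_cell_types = deg_cell_types,
    noise_inflation_old = noise_inflation_old,
    noise_cell_types = noise_cell_types,
    n_tfs = as.integer(n_tfs),
    targets_per_tf = as.integer(targets_per_tf),
    tf_activity_sd = tf_activity_sd,
    mr_effect = mr_effect,
    barcode_length = 8L, umi_length = 8L,
    read_length = as.integer(read_length),
    whitelist = whitelist
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ct <- cfg$cell_types
  stopifnot(all(c("name", "proportion", "cells_per_monkey") %in% names(ct)))
  if (abs(sum(ct$proportion) - 1) > 1e-9)
    stop("cell-type proportions must sum to 1")
  if (any(ct$cells_per_monkey < 3))
    stop("cells_per_monkey must be >= 3 for every cell type ",
         "(the expressed-gene mask needs at least three cells)")
  if (cfg$n_ercc < 2)
    stop("n_ercc must be >= 2 (technical distance needs at least two spike-ins)")
  wl <- cfg$whitelist
  if (anyDuplicated(wl)) stop("whitelist barcodes must be unique")
  if (any(nchar(wl) != cfg$barcode_length))
    stop("whitelist barcodes must all have length ", cfg$barcode_length)
  if (any(grepl("[^ACGT]", wl)))
    stop("whitelist barcodes must be over the alphabet {A,C,G,T}")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$deg_fraction < 0 || cfg$deg_fraction > 1)
    stop("deg_fraction must lie in [0, 1]")
  if (cfg$noise_inflation_old < 1) stop("noise_inflation_old must be >= 1")
  if (cfg$n_tfs > 0 && cfg$n_tfs * (cfg$targets_per_tf + 1) + cfg$targets_per_tf > cfg$n_genes)
    stop("n_genes too small for the requested regulon structure")
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_cell_types <- function() {
  tibble::tibble(
    name = c("EC", "SMC", "AF", "IMM"),
    proportion = c(0.4, 0.3, 0.2, 0.1),
    cells_per_monkey = c(24L, 18L, 12L, 6L)
  )
}

#' @rdname sim_config
#' @param n number of whitelist barcodes (one 96-barcode pool by default).
#' @export
default_whitelist <- function(n = 96L) {
  # fixed internal seed: the whitelist is a constant resource, not a draw
  withr::with_seed(760914L, {
    repeat {
      wl <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE), collapse = ""),
        character(1))
      if (!anyDuplicated(wl)) return(wl)
    }
  })
}

#' Simulate a UMI count matrix with planted age effects
#'
#' Draws negative-binomial counts for every (gene, cell) under the law
#' described in [sim_config()] and returns both the experiment and the ground
#' truth of every planted effect. ERCC rows carry purely technical variation:
#' their expected counts are identical across all cells of a monkey and they
#' receive neither the biological deviation factor nor any age effect.
#' Old-cell noise inflation scales the per-cell multiplicative deviation
#' around the cell-type mean, not the mean itself, so group means are
#' untouched and the noise statistic is isolated from the DEG statistic.
#'
#' @param config a [sim_config()].
#' @return A list with elements `experiment` (a [umi_experiment()]) and
#'   `truth` (list: `deg_genes` tibble (gene, cell_type, direction),
#'   `noise_inflated_cells`, `hub_tf`, `regulons` tibble (tf, target),
#'   `cell_labels`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(cfg) {
  ct <- cfg$cell_types
  monkeys <- tibble::tibble(
    monkey = c(sprintf("Y%02d", seq_len(cfg$n_monkeys_young)),
               sprintf("O%02d", seq_len(cfg$n_monkeys_old))),
    age_group = rep(c("young", "old"), c(cfg$n_monkeys_young, cfg$n_monkeys_old))
  )
  cells <- tidyr::expand_grid(monkeys, ct) |>
    dplyr::rowwise() |>
    dplyr::mutate(ids = list(sprintf("%s_%s_c%02d", .data$monkey, .data$name,
                                     seq_len(.data$cells_per_monkey)))) |>
    dplyr::ungroup() |>
    tidyr::unnest("ids") |>
    dplyr::transmute(cell_id = .data$ids, monkey = .data$monkey,
                     age_group = .data$age_group, cell_type = .data$name)
  cells$region <- rep_len(c("AA", "CA"), nrow(cells))
  n_cells <- nrow(cells)

  # gene universe: TF genes first, then ordinary genes, then ERCC rows
  tf_ids <- if (cfg$n_tfs > 0) sprintf("TF%02d", seq_len(cfg$n_tfs)) else character(0)
  n_ord <- cfg$n_genes - cfg$n_tfs
  gene_ids <- c(tf_ids, sprintf("G%04d", seq_len(n_ord)))
  ercc_ids <- sprintf("ERCC-%04d", seq_len(cfg$n_ercc))
  genes <- tibble::tibble(
    gene_id = c(gene_ids, ercc_ids),
    is_ercc = rep(c(FALSE, TRUE), c(cfg$n_genes, cfg$n_ercc)),
    is_tf = c(rep(c(TRUE, FALSE), c(cfg$n_tfs, n_ord)), rep(FALSE, cfg$n_ercc))
  )

  lambda <- stats::rlnorm(cfg$n_genes, cfg$baseline_log_mean_mu,
                          cfg$baseline_log_mean_sigma)
  lambda_ercc <- stats::rlnorm(cfg$n_ercc, cfg$baseline_log_mean_mu,
                               cfg$baseline_log_mean_sigma)
  size_fac <- stats::rlnorm(n_cells, -cfg$lib_size_sd^2 / 2, cfg$lib_size_sd)

  # regulons: disjoint target sets, hub gets a double-size regulon
  regulons <- tibble::tibble(tf = character(0), target = character(0))
  hub_tf <- NA_character_
  if (cfg$n_tfs > 0) {
    hub_tf <- sample(tf_ids, 1L)
    ord_ids <- setdiff(gene_ids, tf_ids)
    sizes <- ifelse(tf_ids == hub_tf, 2L * cfg$targets_per_tf, cfg$targets_per_tf)
    pool <- sample(ord_ids, sum(sizes))
    regulons <- tibble::tibble(
      tf = rep(tf_ids, sizes),
      target = pool
    )
  }

  # planted old/young DEGs, outside any regulon so effects stay separable
  free <- setdiff(gene_ids, c(tf_ids, regulons$target))
  n_deg <- min(round(cfg$deg_fraction * cfg$n_genes), length(free))
  deg_types <- cfg$deg_cell_types %||% ct$name
  deg_genes <- tibble::tibble(gene = character(0), cell_type = character(0),
                              direction = character(0))
  if (n_deg > 0) {
    picked <- sample(free, n_deg)
    dirs <- rep_len(c("up", "down"), n_deg)
    shared <- stats::runif(n_deg) < cfg$deg_share_fraction & length(deg_types) >= 2
    deg_genes <- purrr::map_dfr(seq_len(n_deg), function(i) {
      k <- if (shared[i]) 2L else 1L
      tibble::tibble(gene = picked[i],
                     cell_type = sample(deg_types, k),
                     direction = dirs[i])
    })
  }

  # log expected count, biological genes
  logmu <- matrix(log(lambda), nrow = cfg$n_genes, ncol = n_cells)
  logmu <- sweep(logmu, 2, log(size_fac), "+")

  # TF activity: shared per-cell factor on a TF and all its targets
  if (cfg$n_tfs > 0) {
    act <- matrix(stats::rnorm(cfg$n_tfs * n_cells, -cfg$tf_activity_sd^2 / 2,
                               cfg$tf_activity_sd),
                  nrow = cfg$n_tfs, dimnames = list(tf_ids, NULL))
    logmu[seq_len(cfg$n_tfs), ] <- logmu[seq_len(cfg$n_tfs), ] + act
    tgt_idx <- match(regulons$target, gene_ids)
    tf_idx <- match(regulons$tf, tf_ids)
    logmu[tgt_idx, ] <- logmu[tgt_idx, ] + act[tf_idx, , drop = FALSE]
  }

  old <- cells$age_group == "old"
  # hub regulon coherently downshifted in old cells
  if (cfg$n_tfs > 0 && cfg$mr_effect != 0) {
    reg_idx <- match(c(hub_tf, regulons$target[regulons$tf == hub_tf]), gene_ids)
    logmu[reg_idx, old] <- logmu[reg_idx, old] - cfg$mr_effect * log(2)
  }
  # planted DEGs in old cells of their cell type(s)
  if (nrow(deg_genes) > 0) {
    for (i in seq_len(nrow(deg_genes))) {
      gi <- match(deg_genes$gene[i], gene_ids)
      ci <- old & cells$cell_type == deg_genes$cell_type[i]
      sgn <- if (deg_genes$direction[i] == "up") 1 else -1
      logmu[gi, ci] <- logmu[gi, ci] + sgn * cfg$deg_log2fc * log(2)
    }
  }

  # per-cell biological deviation; sd inflated in old cells of the noise types
  noise_types <- cfg$noise_cell_types %||% ct$name
  inflated <- old & cells$cell_type %in% noise_types & cfg$noise_inflation_old > 1
  dev_sd <- ifelse(inflated, cfg$bio_noise_sd * cfg$noise_inflation_old,
                   cfg$bio_noise_sd)
  if (cfg$bio_noise_sd > 0) {
    dev <- matrix(stats::rnorm(cfg$n_genes * n_cells), nrow = cfg$n_genes)
    dev <- sweep(dev, 2, dev_sd, "*")
    dev <- sweep(dev, 2, dev_sd^2 / 2, "-")  # mean-one lognormal factor
    logmu <- logmu + dev
  }

  size <- 1 / cfg$nb_dispersion
  counts_bio <- matrix(
    stats::rnbinom(cfg$n_genes * n_cells, mu = exp(logmu), size = size),
    nrow = cfg$n_genes
  )
  counts_ercc <- matrix(
    stats::rnbinom(cfg$n_ercc * n_cells,
                   mu = rep(lambda_ercc, n_cells), size = size),
    nrow = cfg$n_ercc
  )
  counts <- rbind(counts_bio, counts_ercc)
  storage.mode(counts) <- "integer"

  # alignment metadata emulating the upstream read processing: every UMI is
  # covered by several reads, and a plausible mapping ratio per cell
  totals <- colSums(counts_bio)
  cells$aligned_reads <- as.integer(round(totals * stats::runif(n_cells, 5, 15)))
  cells$mapping_ratio <- stats::runif(n_cells, 0.3, 0.9)

  exper <- umi_experiment(counts, genes, cells)
  truth <- list(
    deg_genes = deg_genes,
    noise_inflated_cells = cells$cell_id[inflated],
    hub_tf = hub_tf,
    regulons = regulons,
    cell_labels = cells
  )
  list(experiment = exper, truth = truth)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build a toy transcriptome of random transcripts
#'
#' Random uniform sequences long enough that distinct transcripts essentially
#' never share a k-mer at the k used by [assign_genes()], so read-to-gene
#' assignment on simulated reads is unambiguous.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param length transcript length in nt (all equal).
#' @param seed RNG seed.
#' @return Named character vector of class `toy_transcriptome`.
#' @export
make_toy_transcriptome <- function(gene_ids, length = 500L, seed = 1L) {
  stopifnot(length(gene_ids) > 0, !anyDuplicated(gene_ids))
  withr::with_seed(seed, {
    seqs <- vapply(gene_ids, function(g)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
      character(1))
  })
  structure(seqs, class = "toy_transcriptome")
}

#' Write / read a toy transcriptome as FASTA
#' @param x named character vector of transcript sequences.
#' @param path FASTA file path.
#' @export
write_transcriptome <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unclass(x)), path)
  invisible(path)
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  structure(stats::setNames(as.character(ss), names(ss)),
            class = "toy_transcriptome")
}

#' Simulate barcoded paired-end reads from UMI events
#'
#' Emits the STRT-style read layout: Read 2 starts with the cell's 8 nt
#' barcode followed by the 8 nt UMI (then oligo-dT filler); Read 1 is a
#' substring of the source transcript, optionally ending in a polyA run so
#' the trimmer has work to do. Each UMI event produces one or more duplicate
#' read pairs (PCR duplicates); the returned truth table records every event
#' and its duplication level, so the demultiplexed matrix can be compared to
#' truth exactly.
#'
#' @param config a [sim_config()]; cells are assigned whitelist barcodes in
#'   order, so the simulated experiment must have at most
#'   `length(config$whitelist)` cells.
#' @param transcriptome a [make_toy_transcriptome()] covering every gene with
#'   counts (ERCC rows included if present).
#' @param r1_path,r2_path output FASTQ paths (gzip if ending in `.gz`).
#' @param experiment optional [umi_experiment()] giving the event counts;
#'   defaults to `simulate_counts(config)$experiment`.
#' @param dup_rate mean number of extra PCR-duplicate reads per UMI event.
#' @param polya_prob fraction of reads carrying a 3' polyA run.
#' @param polya_len length of the appended polyA run.
#' @return Tibble truth table: cell_id, barcode, gene, umi, n_reads.
#' @export
simulate_reads <- function(config, transcriptome, r1_path, r2_path,
                           experiment = NULL, dup_rate = 0.5,
                           polya_prob = 0.25, polya_len = 15L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(transcriptome) == 0) stop("transcriptome is empty")
  if (is.null(experiment)) experiment <- simulate_counts(config)$experiment
  counts <- experiment$counts
  if (ncol(counts) > length(config$whitelist))
    stop("more cells (", ncol(counts), ") than whitelist barcodes (",
         length(config$whitelist), ")")
  used <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(used, names(transcriptome))
  if (length(missing) > 0)
    stop("transcriptome lacks sequences for: ", paste(utils::head(missing, 5), collapse = ", "))
  if (any(nchar(transcriptome[used]) < config$read_length))
    stop("all transcripts must be at least read_length (", config$read_length, ") nt")

  barcodes <- config$whitelist[seq_len(ncol(counts))]
  names(barcodes) <- colnames(counts)

  withr::with_seed(config$seed + 1L, {
    nz <- which(counts > 0, arr.ind = TRUE)
    events <- purrr::map_dfr(seq_len(nrow(nz)), function(i) {
      k <- counts[nz[i, 1], nz[i, 2]]
      tibble::tibble(
        cell_id = colnames(counts)[nz[i, 2]],
        gene = rownames(counts)[nz[i, 1]],
        umi = int_to_umi(sample.int(4^8, k), config$umi_length)
      )
    })
    events$barcode <- unname(barcodes[events$cell_id])
    events$n_reads <- 1L + stats::rpois(nrow(events), dup_rate)

    idx <- rep(seq_len(nrow(events)), events$n_reads)
    gene <- events$gene[idx]
    tlen <- nchar(transcriptome[gene])
    rl <- config$read_length
    has_pa <- stats::runif(length(idx)) < polya_prob
    ins_len <- ifelse(has_pa, rl - polya_len, rl)
    start <- 1L + floor(stats::runif(length(idx)) * (tlen - ins_len + 1))
    r1 <- substr(transcriptome[gene], start, start + ins_len - 1L)
    r1[has_pa] <- paste0(r1[has_pa], strrep("A", polya_len))
    dt_fill <- strrep("T", max(0L, rl - 16L))
    r2 <- paste0(events$barcode[idx], events$umi[idx], dt_fill)

    write_fastq(sprintf("read%06d/1", seq_along(r1)), r1, r1_path)
    write_fastq(sprintf("read%06d/2", seq_along(r2)), r2, r2_path)
  })
  events[, c("cell_id", "barcode", "gene", "umi", "n_reads")]
}

int_to_umi <- function(i, len) {
  i <- i - 1L
  chars <- c("A", "C", "G", "T")
  out <- character(length(i))
  for (p in seq_len(len)) {
    out <- paste0(chars[i %% 4L + 1L], out)
    i <- i %/% 4L
  }
  out
}

write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}
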