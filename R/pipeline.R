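#' Bundled demonstration pipeline configuration
#'
#' A small, fully self-contained configuration for [run_pipeline()]: a
#' simulated two-cell-type design (2 young + 2 old monkeys, 300 cells, 500
#' genes + 40 ERCC rows) with planted differential genes, old-cell noise
#' inflation and a downregulated hub regulon, followed by every analysis
#' stage. The cell-QC gene floor is lowered to match the reduced gene
#' panel; every other threshold is the standard preset. Runs in well under
#' a minute on one CPU.
#'
#' @param seed integer seed.
#' @return A config list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "qc", "deg", "noise", "mrs"),
    sim = list(
      n_monkeys_young = 2L, n_monkeys_old = 2L,
      cell_types = tibble::tibble(
        name = c("EC", "SMC"), proportion = c(0.55, 0.45),
        cells_per_monkey = c(40L, 35L)),
      n_genes = 500L, n_ercc = 40L,
      n_tfs = 15L, targets_per_tf = 8L,
      deg_fraction = 0.06, deg_log2fc = 1.5,
      noise_inflation_old = 1.5, mr_effect = 1),
    qc = list(preset = "strt", min_genes = 200L),
    deg = list(), noise = list(), mrs = list()
  )
}

#' Run the full analysis pipeline into a run directory
#'
#' Orchestrates the stages — simulate (or load/demultiplex) -> cell & gene
#' QC -> normalization/HVG -> old/young differential expression ->
#' transcriptional noise -> master-regulator analysis — writing per-stage
#' TSV/JSON outputs, a run log, and a manifest with the seed, the full
#' parameter echo and an md5 checksum of every output file. All randomness
#' derives from `config$seed`, so a rerun with the same configuration
#' reproduces identical checksums.
#'
#' @param config a named list (or YAML file path) with elements:
#'   \describe{
#'     \item{seed}{integer seed (required).}
#'     \item{stages}{character vector of stages to run; default
#'       `c("simulate","qc","deg","noise","mrs")`. `"demux"` may replace
#'       `"simulate"` when FASTQ inputs are given.}
#'     \item{sim}{arguments for [sim_config()] (simulate stage).}
#'     \item{input}{directory of a written experiment (alternative to
#'       simulate).}
#'     \item{demux}{list r1, r2, whitelist, transcriptome, max_mismatch.}
#'     \item{qc}{list preset, scale, hvg_factor plus [qc_thresholds()]
#'       overrides.}
#'     \item{deg}{list base, lfc_threshold, alpha.}
#'     \item{noise}{list scale, hvg_only, sqrt_dim_norm.}
#'     \item{mrs}{list tf_list, top_k, min_size, alpha, cell_type.}
#'   }
#' @param out_dir run directory (created; stage subdirectories inside).
#' @return The manifest, invisibly; all outputs are on disk under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: `seed` is required")
  stages <- config$stages %||% c("simulate", "qc", "deg", "noise", "mrs")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  run_stage <- function(name, fun) {
    logf("stage ", name, ": start")
    out <- tryCatch(fun(), error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
    logf("stage ", name, ": done")
    out
  }
  exper <- NULL
  truth <- NULL
  outputs <- character(0)
  save_tsv <- function(x, stage, file) {
    dir.create(file.path(out_dir, stage), showWarnings = FALSE)
    p <- file.path(out_dir, stage, file)
    readr::write_tsv(tibble::as_tibble(x), p)
    outputs <<- c(outputs, p)
    p
  }

  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", function() {
      sim_args <- config$sim
      if (!is.null(sim_args$cell_types) && !is.data.frame(sim_args$cell_types))
        sim_args$cell_types <- dplyr::bind_rows(sim_args$cell_types)
      cfg <- do.call(sim_config, c(list(seed = config$seed), sim_args))
      simulate_counts(cfg)
    })
    exper <- sim$experiment
    truth <- sim$truth
    dir.create(file.path(out_dir, "simdata"), showWarnings = FALSE)
    write_experiment(exper, file.path(out_dir, "simdata"))
    outputs <- c(outputs, file.path(out_dir, "simdata",
                                    c("counts.tsv", "genes.tsv", "cells.tsv")))
    save_tsv(truth$deg_genes, "simdata", "truth_deg_genes.tsv")
    save_tsv(truth$regulons, "simdata", "truth_regulons.tsv")
    save_tsv(tibble::tibble(cell_id = truth$noise_inflated_cells),
             "simdata", "truth_noise_cells.tsv")
  } else if ("demux" %in% stages) {
    dm <- config$demux
    for (fld in c("r1", "r2", "whitelist", "transcriptome"))
      if (is.null(dm[[fld]])) stop("config error: demux$", fld, " is required")
    res <- run_stage("demux", function()
      demux_fastq(dm$r1, dm$r2, dm$whitelist, dm$transcriptome,
                  max_mismatch = dm$max_mismatch %||% 0))
    exper <- res$experiment
    if (!is.null(dm$cell_meta)) {
      meta <- readr::read_tsv(dm$cell_meta, show_col_types = FALSE)
      if (!"cell_id" %in% names(meta))
        stop("config error: demux$cell_meta must have a `cell_id` column")
      exper$cells <- dplyr::left_join(exper$cells, meta, by = "cell_id")
    }
    save_tsv(res$report, "demux", "read_report.tsv")
    dir.create(file.path(out_dir, "demux"), showWarnings = FALSE)
    write_experiment(exper, file.path(out_dir, "demux"))
    outputs <- c(outputs, file.path(out_dir, "demux",
                                    c("counts.tsv", "genes.tsv", "cells.tsv")))
  } else if (!is.null(config$input)) {
    exper <- run_stage("load", function() read_experiment(config$input))
  } else {
    stop("config error: provide a simulate/demux stage or an `input` directory")
  }

  hvg <- NULL
  if ("qc" %in% stages) {
    qc <- config$qc %||% list()
    exper <- run_stage("qc", function() {
      thr_over <- qc[setdiff(names(qc), c("preset", "scale", "hvg_factor"))]
      thr <- do.call(qc_thresholds, c(list(preset = qc$preset %||% "strt"), thr_over))
      fc <- filter_cells(exper, thr)
      save_tsv(fc$report, "qc", "cell_report.tsv")
      kept <- filter_genes(fc$experiment)
      kept <- log_normalize(kept, scale = qc$scale %||% 1e5)
      disp <- fit_dispersion(kept)
      save_tsv(disp, "qc", "dispersion.tsv")
      hvg <<- select_hvg(disp, factor = qc$hvg_factor %||% 3)
      save_tsv(tibble::tibble(gene_id = hvg), "qc", "hvg.tsv")
      kept
    })
  } else if (is.null(exper$logcounts)) {
    exper <- log_normalize(exper)
  }

  records <- NULL
  called <- NULL
  if ("deg" %in% stages) {
    dg <- config$deg %||% list()
    run_stage("deg", function() {
      records <<- age_de_test(exper, base = dg$base %||% "natural")
      called <<- call_degs(records, lfc_threshold = dg$lfc_threshold %||% 0.5,
                           alpha = dg$alpha %||% 0.05)
      save_tsv(records, "deg", "deg_records.tsv")
      save_tsv(called, "deg", "deg_called.tsv")
      if (dplyr::n_distinct(called$cell_type) >= 2) {
        summ <- shared_deg_summary(called)
        save_tsv(summ$per_type, "deg", "per_type_counts.tsv")
        save_tsv(summ$pairwise, "deg", "pairwise_shared.tsv")
        p <- file.path(out_dir, "deg", "summary.json")
        jsonlite::write_json(list(
          n_deg = nrow(summ$membership),
          n_shared = length(summ$shared_genes),
          shared_fraction = summ$shared_fraction), p, auto_unbox = TRUE)
        outputs <<- c(outputs, p)
      }
    })
  }

  if ("noise" %in% stages) {
    nz <- config$noise %||% list()
    run_stage("noise", function() {
      noise <- transcriptional_noise(
        exper, scale = nz$scale %||% "lognorm",
        hvg = if (isTRUE(nz$hvg_only)) hvg else NULL,
        sqrt_dim_norm = isTRUE(nz$sqrt_dim_norm))
      save_tsv(noise, "noise", "noise.tsv")
      save_tsv(compare_noise(noise), "noise", "comparison.tsv")
    })
  }

  if ("mrs" %in% stages) {
    mr <- config$mrs %||% list()
    if (is.null(records)) stop("config error: mrs stage needs the deg stage")
    run_stage("mrs", function() {
      tf_list <- mr$tf_list %||%
        (if ("is_tf" %in% names(exper$genes)) exper$genes$gene_id[exper$genes$is_tf]
         else stop("no TF list: supply mrs$tf_list or an `is_tf` gene flag"))
      tf_list <- intersect(tf_list, exper$genes$gene_id)
      edges <- infer_edges(exper, tf_list, top_k = mr$top_k %||% 1L)
      save_tsv(edges, "mrs", "edges.tsv")
      sig <- compute_signature(records, cell_type = mr$cell_type)
      scored <- score_regulons(edges, sig, min_size = mr$min_size %||% 5L)
      mrs <- candidate_mrs(scored, edges, deg_genes = called,
                           alpha = mr$alpha %||% 0.05)
      save_tsv(mrs, "mrs", "mr_table.tsv")
    })
  }

  manifest <- list(
    package = "vascaging",
    version = as.character(utils::packageVersion("vascaging")),
    seed = config$seed,
    stages = stages,
    parameters = config,
    checksums = {
      sums <- tools::md5sum(sort(outputs))
      names(sums) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                          out_dir), "/?"), "", names(sums))
      as.list(sums)
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline complete: ", length(outputs), " output files")
  invisible(manifest)
}
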