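make_qc_experiment <- function(detected, umi, mapping, aligned) {
  # one cell per scenario; genes split so `detected` genes carry the UMIs
  n_genes <- 1200L
  counts <- sapply(seq_along(detected), function(i) {
    v <- integer(n_genes)
    d <- detected[i]
    v[seq_len(d)] <- 1L
    v[1] <- v[1] + umi[i] - d
    v
  })
  toy_experiment(counts,
                 cells = tibble::tibble(
                   cell_id = sprintf("c%02d", seq_along(detected)),
                   mapping_ratio = mapping, aligned_reads = aligned))
}

test_that("cell filter applies every STRT boundary exactly", {
  x <- make_qc_experiment(
    detected = c(999L, 1000L, 1100L, 1100L, 1100L, 1100L, 1100L),
    umi = c(5000L, 5000L, 3000L, 3001L, 5000L, 5000L, 5000L),
    mapping = c(0.5, 0.5, 0.5, 0.5, 0.10, 0.5, 0.5),
    aligned = c(2e4, 2e4, 2e4, 2e4, 2e4, 9999, 1e4))
  res <- filter_cells(x, qc_thresholds("strt"))
  kept <- res$experiment$cells$cell_id
  expect_false("c01" %in% kept)  # 999 genes, below the 1000 floor
  expect_true("c02" %in% kept)   # exactly 1000 genes is inclusive
  expect_false("c03" %in% kept)  # UMI exactly 3000 fails the strict >
  expect_true("c04" %in% kept)   # 3001 passes
  expect_false("c05" %in% kept)  # mapping ratio exactly 10% fails (strict)
  expect_false("c06" %in% kept)  # 9999 aligned reads below 1e4
  expect_true("c07" %in% kept)   # exactly 1e4 aligned is inclusive
  # the report attributes each failure to its predicate
  rep1 <- dplyr::filter(res$report, cell_id == "c03", !pass)
  expect_identical(rep1$predicate, "umi")
})

test_that("10x preset applies the gene and mitochondria rules", {
  counts <- rbind(matrix(1L, nrow = 2500, ncol = 3), matrix(0L, 50, 3))
  counts[1, ] <- c(1000L, 430L, 1000L)   # tune mito fractions via gene 1
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:2550),
                          is_ercc = FALSE,
                          is_mito = c(TRUE, rep(FALSE, 2549)))
  counts[2, 2] <- 0L  # cell 2 has 2499 detected genes
  x <- umi_experiment(counts, genes,
                      tibble::tibble(cell_id = c("a", "b", "c")))
  mito_frac <- colSums(counts[1, , drop = FALSE]) / colSums(counts)
  res <- filter_cells(x, qc_thresholds("tenx"))
  expect_true(mito_frac[1] > 0.15 && !"a" %in% res$experiment$cells$cell_id)
  expect_true(mito_frac[2] < 0.15 && "b" %in% res$experiment$cells$cell_id)
  # missing the mito flag is an explicit error
  x2 <- toy_experiment(counts)
  expect_error(filter_cells(x2, qc_thresholds("tenx")), "is_mito")
})

test_that("STRT preset refuses matrices without alignment metadata", {
  x <- toy_experiment(matrix(5L, 10, 4))
  expect_error(filter_cells(x, qc_thresholds("strt")), "mapping_ratio")
})

test_that("cell filter equals an independent predicate oracle on random data", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n_cells <- 30L
    lambda <- runif(n_cells, 0.5, 1.5)  # straddle every threshold
    counts <- sapply(lambda, function(l) rpois(1500, l))
    x <- toy_experiment(counts,
      cells = tibble::tibble(cell_id = sprintf("c%02d", 1:n_cells),
                             mapping_ratio = runif(n_cells, 0.05, 0.3),
                             aligned_reads = sample(c(5e3, 2e4), n_cells, TRUE)))
    thr <- qc_thresholds("strt", min_genes = 700L, max_genes = 900L,
                         min_umi = 1700L)
    kept <- filter_cells(x, thr)$experiment$cells$cell_id
    oracle <- x$cells$cell_id[vapply(seq_len(n_cells), function(i) {
      d <- sum(counts[, i] >= 1); u <- sum(counts[, i])
      d >= 700 && d <= 900 && u > 1700 &&
        x$cells$mapping_ratio[i] > 0.10 &&
        x$cells$aligned_reads[i] >= 1e4 && x$cells$aligned_reads[i] <= 3e6
    }, logical(1))]
    expect_identical(kept, oracle)
  }
})

test_that("gene filter keeps count>=2-in->=3-cells genes and exempts ERCC", {
  counts <- rbind(
    c(2L, 2L, 2L, 0L, 0L),   # exactly the boundary: kept
    c(2L, 2L, 0L, 0L, 0L),   # only two supporting cells: dropped
    c(1L, 1L, 1L, 1L, 1L),   # never reaches count 2: dropped
    c(9L, 9L, 9L, 9L, 9L),   # kept
    c(0L, 0L, 0L, 0L, 0L))   # ERCC row, empty, still retained
  x <- toy_experiment(counts, is_ercc = c(rep(FALSE, 4), TRUE))
  kept <- filter_genes(x)$genes$gene_id
  expect_setequal(kept, c("g001", "g004", "g005"))
  # oracle scan on random matrices
  withr::local_seed(8)
  for (rep in 1:10) {
    m <- matrix(rpois(200 * 15, 0.8), ncol = 15)
    y <- toy_experiment(m)
    expect_identical(filter_genes(y)$genes$gene_id,
                     y$genes$gene_id[rowSums(m >= 2) >= 3])
  }
})

test_that("filters are idempotent", {
  sim <- simulate_counts(small_sim_config(seed = 6L, n_genes = 200L))
  f1 <- filter_genes(sim$experiment)
  expect_identical(filter_genes(f1)$counts, f1$counts)
  thr <- qc_thresholds("strt", min_genes = 50L)
  c1 <- filter_cells(sim$experiment, thr)$experiment
  expect_identical(filter_cells(c1, thr)$experiment$counts, c1$counts)
})

test_that("log-normalization matches its closed form and invariances", {
  x <- toy_experiment(matrix(c(1L, 1L, 2L), ncol = 1))
  ln <- log_normalize(x, scale = 1e5)
  expect_equal(ln$logcounts[1, 1], log(1 * 1e5 / 4 + 1))
  expect_equal(ln$logcounts[1, 1], 10.1267, tolerance = 1e-4)
  # zero counts map to exactly zero
  y <- toy_experiment(matrix(c(0L, 3L), ncol = 1))
  expect_identical(log_normalize(y)$logcounts[1, 1], 0)
  # scale invariance: doubling all counts in a cell changes nothing
  a <- toy_experiment(matrix(c(1L, 4L, 5L), ncol = 1))
  b <- toy_experiment(matrix(c(2L, 8L, 10L), ncol = 1))
  expect_equal(log_normalize(a)$logcounts, log_normalize(b)$logcounts)
  # strictly monotone in count within a cell
  m <- toy_experiment(matrix(c(0L, 1L, 2L, 7L), ncol = 1))
  expect_true(all(diff(log_normalize(m)$logcounts[, 1]) > 0))
  # ERCC rows are excluded from the per-cell total but share its factor
  e <- toy_experiment(matrix(c(3L, 1L), ncol = 1), is_ercc = c(FALSE, TRUE))
  le <- log_normalize(e, scale = 10)
  expect_equal(le$logcounts[1, 1], log1p(3 * 10 / 3))
  expect_equal(le$logcounts[2, 1], log1p(1 * 10 / 3))
  # zero-total cells are an error naming the cell
  z <- toy_experiment(matrix(c(0L, 0L, 0L, 2L), ncol = 2))
  expect_error(log_normalize(z), "c001")
})

test_that("dispersion fit recovers the generating overdispersion", {
  withr::local_seed(41)
  mu <- rlnorm(400, log(5), 1)
  nb <- matrix(rnbinom(400 * 800, mu = rep(mu, 800), size = 2), nrow = 400)
  x <- toy_experiment(nb)
  d <- fit_dispersion(x)
  expect_equal(median(d$dispersion_empirical), 0.5, tolerance = 0.1)
  # Poisson counts carry no overdispersion
  po <- toy_experiment(matrix(rpois(300 * 500, rep(mu[1:300], 500)), nrow = 300))
  dp <- fit_dispersion(po)
  expect_lt(median(dp$dispersion_empirical), 0.02)
  # constant gene: variance 0 implies dispersion 0
  cst <- toy_experiment(rbind(matrix(rpois(40 * 30, 5), 40), rep(3L, 30)))
  dc <- fit_dispersion(cst)
  expect_identical(dc$dispersion_empirical[41], 0)
  expect_error(fit_dispersion(toy_experiment(matrix(1L, 5, 5))), "20 genes")
})

test_that("HVG selection applies the three-times-trend rule", {
  tab <- tibble::tibble(gene_id = c("a", "b", "c"),
                        mean = c(1, 1, 1),
                        dispersion_empirical = c(3.1, 2.9, 0.5),
                        dispersion_fit = c(1, 1, 1))
  expect_identical(select_hvg(tab), "a")
  # homogeneous matrix: few genes exceed 3x the trend
  withr::local_seed(42)
  mu <- rlnorm(500, log(5), 1)
  nb <- matrix(rnbinom(500 * 600, mu = rep(mu, 600), size = 5), nrow = 500)
  d0 <- fit_dispersion(toy_experiment(nb))
  expect_lte(length(select_hvg(d0)) / nrow(d0), 0.05)
  # planted high-variance genes are recovered
  hot <- matrix(rnbinom(20 * 600, mu = rep(mu[1:20], 600), size = 0.2),
                nrow = 20)
  m2 <- rbind(nb, hot)
  rownames(m2) <- sprintf("g%03d", seq_len(nrow(m2)))
  d1 <- fit_dispersion(toy_experiment(m2))
  expect_true(all(sprintf("g%03d", 501:520) %in% select_hvg(d1)))
})
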