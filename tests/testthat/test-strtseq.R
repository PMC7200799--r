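test_that("read pairs parse positionally into barcode and UMI", {
  wl <- c("AAAACCCC", "GGGGTTTT", "ACGTACGT")
  res <- parse_read_pairs(paste0("AAAACCCC", "GGGGTTTT", strrep("T", 20)), wl)
  expect_identical(res$barcode, "AAAACCCC")
  expect_identical(res$umi, "GGGGTTTT")
  expect_identical(res$status, "ok")
  # a 15 nt read2 cannot carry barcode + UMI
  short <- parse_read_pairs(strrep("A", 15), wl)
  expect_identical(short$status, "too_short")
  expect_true(is.na(short$barcode))
})

test_that("barcode rescue matches a brute-force Hamming search", {
  withr::local_seed(21)
  wl <- default_whitelist(48)
  mutate_at <- function(bc, pos) {
    s <- strsplit(bc, "")[[1]]
    s[pos] <- setdiff(c("A", "C", "G", "T"), s[pos])[1]
    paste(s, collapse = "")
  }
  queries <- unname(c(wl[1:5],
               vapply(wl[6:15], mutate_at, character(1), pos = 3),
               replicate(10, paste(sample(c("A", "C", "G", "T"), 8,
                                          replace = TRUE), collapse = ""))))
  r2 <- paste0(queries, strrep("T", 30))
  strict <- parse_read_pairs(r2, wl, max_mismatch = 0)
  lenient <- parse_read_pairs(r2, wl, max_mismatch = 1)
  # oracle: full Hamming-distance scan of the whitelist
  hdist <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in seq_along(queries)) {
    d <- vapply(wl, hdist, numeric(1), a = queries[i])
    expect_identical(strict$status[i] == "ok", any(d == 0))
    if (any(d == 0)) {
      expect_identical(lenient$barcode[i], queries[i])
    } else if (sum(d == 1) == 1) {
      expect_identical(lenient$status[i], "ok")
      expect_identical(lenient$barcode[i], wl[d == 1])
    } else if (sum(d == 1) > 1) {
      expect_identical(lenient$status[i], "barcode_ambiguous")
    } else {
      expect_identical(lenient$status[i], "barcode_unmatched")
    }
  }
})

test_that("trimming strips TSO, adapter and polyA and nothing else", {
  expect_identical(trim_reads(paste0("ACGTACGTACGT", strrep("A", 15))),
                   "ACGTACGTACGT")
  # a 9-A run is below the polyA minimum and is kept
  expect_identical(trim_reads(paste0("ACGT", strrep("A", 9))),
                   paste0("ACGT", strrep("A", 9)))
  expect_identical(trim_reads("GGCCATTA"), "GGCCATTA")
  tso <- "AAGCAGTGGT"; ad <- "CTGTCTCTTATACACA"
  insert <- "TTGACCGGTACGATCGGACT"
  expect_identical(trim_reads(paste0(tso, insert, ad), tso = tso, adapter = ad),
                   insert)
  # partial 3' adapter overlap
  expect_identical(
    trim_reads(paste0(insert, substr(ad, 1, 7)), tso = tso, adapter = ad),
    insert)
  # oracle: brute-force pattern stripping
  strip <- function(s) {
    if (startsWith(s, tso)) s <- substring(s, nchar(tso) + 1)
    for (k in rev(5:nchar(ad)))
      if (endsWith(s, substr(ad, 1, k))) {
        s <- substr(s, 1, nchar(s) - k); break
      }
    sub("A{10,}$", "", s)
  }
  withr::local_seed(5)
  cases <- replicate(40, {
    ins <- paste(sample(c("C", "G", "T"), sample(30:60, 1), replace = TRUE),
                 collapse = "")
    paste0(if (runif(1) < 0.5) tso else "", ins,
           if (runif(1) < 0.4) strrep("A", sample(10:20, 1)) else "",
           if (runif(1) < 0.4) substr(ad, 1, sample(5:nchar(ad), 1)) else "")
  })
  expect_identical(trim_reads(cases, tso = tso, adapter = ad),
                   vapply(cases, strip, character(1), USE.NAMES = FALSE))
})

test_that("read QC applies the length and N-fraction boundaries exactly", {
  expect_false(qc_reads(strrep("C", 36)))   # shorter than 37 fails
  expect_true(qc_reads(strrep("C", 37)))    # 37 passes
  expect_false(qc_reads(paste0(strrep("N", 11), strrep("C", 89))))  # 11% N
  expect_true(qc_reads(paste0(strrep("N", 10), strrep("C", 90))))   # 10% N
  expect_identical(qc_reads(c("", strrep("G", 100))), c(FALSE, TRUE))
})

test_that("k-mer vote assigns unambiguous reads and refuses ties", {
  tr <- make_toy_transcriptome(c("gA", "gB", "gC"), length = 300, seed = 2L)
  expect_identical(assign_genes(substr(tr[["gA"]], 50, 130), tr), "gA")
  # half-and-half chimeric read votes equally for two genes
  chimera <- paste0(substr(tr[["gA"]], 1, 30), substr(tr[["gB"]], 1, 30))
  expect_true(is.na(assign_genes(chimera, tr)))
  # no matching k-mers at all
  expect_true(is.na(assign_genes(strrep("A", 60), tr)))
  # shared sequence between transcripts is ambiguous and never counted
  tr2 <- c(gX = tr[["gA"]], gY = tr[["gA"]])
  expect_true(is.na(assign_genes(substr(tr[["gA"]], 10, 90),
                                 structure(tr2, class = "toy_transcriptome"))))
  # simulated reads from orthogonal transcripts assign perfectly
  withr::local_seed(3)
  reads <- vapply(sample(names(tr), 50, replace = TRUE), function(g) {
    s <- sample.int(nchar(tr[[g]]) - 80, 1)
    substr(tr[[g]], s, s + 79)
  }, character(1))
  expect_identical(unname(assign_genes(reads, tr)),
                   unname(names(reads)))
})

test_that("UMI collapsing counts distinct UMIs and is order-invariant", {
  ev <- tibble::tibble(cell_id = "c1", gene = "g1",
                       umi = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC"))
  expect_identical(collapse_umis(ev)$counts["g1", "c1"], 2L)
  # empty event list over declared dimensions
  empty <- collapse_umis(tibble::tibble(cell_id = character(0),
                                        gene = character(0),
                                        umi = character(0)),
                         cells = c("c1", "c2"), genes = c("g1", "g2"))
  expect_identical(sum(empty$counts), 0L)
  expect_identical(dim(empty$counts), c(2L, 2L))

  withr::local_seed(13)
  ev <- tibble::tibble(
    cell_id = sample(sprintf("c%02d", 1:8), 3000, replace = TRUE),
    gene = sample(sprintf("g%02d", 1:12), 3000, replace = TRUE),
    umi = sample(int_to_umi(sample.int(200, 3000, replace = TRUE), 8)))
  m <- collapse_umis(ev)
  # set-based oracle
  oracle <- tapply(ev$umi, list(factor(ev$gene, rownames(m$counts)),
                                factor(ev$cell_id, colnames(m$counts))),
                   function(u) length(unique(u)))
  oracle[is.na(oracle)] <- 0
  expect_identical(unname(m$counts), unname(matrix(as.integer(oracle),
                                                   nrow = nrow(oracle))))
  # idempotence and shuffle invariance
  expect_identical(collapse_umis(dplyr::bind_rows(ev, ev))$counts, m$counts)
  expect_identical(collapse_umis(ev[sample(nrow(ev)), ])$counts, m$counts)
  # counts never exceed read counts; equal iff all UMIs distinct
  reads <- dplyr::count(ev, cell_id, gene)
  idx <- cbind(match(reads$gene, rownames(m$counts)),
               match(reads$cell_id, colnames(m$counts)))
  expect_true(all(m$counts[idx] <= reads$n))
})

test_that("demultiplexing reproduces the simulated truth exactly", {
  cfg <- small_sim_config(seed = 17L, n_genes = 30L, n_ercc = 4L,
                          cells_per_monkey = 5L,
                          baseline_log_mean_mu = log(3))
  sim <- simulate_counts(cfg)
  tr <- make_toy_transcriptome(sim$experiment$genes$gene_id, length = 400,
                               seed = 8L)
  r1 <- withr::local_tempfile(fileext = ".fq")
  r2 <- withr::local_tempfile(fileext = ".fq")
  truth <- simulate_reads(cfg, tr, r1, r2, experiment = sim$experiment)
  res <- demux_fastq(r1, r2, cfg$whitelist, tr)
  expect_identical(res$report$outcome, "ok")
  bcmap <- dplyr::distinct(truth, cell_id, barcode)
  want <- sim$experiment$counts[, bcmap$cell_id, drop = FALSE]
  colnames(want) <- bcmap$barcode
  used <- rownames(want)[rowSums(want) > 0]
  got <- res$experiment$counts[used, colnames(want), drop = FALSE]
  expect_identical(got, want[used, , drop = FALSE])
  # demux emits the per-cell alignment metadata the QC filters need
  expect_true(all(c("aligned_reads", "mapping_ratio") %in%
                    names(res$experiment$cells)))
  expect_true(all(res$experiment$cells$mapping_ratio == 1))
})
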