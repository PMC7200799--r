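#' Parse barcoded read pairs into (barcode, UMI) assignments
#'
#' In the STRT-style layout the first 8 nt of Read 2 are the cell barcode and
#' the next 8 nt the UMI (positions 1-8 and 9-16, 1-based inclusive; the
#' remainder is oligo-dT and ignored). Barcodes are matched to the whitelist
#' exactly by default; with `max_mismatch = 1` a barcode is rescued iff it has
#' a unique whitelist neighbour at Hamming distance 1 (ambiguous rescues are
#' rejected).
#'
#' @param read2 character vector of Read 2 sequences.
#' @param whitelist character vector of valid 8 nt barcodes.
#' @param max_mismatch 0 (exact) or 1 (unique Hamming-1 rescue).
#' @return Tibble with columns `barcode`, `umi`, `status`
#'   (`"ok"`, `"too_short"`, `"barcode_unmatched"`, `"barcode_ambiguous"`).
#'   Rescued barcodes are reported corrected to their whitelist form.
#' @export
parse_read_pairs <- function(read2, whitelist, max_mismatch = 0) {
  stopifnot(max_mismatch %in% c(0, 1))
  n <- length(read2)
  bc <- substr(read2, 1L, 8L)
  umi <- substr(read2, 9L, 16L)
  status <- rep("ok", n)
  short <- nchar(read2) < 16L
  status[short] <- "too_short"

  hit <- bc %in% whitelist
  need <- !short & !hit
  if (max_mismatch == 1 && any(need)) {
    res <- vapply(bc[need], hamming1_rescue, character(1), whitelist = whitelist)
    bc[need] <- ifelse(is.na(res) | res %in% c("", "AMBIG"), bc[need], res)
    status[need][res == "AMBIG"] <- "barcode_ambiguous"
    status[need][res == ""] <- "barcode_unmatched"
  } else {
    status[need] <- "barcode_unmatched"
  }
  bad <- status != "ok"
  bc[bad] <- NA_character_
  umi[bad] <- NA_character_
  tibble::tibble(barcode = bc, umi = umi, status = status)
}

# unique Hamming-1 neighbour in the whitelist, "" if none, "AMBIG" if several
hamming1_rescue <- function(bc, whitelist) {
  cand <- whitelist[hamming_distance(bc, whitelist) == 1L]
  if (length(cand) == 1L) cand else if (length(cand) == 0L) "" else "AMBIG"
}

hamming_distance <- function(x, ys) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(ys, ""), function(y) {
    if (length(y) != length(xs)) return(NA_integer_)
    sum(y != xs)
  }, integer(1))
}

#' Trim template-switch oligo, polyA and adapter from cDNA reads
#'
#' Removes, in order: a configured TSO prefix (exact match at the 5' end), a
#' configured adapter (exact suffix, or the longest adapter prefix of at
#' least `min_overlap` nt overhanging the 3' end), and a trailing polyA run
#' of at least `min_polya` nt. An empty result is allowed; [qc_reads()]
#' rejects it later.
#'
#' @param reads character vector of cDNA (Read 1) sequences.
#' @param tso,adapter sequences to strip; NULL disables that step. The
#'   emulated protocol does not publish its oligo sequences, so both default
#'   to NULL and are configuration-supplied placeholders.
#' @param min_polya minimum trailing polyA run length to trim (default 10).
#' @param min_overlap minimum adapter prefix overlap at the read 3' end.
#' @return Character vector of trimmed reads.
#' @export
trim_reads <- function(reads, tso = NULL, adapter = NULL, min_polya = 10L,
                       min_overlap = 5L) {
  out <- reads
  if (!is.null(tso) && nzchar(tso)) {
    has <- startsWith(out, tso)
    out[has] <- substr(out[has], nchar(tso) + 1L, nchar(out[has]))
  }
  if (!is.null(adapter) && nzchar(adapter)) {
    # strip one adapter occurrence: the longest prefix of the adapter
    # (full length down to min_overlap) matching the read's 3' end
    done <- rep(FALSE, length(out))
    for (k in rev(seq(min_overlap, nchar(adapter)))) {
      pre <- substr(adapter, 1L, k)
      has <- !done & endsWith(out, pre)
      out[has] <- substr(out[has], 1L, nchar(out[has]) - k)
      done <- done | has
    }
  }
  out <- sub(sprintf("A{%d,}$", as.integer(min_polya)), "", out)
  out
}

#' Read-level quality control
#'
#' A read fails iff it is shorter than `min_length` (default 37 nt) or its
#' fraction of undetermined nucleotides exceeds `max_n_frac` (default 10%,
#' strictly: 10% exactly still passes).
#'
#' @param reads character vector of (trimmed) cDNA sequences.
#' @param min_length minimum read length kept (37: a 36 nt read fails).
#' @param max_n_frac maximum tolerated N fraction (0.10).
#' @return Logical vector, TRUE = pass.
#' @export
qc_reads <- function(reads, min_length = 37L, max_n_frac = 0.10) {
  len <- nchar(reads)
  n_n <- nchar(reads) - nchar(gsub("N", "", reads, fixed = TRUE))
  len >= min_length & ifelse(len > 0, n_n / len, 1) <= max_n_frac
}

#' Assign reads to genes by k-mer majority vote
#'
#' A toy stand-in for genome alignment: every transcript's k-mers are
#' indexed; a read is assigned to the gene that receives a strict majority of
#' its exact k-mer matches, and left unassigned on a tie or when no k-mer
#' matches (only unambiguous assignments are counted). K-mers shared by
#' several transcripts are dropped from the index.
#'
#' @param reads character vector of trimmed, QC-passing cDNA sequences.
#' @param transcriptome a [make_toy_transcriptome()] (named sequences).
#' @param k k-mer length (default 21; must not exceed the read length to get
#'   any votes).
#' @return Character vector of gene identifiers, NA where unassigned.
#' @export
assign_genes <- function(reads, transcriptome, k = 21L) {
  stopifnot(length(transcriptome) > 0)
  idx <- kmer_index(transcriptome, k)
  vote <- function(read) {
    if (nchar(read) < k) return(NA_character_)
    kmers <- unique(substring(read, 1:(nchar(read) - k + 1L),
                              k:nchar(read)))
    hits <- idx[kmers]
    hits <- hits[!is.na(hits) & hits != ""]
    if (length(hits) == 0) return(NA_character_)
    tab <- table(hits)
    top <- tab[tab == max(tab)]
    if (length(top) > 1L || max(tab) * 2L <= length(hits)) return(NA_character_)
    names(top)
  }
  vapply(reads, vote, character(1), USE.NAMES = FALSE)
}

# named vector kmer -> gene; multi-gene kmers mapped to "" (ambiguous)
kmer_index <- function(transcriptome, k) {
  per_gene <- lapply(names(transcriptome), function(g) {
    s <- transcriptome[[g]]
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  kmers <- unlist(per_gene)
  genes <- rep(names(transcriptome), lengths(per_gene))
  dup <- kmers %in% kmers[duplicated(kmers)]
  idx <- genes
  idx[dup] <- ""
  stats::setNames(idx, kmers)[!duplicated(kmers)]
}

#' Collapse UMI events into a count matrix
#'
#' Reads sharing the same (cell, gene, UMI) are merged as one molecule:
#' count(cell, gene) is the number of distinct UMI strings observed for that
#' pair. The operation is idempotent and order-independent.
#'
#' @param events tibble/data.frame with columns `cell_id` (or `barcode`),
#'   `gene`, `umi`; one row per read or per event.
#' @param cells,genes optional identifier vectors fixing the output
#'   dimensions (cells/genes with no events get zero columns/rows).
#' @param cell_meta optional tibble of per-cell metadata joined by `cell_id`.
#' @return A [umi_experiment()] of UMI counts.
#' @export
collapse_umis <- function(events, cells = NULL, genes = NULL, cell_meta = NULL) {
  events <- tibble::as_tibble(events)
  if (!"cell_id" %in% names(events) && "barcode" %in% names(events))
    events <- dplyr::rename(events, cell_id = "barcode")
  stopifnot(all(c("cell_id", "gene", "umi") %in% names(events)))
  cells <- cells %||% sort(unique(events$cell_id))
  genes <- genes %||% sort(unique(events$gene))
  counts <- matrix(0L, nrow = length(genes), ncol = length(cells),
                   dimnames = list(genes, cells))
  if (nrow(events) > 0) {
    uniq <- dplyr::distinct(events, .data$cell_id, .data$gene, .data$umi) |>
      dplyr::count(.data$cell_id, .data$gene)
    counts[cbind(match(uniq$gene, genes), match(uniq$cell_id, cells))] <- uniq$n
  }
  gene_tbl <- tibble::tibble(gene_id = genes,
                             is_ercc = startsWith(genes, "ERCC-"))
  cell_tbl <- tibble::tibble(cell_id = cells)
  if (!is.null(cell_meta))
    cell_tbl <- dplyr::left_join(cell_tbl, tibble::as_tibble(cell_meta),
                                 by = "cell_id")
  umi_experiment(counts, gene_tbl, cell_tbl)
}

#' Demultiplex paired FASTQ files into a UMI count matrix
#'
#' Full read-processing chain: parse Read 2 into barcode + UMI, trim Read 1
#' (TSO / adapter / polyA), apply read QC (length >= 37, N <= 10%), assign
#' genes by k-mer vote, and collapse UMIs within (cell, gene). Per-cell
#' `aligned_reads` (gene-assigned read count) and `mapping_ratio`
#' (assigned / QC-passing reads) are emitted into the cell metadata so the
#' downstream cell filters can be applied.
#'
#' @param r1_path,r2_path FASTQ paths (Read 1 = cDNA, Read 2 = barcode+UMI).
#' @param whitelist barcode whitelist (character vector, or path to a text
#'   file with one barcode per line).
#' @param transcriptome a [make_toy_transcriptome()] or FASTA path.
#' @param max_mismatch barcode matching tolerance (0 or 1).
#' @param tso,adapter,min_polya trimming configuration, see [trim_reads()].
#' @param k k-mer length for [assign_genes()].
#' @return List: `experiment` (a [umi_experiment()], cells keyed by barcode),
#'   `report` (tibble of read counts by processing outcome).
#' @export
demux_fastq <- function(r1_path, r2_path, whitelist, transcriptome,
                        max_mismatch = 0, tso = NULL, adapter = NULL,
                        min_polya = 10L, k = 21L) {
  if (length(whitelist) == 1 && file.exists(whitelist))
    whitelist <- readLines(whitelist)
  if (is.character(transcriptome) && length(transcriptome) == 1 &&
      file.exists(transcriptome))
    transcriptome <- read_transcriptome(transcriptome)
  r1 <- as.character(Biostrings::readDNAStringSet(r1_path, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(r2_path, format = "fastq"))
  if (length(r1) != length(r2))
    stop("R1 and R2 have different read counts (", length(r1), " vs ", length(r2), ")")

  parsed <- parse_read_pairs(r2, whitelist, max_mismatch = max_mismatch)
  trimmed <- trim_reads(r1, tso = tso, adapter = adapter, min_polya = min_polya)
  qc_ok <- qc_reads(trimmed)

  stage <- dplyr::case_when(
    parsed$status != "ok" ~ parsed$status,
    !qc_ok ~ "read_qc_fail",
    TRUE ~ "ok"
  )
  keep <- stage == "ok"
  gene <- rep(NA_character_, length(r1))
  gene[keep] <- assign_genes(trimmed[keep], transcriptome, k = k)
  stage[keep & is.na(gene)] <- "unassigned"
  final <- stage == "ok"

  report <- tibble::as_tibble(table(outcome = stage), .name_repair = "minimal")
  names(report) <- c("outcome", "reads")

  events <- tibble::tibble(cell_id = parsed$barcode[final],
                           gene = gene[final],
                           umi = parsed$umi[final])
  exper <- collapse_umis(events)
  per_bc_qc <- table(factor(parsed$barcode[stage %in% c("ok", "unassigned")],
                            levels = exper$cells$cell_id))
  per_bc_assigned <- table(factor(parsed$barcode[final],
                                  levels = exper$cells$cell_id))
  exper$cells$aligned_reads <- as.integer(per_bc_assigned)
  exper$cells$mapping_ratio <- ifelse(per_bc_qc > 0,
                                      as.numeric(per_bc_assigned) / as.numeric(per_bc_qc),
                                      NA_real_)
  list(experiment = exper, report = report)
}
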