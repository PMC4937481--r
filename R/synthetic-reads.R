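# RNA-seq read simulation: error-free fixed-length reads emitted
# pre-aligned (SAM). Exonic coverage is Poisson in expression x length;
# intronic coverage additionally carries the post-splicing maintenance
# factor, elevated for structured introns.

#' Simulate mapped RNA-seq reads for the focal genome
#'
#' Per-gene exonic read counts are Poisson with mean proportional to
#' expression x exonic length; per-intron counts are Poisson with mean
#' proportional to expression x maintenance factor x intron length.
#' Reads are placed uniformly within their feature and recorded with
#' the true per-feature counts in a ledger.
#'
#' @param sim a `genome_sim` object from [simulate_genome_set()].
#' @param params the [sim_params()] used (defaults to the generating
#'   parameters recorded in the truth ledger).
#' @param path optional path; when given, reads are also written as SAM.
#' @return A list with `reads` (tibble: `qname`, `chrom`, `start`,
#'   `span`, `strand`, `seq`), `total_mapped`, `ledger` (tibble:
#'   `feature_id`, `class`, `gene_id`, `true_count`, `length`), and
#'   `chrom_lengths`.
#' @export
simulate_reads <- function(sim, params = sim$truth$params, path = NULL) {
  set.seed(stage_seed(params, "reads"))
  ann <- sim$annotations
  genes <- sim$truth$genes
  chrom <- get_chrom(sim$genomes, "focal", "chrI")
  rl <- params$read_length

  reads <- list()
  ledger <- list()
  for (i in seq_len(nrow(ann))) {
    gid <- ann$gene_id[i]
    info <- genes[genes$gene_id == gid, ]
    ex <- ann$exons[[i]]
    introns <- ann$introns[[i]]
    exon_len <- sum(ex$end - ex$start)
    n_ex <- rpois(1, info$expression * (exon_len / 1000) * params$depth)
    ledger[[length(ledger) + 1]] <- tibble(
      feature_id = gid, class = "CDS", gene_id = gid,
      true_count = n_ex, length = exon_len)
    if (n_ex > 0) {
      # distribute across exons by length, place uniformly inside
      w <- (ex$end - ex$start) / exon_len
      which_ex <- sample(nrow(ex), n_ex, replace = TRUE, prob = w)
      for (k in seq_len(n_ex)) {
        e <- ex[which_ex[k], ]
        len <- min(rl, e$end - e$start)
        s <- e$start + sample.int(e$end - e$start - len + 1L, 1) - 1L
        reads[[length(reads) + 1]] <- c(start = s, len = len)
      }
    }
    if (nrow(introns) > 0) {
      iv <- introns[1, ]
      ilen <- iv$end - iv$start
      n_in <- rpois(1, info$expression * info$maintenance_factor *
                      (ilen / 1000) * params$depth)
      iid <- paste0(gid, ".i1")
      ledger[[length(ledger) + 1]] <- tibble(
        feature_id = iid, class = "intron", gene_id = gid,
        true_count = n_in, length = ilen)
      if (n_in > 0) {
        for (k in seq_len(n_in)) {
          len <- min(rl, ilen)
          s <- iv$start + sample.int(ilen - len + 1L, 1) - 1L
          reads[[length(reads) + 1]] <- c(start = s, len = len)
        }
      }
    }
  }
  ledger <- bind_rows(ledger)
  mat <- do.call(rbind, reads)
  if (is.null(mat)) mat <- matrix(integer(), ncol = 2,
                                  dimnames = list(NULL, c("start", "len")))
  reads_tbl <- tibble(
    qname = sprintf("read%06d", seq_len(nrow(mat))),
    chrom = "chrI",
    start = as.integer(mat[, "start"]),
    span = as.integer(mat[, "len"]),
    strand = "+"
  )
  reads_tbl$seq <- vapply(seq_len(nrow(reads_tbl)), function(k) {
    subseq0(chrom, reads_tbl$start[k], reads_tbl$start[k] + reads_tbl$span[k])
  }, "")
  chrom_lengths <- c(chrI = nchar(chrom))
  if (!is.null(path)) write_sam(reads_tbl, chrom_lengths, path)
  list(reads = reads_tbl, total_mapped = nrow(reads_tbl),
       ledger = ledger, chrom_lengths = chrom_lengths)
}

#' Simulate per-gene counts directly (no read placement)
#'
#' A fast counts-level twin of [simulate_reads()] for calibration
#' studies that only need an expression table: draws the same Poisson
#' counts per CDS and intron without materialising reads.
#'
#' @param sim a `genome_sim` object.
#' @param params simulation parameters.
#' @return A tibble with `feature_id`, `class`, `gene_id`, `count`,
#'   `length`.
#' @export
simulate_feature_counts <- function(sim, params = sim$truth$params) {
  ann <- sim$annotations
  genes <- sim$truth$genes
  rows <- purrr::map(seq_len(nrow(ann)), function(i) {
    gid <- ann$gene_id[i]
    info <- genes[genes$gene_id == gid, ]
    exon_len <- sum(ann$exons[[i]]$end - ann$exons[[i]]$start)
    out <- tibble(feature_id = gid, class = "CDS", gene_id = gid,
                  count = rpois(1, info$expression * exon_len / 1000 *
                                  params$depth),
                  length = exon_len)
    if (nrow(ann$introns[[i]]) > 0) {
      ilen <- ann$introns[[i]]$end[1] - ann$introns[[i]]$start[1]
      out <- bind_rows(out, tibble(
        feature_id = paste0(gid, ".i1"), class = "intron", gene_id = gid,
        count = rpois(1, info$expression * info$maintenance_factor *
                        ilen / 1000 * params$depth),
        length = ilen))
    }
    out
  })
  bind_rows(rows)
}

#' Simulate CRAC cross-linking count tables
#'
#' One table per pseudo-experiment: per-gene counts are Poisson with
#' mean proportional to gene expression times a per-experiment library
#' scale, multiplied by the enrichment factor for structured-intron
#' genes.
#'
#' @param sim a `genome_sim` object.
#' @param params simulation parameters (`n_crac_experiments`,
#'   `crac_enrichment`).
#' @param dir optional directory; when given, tables are written as
#'   `crac_expt_01.tsv` ... with columns `gene_id`, `count`.
#' @return A named list of tibbles (`gene_id`, `count`), one per
#'   experiment.
#' @export
simulate_crac <- function(sim, params = sim$truth$params, dir = NULL) {
  set.seed(stage_seed(params, "crac"))
  genes <- sim$truth$genes |> filter(.data$has_intron)
  mult <- ifelse(genes$structured, params$crac_enrichment, 1)
  out <- purrr::map(seq_len(params$n_crac_experiments), function(e) {
    lib <- rlnorm(1, 0, 0.3)  # per-experiment library depth
    tibble(gene_id = genes$gene_id,
           count = rpois(nrow(genes), 0.5 * lib * genes$expression * mult))
  })
  names(out) <- sprintf("crac_expt_%02d", seq_along(out))
  if (!is.null(dir)) {
    for (nm in names(out)) {
      write_tsv_meta(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     meta = c(experiment = nm))
    }
  }
  out
}
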