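# GFF3 reading/writing via rtracklayer. GFF3 is 1-based inclusive;
# everything downstream of these functions uses 0-based half-open
# coordinates. Introns are derived as the gaps between consecutive
# exons, and exon/intron lists are kept in transcription order
# (genomic-descending for minus-strand genes).

#' Read gene annotations from GFF3
#'
#' @param path path to a GFF3 file with `gene` and `exon` features
#'   (exons carry a `Parent` attribute naming the gene).
#' @param genomes optional genome tibble from [read_fasta()]; when
#'   supplied, exons falling outside their chromosome are an error.
#' @param species_id species label for the annotations.
#' @return A tibble with one row per gene: `gene_id`, `species_id`,
#'   `chrom_id`, `strand`, and list-columns `exons` and `introns`
#'   holding tibbles of 0-based half-open `start`/`end` intervals in
#'   transcription order. Single-exon genes have zero-row `introns`.
#' @export
read_gff3 <- function(path, genomes = NULL, species_id = "focal") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  is_gene <- meta$type == "gene"
  is_exon <- meta$type == "exon"
  if (!any(is_gene) || !any(is_exon)) {
    abort("GFF3 must contain gene and exon features")
  }
  genes <- gr[is_gene]
  exons <- gr[is_exon]
  parent_raw <- S4Vectors::mcols(exons)$Parent
  parent <- vapply(as.list(parent_raw), function(p) as.character(p)[1], "")
  gene_ids <- as.character(S4Vectors::mcols(genes)$ID)

  out <- purrr::map(seq_along(genes), function(i) {
    gid <- gene_ids[i]
    strand <- as.character(BiocGenerics::strand(genes[i]))
    chrom <- as.character(GenomicRanges::seqnames(genes[i]))
    ex <- exons[parent == gid]
    if (length(ex) == 0) abort(sprintf("gene %s has no exons", gid))
    iv <- gff_to_internal(BiocGenerics::start(ex), BiocGenerics::end(ex)) |>
      arrange(.data$start)
    if (nrow(iv) > 1 &&
        any(iv$start[-1] < iv$end[-nrow(iv)])) {
      abort(sprintf("overlapping exons in gene %s", gid))
    }
    if (!is.null(genomes)) {
      clen <- nchar(get_chrom(genomes, species_id, chrom))
      if (any(iv$start < 0) || any(iv$end > clen)) {
        abort(sprintf("exon outside chromosome bounds in gene %s", gid))
      }
    }
    introns <- if (nrow(iv) > 1) {
      tibble(start = iv$end[-nrow(iv)], end = iv$start[-1])
    } else {
      tibble(start = integer(), end = integer())
    }
    if (strand == "-") {  # transcription order
      iv <- iv[rev(seq_len(nrow(iv))), ]
      introns <- introns[rev(seq_len(nrow(introns))), ]
    }
    tibble(gene_id = gid, species_id = species_id, chrom_id = chrom,
           strand = strand, exons = list(iv), introns = list(introns))
  })
  bind_rows(out)
}

#' Write gene annotations to GFF3
#'
#' @param genes annotation tibble in the layout produced by
#'   [read_gff3()] or [simulate_genome_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- purrr::pmap(genes, function(gene_id, species_id, chrom_id,
                                      strand, exons, introns, ...) {
    ex <- exons |> arrange(.data$start)
    g <- internal_to_gff(min(ex$start), max(ex$end))
    lines <- sprintf("%s\tintronscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     chrom_id, g$start, g$end, strand, gene_id)
    eg <- internal_to_gff(ex$start, ex$end)
    lines <- c(lines, sprintf(
      "%s\tintronscreen\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
      chrom_id, eg$start, eg$end, strand, gene_id,
      seq_len(nrow(eg)), gene_id))
    lines
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Extract the spliced CDS of a gene in transcript sense
#'
#' @param gene one row of an annotation tibble.
#' @param genomes genome tibble.
#' @return A character scalar (transcript-sense DNA).
#' @export
gene_cds <- function(gene, genomes) {
  chrom <- get_chrom(genomes, gene$species_id, gene$chrom_id)
  ex <- gene$exons[[1]] |> arrange(.data$start)
  parts <- purrr::map_chr(seq_len(nrow(ex)),
                          function(i) subseq0(chrom, ex$start[i], ex$end[i]))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Extract an intron sequence in transcript sense
#'
#' @param gene one row of an annotation tibble.
#' @param genomes genome tibble.
#' @param which index of the intron in transcription order.
#' @return A character scalar; minus-strand introns are reverse
#'   complemented into the sense of the host transcript.
#' @export
intron_seq <- function(gene, genomes, which = 1) {
  introns <- gene$introns[[1]]
  if (nrow(introns) < which) abort("gene has no such intron")
  chrom <- get_chrom(genomes, gene$species_id, gene$chrom_id)
  s <- subseq0(chrom, introns$start[which], introns$end[which])
  if (gene$strand == "-") s <- revcomp(s)
  s
}
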