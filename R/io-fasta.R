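# FASTA reading/writing. Parsing is delegated to Biostrings; this layer
# enforces the pipeline's alphabet contract ({A,C,G,T,N}, uppercase,
# U mapped to T) and reports offending records by name.

#' Read a FASTA file into a genome tibble
#'
#' @param path path to a FASTA file.
#' @param species_id species label attached to every record; defaults to
#'   the file name without extension.
#' @return A tibble with columns `species_id`, `chrom_id`, `residues`.
#'   Residues are uppercased and U is mapped to T; characters outside
#'   \{A,C,G,T,N\} are an error naming the record.
#' @export
read_fasta <- function(path, species_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- chartr("u", "t", toupper(as.character(recs)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("illegal characters in FASTA record '%s'", ids[bad][1]))
  }
  if (is.null(species_id)) {
    species_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                      basename(path), ignore.case = TRUE)
  }
  tibble(species_id = species_id, chrom_id = ids, residues = unname(seqs))
}

#' Write a genome tibble (or any named sequence set) to FASTA
#'
#' @param x a tibble with `chrom_id` and `residues` columns, or a named
#'   character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- setNames(x$residues, x$chrom_id)
  } else {
    seqs <- x
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @noRd
get_chrom <- function(genomes, species, chrom) {
  hit <- genomes$residues[genomes$species_id == species &
                            genomes$chrom_id == chrom]
  if (length(hit) != 1) {
    abort(sprintf("chromosome %s/%s not found", species, chrom))
  }
  hit
}
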