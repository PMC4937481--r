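# The published conservation table of predicted intronic structures,
# shipped as a plain-text fixture. Rows describing a duplicated
# ribosomal gene pair carry the paralogous locus in extra columns;
# expanding them yields one row per predicted-structure intron.

#' Read the conservation table of predicted intronic structures
#'
#' @param path path to the TSV (defaults to the copy shipped with the
#'   package).
#' @return A tibble with one row per table entry: `no`, `locus`,
#'   `gene`, `paralog_locus`, `paralog_gene`, `conservation`, `note`.
#' @export
read_conservation_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "structure_conservation.tsv",
                        package = "intronscreen")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE) |>
    mutate(across(c("paralog_locus", "paralog_gene", "note"),
                  ~ ifelse(is.na(.x), "", .x)))
}

#' Expand paralog rows into one row per predicted-structure intron
#'
#' @param tab tibble from [read_conservation_table()].
#' @return A tibble with `locus`, `gene`, `conservation`, `note`,
#'   `is_rp` (gene name starts RPL/RPS) and `is_snorna` (known snoRNA
#'   annotated in the note); one row per intron.
#' @export
expand_conservation_table <- function(tab = read_conservation_table()) {
  main <- tab |> select("locus", "gene", "conservation", "note")
  paralogs <- tab |>
    filter(nzchar(.data$paralog_locus)) |>
    select(locus = "paralog_locus", gene = "paralog_gene",
           "conservation", "note")
  bind_rows(main, paralogs) |>
    mutate(is_rp = grepl("^RP[LS]", .data$gene),
           is_snorna = grepl("^snR", .data$note))
}

#' Summary counts of the conservation table
#'
#' @param expanded tibble from [expand_conservation_table()].
#' @return A list with `n_introns` (predicted-structure introns after
#'   paralog expansion) and `n_rp` (those in ribosomal-protein genes).
#' @export
conservation_counts <- function(expanded = expand_conservation_table()) {
  list(n_introns = nrow(expanded), n_rp = sum(expanded$is_rp))
}
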