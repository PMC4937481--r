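# Ortholog mapping: translated seed-and-extend search of each focal
# coding sequence against the comparison genomes (six frames, BLOSUM62
# 3-mer seeds with neighbourhood, X-drop extension, diagonal chaining
# across frames to bridge target introns), 65% query-coverage and
# e-value filters; then flank extension around gene hits and a
# nucleotide-level search (word size 3) for the orthologous intron with
# best-hit selection.
#
# E-values use a Karlin-Altschul style approximation with fixed
# (lambda, K) constants; they order hits consistently but are not
# calibrated against any external search engine.

#' @noRd
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      if (!"*" %in% rownames(m)) {
        m <- rbind(cbind(m, `*` = -4), `*` = c(rep(-4, ncol(m)), 1))
      }
      cache <<- m
    }
    cache
  }
})

#' @noRd
encode_protein <- function(x, alphabet) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], alphabet)
  codes[is.na(codes)] <- match("X", alphabet)
  codes
}

#' @noRd
translate_frames <- function(dna) {
  # all six frame translations; returns list of list(prot, frame, strand)
  out <- list()
  L <- nchar(dna)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (f in 0:2) {
      len <- (L - f) %/% 3 * 3
      if (len < 3) next
      prot <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1, f + len)),
        if.fuzzy.codon = "X")))
      out[[length(out) + 1]] <- list(prot = prot, frame = f, strand = strand)
    }
  }
  out
}

# BLOSUM62 neighbourhood of every query 3-mer: tibble(word, qpos) of
# all words scoring >= threshold against the query word at qpos.
# Computed once per query and reused across all target frames.
#' @noRd
query_neighborhoods <- function(qprot, subst, threshold) {
  alphabet <- rownames(subst)
  k <- 3L
  nq <- nchar(qprot)
  if (nq < k) return(tibble(word = character(), qpos = integer()))
  aa20 <- setdiff(alphabet, c("B", "Z", "X", "*"))
  out <- vector("list", nq - k + 1)
  qwords <- substring(qprot, 1:(nq - k + 1), k:nq)
  cache <- new.env()
  for (i in seq_along(qwords)) {
    w <- qwords[i]
    words <- cache[[w]]
    if (is.null(words)) {
      qa <- strsplit(w, "")[[1]]
      if (any(!qa %in% alphabet)) {
        words <- character(0)
      } else {
        s1 <- subst[qa[1], aa20]; s2 <- subst[qa[2], aa20]
        s3 <- subst[qa[3], aa20]
        grid <- outer(outer(s1, s2, "+"), s3, "+")
        keep <- which(grid >= threshold, arr.ind = TRUE)
        words <- if (nrow(keep)) {
          paste0(aa20[keep[, 1]], aa20[keep[, 2]], aa20[keep[, 3]])
        } else {
          character(0)
        }
      }
      cache[[w]] <- words
    }
    if (length(words)) out[[i]] <- tibble(word = words, qpos = i)
  }
  bind_rows(out)
}

# seed positions: join query neighbourhood words against the target
# 3-mer index; returns tibble(qpos, tpos)
#' @noRd
protein_seeds <- function(neigh, tindex) {
  if (nrow(neigh) == 0) return(tibble(qpos = integer(), tpos = integer()))
  hit <- tindex[neigh$word]
  lens <- lengths(hit)
  keep <- lens > 0
  if (!any(keep)) return(tibble(qpos = integer(), tpos = integer()))
  tibble(qpos = rep(neigh$qpos[keep], lens[keep]),
         tpos = unlist(hit[keep], use.names = FALSE))
}

# Precompute six-frame translations, integer codes and 3-mer indexes
# for every chromosome of the given species.
#' @noRd
build_target_index <- function(genomes, species, subst) {
  alphabet <- rownames(subst)
  idx <- list()
  for (sp in species) {
    chroms <- genomes[genomes$species_id == sp, ]
    for (ci in seq_len(nrow(chroms))) {
      frames <- translate_frames(chroms$residues[ci])
      frames <- purrr::map(frames, function(fr) {
        nt <- nchar(fr$prot)
        if (nt < 3 || grepl("^\\*+$", fr$prot)) return(NULL)
        twords <- substring(fr$prot, 1:(nt - 2), 3:nt)
        fr$tindex <- split(seq_along(twords), twords)
        fr$tcodes <- encode_protein(fr$prot, alphabet)
        fr
      })
      idx[[paste(sp, chroms$chrom_id[ci], sep = "\r")]] <- list(
        species_id = sp, chrom_id = chroms$chrom_id[ci],
        chrom_len = nchar(chroms$residues[ci]),
        frames = purrr::compact(frames))
    }
  }
  idx
}

# Ungapped X-drop extension of seed hits. A two-hit rule (two seeds on
# the same diagonal within `two_hit_window` residues) gates extension,
# and each diagonal is walked left to right so a seed already covered
# by an extended segment is skipped.
#' @noRd
extend_seeds <- function(seeds, qcodes, tcodes, subst, xdrop,
                         min_score = 40, two_hit_window = 40L) {
  if (nrow(seeds) == 0) return(tibble())
  seeds$diag <- seeds$tpos - seeds$qpos
  segs <- list()
  for (dd in split(seeds, seeds$diag)) {
    qp <- sort(unique(dd$qpos))
    if (length(qp) < 2) next
    close_next <- c(diff(qp) <= two_hit_window, FALSE)
    close_prev <- c(FALSE, diff(qp) <= two_hit_window)
    cand <- qp[close_next | close_prev]
    if (length(cand) == 0) next
    d <- dd$diag[1]
    covered <- -1L
    for (q in cand) {
      if (q <= covered) next
      ext <- .xdrop_extend_cpp(qcodes, tcodes, subst, q, q + d, 3L, xdrop)
      covered <- ext$a_end
      if (ext$score < min_score) next
      segs[[length(segs) + 1]] <- tibble(
        q_start = ext$a_start, q_end = ext$a_end,
        t_start = ext$b_start, t_end = ext$b_end,
        score = ext$score)
    }
  }
  bind_rows(segs) |> dplyr::distinct()
}

# protein-frame coordinates -> genomic nt interval (0-based half-open)
#' @noRd
frame_to_genomic <- function(t_start, t_end, frame, strand, chrom_len) {
  nt_start <- frame + 3L * (t_start - 1L)
  nt_end <- frame + 3L * t_end
  if (strand == "+") {
    c(nt_start, nt_end)
  } else {
    c(chrom_len - nt_end, chrom_len - nt_start)
  }
}

#' Translated search for gene orthologs in target genomes
#'
#' Six-frame translated seed-and-extend local search of the query CDS
#' against each target genome. Ungapped segments found in individual
#' frames are chained across frames along the genome (maximum
#' coordinate gap `max_chain_gap`), so a target gene whose intron
#' shifts the downstream exon into another frame still yields one
#' gene-level hit. Hits with query coverage below `min_coverage` or
#' e-value above `e_max_protein` are discarded; at most one hit is
#' retained per target locus.
#'
#' @param gene one row of an annotation tibble (the query gene).
#' @param genomes genome tibble holding the focal and target genomes.
#' @param target_species character vector of species to search
#'   (default: all species in `genomes` other than the query's).
#' @param params a [search_params()] object.
#' @param index optional precomputed target index (built internally
#'   when absent; [map_orthologs()] builds it once for all genes).
#' @return A tibble of translated hits: `query_gene`, `species_id`,
#'   `chrom_id`, `start`, `end` (genomic, 0-based half-open), `strand`,
#'   `score`, `evalue`, `query_coverage`.
#' @export
find_gene_orthologs <- function(gene, genomes,
                                target_species = NULL,
                                params = search_params(),
                                index = NULL) {
  subst <- blosum62()
  cds <- gene_cds(gene, genomes)
  cds <- substr(cds, 1, nchar(cds) %/% 3 * 3)
  if (nchar(cds) < 3 * params$word_protein) {
    return(tibble())  # CDS shorter than one seed: no-hit result
  }
  qprot <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X")))
  qlen <- nchar(qprot)
  qcodes <- encode_protein(qprot, rownames(subst))
  if (is.null(target_species)) {
    target_species <- unique(genomes$species_id)
  }
  if (is.null(index)) {
    index <- build_target_index(genomes, target_species, subst)
  }
  neigh <- query_neighborhoods(qprot, subst, params$seed_threshold)

  hits <- list()
  for (tgt in index) {
    if (!tgt$species_id %in% target_species) next
    clen <- tgt$chrom_len
    segs <- list()
    for (fr in tgt$frames) {
      seeds <- protein_seeds(neigh, fr$tindex)
      fs <- extend_seeds(seeds, qcodes, fr$tcodes, subst,
                         params$xdrop_protein,
                         min_score = params$min_segment_score)
      if (nrow(fs) == 0) next
      gpos <- t(vapply(seq_len(nrow(fs)), function(i) {
        frame_to_genomic(fs$t_start[i], fs$t_end[i], fr$frame,
                         fr$strand, clen)
      }, numeric(2)))
      segs[[length(segs) + 1]] <- fs |>
        mutate(g_start = gpos[, 1], g_end = gpos[, 2],
               strand = fr$strand)
    }
    segs <- bind_rows(segs)
    if (nrow(segs) == 0) next
    hits[[length(hits) + 1]] <- chain_segments(segs, params) |>
      mutate(query_gene = gene$gene_id, species_id = tgt$species_id,
             chrom_id = tgt$chrom_id,
             query_coverage = pmin(.data$q_cover / qlen, 1),
             evalue = params$k_protein * qlen * clen *
               exp(-params$lambda_protein * .data$score))
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(out)
  out |>
    filter(.data$query_coverage >= params$min_coverage,
           .data$evalue <= params$e_max_protein) |>
    select("query_gene", "species_id", "chrom_id", "start" = "g_start",
           "end" = "g_end", "strand", "score", "evalue",
           "query_coverage") |>
    arrange(.data$species_id, .data$evalue)
}

# Chain frame segments into gene-level hits. Segments are clustered by
# strand and genomic locus (gap <= max_chain_gap); within a cluster a
# colinear chain is grown greedily from the best-scoring segment:
# a segment joins only if it is consistent in both query and genomic
# order (transcript orientation on the minus strand) and within
# max_chain_gap of the chain.
#' @noRd
chain_segments <- function(segs, params) {
  segs <- segs |> arrange(.data$strand, .data$g_start)
  loci <- list()
  for (strand in unique(segs$strand)) {
    ss <- segs |> filter(.data$strand == !!strand)
    cluster <- cumsum(c(1, diff(ss$g_start) > params$max_chain_gap))
    for (cl in unique(cluster)) {
      cc <- ss[cluster == cl, ] |> arrange(desc(.data$score))
      kept <- cc[1, ]
      if (nrow(cc) > 1) {
        for (i in 2:nrow(cc)) {
          cand <- cc[i, ]
          # X-drop extensions overrun splice boundaries by a few
          # residues, so segments of adjacent exons may overlap
          # slightly in the query; reject only substantial overlaps
          q_over <- any(pmin(kept$q_end, cand$q_end) -
                          pmax(kept$q_start, cand$q_start) + 1 > 30)
          if (q_over) next
          # colinearity: query order must match transcript order
          consistent <- vapply(seq_len(nrow(kept)), function(j) {
            dq <- cand$q_start - kept$q_start[j]
            dg <- cand$g_start - kept$g_start[j]
            if (strand == "-") dg <- -dg
            sign(dq) == sign(dg) &&
              min(abs(cand$g_start - kept$g_end[j]),
                  abs(kept$g_start[j] - cand$g_end)) <=
                params$max_chain_gap
          }, logical(1))
          if (all(consistent)) kept <- bind_rows(kept, cand)
        }
      }
      # covered query residues: union of the kept segment intervals
      iv <- IRanges::reduce(IRanges::IRanges(kept$q_start, kept$q_end))
      loci[[length(loci) + 1]] <- tibble(
        g_start = min(kept$g_start), g_end = max(kept$g_end),
        strand = strand, score = sum(kept$score),
        q_cover = sum(BiocGenerics::width(iv)))
    }
  }
  loci <- bind_rows(loci) |> arrange(desc(.data$score))
  # one hit per genomic locus: drop hits overlapping a better one
  keep <- rep(TRUE, nrow(loci))
  if (nrow(loci) > 1) {
    for (i in 2:nrow(loci)) {
      for (j in seq_len(i - 1)) {
        if (!keep[j]) next
        ov <- min(loci$g_end[i], loci$g_end[j]) -
          max(loci$g_start[i], loci$g_start[j])
        if (ov > 0) { keep[i] <- FALSE; break }
      }
    }
  }
  loci[keep, ]
}

#' Extend a gene hit by 5' and 3' flanking sequence
#'
#' Adds `flank_5p` nt upstream and `flank_3p` nt downstream of the hit
#' in transcript orientation (amounts swap ends on the minus strand),
#' clipped at the chromosome boundaries, and extracts the extended
#' sequence in transcript sense.
#'
#' @param hit one row of the tibble from [find_gene_orthologs()].
#' @param genomes genome tibble.
#' @param flank_5p,flank_3p flank lengths in nt.
#' @return A one-row tibble: the hit plus `ext_start`, `ext_end` and
#'   `sequence` (transcript-sense DNA of the extended interval).
#' @export
extend_flanks <- function(hit, genomes, flank_5p = 1000, flank_3p = 300) {
  chrom <- get_chrom(genomes, hit$species_id, hit$chrom_id)
  clen <- nchar(chrom)
  if (hit$strand == "+") {
    s <- max(0L, hit$start - flank_5p)
    e <- min(clen, hit$end + flank_3p)
  } else {
    s <- max(0L, hit$start - flank_3p)
    e <- min(clen, hit$end + flank_5p)
  }
  seqs <- subseq0(chrom, s, e)
  if (hit$strand == "-") seqs <- revcomp(seqs)
  bind_rows(hit) |> mutate(ext_start = s, ext_end = e, sequence = seqs)
}

#' @noRd
nt_subst_matrix <- function(params) {
  m <- matrix(params$mismatch_nt, 5, 5)
  diag(m) <- params$match_nt
  m[5, ] <- m[, 5] <- 0  # N never rewards or penalises
  m
}

#' Search an ortholog locus for the orthologous intron
#'
#' Nucleotide seed-and-extend local search (word size
#' `params$word_nt`) of the focal intron against the extended locus
#' sequence. Seed-dense diagonals define candidate regions which are
#' re-aligned with an affine-gap local aligner; hits with e-value above
#' `e_max_nt` are discarded and the lowest-e-value survivor is flagged
#' `is_best_hit` (ties: higher score, then leftmost).
#'
#' @param intron focal intron sequence (transcript sense).
#' @param locus one-row tibble from [extend_flanks()].
#' @param params a [search_params()] object.
#' @return A tibble of intron hits: `species_id`, `locus_start`,
#'   `locus_end` (coordinates in the transcript-sense locus sequence,
#'   0-based half-open), `score`, `evalue`, `identity`, `sequence`,
#'   `is_best_hit`.
#' @export
find_intron_ortholog <- function(intron, locus, params = search_params()) {
  if (!nzchar(intron)) abort("empty intron sequence")
  target <- locus$sequence
  m <- nchar(intron); n <- nchar(target)
  k <- params$word_nt
  if (n < k) return(tibble())
  subst <- nt_subst_matrix(params)
  qwords <- substring(intron, 1:(m - k + 1), k:m)
  twords <- substring(target, 1:(n - k + 1), k:n)
  tindex <- split(seq_along(twords), twords)
  qhits <- purrr::imap(tindex[intersect(unique(qwords), names(tindex))],
                       function(pos, w) {
                         tibble(qpos = which(qwords == w)) |>
                           tidyr::expand_grid(tpos = pos)
                       })
  seeds <- bind_rows(qhits)
  if (nrow(seeds) == 0) return(tibble())
  seeds <- seeds |> mutate(diag = .data$tpos - .data$qpos)
  # candidate regions: diagonal bands whose seed count clearly exceeds
  # the word-size-3 background expectation (m * band / 4^k per band)
  band <- 20L
  bg <- m * band / 4^k
  min_seeds <- bg + max(5 * sqrt(bg), 8)
  seeds <- seeds |> mutate(band_id = .data$diag %/% band)
  dens <- seeds |> dplyr::count(.data$band_id) |>
    filter(.data$n >= min_seeds)
  if (nrow(dens) == 0) return(tibble())
  # merge adjacent dense bands into regions
  bands <- sort(dens$band_id)
  groups <- cumsum(c(1, diff(bands) > 1))
  qc <- encode_dna(intron)
  out <- list()
  for (g in unique(groups)) {
    bb <- bands[groups == g]
    sel <- seeds |> filter(.data$band_id %in% bb)
    r_start <- max(0L, min(sel$tpos) - 1L - band)
    r_end <- min(n, max(sel$tpos) + k + band)
    tc <- encode_dna(subseq0(target, r_start, r_end))
    al <- .align_affine_cpp(qc, tc, subst, params$gap_open_nt,
                            params$gap_extend_nt, TRUE)
    if (al$score <= 0) next
    aligned <- al$a_idx > 0 & al$b_idx > 0
    ident <- mean(qc[al$a_idx[aligned]] == tc[al$b_idx[aligned]])
    out[[length(out) + 1]] <- tibble(
      species_id = locus$species_id,
      locus_start = r_start + al$b_start - 1L,
      locus_end = r_start + al$b_end,
      score = al$score,
      identity = ident)
  }
  out <- bind_rows(out)
  if (nrow(out) == 0) return(out)
  out <- out |>
    mutate(evalue = params$k_nt * m * n * exp(-params$lambda_nt * .data$score),
           sequence = substr(target, .data$locus_start + 1, .data$locus_end)) |>
    filter(.data$evalue <= params$e_max_nt) |>
    arrange(.data$evalue, desc(.data$score), .data$locus_start)
  if (nrow(out) > 0) {
    out$is_best_hit <- seq_len(nrow(out)) == 1
  }
  out
}

#' Map orthologous introns for every focal intron-containing gene
#'
#' Runs the full ortholog-mapping stage: translated gene search in each
#' comparison genome, flank extension of the best gene hit per species,
#' and nucleotide intron search with best-hit selection.
#'
#' @param sim a `genome_sim` object (or a list with `genomes` and
#'   `annotations` in the same layout).
#' @param params a [search_params()] object.
#' @return A tibble with one row per (intron, species) best hit:
#'   `intron_id`, `gene_id`, `species_id`, `score`, `evalue`,
#'   `identity`, `sequence`.
#' @export
map_orthologs <- function(sim, params = search_params()) {
  ann <- sim$annotations
  targets <- setdiff(unique(sim$genomes$species_id),
                     unique(ann$species_id))
  index <- build_target_index(sim$genomes, targets, blosum62())
  out <- list()
  for (i in seq_len(nrow(ann))) {
    gene <- ann[i, ]
    if (nrow(gene$introns[[1]]) == 0) next
    focal_intron <- intron_seq(gene, sim$genomes, 1)
    ghits <- find_gene_orthologs(gene, sim$genomes, targets, params, index)
    if (nrow(ghits) == 0) next
    best_gene <- ghits |> group_by(.data$species_id) |>
      arrange(.data$evalue, desc(.data$score)) |>
      dplyr::slice(1) |> ungroup()
    for (s in seq_len(nrow(best_gene))) {
      locus <- extend_flanks(best_gene[s, ], sim$genomes,
                             params$flank_5p, params$flank_3p)
      ih <- find_intron_ortholog(focal_intron, locus, params)
      if (nrow(ih) == 0) next
      best <- ih |> filter(.data$is_best_hit)
      out[[length(out) + 1]] <- tibble(
        intron_id = paste0(gene$gene_id, ".i1"),
        gene_id = gene$gene_id,
        species_id = best$species_id,
        score = best$score, evalue = best$evalue,
        identity = best$identity, sequence = best$sequence)
    }
  }
  bind_rows(out)
}

#' Assemble ortholog sets from mapped intron hits
#'
#' @param sim a `genome_sim` object (for focal intron sequences).
#' @param hits tibble from [map_orthologs()].
#' @return A tibble with `intron_id`, `gene_id`, `n_orthologs` and a
#'   list-column `sequences` (named character vector, focal first).
#' @export
build_ortholog_sets <- function(sim, hits) {
  ann <- sim$annotations
  sets <- purrr::map(seq_len(nrow(ann)), function(i) {
    gene <- ann[i, ]
    if (nrow(gene$introns[[1]]) == 0) return(NULL)
    iid <- paste0(gene$gene_id, ".i1")
    hh <- hits |> filter(.data$intron_id == iid)
    seqs <- c(setNames(intron_seq(gene, sim$genomes, 1), "focal"),
              setNames(hh$sequence, hh$species_id))
    tibble(intron_id = iid, gene_id = gene$gene_id,
           n_orthologs = nrow(hh), sequences = list(seqs))
  })
  bind_rows(purrr::compact(sets))
}

#' Ortholog-count histogram
#'
#' For each ortholog count k, the number of focal introns with exactly
#' k orthologous introns; the histogram total equals the number of
#' focal introns.
#'
#' @param sets tibble from [build_ortholog_sets()] (needs
#'   `n_orthologs`).
#' @return A tibble with `k` and `n_introns`.
#' @export
count_orthologs <- function(sets) {
  sets |> dplyr::count(k = .data$n_orthologs, name = "n_introns") |>
    arrange(.data$k)
}
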