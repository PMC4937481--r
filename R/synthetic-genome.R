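# Synthetic comparative genome panel with planted intronic hairpins.
# The generator is first-class, tested code: it produces every input the
# pipeline consumes together with a ground-truth ledger, so each
# downstream stage can be tested for parameter recovery.

#' Validate a pairing vector (partner indices, 0 = unpaired)
#' @noRd
check_nested_pairing <- function(pairing) {
  n <- length(pairing)
  open <- integer(0)
  for (i in seq_len(n)) {
    p <- pairing[i]
    if (p == 0) next
    if (p < 1 || p > n || pairing[p] != i || p == i) {
      abort("invalid pairing: partners must be mutual")
    }
    if (p > i) {
      open <- c(open, i)
    } else {
      if (length(open) == 0 || tail(open, 1) != p) {
        abort("pairing is not nested")
      }
      open <- head(open, -1)
    }
  }
  invisible(TRUE)
}

WC_PARTNER <- c(A = "T", C = "G", G = "C", T = "A")

#' Evolve a sequence carrying a base-paired structure
#'
#' Applies per-site substitutions at rate `divergence`. Positions inside
#' a stem are co-evolved: when either side of a pair is substituted,
#' with probability `compensatory_rate` the partner position is
#' substituted as well so that Watson-Crick complementarity is restored
#' (a compensatory mutation); otherwise the two sides evolve
#' independently. Unpaired (loop and flanking) positions evolve
#' neutrally.
#'
#' @param sequence DNA string.
#' @param pairing integer vector of partner indices (1-based, 0 for
#'   unpaired), same length as `sequence`; must be nested and
#'   complementary (Watson-Crick or G.U) at paired positions.
#' @param divergence per-site substitution probability.
#' @param compensatory_rate probability a stem substitution is
#'   compensated.
#' @param seed optional integer seed; when `NULL` the current RNG state
#'   is used.
#' @return The evolved DNA string.
#' @export
evolve_hairpin <- function(sequence, pairing, divergence, compensatory_rate,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(pairing) != length(chars)) {
    abort("`pairing` must have one entry per residue")
  }
  check_nested_pairing(pairing)
  paired_left <- which(pairing > seq_along(pairing))
  for (i in paired_left) {
    j <- pairing[i]
    if (!is_complementary(chars[i], chars[j])) {
      abort(sprintf("positions %d and %d are paired but not complementary",
                    i, j))
    }
  }
  check_probability(divergence, "divergence")
  check_probability(compensatory_rate, "compensatory_rate")

  sub_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1)

  # unpaired positions: neutral
  for (i in which(pairing == 0)) {
    if (runif(1) < divergence) chars[i] <- sub_base(chars[i])
  }
  # paired positions: joint model per pair
  for (i in paired_left) {
    j <- pairing[i]
    si <- runif(1) < divergence
    sj <- runif(1) < divergence
    if (!si && !sj) next
    if (si) chars[i] <- sub_base(chars[i])
    if (sj) chars[j] <- sub_base(chars[j])
    if (runif(1) < compensatory_rate) {
      # compensate: restore Watson-Crick complementarity at the partner
      # of the (first) substituted side
      if (si) chars[j] <- WC_PARTNER[[chars[i]]]
      else chars[i] <- WC_PARTNER[[chars[j]]]
    }
  }
  paste(chars, collapse = "")
}

# Draw a hairpin (stem + loop) and return its sequence and pairing
#' @noRd
make_hairpin <- function(stem_range, loop_range) {
  stem <- sample(seq(stem_range[1], stem_range[2]), 1)
  loop <- sample(seq(loop_range[1], loop_range[2]), 1)
  left <- random_dna(stem)
  right <- revcomp(left)
  seqs <- paste0(left, random_dna(loop), right)
  n <- 2 * stem + loop
  pairing <- integer(n)
  pairing[1:stem] <- n:(n - stem + 1)
  pairing[n:(n - stem + 1)] <- 1:stem
  list(seq = seqs, pairing = pairing, stem = stem, loop = loop)
}

#' Simulate a focal genome plus a panel of diverged comparison genomes
#'
#' Builds one focal chromosome of intron-containing genes (a fraction of
#' which carry a planted hairpin inside the intron), then derives one
#' genome per comparison species by per-site neutral substitution, with
#' hairpin regions co-evolved by [evolve_hairpin()]. Gene and intron
#' presence per species follow per-clade retention probabilities, so the
#' ortholog-count histogram is skewed the way a real comparative panel
#' is. Per-gene expression levels and intron maintenance factors are
#' drawn here and recorded in the truth ledger for the read and CRAC
#' simulators.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `genome_sim` with elements `genomes` (tibble:
#'   `species_id`, `chrom_id`, `residues`), `annotations` (focal gene
#'   tibble as from [read_gff3()]), and `truth` (list with `genes`,
#'   `introns`, `presence` tibbles and the generating `params`).
#' @export
simulate_genome_set <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params, "genome"))

  n <- params$n_genes
  has_intron <- runif(n) < params$intron_fraction
  is_rp <- has_intron & runif(n) < params$rp_fraction
  structured <- has_intron & runif(n) < params$structured_fraction
  gene_ids <- character(n)
  rp_i <- 0; other_i <- 0
  for (g in seq_len(n)) {
    if (is_rp[g]) {
      rp_i <- rp_i + 1
      gene_ids[g] <- sprintf("%s%d", sample(c("RPL", "RPS"), 1), rp_i)
    } else {
      other_i <- other_i + 1
      gene_ids[g] <- sprintf("YGEN%03d", other_i)
    }
  }

  # per-gene transcript parts (transcript sense)
  exon1_len <- sample(150:300, n, replace = TRUE)
  exon2_len <- sample(150:300, n, replace = TRUE)
  adj <- (3 - (exon1_len + exon2_len) %% 3) %% 3
  exon2_len <- exon2_len + adj
  intron_len <- ifelse(has_intron, sample(150:350, n, replace = TRUE), 0L)

  exon1 <- vapply(exon1_len, random_dna, "")
  exon2 <- vapply(exon2_len, random_dna, "")
  intron <- vapply(intron_len, function(L) {
    if (L == 0) "" else random_dna(L)
  }, "")

  hairpins <- vector("list", n)
  pairing <- vector("list", n)
  for (g in which(structured)) {
    hp <- make_hairpin(params$stem_range, params$loop_range)
    L <- intron_len[g]
    hl <- nchar(hp$seq)
    off <- sample(10:(L - hl - 10), 1)
    intron[g] <- paste0(substr(intron[g], 1, off), hp$seq,
                        substr(intron[g], off + hl + 1, L))
    pv <- integer(L)
    pv[(off + 1):(off + hl)] <- ifelse(hp$pairing == 0, 0L,
                                       hp$pairing + off)
    hairpins[[g]] <- c(start = off, end = off + hl)  # 0-based half-open
    pairing[[g]] <- pv
  }

  species <- tibble(
    species_id = unlist(purrr::imap(params$clades, function(d, nm) {
      sprintf("%s_%d", nm, seq_along(d))
    })),
    clade = rep(names(params$clades), lengths(params$clades)),
    divergence = unlist(params$clades)
  )

  # --- focal chromosome and annotation
  strands <- sample(c("+", "-"), n, replace = TRUE)
  build_chrom <- function(present, intron_present, seq_fun, strand_vec) {
    pos <- 0L
    parts <- character(0)
    rows <- list()
    for (g in seq_len(n)) {
      spacer <- random_dna(sample(200:400, 1))
      parts <- c(parts, spacer)
      pos <- pos + nchar(spacer)
      if (!present[g]) next
      tx <- seq_fun(g, intron_present[g])
      gstart <- pos
      glen <- nchar(tx)
      genomic <- if (strand_vec[g] == "+") tx else revcomp(tx)
      parts <- c(parts, genomic)
      pos <- pos + glen
      # exon intervals in genomic coordinates (0-based half-open)
      e1 <- exon1_len[g]; e2 <- exon2_len[g]
      il <- if (intron_present[g]) intron_len[g] else 0L
      if (strand_vec[g] == "+") {
        ex <- tibble(start = c(gstart, gstart + e1 + il),
                     end = c(gstart + e1, gstart + glen))
      } else {
        # transcript runs right-to-left on the genome
        ex <- tibble(start = c(gstart + e2 + il, gstart),
                     end = c(gstart + glen, gstart + e2))
      }
      if (il == 0L) ex <- tibble(start = gstart, end = gstart + glen)
      rows[[length(rows) + 1]] <- list(g = g, exons = ex,
                                       strand = strand_vec[g],
                                       start = gstart, len = glen)
    }
    list(seq = paste(parts, collapse = ""), rows = rows)
  }

  focal_tx <- function(g, with_intron) {
    if (with_intron && has_intron[g]) {
      paste0(exon1[g], intron[g], exon2[g])
    } else {
      paste0(exon1[g], exon2[g])
    }
  }
  focal <- build_chrom(rep(TRUE, n), has_intron, focal_tx, strands)

  ann <- bind_rows(purrr::map(focal$rows, function(r) {
    ex_tx <- r$exons  # already in genomic-ascending? build transcription order
    ex <- ex_tx |> arrange(.data$start)
    introns <- if (nrow(ex) > 1) {
      tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
    } else {
      tibble(start = integer(), end = integer())
    }
    if (r$strand == "-") {
      ex <- ex[rev(seq_len(nrow(ex))), ]
      introns <- introns[rev(seq_len(nrow(introns))), ]
    }
    tibble(gene_id = gene_ids[r$g], species_id = "focal",
           chrom_id = "chrI", strand = r$strand,
           exons = list(ex), introns = list(introns))
  }))

  # --- comparison genomes
  genomes <- list(tibble(species_id = "focal", chrom_id = "chrI",
                         residues = focal$seq))
  presence <- list()
  for (s in seq_len(nrow(species))) {
    d <- species$divergence[s]
    cl <- species$clade[s]
    present <- runif(n) < params$gene_retention[[cl]]
    ipres <- has_intron & present & runif(n) < params$retention[[cl]]
    sp_strands <- sample(c("+", "-"), n, replace = TRUE)
    sp_tx <- function(g, with_intron) {
      dc <- d * params$coding_rate_ratio  # exons under purifying selection
      e1 <- mutate_neutral(exon1[g], dc)
      e2 <- mutate_neutral(exon2[g], dc)
      if (!with_intron) return(paste0(e1, e2))
      iv <- if (structured[g]) {
        evolve_hairpin(intron[g], pairing[[g]], d, params$compensatory_rate)
      } else {
        mutate_neutral(intron[g], d)
      }
      paste0(e1, iv, e2)
    }
    chrom <- build_chrom(present, ipres, sp_tx, sp_strands)
    genomes[[length(genomes) + 1]] <-
      tibble(species_id = species$species_id[s], chrom_id = "chrI",
             residues = chrom$seq)
    for (r in chrom$rows) {
      g <- r$g
      if (!has_intron[g]) next
      il <- if (ipres[g]) intron_len[g] else 0L
      if (il > 0) {
        e1 <- exon1_len[g]; e2 <- exon2_len[g]
        if (r$strand == "+") {
          is0 <- r$start + e1
        } else {
          is0 <- r$start + e2
        }
        iv <- c(is0, is0 + il)
      } else {
        iv <- c(NA_integer_, NA_integer_)
      }
      presence[[length(presence) + 1]] <- tibble(
        gene_id = gene_ids[g], species_id = species$species_id[s],
        clade = cl, gene_present = TRUE, intron_present = ipres[g],
        intron_start = iv[1], intron_end = iv[2], strand = r$strand)
    }
  }
  presence <- bind_rows(presence)

  expression <- rlnorm(n, params$expr_meanlog, params$expr_sdlog)
  maintenance <- ifelse(structured,
                        params$maintenance_base * params$maintenance_multiplier,
                        params$maintenance_base)

  truth <- list(
    genes = tibble(gene_id = gene_ids, is_rp = is_rp,
                   has_intron = has_intron, structured = structured,
                   expression = expression,
                   maintenance_factor = ifelse(has_intron, maintenance, NA)),
    introns = tibble(
      intron_id = ifelse(has_intron, paste0(gene_ids, ".i1"), NA),
      gene_id = gene_ids,
      structured = structured,
      hairpin_start = vapply(seq_len(n), function(g) {
        if (structured[g]) hairpins[[g]][["start"]] else NA_integer_
      }, numeric(1)),
      hairpin_end = vapply(seq_len(n), function(g) {
        if (structured[g]) hairpins[[g]][["end"]] else NA_integer_
      }, numeric(1)),
      pairing = pairing
    ) |> filter(!is.na(.data$intron_id)),
    presence = presence,
    species = species,
    params = params
  )

  structure(list(genomes = bind_rows(genomes), annotations = ann,
                 truth = truth),
            class = "genome_sim")
}

#' Extract ortholog sets from the truth ledger
#'
#' Uses the planted per-species intron coordinates to assemble, for each
#' focal intron, the set of orthologous intron sequences in transcript
#' sense. This bypasses the search stage and is the reference substrate
#' for testing the structure screen in isolation.
#'
#' @param sim a `genome_sim` object.
#' @return A tibble with `intron_id`, `gene_id`, `structured`, and a
#'   list-column `sequences` (named character vector, focal first).
#' @export
truth_ortholog_sets <- function(sim) {
  ann <- sim$annotations
  sets <- purrr::map(seq_len(nrow(ann)), function(i) {
    gene <- ann[i, ]
    if (nrow(gene$introns[[1]]) == 0) return(NULL)
    gid <- gene$gene_id
    focal_seq <- intron_seq(gene, sim$genomes, 1)
    pres <- sim$truth$presence |>
      filter(.data$gene_id == gid, .data$intron_present)
    orth <- purrr::map_chr(seq_len(nrow(pres)), function(k) {
      chrom <- get_chrom(sim$genomes, pres$species_id[k], "chrI")
      s <- subseq0(chrom, pres$intron_start[k], pres$intron_end[k])
      if (pres$strand[k] == "-") s <- revcomp(s)
      s
    })
    seqs <- c(setNames(focal_seq, "focal"),
              setNames(orth, pres$species_id))
    tr <- sim$truth$introns |> filter(.data$gene_id == gid)
    tibble(intron_id = paste0(gid, ".i1"), gene_id = gid,
           structured = tr$structured[1], sequences = list(seqs))
  })
  bind_rows(purrr::compact(sets))
}
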