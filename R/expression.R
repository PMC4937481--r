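# Intron/CDS expression quantification: any-overlap read counting over
# features, RPKM, host-normalised intron expression, the
# expression-evidence rule, and the ribosomal-protein group comparison.

#' Count reads over features (any-overlap rule)
#'
#' A read is assigned to a feature when at least one nucleotide of its
#' reference span overlaps the feature; a read overlapping several
#' features (e.g. spanning an exon-intron boundary) is counted for
#' each. Counting is unstranded.
#'
#' @param alignments a `read_alignments` object from [read_sam()] (or a
#'   compatible list with a `reads` tibble).
#' @param features tibble with `feature_id`, `class`, `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return The `features` tibble with a `count` column appended.
#' @export
count_reads <- function(alignments, features) {
  reads <- alignments$reads
  if (!all(features$chrom %in% names(alignments$chrom_lengths))) {
    abort("feature on unknown chromosome")
  }
  counts <- integer(nrow(features))
  for (ch in unique(features$chrom)) {
    fsel <- which(features$chrom == ch)
    rsel <- reads |> filter(.data$chrom == ch)
    if (nrow(rsel) == 0) next
    fr <- IRanges::IRanges(start = features$start[fsel] + 1L,
                           end = features$end[fsel])
    rr <- IRanges::IRanges(start = rsel$start + 1L,
                           end = rsel$start + rsel$span)
    ov <- IRanges::countOverlaps(fr, rr, minoverlap = 1L)
    counts[fsel] <- ov
  }
  features |> mutate(count = counts)
}

#' Annotation tibble -> feature table for counting
#'
#' One `CDS` feature per exon interval (counts are summed per gene) and
#' one `intron` feature per intron.
#'
#' @param annotations focal annotation tibble.
#' @return A tibble with `feature_id`, `class`, `gene_id`, `chrom`,
#'   `start`, `end`.
#' @export
annotation_features <- function(annotations) {
  rows <- purrr::map(seq_len(nrow(annotations)), function(i) {
    g <- annotations[i, ]
    ex <- g$exons[[1]]
    out <- tibble(feature_id = g$gene_id, class = "CDS",
                  gene_id = g$gene_id, chrom = g$chrom_id,
                  start = ex$start, end = ex$end)
    introns <- g$introns[[1]]
    if (nrow(introns) > 0) {
      out <- bind_rows(out, tibble(
        feature_id = paste0(g$gene_id, ".i", seq_len(nrow(introns))),
        class = "intron", gene_id = g$gene_id, chrom = g$chrom_id,
        start = introns$start, end = introns$end))
    }
    out
  })
  bind_rows(rows)
}

#' Reads per kilobase of feature per million mapped reads
#'
#' @param count read count (vectorised).
#' @param length_nt feature length in nt.
#' @param total_mapped total mapped reads in the library.
#' @return RPKM = count / (length_nt/1000) / (total_mapped/1e6).
#' @export
rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) abort("feature length must be > 0")
  if (length(total_mapped) != 1 || total_mapped <= 0) {
    abort("total_mapped must be a positive scalar")
  }
  count / (length_nt / 1000) / (total_mapped / 1e6)
}

#' Expression-evidence rule
#'
#' A feature has evidence of expression when it has more than 150 reads
#' or at least 20 RPKM.
#'
#' @param count read count (vectorised).
#' @param rpkm_value RPKM.
#' @return Logical vector.
#' @export
evidence <- function(count, rpkm_value) {
  count > 150 | rpkm_value >= 20
}

#' Host-normalised intron expression
#'
#' @param intron_rpkm intron RPKM (vectorised).
#' @param host_cds_rpkm host CDS RPKM.
#' @return intron/host ratio; `NA` (undefined, excluded from group
#'   statistics) where the host RPKM is 0.
#' @export
normalize_by_host <- function(intron_rpkm, host_cds_rpkm) {
  ifelse(host_cds_rpkm > 0, intron_rpkm / host_cds_rpkm, NA_real_)
}

#' Build the expression table from counted features
#'
#' Sums CDS counts per gene, computes RPKM for introns and CDS,
#' host-normalised intron expression, the evidence flag, and the
#' ribosomal-protein / prediction annotations.
#'
#' @param counted feature tibble with `count` (from [count_reads()] or
#'   a counts-level simulation); needs `feature_id`, `class`,
#'   `gene_id`, `count` and per-interval lengths (`start`/`end` or
#'   `length`).
#' @param total_mapped total mapped reads.
#' @param predictions character vector of intron ids with predicted
#'   structures (sets `has_prediction`).
#' @return A tibble with one row per feature: `feature_id`, `class`,
#'   `gene_id`, `count`, `length`, `rpkm`, `host_rpkm` (introns),
#'   `normalized`, `evidence`, `is_rp`, `has_prediction`.
#' @export
expression_table <- function(counted, total_mapped, predictions = character()) {
  if (!"length" %in% names(counted)) {
    counted <- counted |> mutate(length = .data$end - .data$start)
  }
  tab <- counted |>
    group_by(.data$feature_id, .data$class, .data$gene_id) |>
    summarise(count = sum(.data$count), length = sum(.data$length),
              .groups = "drop") |>
    mutate(rpkm = rpkm(.data$count, .data$length, total_mapped))
  host <- tab |> filter(.data$class == "CDS") |>
    select("gene_id", host_rpkm = "rpkm")
  tab |>
    left_join(host, by = "gene_id") |>
    mutate(
      host_rpkm = ifelse(.data$class == "intron", .data$host_rpkm, NA_real_),
      normalized = ifelse(.data$class == "intron",
                          normalize_by_host(.data$rpkm, .data$host_rpkm),
                          NA_real_),
      evidence = evidence(.data$count, .data$rpkm),
      is_rp = grepl("^RP[LS]", .data$gene_id),
      has_prediction = .data$feature_id %in% predictions)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value by rank-sum enumeration (dynamic-programming
#' count of rank-sum arrangements) when both groups are small
#' (min(n) <= 8, total <= 25) and tie-free; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param group_a,group_b numeric vectors.
#' @return A list with `U` (statistic of `group_a`), `p` (two-sided),
#'   and `method` ("exact" or "normal").
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0) abort("both groups must be non-empty")
  all_v <- c(group_a, group_b)
  r <- rank(all_v)
  ra <- sum(r[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  ties <- any(duplicated(all_v))
  n <- na + nb
  if (!ties && min(na, nb) <= 8 && n <= 25) {
    # exact: DP count of subsets of ranks 1..n of size na by rank sum
    counts <- mw_ranksum_counts(n, na)
    total <- choose(n, na)
    # U and its reflection; two-sided p doubles the smaller tail
    u_lo <- min(U, na * nb - U)
    # rank sums corresponding to U' <= u_lo
    p_tail <- sum(counts[seq_len(u_lo + 1)]) / total
    p <- min(1, 2 * p_tail)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  tie_tab <- table(all_v)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  zc <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(zc))
  list(U = U, p = min(1, p), method = "normal")
}

# counts[k+1] = number of na-subsets of ranks 1..n with U statistic k
#' @noRd
mw_ranksum_counts <- function(n, na) {
  nb <- n - na
  umax <- na * nb
  # generating-function recurrence:
  # N(u; na, nb) = N(u - nb; na - 1, nb) + N(u; na, nb - 1)
  memo <- new.env()
  count_fun <- function(u, a, b) {
    if (u < 0) return(0)
    if (a == 0) return(if (u == 0) 1 else 0)
    if (b == 0) return(if (u == 0) 1 else 0)
    key <- paste(u, a, b)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- count_fun(u - b, a - 1, b) + count_fun(u, a, b - 1)
    memo[[key]] <- v
    v
  }
  vapply(0:umax, count_fun, numeric(1), a = na, b = nb)
}

#' Ribosomal-protein intron group comparison
#'
#' Medians and Mann-Whitney tests comparing RP introns carrying
#' predicted structures against all RP introns, on raw and
#' host-normalised intron expression.
#'
#' @param expr expression table from [expression_table()].
#' @return A tibble with one row per measure (`rpkm`, `normalized`):
#'   group sizes, medians and the two-sided Mann-Whitney p-value of
#'   prediction-group vs non-prediction RP introns.
#' @export
group_compare <- function(expr) {
  rp <- expr |> filter(.data$class == "intron", .data$is_rp)
  pred <- rp |> filter(.data$has_prediction)
  rest <- rp |> filter(!.data$has_prediction)
  measure <- function(name, col) {
    a <- pred[[col]]; b <- rest[[col]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    mw <- if (length(a) > 0 && length(b) > 0) {
      mann_whitney(a, b)
    } else {
      list(U = NA_real_, p = NA_real_)
    }
    tibble(measure = name,
           n_pred = length(a), n_all = length(a) + length(b),
           median_pred = median(a), median_all = median(c(a, b)),
           U = mw$U, p = mw$p)
  }
  bind_rows(measure("rpkm", "rpkm"), measure("normalized", "normalized"))
}
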