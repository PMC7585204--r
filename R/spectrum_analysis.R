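#' SNV sharing across groups in fixed-width position bins
#'
#' Positions are binned into non-overlapping `bin`-bp bins; several SNVs
#' from one group in the same bin count as a single instance. Each occupied
#' bin is scored by the number of groups with an SNV in it, and the counts
#' are reported in the conventional sharing categories: `1`, `2-3`, `4-6`
#' when grouping by region, and `1`, `2-3`, `>=4` when grouping by animal.
#'
#' @param samples Named list: one vector of 0-based SNV positions per group.
#' @param L Genome length.
#' @param bin Bin width in bp (default 10).
#' @param group_by `"region"` (category edges 1 / 2-3 / 4-6) or `"animal"`
#'   (1 / 2-3 / >=4).
#' @return List: `histogram` (named counts per sharing category),
#'   `levels` (per-bin sharing level for occupied bins), `n_bins_occupied`.
#' @export
snv_sharing <- function(samples, L, bin = 10L, group_by = c("region", "animal")) {
  group_by <- match.arg(group_by)
  if (bin < 1L) stop("bin width must be at least 1")
  stopifnot(is.list(samples), length(samples) >= 1L)
  occupied <- lapply(samples, function(p) {
    if (length(p) && any(p < 0 | p >= L)) stop("positions must lie in [0, L)")
    unique(p %/% bin)
  })
  all_bins <- sort(unique(unlist(occupied)))
  if (!length(all_bins)) {
    levels <- integer(0)
  } else {
    occ <- vapply(occupied, function(b) all_bins %in% b,
                  logical(length(all_bins)))
    levels <- rowSums(matrix(occ, nrow = length(all_bins)))
    names(levels) <- all_bins
  }
  if (group_by == "region") {
    edges <- list("1" = c(1, 1), "2-3" = c(2, 3), "4-6" = c(4, 6))
  } else {
    edges <- list("1" = c(1, 1), "2-3" = c(2, 3), ">=4" = c(4, Inf))
  }
  histogram <- vapply(edges, function(e) {
    sum(levels >= e[1L] & levels <= e[2L])
  }, numeric(1L))
  list(histogram = histogram, levels = levels,
       n_bins_occupied = length(levels))
}

#' Binned, max-normalized allele-fraction profile
#'
#' Sums SNV allele fractions in `bin`-bp bins across the genome and scales
#' the profile so the highest bin is 1. With no SNVs the all-zero profile is
#' returned unnormalized (attribute `normalized = FALSE`). The final bin is
#' partial when `L` is not a multiple of `bin` (attribute `partial_last`).
#'
#' @param snvs `data.frame` with 0-based `pos5` (or `pos`) and
#'   `allele_fraction` (or `fraction`).
#' @param L Genome length.
#' @param bin Bin width in bp (default 100).
#' @return Numeric vector of `ceiling(L / bin)` bin values.
#' @export
binned_allele_fraction <- function(snvs, L, bin = 100L) {
  pos <- if ("pos5" %in% names(snvs)) snvs$pos5 else snvs$pos
  af <- if ("allele_fraction" %in% names(snvs)) snvs$allele_fraction else snvs$fraction
  n_bins <- ceiling(L / bin)
  values <- numeric(n_bins)
  if (length(pos)) {
    stopifnot(all(af > 0 & af <= 1))
    sums <- tapply(af, pos %/% bin, sum)
    values[as.integer(names(sums)) + 1L] <- sums
  }
  normalized <- FALSE
  if (any(values > 0)) {
    values <- values / max(values)
    normalized <- TRUE
  }
  attr(values, "normalized") <- normalized
  attr(values, "partial_last") <- (L %% bin) != 0L
  values
}

#' Cumulative position distribution
#'
#' Step function of the cumulative percentage of variants along the genome,
#' reported at each distinct position and reaching 100 percent at `L`.
#'
#' @param pos 0-based positions (SNV sites or VLRD 5' breakpoints).
#' @param L Genome length.
#' @return `data.frame` with `pos` (1-based step ends) and `cum_percent`.
#' @export
cumulative_position <- function(pos, L) {
  if (!length(pos)) stop("empty variant set")
  tab <- table(factor(sort(pos)))
  at <- as.integer(names(tab))
  cum <- 100 * cumsum(as.integer(tab)) / length(pos)
  out <- data.frame(pos = at + 1L, cum_percent = as.numeric(cum))
  if (out$pos[nrow(out)] < L) {
    out <- rbind(out, data.frame(pos = L, cum_percent = 100))
  }
  out
}

#' Mutation-type spectrum of SNVs
#'
#' Counts the 12 substitution classes on the reference strand, the
#' pyrimidine-collapsed 6-class view, and the transition/transversion
#' totals (transitions: A>G, G>A, C>T, T>C).
#'
#' @param snvs `data.frame` with `pos5` (or `pos`), `ref`, `alt`.
#' @param g The [circular_genome()]; reference bases are checked against it.
#' @return List: `classes` (named 12-vector), `collapsed` (named 6-vector),
#'   `ti`, `tv`, `n`.
#' @export
mutation_spectrum <- function(snvs, g) {
  pos <- if ("pos5" %in% names(snvs)) snvs$pos5 else snvs$pos
  if (length(pos)) {
    genome_ref <- substring(g$sequence, pos + 1L, pos + 1L)
    bad <- genome_ref != snvs$ref
    if (any(bad)) {
      stop("SNV ref base disagrees with genome at 0-based position ",
           pos[which(bad)[1L]])
    }
  }
  bases <- c("A", "C", "G", "T")
  cls <- unlist(lapply(bases, function(r) {
    paste0(r, ">", setdiff(bases, r))
  }))
  counts <- stats::setNames(integer(12L), cls)
  if (length(pos)) {
    obs <- table(paste0(snvs$ref, ">", snvs$alt))
    counts[names(obs)] <- as.integer(obs)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  collapse_key <- vapply(cls, function(k) {
    r <- substr(k, 1L, 1L); a <- substr(k, 3L, 3L)
    if (r %in% c("A", "G")) paste0(comp[r], ">", comp[a]) else k
  }, character(1L))
  collapsed <- tapply(counts, collapse_key, sum)
  ti_classes <- c("A>G", "G>A", "C>T", "T>C")
  ti <- sum(counts[ti_classes])
  list(classes = counts, collapsed = collapsed[sort(names(collapsed))],
       ti = ti, tv = sum(counts) - ti, n = sum(counts))
}

# Does arc [s1, s1+l1) overlap arc [s2, s2+l2) on the circle?
arcs_overlap <- function(s1, l1, s2, l2, L) {
  (((s2 - s1) %% L) < l1) | (((s1 - s2) %% L) < l2)
}

#' Per-gene, length-normalized SNV and deletion load
#'
#' SNV load is the number of SNVs inside each gene divided by the gene
#' length; deletion load counts deletions whose deleted arc overlaps the
#' gene (optionally weighting each deletion by its allele fraction). Both
#' vectors are min-max scaled to \[0, 1\] and their Pearson correlation is
#' attached.
#'
#' @param variants Classified variant `data.frame` (`kind`, `pos5`,
#'   `length`, optionally `allele_fraction`).
#' @param g The [circular_genome()]; must carry gene annotation.
#' @param weight `"count"` (default) or `"allele_fraction"`.
#' @return `data.frame` (gene_id, category, gene_length, snv_load, del_load,
#'   snv_scaled, del_scaled) with attributes `pearson_r` and `pearson_p`.
#' @export
per_gene_load <- function(variants, g, weight = c("count", "allele_fraction")) {
  weight <- match.arg(weight)
  genes <- g$genes
  if (!nrow(genes)) stop("genome carries no gene annotation")
  L <- g$length
  glen <- (genes$end - genes$start) %% L
  w <- function(v) {
    if (weight == "count") rep(1, nrow(v)) else v$allele_fraction
  }
  snvs <- variants[variants$kind == "SNV", , drop = FALSE]
  dels <- variants[variants$kind != "SNV", , drop = FALSE]
  snv_load <- del_load <- numeric(nrow(genes))
  if (nrow(snvs)) {
    ws <- w(snvs)
    for (k in seq_len(nrow(genes))) {
      inside <- if (genes$end[k] > genes$start[k]) {
        snvs$pos5 >= genes$start[k] & snvs$pos5 < genes$end[k]
      } else {
        snvs$pos5 >= genes$start[k] | snvs$pos5 < genes$end[k]
      }
      snv_load[k] <- sum(ws[inside]) / glen[k]
    }
  }
  if (nrow(dels)) {
    wd <- w(dels)
    for (k in seq_len(nrow(genes))) {
      ov <- arcs_overlap(dels$pos5, dels$length, genes$start[k], glen[k], L)
      del_load[k] <- sum(wd[ov]) / glen[k]
    }
  }
  scale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(0, length(x)))
    (x - rng[1L]) / diff(rng)
  }
  out <- data.frame(gene_id = genes$gene_id, category = genes$category,
                    gene_length = glen, snv_load = snv_load,
                    del_load = del_load, snv_scaled = scale01(snv_load),
                    del_scaled = scale01(del_load),
                    stringsAsFactors = FALSE)
  pr <- pearson_cor(out$snv_scaled, out$del_scaled)
  attr(out, "pearson_r") <- pr$r
  attr(out, "pearson_p") <- pr$p
  out
}

#' Distance from VLRD 5' breakpoints to the nearest SNV
#'
#' @param vlrd_pos5 0-based VLRD 5' breakpoint positions.
#' @param snv_pos 0-based SNV positions.
#' @param L Genome length.
#' @return List: `mean_bp`, `sd_bp`, `co_position_fraction` (fraction of
#'   breakpoints at circular distance 0 from an SNV), `distances`.
#' @export
vlrd_snv_proximity <- function(vlrd_pos5, snv_pos, L) {
  if (!length(vlrd_pos5) || !length(snv_pos)) {
    stop("both the VLRD and the SNV set must be non-empty")
  }
  d <- vapply(vlrd_pos5, function(p) {
    min(circular_distance(rep(p, length(snv_pos)), snv_pos, L))
  }, numeric(1L))
  list(mean_bp = mean(d), sd_bp = stats::sd(d),
       co_position_fraction = mean(d == 0), distances = d)
}

#' Normalize per-sample variant counts for cross-sample comparison
#'
#' `fold_vs_reference_mean` divides every count by the mean count of a
#' reference sample group (e.g. the 10-week wild-type samples);
#' `min_sample` divides by the smallest per-sample count, so the lowest
#' sample maps to 1.
#'
#' @param counts Numeric vector of per-sample counts (named or not).
#' @param mode `"fold_vs_reference_mean"` or `"min_sample"`.
#' @param reference Logical vector marking the reference samples (required
#'   for fold mode).
#' @return Numeric vector of normalized counts.
#' @export
normalize_counts <- function(counts, mode = c("fold_vs_reference_mean",
                                              "min_sample"),
                             reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "fold_vs_reference_mean") {
    if (is.null(reference) || !any(reference)) {
      stop("fold normalization requires a non-empty reference group")
    }
    ref <- mean(counts[reference])
    if (ref == 0) stop("reference group mean is zero: cannot normalize")
    counts / ref
  } else {
    m <- min(counts)
    if (m == 0) stop("minimum sample count is zero: cannot normalize")
    counts / m
  }
}
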