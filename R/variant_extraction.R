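#' Downsample alignments to a fixed number of mapped records
#'
#' Cross-sample comparability requires the same number of aligned reads per
#' sample; this draws a uniform random subset of exactly `target_n` mapped
#' records, keeping or dropping mate pairs together (whole query names are
#' sampled). Deterministic under `seed`.
#'
#' @param records Alignment `data.frame`.
#' @param target_n Number of mapped records to keep.
#' @param seed Integer seed.
#' @param sample_id Optional label used in error messages.
#' @return Subset of `records`.
#' @export
downsample_alignments <- function(records, target_n, seed, sample_id = "sample") {
  mapped <- records[bitwAnd(records$flag, 4L) == 0L, , drop = FALSE]
  n <- nrow(mapped)
  if (target_n > n) {
    stop("downsampling ", sample_id, ": requested ", target_n,
         " records but only ", n, " mapped records available")
  }
  if (target_n == n) return(mapped)
  set.seed(seed)
  qn <- unique(mapped$qname)
  perm <- sample(qn)
  sizes <- table(mapped$qname)[perm]
  cum <- cumsum(as.integer(sizes))
  k <- which(cum == target_n)
  if (!length(k)) {
    stop("downsampling ", sample_id, ": cannot reach exactly ", target_n,
         " records while keeping mate pairs together")
  }
  keep <- perm[seq_len(k[1L])]
  mapped[mapped$qname %in% keep, , drop = FALSE]
}

# Canonical (left-aligned) junction position for a deletion of `len` starting
# at `pos5` (0-based, first deleted base): shift left while the base before
# the gap equals the last deleted base. `dseq` is the doubled sequence.
left_align_junction <- function(dseq, L, pos5, len) {
  p <- as.integer(pos5 %% L)
  while (p > 0L &&
         substr(dseq, p, p) == substr(dseq, p + len, p + len)) {
    p <- p - 1L
  }
  p
}

#' Extract raw SNV and deletion calls from doubled-reference alignments
#'
#' Walks each record's CIGAR to collect per-site mismatch evidence (SNVs) and
#' junction evidence from `D` operations; additionally pairs supplementary
#' alignments with their primaries to recover junctions reported as split
#' alignments. Evidence within `trim_border` bases of either read end is
#' ignored. Positions are normalized modulo `L`, so evidence from the two
#' tandem reference copies merges into a single record; a read never counts
#' twice for the same variant. Deletion breakpoints are left-aligned. Calls
#' with allele fraction below `min_fraction` are dropped at this stage.
#'
#' @param records Alignment `data.frame` (positions 0-based on the doubled
#'   reference).
#' @param g The [circular_genome()].
#' @param trim_border Bases ignored at each read end (default 5).
#' @param min_fraction Minimum allele fraction retained (default 0.005).
#' @return `data.frame` of raw variants: `kind` (`SNV`/`DEL`), `pos5`, `pos3`
#'   (0-based normalized), `length`, `ref`, `alt`, `support`, `depth`,
#'   `quality`, `allele_fraction`. Deletion quality is the mean over
#'   supporting reads of the minimum of the two flanking aligned-segment mean
#'   phred scores; SNV quality is the mean phred of supporting bases.
#' @export
extract_variants <- function(records, g, trim_border = 5L, min_fraction = 0.005) {
  stopifnot(inherits(g, "circular_genome"))
  L <- g$length
  dseq <- paste0(g$sequence, g$sequence)
  rec <- records[bitwAnd(records$flag, 4L) == 0L &
                   bitwAnd(records$flag, 256L) == 0L &
                   bitwAnd(records$flag, 1024L) == 0L, , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(kind = character(), pos5 = integer(), pos3 = integer(),
                      length = integer(), ref = character(), alt = character(),
                      support = integer(), depth = integer(), quality = numeric(),
                      allele_fraction = numeric(), stringsAsFactors = FALSE))
  }
  ops_list <- parse_cigar(rec$cigar)
  read_key <- paste0(rec$qname, "/", bitwAnd(rec$flag, 192L))

  snv_pos <- integer(0); snv_alt <- character(0)
  snv_read <- character(0); snv_qual <- numeric(0)
  del_pos <- integer(0); del_len <- integer(0)
  del_read <- character(0); del_qual <- numeric(0)
  # delta-encoded coverage accumulators on the normalized circle
  delta_m <- numeric(L + 1L)     # aligned (M) bases
  delta_span <- numeric(L + 1L)  # full reference span incl. deletions

  add_cov <- function(delta, s, e) {  # [s, e) on doubled ref, normalized
    if (e <= s) return(delta)
    s_n <- s %% L; e_n <- s_n + (e - s)
    if (e_n <= L) {
      delta[s_n + 1L] <- delta[s_n + 1L] + 1
      delta[e_n + 1L] <- delta[e_n + 1L] - 1
    } else {
      delta[s_n + 1L] <- delta[s_n + 1L] + 1
      delta[L + 1L] <- delta[L + 1L] - 1
      delta[1L] <- delta[1L] + 1
      delta[e_n - L + 1L] <- delta[e_n - L + 1L] - 1
    }
    delta
  }

  sup_flag <- bitwAnd(rec$flag, 2048L) != 0L
  seg_first <- integer(nrow(rec)); seg_last <- integer(nrow(rec))
  seg_start_ref <- integer(nrow(rec))

  for (i in seq_len(nrow(rec))) {
    ops <- ops_list[[i]]
    rl_implied <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
    if (rl_implied != nchar(rec$seq[i]) && rec$seq[i] != "*") {
      stop("malformed record ", rec$qname[i],
           ": CIGAR consumes ", rl_implied, " bases but SEQ has ",
           nchar(rec$seq[i]))
    }
    rlen <- rl_implied
    ref_cur <- rec$pos[i]; read_cur <- 0L
    qual_int <- NULL
    mean_seg_qual <- function(r0, r1) {  # read offsets [r0, r1)
      if (is.null(qual_int)) {
        qual_int <<- utf8ToInt(rec$qual[i]) - 33L
      }
      if (r1 <= r0) return(NA_real_)
      mean(qual_int[(r0 + 1L):r1])
    }
    segs <- list()  # ref, read, len of each M segment
    d_here <- list()
    for (k in seq_len(nrow(ops))) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        segs[[length(segs) + 1L]] <- c(ref = ref_cur, read = read_cur, len = len)
        ref_cur <- ref_cur + len; read_cur <- read_cur + len
      } else if (op == "I" || op == "S") {
        read_cur <- read_cur + len
      } else if (op == "D" || op == "N") {
        d_here[[length(d_here) + 1L]] <- c(pos = ref_cur, len = len,
                                           read_at = read_cur)
        ref_cur <- ref_cur + len
      }
    }
    if (ref_cur > 2L * L) {
      stop("malformed record ", rec$qname[i], ": alignment extends past 2L")
    }
    seg_start_ref[i] <- rec$pos[i]
    seg_first[i] <- rec$pos[i]
    seg_last[i] <- ref_cur
    delta_span <- add_cov(delta_span, rec$pos[i], ref_cur)

    for (sg in segs) {
      delta_m <- add_cov(delta_m, sg["ref"], sg["ref"] + sg["len"])
      # mismatch scan on the aligned segment
      rd <- substr(rec$seq[i], sg["read"] + 1L, sg["read"] + sg["len"])
      rf <- substr(dseq, sg["ref"] + 1L, sg["ref"] + sg["len"])
      if (rd != rf) {
        rd_i <- utf8ToInt(rd); rf_i <- utf8ToInt(rf)
        mm <- which(rd_i != rf_i)
        if (length(mm)) {
          read_at <- sg["read"] + mm - 1L
          keep <- read_at >= trim_border & read_at < (rlen - trim_border)
          mm <- mm[keep]; read_at <- read_at[keep]
          if (length(mm)) {
            if (is.null(qual_int)) qual_int <- utf8ToInt(rec$qual[i]) - 33L
            snv_pos <- c(snv_pos, as.integer((sg["ref"] + mm - 1L) %% L))
            snv_alt <- c(snv_alt, strsplit(rd, "")[[1L]][mm])
            snv_read <- c(snv_read, rep(read_key[i], length(mm)))
            snv_qual <- c(snv_qual, qual_int[read_at + 1L])
          }
        }
      }
    }
    for (dv in d_here) {
      read_at <- dv["read_at"]
      if (read_at < trim_border || (rlen - read_at) < trim_border) next
      q5 <- mean_seg_qual(max(0L, read_at - 10L), read_at)
      q3 <- mean_seg_qual(read_at, min(rlen, read_at + 10L))
      p5 <- left_align_junction(dseq, L, dv["pos"], dv["len"])
      del_pos <- c(del_pos, p5)
      del_len <- c(del_len, as.integer(dv["len"]))
      del_read <- c(del_read, read_key[i])
      del_qual <- c(del_qual, min(q5, q3, na.rm = TRUE))
    }
  }

  # junctions from split primary + supplementary alignment pairs
  if (any(sup_flag)) {
    for (qn in unique(rec$qname[sup_flag])) {
      idx <- which(rec$qname == qn)
      for (mate_bits in unique(bitwAnd(rec$flag[idx], 192L))) {
        ii <- idx[bitwAnd(rec$flag[idx], 192L) == mate_bits]
        if (length(ii) != 2L) next
        ii <- ii[order(rec$pos[ii])]
        left_end <- seg_last[ii[1L]]
        right_start <- seg_first[ii[2L]]
        gap <- right_start - left_end
        if (gap < 1L) next
        p5 <- left_align_junction(dseq, L, left_end, gap)
        del_pos <- c(del_pos, p5)
        del_len <- c(del_len, as.integer(gap))
        del_read <- c(del_read, read_key[ii[1L]])
        del_qual <- c(del_qual, mean(utf8ToInt(rec$qual[ii[1L]]) - 33L))
      }
    }
  }

  cov_m <- cumsum(delta_m)[seq_len(L)]
  cov_span <- cumsum(delta_span)[seq_len(L)]

  out <- list()
  if (length(snv_pos)) {
    key <- paste(snv_pos, snv_alt, sep = ":")
    # one vote per read per variant
    first <- !duplicated(paste(key, snv_read, sep = "@"))
    key <- key[first]; snv_pos <- snv_pos[first]; snv_alt <- snv_alt[first]
    snv_qual <- snv_qual[first]
    support <- as.integer(table(key)[key])
    agg <- !duplicated(key)
    qual_mean <- tapply(snv_qual, key, mean)[key]
    pos_u <- snv_pos[agg]; alt_u <- snv_alt[agg]
    out$snv <- data.frame(
      kind = "SNV", pos5 = pos_u, pos3 = NA_integer_, length = NA_integer_,
      ref = substring(g$sequence, pos_u + 1L, pos_u + 1L), alt = alt_u,
      support = support[agg], depth = as.integer(cov_m[pos_u + 1L]),
      quality = as.numeric(qual_mean[agg]), stringsAsFactors = FALSE)
  }
  if (length(del_pos)) {
    key <- paste(del_pos, del_len, sep = ":")
    first <- !duplicated(paste(key, del_read, sep = "@"))
    key <- key[first]; del_pos <- del_pos[first]; del_len <- del_len[first]
    del_qual <- del_qual[first]
    support <- as.integer(table(key)[key])
    agg <- !duplicated(key)
    qual_mean <- tapply(del_qual, key, mean)[key]
    pos_u <- del_pos[agg]; len_u <- del_len[agg]
    out$del <- data.frame(
      kind = "DEL", pos5 = pos_u, pos3 = as.integer((pos_u + len_u) %% L),
      length = len_u, ref = NA_character_, alt = NA_character_,
      support = support[agg], depth = as.integer(cov_span[pos_u + 1L]),
      quality = as.numeric(qual_mean[agg]), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(kind = character(), pos5 = integer(), pos3 = integer(),
                      length = integer(), ref = character(), alt = character(),
                      support = integer(), depth = integer(), quality = numeric(),
                      allele_fraction = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$depth <- pmax(res$depth, res$support)
  res$allele_fraction <- res$support / res$depth
  res <- res[res$allele_fraction >= min_fraction, , drop = FALSE]
  res <- res[order(res$kind, res$pos5, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply the post-call support/depth/quality filters
#'
#' Retains SNVs with support >= 4, depth >= 50 and quality >= 20, and
#' deletions with support >= 2, depth >= 25 and quality >= 10 (all
#' comparisons inclusive: the thresholds are stated minima). Per-filter
#' rejection counts are reported via [message()] and attached as the
#' `"rejections"` attribute.
#'
#' @param variants Raw variant `data.frame` from [extract_variants()].
#' @param snv_min_support,snv_min_depth,snv_min_quality SNV thresholds.
#' @param del_min_support,del_min_depth,del_min_quality Deletion thresholds.
#' @param quiet Suppress the rejection-count message.
#' @return Filtered variants (input order preserved).
#' @export
apply_post_filters <- function(variants,
                               snv_min_support = 4L, snv_min_depth = 50L,
                               snv_min_quality = 20,
                               del_min_support = 2L, del_min_depth = 25L,
                               del_min_quality = 10, quiet = FALSE) {
  if (!nrow(variants)) return(variants)
  is_snv <- variants$kind == "SNV"
  ok_support <- ifelse(is_snv, variants$support >= snv_min_support,
                       variants$support >= del_min_support)
  ok_depth <- ifelse(is_snv, variants$depth >= snv_min_depth,
                     variants$depth >= del_min_depth)
  ok_quality <- ifelse(is_snv, variants$quality >= snv_min_quality,
                       variants$quality >= del_min_quality)
  rejections <- c(support = sum(!ok_support),
                  depth = sum(ok_support & !ok_depth),
                  quality = sum(ok_support & ok_depth & !ok_quality))
  if (!quiet) {
    message("post-filters rejected: ", rejections["support"], " by support, ",
            rejections["depth"], " by depth, ", rejections["quality"],
            " by quality")
  }
  out <- variants[ok_support & ok_depth & ok_quality, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Classify deletions into ordinary deletions and very-long-range deletions
#'
#' Deletions with reference span at most `boundary` (15 kb) keep class
#' `"DEL"`; longer junctions become class `"VLRD"` (on a circular genome a
#' VLRD is indistinguishable from a short duplication/multimer). The two
#' classes partition the deletion set; SNVs keep class `"SNV"`.
#'
#' @param variants Variant `data.frame`.
#' @param boundary Length boundary in bp (default 15000).
#' @param sample_id Optional sample label column to attach.
#' @return The input with a `class` column (and `sample_id` if given).
#' @export
classify_deletions <- function(variants, boundary = 15000L, sample_id = NULL) {
  variants$class <- ifelse(variants$kind == "SNV", "SNV",
                           ifelse(variants$length > boundary, "VLRD", "DEL"))
  if (!is.null(sample_id)) variants$sample_id <- sample_id
  variants
}

#' Count discordant records (samtools -F 1294 semantics)
#'
#' Counts records with none of the bits {proper pair (0x2), unmapped (0x4),
#' mate unmapped (0x8), secondary (0x100), duplicate (0x400)} set, i.e. the
#' records a `samtools view -F 1294` extraction would keep.
#'
#' @param records Alignment `data.frame`.
#' @return Integer count; warns if unpaired records are present.
#' @export
count_discordant <- function(records) {
  if (nrow(records) && any(bitwAnd(records$flag, 1L) == 0L)) {
    warning("unpaired records present; discordance is a pair-level notion")
  }
  sum(bitwAnd(records$flag, 1294L) == 0L)
}

#' Write classified variants as a tidy TSV (1-based positions)
#' @param variants Classified variant `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(variants)) variants$sample_id else NA,
    class = if ("class" %in% names(variants)) variants$class else variants$kind,
    pos5_1based = variants$pos5 + 1L,
    pos3_1based = ifelse(is.na(variants$pos3), NA_integer_, variants$pos3 + 1L),
    length = variants$length, ref = variants$ref, alt = variants$alt,
    support = variants$support, depth = variants$depth,
    quality = variants$quality, allele_fraction = variants$allele_fraction)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variants as minimal VCF 4.2
#'
#' SNVs are written as plain substitutions; deletions as symbolic `<DEL>`
#' records with `END` and `SVLEN` INFO fields (`POS` is the 1-based position
#' of the last retained base before the gap, per VCF convention for symbolic
#' alleles).
#'
#' @param variants Classified variant `data.frame`.
#' @param g The [circular_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", g$name, g$length),
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$kind == "SNV") {
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.1f\tPASS\tAF=%g",
                           g$name, v$pos5 + 1L, v$ref, v$alt, v$quality,
                           v$allele_fraction), con)
      } else {
        anchor <- (v$pos5 - 1L) %% g$length
        writeLines(sprintf(
          "%s\t%d\t.\t%s\t<DEL>\t%.1f\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d;AF=%g",
          g$name, anchor + 1L,
          substring(g$sequence, anchor + 1L, anchor + 1L), v$quality,
          (v$pos5 + v$length) %% g$length, v$length, v$allele_fraction), con)
      }
    }
  }
  invisible(path)
}
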