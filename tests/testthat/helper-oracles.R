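# Independent oracles used across the suite. These deliberately use naive
# algorithms (enumeration, brute-force scans) and share no code with the
# implementation paths they check.

random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

random_genome <- function(L, seed = NULL, genes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  circular_genome("g", random_seq(L), genes)
}

rotate_seq <- function(s, r) {
  L <- nchar(s)
  r <- r %% L
  if (r == 0) return(s)
  paste0(substr(s, r + 1, L), substr(s, 1, r))
}

# Exhaustive global-alignment score: enumerate every monotone alignment path,
# score each with the affine gap model (gap of length k costs open + k*extend)
# and penalty-free terminal gap runs, take the maximum.
enum_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                             match = 5, mismatch = -4) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  score_ops <- function(ops) {
    runs <- rle(ops)
    k <- length(runs$lengths)
    sc <- 0; ia <- 0; ib <- 0
    for (r in seq_len(k)) {
      op <- runs$values[r]; len <- runs$lengths[r]
      if (op == "M") {
        for (t in seq_len(len)) {
          ia <- ia + 1; ib <- ib + 1
          sc <- sc + if (av[ia] == bv[ib]) match else mismatch
        }
      } else {
        if (op == "X") ia <- ia + len else ib <- ib + len
        if (r != 1 && r != k) sc <- sc - (gap_open + len * gap_extend)
      }
    }
    sc
  }
  rec <- function(ia, ib, ops) {
    if (ia == n && ib == m) {
      s <- score_ops(ops)
      if (s > best) best <<- s
      return(invisible())
    }
    if (ia < n && ib < m) rec(ia + 1, ib + 1, c(ops, "M"))
    if (ia < n) rec(ia + 1, ib, c(ops, "X"))
    if (ib < m) rec(ia, ib + 1, c(ops, "Y"))
  }
  rec(0, 0, character(0))
  best
}

# Brute-force distance from a breakpoint pair to the nearest repeat pair:
# every repeat, both copy assignments, distances enumerated base by base.
bf_breakpoint_repeat_distance <- function(p5, p3, repeats, L) {
  point_arc <- function(p, start, len) {
    min(vapply(seq_len(len) - 1L, function(o) {
      b <- (start + o) %% L
      d <- abs(p - b)
      min(d, L - d)
    }, numeric(1)))
  }
  best <- Inf
  for (r in seq_len(nrow(repeats))) {
    dA5 <- point_arc(p5, repeats$posA[r], repeats$length[r])
    dB3 <- point_arc(p3, repeats$posB[r], repeats$length[r])
    dB5 <- point_arc(p5, repeats$posB[r], repeats$length[r])
    dA3 <- point_arc(p3, repeats$posA[r], repeats$length[r])
    best <- min(best, (dA5 + dB3) / 2, (dB5 + dA3) / 2)
  }
  best
}

# Variant set as a canonical key for planted-truth comparisons.
variant_key <- function(v) {
  sort(paste(v$kind, v$pos5, ifelse(is.na(v$length), "", v$length),
             ifelse(is.na(v$alt), "", v$alt)))
}

# Minimal hand-built alignment record.
make_record <- function(qname, flag, pos, cigar, seq,
                        qual = paste(rep("?", nchar(seq)), collapse = ""),
                        rnext = "=", pnext = 0L, tlen = 0L) {
  data.frame(qname = qname, flag = as.integer(flag), rname = "dMT",
             pos = as.integer(pos), mapq = 60L, cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext),
             tlen = as.integer(tlen), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}
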