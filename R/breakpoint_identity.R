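#' Global alignment with affine gaps and free end gaps
#'
#' Needleman-Wunsch with an affine gap model in the needle style: a gap of
#' length k costs `gap_open + k * gap_extend`, and gaps at either end of the
#' alignment are penalty-free. Identity is the percentage of alignment
#' columns (end-gap columns included) that are matches. Tie-break on
#' traceback is deterministic: match/mismatch is preferred over a gap, and a
#' gap in `a` over a gap in `b`.
#'
#' @param a,b DNA strings (`A`/`C`/`G`/`T` only, non-empty).
#' @param gap_open Gap opening penalty (default 10).
#' @param gap_extend Per-column gap extension penalty (default 0.5).
#' @param match Match score (default 5, the EMBOSS nucleotide default).
#' @param mismatch Mismatch score (default -4).
#' @return List: `score`, `identity` (percent), `aln_length`, `matches`,
#'   `aligned_a`, `aligned_b`.
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         match = 5, mismatch = -4) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) {
    stop("ambiguous bases: only A/C/G/T are alignable")
  }
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  go <- gap_open + gap_extend  # cost of the first gapped column
  ge <- gap_extend
  NEG <- -1e18

  M <- matrix(NEG, n + 1L, m + 1L)   # a_i ~ b_j
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consumes a_i)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consumes b_j)
  M[1L, 1L] <- 0
  X[seq_len(n) + 1L, 1L] <- 0        # free leading gap in b
  Y[1L, seq_len(m) + 1L] <- 0        # free leading gap in a
  for (i in seq_len(n)) {
    si <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- si[j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - go, X[i, j + 1L] - ge,
                               Y[i, j + 1L] - go)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - go, X[i + 1L, j] - go,
                               Y[i + 1L, j] - ge)
    }
  }
  # free trailing gaps: best cell on the last row or column completes the
  # alignment, with the remaining tail gapped at no cost
  best <- c(-Inf, 0L, 0L)
  consider <- function(i, j) {
    v <- max(M[i + 1L, j + 1L], X[i + 1L, j + 1L], Y[i + 1L, j + 1L])
    if (v > best[1L]) best <<- c(v, i, j)
  }
  for (i in 0:n) consider(i, m)
  for (j in 0:m) consider(n, j)
  score <- best[1L]; ei <- best[2L]; ej <- best[3L]

  # traceback from (ei, ej); preference: M, then X (gap in b... gap-in-a is
  # Y consuming b? naming: X consumes a against a gap in b); spec order is
  # match/mismatch, then gap in a, then gap in b => M, Y, X
  ops <- character(0)
  i <- ei; j <- ej
  state <- {
    v <- c(M[i + 1L, j + 1L], Y[i + 1L, j + 1L], X[i + 1L, j + 1L])
    c("M", "Y", "X")[which.max(v)]
  }
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "M") {
      if (i == 0L || j == 0L) break
      s <- ifelse(av[i] == bv[j], match, mismatch)
      prev <- M[i + 1L, j + 1L] - s
      cand <- c(M = M[i, j], Y = Y[i, j], X = X[i, j])
      state_new <- names(cand)[which(abs(cand - prev) < tol)][1L]
      ops <- c("M", ops); i <- i - 1L; j <- j - 1L
      if (i == 0L && j == 0L) break
      state <- state_new
    } else if (state == "X") {
      if (i == 0L) break
      cur <- X[i + 1L, j + 1L]
      if (j == 0L && abs(cur) < tol && i > 0L) {
        # inside the free leading gap column block
        ops <- c(rep("X", i), ops); i <- 0L; break
      }
      cand <- c(M = M[i, j + 1L] - go, X = X[i, j + 1L] - ge,
                Y = Y[i, j + 1L] - go)
      state_new <- names(cand)[which(abs(cand - cur) < tol)][1L]
      if (is.na(state_new)) { ops <- c(rep("X", i), ops); i <- 0L; break }
      ops <- c("X", ops); i <- i - 1L
      state <- state_new
    } else {
      if (j == 0L) break
      cur <- Y[i + 1L, j + 1L]
      if (i == 0L && abs(cur) < tol && j > 0L) {
        ops <- c(rep("Y", j), ops); j <- 0L; break
      }
      cand <- c(M = M[i + 1L, j] - go, X = X[i + 1L, j] - go,
                Y = Y[i + 1L, j] - ge)
      state_new <- names(cand)[which(abs(cand - cur) < tol)][1L]
      if (is.na(state_new)) { ops <- c(rep("Y", j), ops); j <- 0L; break }
      ops <- c("Y", ops); j <- j - 1L
      state <- state_new
    }
  }
  if (i > 0L) ops <- c(rep("X", i), ops)
  if (j > 0L) ops <- c(rep("Y", j), ops)
  # trailing free gaps
  if (ei < n) ops <- c(ops, rep("X", n - ei))
  if (ej < m) ops <- c(ops, rep("Y", m - ej))

  ia <- 0L; ib <- 0L
  ca <- character(length(ops)); cb <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == "M") {
      ia <- ia + 1L; ib <- ib + 1L; ca[k] <- av[ia]; cb[k] <- bv[ib]
    } else if (ops[k] == "X") {
      ia <- ia + 1L; ca[k] <- av[ia]; cb[k] <- "-"
    } else {
      ib <- ib + 1L; ca[k] <- "-"; cb[k] <- bv[ib]
    }
  }
  matches <- sum(ca == cb & ca != "-")
  aln_length <- length(ops)
  list(score = score, identity = 100 * matches / aln_length,
       aln_length = aln_length, matches = matches,
       aligned_a = paste(ca, collapse = ""),
       aligned_b = paste(cb, collapse = ""))
}

#' Sequence identity between the two breakpoint windows of each deletion
#'
#' For each deletion, extracts the `2 * flank`-base window around the 5'
#' junction and the 3' junction (see [extract_window()]) and globally aligns
#' them with [global_align()]. Windows containing `N` are skipped (identity
#' `NA`).
#'
#' @param dels `data.frame` with 0-based `pos5`, `pos3` columns.
#' @param g The [circular_genome()].
#' @param flank Window half-width in bp (default 10: a 20-bp window).
#' @param ... Passed to [global_align()].
#' @return `data.frame`: `pos5`, `pos3`, `length` (if present in `dels`),
#'   `identity`, `aln_length`, `skipped`.
#' @export
breakpoint_window_identity <- function(dels, g, flank = 10L, ...) {
  n <- nrow(dels)
  identity <- rep(NA_real_, n); aln_len <- rep(NA_integer_, n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    w5 <- extract_window(g, dels$pos5[i], flank)
    w3 <- extract_window(g, dels$pos3[i], flank)
    if (attr(w5, "has_n") || attr(w3, "has_n")) {
      skipped[i] <- TRUE
      next
    }
    al <- global_align(as.character(w5), as.character(w3), ...)
    identity[i] <- al$identity
    aln_len[i] <- al$aln_length
  }
  out <- data.frame(pos5 = dels$pos5, pos3 = dels$pos3,
                    identity = identity, aln_length = aln_len,
                    skipped = skipped)
  if ("length" %in% names(dels)) out$length <- dels$length
  out
}

#' Relate breakpoint-window identity to deletion length
#'
#' Pearson correlation of identity against log10(length), plus a
#' normality-gated two-group comparison of identities for deletions of at
#' most `group_split` bp versus longer ones (a length equal to the split
#' goes to the short group).
#'
#' @param results Output of [breakpoint_window_identity()] with a `length`
#'   column.
#' @param group_split Length split in bp (default 100).
#' @return List: `pearson_r`, `p`, `r_undefined`, `group_means` (short,
#'   long), `group_test` (a [location_test_gated()] result or `NULL`).
#' @export
identity_length_relation <- function(results, group_split = 100) {
  ok <- !results$skipped & !is.na(results$identity)
  res <- results[ok, , drop = FALSE]
  if (nrow(res) < 3L) stop("need at least 3 scored deletions")
  r <- NA_real_; p <- NA_real_; undef <- FALSE
  if (stats::sd(res$identity) == 0 || stats::sd(log10(res$length)) == 0) {
    undef <- TRUE
  } else {
    ct <- stats::cor.test(res$identity, log10(res$length))
    r <- unname(ct$estimate); p <- ct$p.value
  }
  short <- res$identity[res$length <= group_split]
  long <- res$identity[res$length > group_split]
  gm <- c(short = mean(short), long = mean(long))
  gt <- if (length(short) >= 2L && length(long) >= 2L) {
    location_test_gated(short, long)
  }
  list(pearson_r = r, p = p, r_undefined = undef,
       group_means = gm, group_test = gt)
}
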