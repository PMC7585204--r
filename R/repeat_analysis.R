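#' Find approximate direct repeats on a circular genome
#'
#' A direct repeat is an unordered pair of same-strand sequence copies of
#' length at least `min_len` whose Hamming mismatch count is at most
#' `floor(length * max_mismatch_rate)` (default: one mismatch per four
#' nucleotides). Copies may wrap the origin but may not overlap each other;
#' only inclusion-maximal repeats (not contained in a longer valid repeat at
#' the same copy offset) are reported, each unordered pair once with
#' `posA < posB`. The production search uses a per-offset prefix-sum scan
#' with a sliding max-deque; [find_direct_repeats_bruteforce()] is an
#' independent exhaustive implementation of the same definition for
#' cross-checking.
#'
#' @param g A [circular_genome()] (or a plain sequence string).
#' @param min_len Minimum repeat length (default 8).
#' @param max_mismatch_rate Maximum mismatch fraction; must be the
#'   reciprocal of an integer (default 0.25).
#' @return `data.frame` with 0-based columns `posA`, `posB` and columns
#'   `length`, `mismatches`.
#' @export
find_direct_repeats <- function(g, min_len = 8L, max_mismatch_rate = 0.25) {
  seq <- if (inherits(g, "circular_genome")) g$sequence else toupper(g)
  denom <- round(1 / max_mismatch_rate)
  if (abs(denom - 1 / max_mismatch_rate) > 1e-9) {
    stop("max_mismatch_rate must be 1/k for integer k")
  }
  .find_repeats_scan(seq, as.integer(min_len), as.integer(denom))
}

#' @rdname find_direct_repeats
#' @export
find_direct_repeats_bruteforce <- function(g, min_len = 8L,
                                           max_mismatch_rate = 0.25) {
  seq <- if (inherits(g, "circular_genome")) g$sequence else toupper(g)
  denom <- round(1 / max_mismatch_rate)
  if (abs(denom - 1 / max_mismatch_rate) > 1e-9) {
    stop("max_mismatch_rate must be 1/k for integer k")
  }
  .find_repeats_bruteforce(seq, as.integer(min_len), as.integer(denom))
}

# Circular distance from point p to the nearest base of the arc
# [start, start + len) (vectorized over start/len).
point_to_arc_distance <- function(p, start, len, L) {
  inside <- ((p - start) %% L) < len
  d_start <- circular_distance(rep(p, length(start)), start, L)
  end <- (start + len - 1L) %% L
  d_end <- circular_distance(rep(p, length(start)), end, L)
  ifelse(inside, 0L, pmin(d_start, d_end))
}

#' Shortest average breakpoint-pair-to-repeat-pair distance
#'
#' For a deletion with breakpoints `pos5`/`pos3`, considers every direct
#' repeat pair and both assignments of its two copies to the two
#' breakpoints; the statistic is the minimum over repeats of the smaller
#' mean of the two copy-to-breakpoint circular distances, each distance
#' measured to the nearest base of the repeat copy.
#'
#' @param pos5,pos3 Breakpoint positions in `[0, L)` (vectorized: one
#'   deletion per element).
#' @param repeats Repeat catalogue from [find_direct_repeats()].
#' @param L Genome length.
#' @return Numeric vector: one shortest average distance per deletion.
#' @export
breakpoint_repeat_distance <- function(pos5, pos3, repeats, L) {
  if (is.null(repeats) || !nrow(repeats)) {
    stop("repeat catalogue is empty; the statistic is undefined")
  }
  vapply(seq_along(pos5), function(i) {
    dA5 <- point_to_arc_distance(pos5[i], repeats$posA, repeats$length, L)
    dB3 <- point_to_arc_distance(pos3[i], repeats$posB, repeats$length, L)
    dB5 <- point_to_arc_distance(pos5[i], repeats$posB, repeats$length, L)
    dA3 <- point_to_arc_distance(pos3[i], repeats$posA, repeats$length, L)
    min(pmin((dA5 + dB3) / 2, (dB5 + dA3) / 2))
  }, numeric(1L))
}

#' Generate an in-silico length-matched null deletion library
#'
#' Draws `n` start positions uniformly on the circle and assigns the
#' observed deletion lengths to them in randomly shuffled order; end
#' positions are `start + length` modulo `L` (null deletions may wrap the
#' origin). The length multiset of the null library is identical to the
#' observed one.
#'
#' @param observed `data.frame` with a `length` column (observed deletions).
#' @param L Genome length.
#' @param seed Integer seed.
#' @return `data.frame` with 0-based `start`, `length`, `end`.
#' @export
generate_null_library <- function(observed, L, seed) {
  n <- nrow(observed)
  if (n < 1L) stop("need at least one observed deletion")
  set.seed(seed)
  starts <- sample.int(L, n, replace = TRUE) - 1L
  lens <- sample(observed$length)
  data.frame(start = starts, length = lens, end = (starts + lens) %% L)
}

#' Compare observed deletions against a null library
#'
#' Computes the breakpoint-to-repeat distance statistic for every deletion
#' in the observed and null sets and compares the two distance samples with
#' a two-sided Welch t-test.
#'
#' @param observed `data.frame` with `pos5`/`pos3` columns (or
#'   `start`/`end`).
#' @param null `data.frame` from [generate_null_library()].
#' @param repeats Repeat catalogue.
#' @param L Genome length.
#' @return List: `mean_obs`, `mean_null`, `p` (NA with a message when either
#'   set has fewer than 2 members), `d_obs`, `d_null`.
#' @export
compare_observed_vs_null <- function(observed, null, repeats, L) {
  get_bp <- function(x) {
    if (all(c("pos5", "pos3") %in% names(x))) {
      list(p5 = x$pos5, p3 = x$pos3)
    } else {
      list(p5 = x$start, p3 = x$end)
    }
  }
  ob <- get_bp(observed); nu <- get_bp(null)
  if (!length(ob$p5) || !length(nu$p5)) stop("both deletion sets must be non-empty")
  d_obs <- breakpoint_repeat_distance(ob$p5, ob$p3, repeats, L)
  d_null <- breakpoint_repeat_distance(nu$p5, nu$p3, repeats, L)
  p <- NA_real_
  if (length(d_obs) >= 2L && length(d_null) >= 2L &&
      (stats::var(d_obs) > 0 || stats::var(d_null) > 0)) {
    p <- stats::t.test(d_obs, d_null)$p.value
  } else if (length(d_obs) < 2L || length(d_null) < 2L) {
    message("fewer than 2 deletions in a set: p undefined, means returned")
  } else {
    p <- 1  # both samples constant: no evidence of a difference
  }
  list(mean_obs = mean(d_obs), mean_null = mean(d_null), p = p,
       d_obs = d_obs, d_null = d_null)
}

#' Write a repeat catalogue as TSV (1-based positions)
#' @param repeats Catalogue from [find_direct_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_tsv <- function(repeats, path) {
  out <- data.frame(posA_1based = repeats$posA + 1L,
                    posB_1based = repeats$posB + 1L,
                    length = repeats$length, mismatches = repeats$mismatches)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
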