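#' Construct a circular genome
#'
#' A `circular_genome` holds the mitochondrial (or any small circular)
#' reference sequence together with its gene annotation. All internal
#' coordinates are 0-based, half-open, on the forward strand; user-facing
#' tables written by the reporting functions are 1-based closed.
#'
#' @param name Sequence name (single string).
#' @param sequence DNA sequence as a single string; `A`/`C`/`G`/`T`/`N` only,
#'   at least 100 bases.
#' @param genes Optional `data.frame` with columns `gene_id`, `start`, `end`
#'   (0-based half-open; `end < start` encodes a feature spanning the
#'   replication origin) and `category` (one of `"protein"`, `"tRNA"`,
#'   `"rRNA"`, `"NCR"`).
#'
#' @return An object of class `circular_genome` with fields `name`,
#'   `sequence`, `length` and `genes`.
#' @export
circular_genome <- function(name, sequence, genes = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 100L) {
    stop("circular genome must be at least 100 bp, got ", L)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters other than A/C/G/T/N")
  }
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), category = character(),
                        stringsAsFactors = FALSE)
  } else {
    required <- c("gene_id", "start", "end", "category")
    if (!all(required %in% names(genes))) {
      stop("gene table must have columns ", paste(required, collapse = ", "))
    }
    genes <- genes[, required]
    genes$start <- as.integer(genes$start %% L)
    genes$end <- as.integer(genes$end %% L)
    len <- (genes$end - genes$start) %% L
    if (any(len == 0L)) {
      stop("zero-length gene feature(s): ",
           paste(genes$gene_id[len == 0L], collapse = ", "))
    }
    bad <- !genes$category %in% c("protein", "tRNA", "rRNA", "NCR")
    if (any(bad)) {
      stop("unknown gene category: ",
           paste(unique(genes$category[bad]), collapse = ", "))
    }
  }
  structure(list(name = name, sequence = sequence, length = L, genes = genes),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("circular_genome '", x$name, "': ", x$length, " bp, ",
      nrow(x$genes), " gene feature(s)\n", sep = "")
  invisible(x)
}

#' Read a circular genome from FASTA (and optionally a BED annotation)
#'
#' @param fasta Path to a single-record FASTA file.
#' @param bed Optional path to a gene annotation BED file (see
#'   [read_gene_bed()]).
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(fasta, bed = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    stop("expected a single-record FASTA, got ", length(seqs), " records")
  }
  genes <- if (!is.null(bed)) read_gene_bed(bed) else NULL
  circular_genome(sub("\\s.*$", "", names(seqs)[1L]),
                  as.character(seqs[[1L]]), genes)
}

#' Write a circular genome (or its doubled reference) as FASTA
#'
#' @param g A [circular_genome()] or `doubled_reference`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path) {
  if (inherits(g, "doubled_reference")) {
    set <- Biostrings::DNAStringSet(g$sequence)
    names(set) <- paste0(g$source$name, "_dMT")
  } else {
    set <- Biostrings::DNAStringSet(g$sequence)
    names(set) <- g$name
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene annotation from BED
#'
#' Expects BED with 0-based half-open intervals: columns chrom, start, end,
#' name (gene id), score (unused), strand (unused), and the feature category
#' (`protein`/`tRNA`/`rRNA`/`NCR`) carried in an extra 7th column, or, for
#' 4/5-column files, in the last column present.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `gene_id`, `start`, `end`, `category`.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 4L) stop("BED annotation needs at least 4 columns")
  category <- if (ncol(tab) >= 7L) tab[[7L]] else tab[[ncol(tab)]]
  data.frame(gene_id = as.character(tab[[4L]]),
             start = as.integer(tab[[2L]]),
             end = as.integer(tab[[3L]]),
             category = as.character(category),
             stringsAsFactors = FALSE)
}

#' Write gene annotation as BED
#' @param g A [circular_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(g, path) {
  genes <- g$genes
  utils::write.table(
    data.frame(g$name, genes$start, genes$end, genes$gene_id, 0L, "+",
               genes$category),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the doubled (tandem duplicated) reference
#'
#' Concatenates the circular sequence with itself so that alignments and
#' deletion junctions crossing the origin become contiguous on a linear
#' reference of length 2L.
#'
#' @param g A [circular_genome()].
#' @return An object of class `doubled_reference` with fields `source` and
#'   `sequence` (length 2L).
#' @export
build_doubled_reference <- function(g) {
  stopifnot(inherits(g, "circular_genome"))
  structure(list(source = g, sequence = paste0(g$sequence, g$sequence)),
            class = "doubled_reference")
}

#' Map a doubled-reference position back to the circle
#'
#' @param p Integer position(s) in `[0, 2L)` on the doubled reference.
#' @param L Circular genome length.
#' @return `p %% L`, in `[0, L)`.
#' @export
normalize_position <- function(p, L) {
  p <- as.numeric(p)
  if (any(p < 0 | p >= 2 * L)) {
    stop("position outside [0, 2L): ", p[which(p < 0 | p >= 2 * L)[1L]])
  }
  as.integer(p %% L)
}

#' Shortest arc distance between two circular positions
#'
#' @param a,b Positions in `[0, L)` (vectorized, recycled).
#' @param L Circular genome length.
#' @return The length of the shorter of the two arcs between `a` and `b`;
#'   symmetric and at most `L/2`.
#' @export
circular_distance <- function(a, b, L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a < 0 | a >= L) || any(b < 0 | b >= L)) {
    stop("positions must lie in [0, L)")
  }
  d <- (a - b) %% L
  as.integer(pmin(d, L - d))
}

#' Extract the sequence window around a breakpoint junction
#'
#' Returns the `2 * flank`-base window centred on the junction immediately
#' before `center`: the `flank` bases ending at `center - 1` followed by the
#' `flank` bases starting at `center`, wrapping the origin as needed. Windows
#' containing `N` are flagged via the `"has_n"` attribute so downstream
#' identity scoring can skip them.
#'
#' @param g A [circular_genome()].
#' @param center Junction position in `[0, L)`.
#' @param flank Bases on each side (`flank >= 1`, `2 * flank <= L`).
#' @return A `2 * flank`-character string with attribute `has_n`.
#' @export
extract_window <- function(g, center, flank) {
  stopifnot(inherits(g, "circular_genome"), flank >= 1)
  L <- g$length
  if (2 * flank > L) stop("flank too large for genome of length ", L)
  if (center < 0 || center >= L) stop("center must lie in [0, L)")
  idx <- ((center - flank):(center + flank - 1L)) %% L
  w <- paste(strsplit(g$sequence, "", fixed = TRUE)[[1L]][idx + 1L],
             collapse = "")
  attr(w, "has_n") <- grepl("N", w, fixed = TRUE)
  w
}

#' Assign a position to a gene
#'
#' Overlapping annotations are broken deterministically: first by feature
#' start, then lexically by `gene_id`. Origin-spanning features (`end <
#' start`) are handled on the circle.
#'
#' @param g A [circular_genome()].
#' @param p Position(s) in `[0, L)`.
#' @return Character vector of gene ids, `"intergenic"` where no feature
#'   covers the position.
#' @export
assign_gene <- function(g, p) {
  stopifnot(inherits(g, "circular_genome"))
  L <- g$length
  p <- as.integer(p)
  if (any(p < 0 | p >= L)) stop("positions must lie in [0, L)")
  genes <- g$genes
  if (nrow(genes) == 0L) return(rep("intergenic", length(p)))
  ord <- order(genes$start, genes$gene_id)
  genes <- genes[ord, ]
  vapply(p, function(pos) {
    inside <- ifelse(genes$end > genes$start,
                     pos >= genes$start & pos < genes$end,
                     pos >= genes$start | pos < genes$end)
    if (any(inside)) genes$gene_id[which(inside)[1L]] else "intergenic"
  }, character(1L))
}
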