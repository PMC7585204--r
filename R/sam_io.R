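#' Write alignment records as plain-text SAM
#'
#' Alignment records travel through the pipeline as a `data.frame` with the
#' eleven mandatory SAM columns (`qname`, `flag`, `rname`, `pos` 0-based
#' internally, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`).
#' On disk, `pos`/`pnext` follow the SAM convention (1-based).
#'
#' @param records Alignment `data.frame`.
#' @param path Output path.
#' @param ref_name Reference sequence name for the `@SQ` header line.
#' @param ref_length Reference length (for the doubled reference, `2L`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, ref_name, ref_length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_length))),
             con)
  if (nrow(records)) {
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                     records$qname, records$flag, records$rname,
                     records$pos + 1L, records$mapq, records$cigar,
                     records$rnext, records$pnext + 1L, records$tlen,
                     records$seq, records$qual)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a plain-text SAM file
#'
#' Parses the eleven mandatory columns; optional tags are dropped. Positions
#' are converted to the package's internal 0-based convention.
#'
#' @param path SAM file path.
#' @return Alignment `data.frame` (see [write_sam()]); the header's first
#'   `@SQ` name/length are attached as attributes `ref_name`/`ref_length`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  ref_name <- NA_character_; ref_length <- NA_integer_
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq)) {
    f <- strsplit(sq[1L], "\t", fixed = TRUE)[[1L]]
    ref_name <- sub("^SN:", "", f[startsWith(f, "SN:")][1L])
    ref_length <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1L]))
  }
  if (!length(body)) {
    rec <- empty_records()
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    get <- function(i) vapply(f, `[[`, character(1L), i)
    rec <- data.frame(qname = get(1L), flag = as.integer(get(2L)),
                      rname = get(3L), pos = as.integer(get(4L)) - 1L,
                      mapq = as.integer(get(5L)), cigar = get(6L),
                      rnext = get(7L), pnext = as.integer(get(8L)) - 1L,
                      tlen = as.integer(get(9L)), seq = get(10L),
                      qual = get(11L), stringsAsFactors = FALSE)
  }
  attr(rec, "ref_name") <- ref_name
  attr(rec, "ref_length") <- ref_length
  rec
}

empty_records <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), qual = character(), stringsAsFactors = FALSE)
}

#' Parse CIGAR strings into operation lists
#'
#' @param cigar Character vector of CIGAR strings.
#' @return List (one element per input) of `data.frame`s with columns `op`
#'   and `len`.
#' @keywords internal
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  toks <- regmatches(cigar, m)
  lapply(toks, function(tt) {
    data.frame(op = sub("^\\d+", "", tt),
               len = as.integer(sub("[MIDNSHP=X]$", "", tt)),
               stringsAsFactors = FALSE)
  })
}

#' Reference-consumed length of CIGAR strings
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference spans (M/D/N/=/X).
#' @keywords internal
cigar_ref_span <- function(cigar) {
  vapply(parse_cigar(cigar), function(ops) {
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L))
}

#' Read-consumed length of CIGAR strings
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of read lengths implied (M/I/S/=/X).
#' @keywords internal
cigar_read_span <- function(cigar) {
  vapply(parse_cigar(cigar), function(ops) {
    sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1L))
}
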