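#' Simulation configuration for synthetic circular-genome data
#'
#' Collects every knob of the synthetic-data generator: genome size and gene
#' count, planted direct repeats, planted SNVs/deletions/very-long-range
#' deletions (VLRDs) with their heteroplasmy fractions, read geometry and
#' coverage. A single integer seed fixes all randomness, so every output is a
#' pure function of the configuration.
#'
#' @param seed Integer seed.
#' @param L Genome length in bp (default 16300, mouse-mtDNA sized).
#' @param n_genes Number of gene features to annotate.
#' @param repeat_plan `data.frame(length, mismatches, posA, posB)`; each row
#'   plants two copies of a random `length`-mer (length >= 8) at `posA` and
#'   `posB` with exactly `mismatches` substitutions in the second copy.
#' @param snv_plan `data.frame(pos, alt, fraction)` with `alt` a base or `NA`
#'   (pick any non-reference base) and `fraction` in (0, 1].
#' @param deletion_plan `data.frame(start, length, fraction)` with lengths at
#'   most 15000 (ordinary deletions).
#' @param vlrd_plan `data.frame(start, length, fraction)` with lengths above
#'   15000 (very-long-range deletions / putative multimers).
#' @param read_length Read length in bp (default 150, paired-end).
#' @param depth Mean coverage.
#' @param error_rate Uniform per-base substitution error rate (default 0:
#'   clean reads; read-level QC is an upstream contract).
#' @param insert_size Fragment length on the molecule (default
#'   `2 * read_length + 50`).
#' @param cohort Optional [cohort_design()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed, L = 16300L, n_genes = 13L,
                              repeat_plan = NULL, snv_plan = NULL,
                              deletion_plan = NULL, vlrd_plan = NULL,
                              read_length = 150L, depth = 100,
                              error_rate = 0, insert_size = NULL,
                              cohort = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L, L >= 100)
  if (is.null(insert_size)) insert_size <- 2L * read_length + 50L
  empty3 <- function(...) {
    nm <- c(...)
    out <- rep(list(numeric(0)), length(nm)); names(out) <- nm
    as.data.frame(out)
  }
  if (is.null(repeat_plan)) repeat_plan <- empty3("length", "mismatches", "posA", "posB")
  if (is.null(snv_plan)) snv_plan <- empty3("pos", "alt", "fraction")
  if (is.null(deletion_plan)) deletion_plan <- empty3("start", "length", "fraction")
  if (is.null(vlrd_plan)) vlrd_plan <- empty3("start", "length", "fraction")
  check_frac <- function(f) all(f > 0 & f <= 1)
  if (!check_frac(snv_plan$fraction) || !check_frac(deletion_plan$fraction) ||
      !check_frac(vlrd_plan$fraction)) {
    stop("allele fractions must lie in (0, 1]")
  }
  for (plan in list(snv_plan$pos, deletion_plan$start, vlrd_plan$start)) {
    if (length(plan) && any(plan < 0 | plan >= L)) {
      stop("planted coordinates must lie in [0, L)")
    }
  }
  if (nrow(repeat_plan) && any(repeat_plan$length < 8L)) {
    stop("planted repeats must be at least 8 bp")
  }
  if (any(c(deletion_plan$length, vlrd_plan$length) >= L)) {
    stop("deletion length must be at most L - 1")
  }
  if (depth < 0 || error_rate < 0 || error_rate > 1) {
    stop("invalid depth or error rate")
  }
  structure(list(seed = as.integer(seed), L = as.integer(L),
                 n_genes = as.integer(n_genes), repeat_plan = repeat_plan,
                 snv_plan = snv_plan, deletion_plan = deletion_plan,
                 vlrd_plan = vlrd_plan, read_length = as.integer(read_length),
                 depth = depth, error_rate = error_rate,
                 insert_size = as.integer(insert_size), cohort = cohort),
            class = "simulation_config")
}

#' Draw deletion lengths from the bimodal short/long mixture
#'
#' Half the lengths are uniform on 1–99 bp (the short mode), half uniform on
#' 1000–15000 bp (the long mode), reproducing the qualitative bimodality of
#' mtDNA deletion sizes.
#'
#' @param n Number of lengths.
#' @return Integer vector of lengths.
#' @export
sample_deletion_lengths <- function(n) {
  short <- stats::runif(n) < 0.5
  out <- integer(n)
  out[short] <- sample.int(99L, sum(short), replace = TRUE)
  out[!short] <- sample(1000:15000, sum(!short), replace = TRUE)
  out
}

#' Generate a synthetic circular genome with planted direct repeats
#'
#' Draws a uniform-composition random genome, plants each planned repeat as
#' two copies with the requested Hamming distance, and annotates `n_genes`
#' evenly spaced gene features (categories cycled over protein/tRNA/rRNA with
#' a final NCR; the last feature spans the origin so origin arithmetic is
#' exercised by default).
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `genome` (a [circular_genome()]) and `repeats`
#'   (`data.frame(posA, posB, length, mismatches)` of planted repeats).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  L <- cfg$L
  bases <- c("A", "C", "G", "T")
  seq_vec <- sample(bases, L, replace = TRUE)

  rp <- cfg$repeat_plan
  if (nrow(rp)) {
    spans <- cbind(c(rp$posA, rp$posB), c(rp$posA, rp$posB) + rep(rp$length, 2) - 1L)
    if (any(spans[, 2L] >= L)) stop("planted repeat copies must not wrap the origin")
    ord <- order(spans[, 1L])
    sp <- spans[ord, , drop = FALSE]
    if (nrow(sp) > 1L && any(sp[-1L, 1L] <= sp[-nrow(sp), 2L])) {
      stop("repeat plan infeasible: planted copies overlap")
    }
    for (i in seq_len(nrow(rp))) {
      len <- rp$length[i]
      unit <- sample(bases, len, replace = TRUE)
      copy <- unit
      if (rp$mismatches[i] > 0L) {
        at <- sample.int(len, rp$mismatches[i])
        copy[at] <- vapply(copy[at], function(b) sample(setdiff(bases, b), 1L),
                           character(1L))
      }
      seq_vec[rp$posA[i] + seq_len(len)] <- unit
      seq_vec[rp$posB[i] + seq_len(len)] <- copy
    }
  }

  genes <- NULL
  if (cfg$n_genes > 0L) {
    slot <- L %/% cfg$n_genes
    starts <- (seq_len(cfg$n_genes) - 1L) * slot
    ends <- starts + max(1L, as.integer(slot * 0.85))
    cats <- rep(c("protein", "tRNA", "rRNA"), length.out = cfg$n_genes)
    cats[cfg$n_genes] <- "NCR"
    # last feature wraps the origin so circular gene assignment is exercised
    ends[cfg$n_genes] <- (starts[cfg$n_genes] +
                            max(1L, as.integer(slot * 0.85))) %% L
    if (ends[cfg$n_genes] == starts[cfg$n_genes]) ends[cfg$n_genes] <- starts[cfg$n_genes] + 1L
    genes <- data.frame(gene_id = sprintf("G%02d", seq_len(cfg$n_genes)),
                        start = starts, end = ends, category = cats,
                        stringsAsFactors = FALSE)
    if (ends[cfg$n_genes] > starts[cfg$n_genes]) {
      genes$end[cfg$n_genes] <- min(ends[cfg$n_genes], L - 1L)
    }
  }
  g <- circular_genome("synthetic_mt", paste(seq_vec, collapse = ""), genes)
  planted <- data.frame(posA = as.integer(rp$posA), posB = as.integer(rp$posB),
                        length = as.integer(rp$length),
                        mismatches = as.integer(rp$mismatches))
  list(genome = g, repeats = planted)
}

# Walk `n_bases` read bases along the doubled reference from `s`, jumping
# the supplied deletion junctions; returns sequence, CIGAR and M segments
# (with read offsets) for downstream SNV placement.
walk_read <- function(dseq, s, n_bases, junctions) {
  parts <- character(0); ops_len <- integer(0); ops_op <- character(0)
  segs <- list()
  cur <- s; remaining <- n_bases; read_off <- 0L
  while (remaining > 0L) {
    cand <- junctions[junctions$pos > cur & junctions$pos < cur + remaining, ,
                      drop = FALSE]
    if (!nrow(cand)) {
      parts <- c(parts, substr(dseq, cur + 1L, cur + remaining))
      ops_op <- c(ops_op, "M"); ops_len <- c(ops_len, remaining)
      segs[[length(segs) + 1L]] <- c(ref = cur, read = read_off, len = remaining)
      cur <- cur + remaining
      remaining <- 0L
    } else {
      j <- cand$pos[which.min(cand$pos)]
      jl <- cand$len[which.min(cand$pos)]
      take <- as.integer(j - cur)
      parts <- c(parts, substr(dseq, cur + 1L, cur + take))
      ops_op <- c(ops_op, "M", "D"); ops_len <- c(ops_len, take, jl)
      segs[[length(segs) + 1L]] <- c(ref = cur, read = read_off, len = take)
      read_off <- read_off + take
      remaining <- remaining - take
      cur <- j + jl
    }
  }
  # drop a trailing D if the walk ended exactly at a junction boundary
  while (length(ops_op) && ops_op[length(ops_op)] == "D") {
    ops_op <- ops_op[-length(ops_op)]; ops_len <- ops_len[-length(ops_len)]
  }
  list(seq = paste(parts, collapse = ""),
       cigar = paste0(ops_len, ops_op, collapse = ""),
       ref_end = cur,
       segs = do.call(rbind, segs))
}

# Reference position reached after consuming `m` molecule bases from `s`.
ref_advance <- function(s, m, junctions) {
  cur <- s
  while (m > 0L) {
    cand <- junctions[junctions$pos > cur & junctions$pos <= cur + m, ,
                      drop = FALSE]
    if (!nrow(cand)) {
      cur <- cur + m; m <- 0L
    } else {
      j <- cand$pos[which.min(cand$pos)]
      jl <- cand$len[which.min(cand$pos)]
      m <- m - (j - cur)
      cur <- j + jl
    }
  }
  cur
}

#' Simulate paired-end alignments against the doubled reference
#'
#' Fragments are placed uniformly on the circle; each fragment carries every
#' planted variant independently with probability equal to its allele
#' fraction. Reads crossing a carried deletion junction are reported with a
#' `D` CIGAR operation spanning the gap (junction-spanning alignments, as a
#' mapper run with a large `maxindel` would produce); VLRD-carrying
#' fragments additionally emit discordant mate pairs flanking the junction
#' (mapped pairs lacking the proper-pair flag, so they survive a
#' `samtools -F 1294` style extraction). Base qualities are constant Q30.
#' Carriage is expressed locally: a read reflects the junctions and
#' substitutions inside its own span, so each planted variant is recoverable
#' from its overlapping reads even when two deleted arcs could not coexist
#' on one molecule (the generator is a test harness for extraction, not a
#' population model).
#'
#' @param g A [circular_genome()] (usually from [generate_genome()]).
#' @param cfg The [simulation_config()].
#' @return List with `records` (alignment `data.frame`, positions 0-based on
#'   the doubled reference) and `truth` (`data.frame` of planted variants
#'   with class labels).
#' @export
simulate_alignments <- function(g, cfg) {
  stopifnot(inherits(g, "circular_genome"), inherits(cfg, "simulation_config"))
  L <- g$length; rl <- cfg$read_length
  n_frags <- as.integer(ceiling(cfg$depth * L / (2 * rl)))
  if (cfg$depth * L / rl < 50) stop("depth too low: need at least 50 reads")
  set.seed(cfg$seed + 1L)
  dseq <- paste0(g$sequence, g$sequence)

  snv <- cfg$snv_plan
  if (nrow(snv)) {
    ref_b <- substring(g$sequence, snv$pos + 1L, snv$pos + 1L)
    alt <- as.character(snv$alt)
    fix <- is.na(alt) | alt == ref_b
    if (any(fix)) {
      alt[fix] <- vapply(ref_b[fix], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1L))
    }
    snv$alt <- alt; snv$ref <- ref_b
  }
  dels <- rbind(
    if (nrow(cfg$deletion_plan)) cbind(cfg$deletion_plan, kind = "DEL"),
    if (nrow(cfg$vlrd_plan)) cbind(cfg$vlrd_plan, kind = "VLRD"))
  n_del <- if (is.null(dels)) 0L else nrow(dels)

  truth <- rbind(
    if (nrow(snv)) data.frame(kind = "SNV", pos5 = as.integer(snv$pos),
                              pos3 = NA_integer_, length = NA_integer_,
                              ref = snv$ref, alt = snv$alt,
                              fraction = snv$fraction,
                              class = "SNV", stringsAsFactors = FALSE),
    if (n_del) {
      # canonical (left-aligned) breakpoints, matching the extractor
      p5 <- vapply(seq_len(n_del), function(k) {
        left_align_junction(dseq, L, dels$start[k], dels$length[k])
      }, integer(1L))
      data.frame(kind = "DEL", pos5 = p5,
                 pos3 = as.integer((p5 + dels$length) %% L),
                 length = as.integer(dels$length),
                 ref = NA_character_, alt = NA_character_,
                 fraction = dels$fraction,
                 class = ifelse(dels$length > 15000, "VLRD", "DEL"),
                 stringsAsFactors = FALSE)
    })
  if (is.null(truth)) {
    truth <- data.frame(kind = character(), pos5 = integer(), pos3 = integer(),
                        length = integer(), ref = character(), alt = character(),
                        fraction = numeric(), class = character(),
                        stringsAsFactors = FALSE)
  }

  qual30 <- paste(rep("?", rl), collapse = "")
  out <- vector("list", 2L * n_frags + 256L)
  n_rec <- 0L
  push <- function(rec) {
    n_rec <<- n_rec + 1L
    out[[n_rec]] <<- rec
  }
  make_rec <- function(qname, flag, pos, cigar, seq, mate_pos, tlen, qual) {
    list(qname = qname, flag = flag, rname = "dMT", pos = as.integer(pos),
         mapq = 60L, cigar = cigar, rnext = "=", pnext = as.integer(mate_pos),
         tlen = as.integer(tlen), seq = seq, qual = qual)
  }

  for (i in seq_len(n_frags)) {
    carries_snv <- if (nrow(snv)) stats::runif(nrow(snv)) < snv$fraction else logical(0)
    carries_del <- if (n_del) stats::runif(n_del) < dels$fraction else logical(0)
    cd <- if (any(carries_del)) dels[carries_del, , drop = FALSE] else NULL
    # junctions appear in both copies of the doubled reference
    junctions <- if (!is.null(cd)) {
      data.frame(pos = c(cd$start, cd$start + L),
                 len = rep(cd$length, 2L))
    } else data.frame(pos = numeric(0), len = numeric(0))

    ok <- FALSE
    for (attempt in 1:50) {
      s1 <- sample.int(L, 1L) - 1L
      s2 <- ref_advance(s1, cfg$insert_size - rl, junctions)
      end2 <- ref_advance(s2, rl, junctions)
      if (end2 <= 2L * L) { ok <- TRUE; break }
    }
    if (!ok) next
    r1 <- walk_read(dseq, s1, rl, junctions)
    r2 <- walk_read(dseq, s2, rl, junctions)

    apply_snvs <- function(r) {
      if (!any(carries_snv)) return(r$seq)
      sv <- r$seq
      pos_d <- c(snv$pos[carries_snv], snv$pos[carries_snv] + L)
      alt_d <- rep(snv$alt[carries_snv], 2L)
      for (k in seq_along(pos_d)) {
        for (si in seq_len(nrow(r$segs))) {
          seg <- r$segs[si, ]
          if (pos_d[k] >= seg["ref"] && pos_d[k] < seg["ref"] + seg["len"]) {
            at <- seg["read"] + (pos_d[k] - seg["ref"]) + 1L
            substr(sv, at, at) <- alt_d[k]
          }
        }
      }
      sv
    }
    seq1 <- apply_snvs(r1); seq2 <- apply_snvs(r2)
    if (cfg$error_rate > 0) {
      mut <- function(sv) {
        hit <- which(stats::runif(nchar(sv)) < cfg$error_rate)
        for (at in hit) {
          substr(sv, at, at) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(sv, at, at)), 1L)
        }
        sv
      }
      seq1 <- mut(seq1); seq2 <- mut(seq2)
    }
    qn <- sprintf("frag%06d", i)
    tl <- end2 - s1
    push(make_rec(qn, 99L, s1, r1$cigar, seq1, s2, tl, qual30))
    push(make_rec(qn, 147L, s2, r2$cigar, seq2, s1, -tl, qual30))
  }

  # discordant pairs supporting VLRD junctions (no junction in the CIGAR)
  if (n_del) {
    vl <- dels[dels$length > 15000, , drop = FALSE]
    if (nrow(vl)) {
      for (v in seq_len(nrow(vl))) {
        n_disc <- stats::rpois(1L, max(2, cfg$depth * vl$fraction[v] / 4))
        for (k in seq_len(n_disc)) {
          off <- sample.int(100L, 1L) + rl
          s1 <- (vl$start[v] - off) %% L
          s2 <- s1 + off + vl$length[v]
          if (s2 + rl > 2L * L) next
          qn <- sprintf("disc%02d_%04d", v, k)
          push(make_rec(qn, 97L, s1, paste0(rl, "M"),
                        substr(dseq, s1 + 1L, s1 + rl), s2, s2 + rl - s1, qual30))
          push(make_rec(qn, 145L, s2, paste0(rl, "M"),
                        substr(dseq, s2 + 1L, s2 + rl), s1, -(s2 + rl - s1), qual30))
        }
      }
    }
  }

  records <- do.call(rbind, lapply(out[seq_len(n_rec)], function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(records)) records <- empty_records()
  list(records = records, truth = truth)
}

#' Cohort design for multi-sample simulations
#'
#' Describes the factorial study layout (genotype x region x age, several
#' animals per genotype-age cell, each animal contributing every region) and
#' the planted effect model on per-sample variant counts: expectation =
#' baseline x age multiplier x genotype-region multiplier x exp(animal
#' effect), counts Poisson.
#'
#' @param genotypes Genotype labels (first level is the reference/WT).
#' @param regions Brain-region labels (default the six sampled regions:
#'   cortex COR, caudate putamen CP, dorsal raphe DR, nucleus accumbens NAc,
#'   paraventricular thalamus PVT, substantia nigra SN).
#' @param ages Ages in weeks.
#' @param animals_per_cell Animals per genotype-age cell (default 4).
#' @param baseline Expected SNV count per sample at the youngest age in the
#'   reference genotype (default 20).
#' @param age_multipliers Named multiplier per age; the default
#'   `c(1, 10, 10)` plants the observed ten-fold rise-then-plateau of SNV
#'   load with ageing.
#' @param deletion_age_multipliers As above for deletion counts (default
#'   `c(1, 2.75, 2.75)`, the 2.5-3-fold rise).
#' @param genotype_region_multipliers Named multiplier per region applied to
#'   the non-reference genotype only (default 3 for COR/NAc/PVT, 1
#'   elsewhere).
#' @param deletion_baseline Baseline deletion count (default `baseline / 2`).
#' @param animal_sd SD of the log-scale animal random effect (default 0.1).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(genotypes = c("WT", "mutant"),
                          regions = c("COR", "CP", "DR", "NAc", "PVT", "SN"),
                          ages = c(10, 50, 80),
                          animals_per_cell = 4L,
                          baseline = 20,
                          age_multipliers = stats::setNames(c(1, 10, 10)[seq_along(ages)], ages),
                          deletion_age_multipliers = stats::setNames(c(1, 2.75, 2.75)[seq_along(ages)], ages),
                          genotype_region_multipliers = NULL,
                          deletion_baseline = baseline / 2,
                          animal_sd = 0.1) {
  if (is.null(genotype_region_multipliers)) {
    genotype_region_multipliers <- stats::setNames(rep(1, length(regions)), regions)
    genotype_region_multipliers[names(genotype_region_multipliers) %in%
                                  c("COR", "NAc", "PVT")] <- 3
  }
  stopifnot(animals_per_cell >= 2L, all(age_multipliers > 0),
            all(genotype_region_multipliers > 0), baseline > 0)
  structure(list(genotypes = genotypes, regions = regions, ages = ages,
                 animals_per_cell = as.integer(animals_per_cell),
                 baseline = baseline, age_multipliers = age_multipliers,
                 deletion_age_multipliers = deletion_age_multipliers,
                 genotype_region_multipliers = genotype_region_multipliers,
                 deletion_baseline = deletion_baseline,
                 animal_sd = animal_sd),
            class = "cohort_design")
}

#' Simulate a multi-sample cohort with planted age/genotype/region effects
#'
#' The fast default (`emit = "counts"`) draws per-sample SNV and deletion
#' counts from the design's Poisson effect model and returns them with tidy
#' metadata — sufficient for the statistics layer and for calibration
#' studies. With `emit = "alignments"`, each sample additionally receives a
#' full synthetic alignment set (variants at random positions with the
#' sample's planted counts) generated through [simulate_alignments()].
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @param emit `"counts"` (default) or `"alignments"`.
#' @param genome Required when `emit = "alignments"`: a [circular_genome()].
#' @param depth,read_length Read geometry for `emit = "alignments"`.
#' @return List with `metadata` (`data.frame`: sample_id, animal, genotype,
#'   region, age_weeks), `counts` (`data.frame`: sample_id, snv_count,
#'   deletion_count, expected_snv), `truth` (per-sample planted variants when
#'   alignments are emitted) and `alignments` (named list of record
#'   `data.frame`s, or `NULL`).
#' @export
simulate_cohort <- function(design, seed, emit = c("counts", "alignments"),
                            genome = NULL, depth = 60, read_length = 150L) {
  stopifnot(inherits(design, "cohort_design"))
  emit <- match.arg(emit)
  set.seed(seed)
  grid <- expand.grid(genotype = design$genotypes,
                      age_weeks = design$ages,
                      animal_idx = seq_len(design$animals_per_cell),
                      stringsAsFactors = FALSE)
  grid$animal <- sprintf("%s_%dwk_m%d", grid$genotype, grid$age_weeks,
                         grid$animal_idx)
  grid$animal_effect <- stats::rnorm(nrow(grid), 0, design$animal_sd)

  meta <- merge(grid, data.frame(region = design$regions), by = NULL)
  meta$sample_id <- sprintf("%s_%s", meta$animal, meta$region)
  gr_mult <- ifelse(meta$genotype == design$genotypes[1L], 1,
                    design$genotype_region_multipliers[meta$region])
  lam_snv <- design$baseline *
    design$age_multipliers[as.character(meta$age_weeks)] *
    gr_mult * exp(meta$animal_effect)
  lam_del <- design$deletion_baseline *
    design$deletion_age_multipliers[as.character(meta$age_weeks)] *
    gr_mult * exp(meta$animal_effect)
  counts <- data.frame(sample_id = meta$sample_id,
                       snv_count = stats::rpois(nrow(meta), lam_snv),
                       deletion_count = stats::rpois(nrow(meta), lam_del),
                       expected_snv = as.numeric(lam_snv),
                       stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = meta$sample_id, animal = meta$animal,
                         genotype = meta$genotype, region = meta$region,
                         age_weeks = meta$age_weeks, stringsAsFactors = FALSE)
  o <- order(metadata$sample_id)
  metadata <- metadata[o, ]; counts <- counts[o, ]
  rownames(metadata) <- rownames(counts) <- NULL

  alignments <- NULL; truth <- NULL
  if (emit == "alignments") {
    if (is.null(genome)) stop("emit = 'alignments' requires a genome")
    alignments <- vector("list", nrow(metadata))
    names(alignments) <- metadata$sample_id
    truth <- vector("list", nrow(metadata))
    L <- genome$length
    for (i in seq_len(nrow(metadata))) {
      n_snv <- min(counts$snv_count[i], 200L)
      n_dl <- min(counts$deletion_count[i], 50L)
      sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
      set.seed(sub_seed)
      snv_plan <- if (n_snv) data.frame(pos = sample.int(L, n_snv) - 1L,
                                        alt = NA_character_,
                                        fraction = stats::runif(n_snv, 0.05, 0.6))
      del_plan <- if (n_dl) data.frame(start = sample.int(L, n_dl) - 1L,
                                       length = sample_deletion_lengths(n_dl),
                                       fraction = stats::runif(n_dl, 0.05, 0.5))
      cfg_i <- simulation_config(seed = sub_seed, L = L, n_genes = 0L,
                                 snv_plan = snv_plan, deletion_plan = del_plan,
                                 read_length = read_length, depth = depth)
      sim <- simulate_alignments(genome, cfg_i)
      alignments[[i]] <- sim$records
      tr <- sim$truth
      if (nrow(tr)) tr$sample_id <- metadata$sample_id[i]
      truth[[i]] <- tr
    }
    truth <- do.call(rbind, truth)
  }
  list(metadata = metadata, counts = counts, truth = truth,
       alignments = alignments)
}

#' Write a simulated cohort to disk
#'
#' Writes `metadata.tsv`, `counts.tsv`, per-sample SAM files (when present)
#' and the truth table.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param ref_name,ref_length Reference header fields for the SAM files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, ref_name = "dMT", ref_length = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$alignments)) {
    if (is.null(ref_length)) stop("ref_length required to write SAM files")
    for (sid in names(cohort$alignments)) {
      write_sam(cohort$alignments[[sid]],
                file.path(dir, paste0(sid, ".sam")), ref_name, ref_length)
    }
  }
  invisible(dir)
}
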