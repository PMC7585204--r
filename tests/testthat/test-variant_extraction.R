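ref_200 <- function(seed = 30) random_genome(200, seed = seed)

test_that("downsampling is exact, deterministic and keeps pairs together", {
  recs <- do.call(rbind, lapply(1:20, function(i) {
    rbind(make_record(sprintf("q%02d", i), 99L, i, "10M", strrep("A", 10)),
          make_record(sprintf("q%02d", i), 147L, i + 20, "10M", strrep("A", 10)))
  }))
  expect_equal(nrow(downsample_alignments(recs, 40, seed = 1)), 40)
  s1 <- downsample_alignments(recs, 20, seed = 5)
  s2 <- downsample_alignments(recs, 20, seed = 5)
  expect_identical(s1, s2)
  # mates survive or vanish together
  expect_true(all(table(s1$qname) == 2))
  expect_error(downsample_alignments(recs, 41, seed = 1, sample_id = "s7"),
               "s7")
  expect_error(downsample_alignments(recs, 19, seed = 1), "mate pairs")
})

test_that("downsampling inclusion frequency is uniform across reads", {
  recs <- do.call(rbind, lapply(1:30, function(i) {
    rbind(make_record(sprintf("q%02d", i), 99L, i, "10M", strrep("A", 10)),
          make_record(sprintf("q%02d", i), 147L, i, "10M", strrep("A", 10)))
  }))
  hits <- integer(30)
  for (s in 1:200) {
    kept <- downsample_alignments(recs, 30, seed = s)
    hits <- hits + (sprintf("q%02d", 1:30) %in% kept$qname)
  }
  p <- 0.5
  se <- sqrt(p * (1 - p) / 200)
  expect_true(all(abs(hits / 200 - p) < 3.6 * se))
})

test_that("reference-matching reads yield no variants", {
  g <- ref_200()
  dseq <- paste0(g$sequence, g$sequence)
  rec <- make_record("r1", 0L, 17, "50M", substr(dseq, 18, 67))
  expect_equal(nrow(extract_variants(rec, g)), 0)
})

test_that("a D operation becomes a deletion with CIGAR arithmetic and left alignment", {
  g <- ref_200()
  dseq <- paste0(g$sequence, g$sequence)
  p <- 30L
  seq <- paste0(substr(dseq, p + 1, p + 20), substr(dseq, p + 121, p + 150))
  rec <- make_record("r1", 0L, p, "20M100D30M", seq)
  v <- extract_variants(rec, g, min_fraction = 0)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "DEL")
  expect_equal(v$length, 100)
  # left alignment oracle: shift while base before gap equals last deleted
  exp_p5 <- 50L
  while (exp_p5 > 0 &&
         substr(dseq, exp_p5, exp_p5) == substr(dseq, exp_p5 + 100, exp_p5 + 100)) {
    exp_p5 <- exp_p5 - 1L
  }
  expect_equal(v$pos5, exp_p5)
})

test_that("evidence in the two doubled-reference copies merges into one variant", {
  g <- ref_200()
  dseq <- paste0(g$sequence, g$sequence)
  p <- 40L
  seq1 <- paste0(substr(dseq, p + 1, p + 20), substr(dseq, p + 51, p + 80))
  rec <- rbind(make_record("r1", 0L, p, "20M30D30M", seq1),
               make_record("r2", 0L, p + 200L, "20M30D30M", seq1))
  v <- extract_variants(rec, g, min_fraction = 0)
  expect_equal(nrow(v), 1)
  expect_equal(v$support, 2)
  # SNV evidence merges the same way
  s <- substr(dseq, p + 1, p + 50)
  alt <- setdiff(c("A", "C", "G", "T"), substr(s, 25, 25))[1]
  substr(s, 25, 25) <- alt
  rec2 <- rbind(make_record("r1", 0L, p, "50M", s),
                make_record("r2", 0L, p + 200L, "50M", s))
  v2 <- extract_variants(rec2, g, min_fraction = 0)
  expect_equal(nrow(v2), 1)
  expect_equal(v2$kind, "SNV")
  expect_equal(v2$pos5, p + 24L)
  expect_equal(v2$support, 2)
})

test_that("read-end evidence inside the border trim is ignored", {
  g <- ref_200()
  dseq <- paste0(g$sequence, g$sequence)
  p <- 10L
  s <- substr(dseq, p + 1, p + 50)
  for (at in c(3L, 48L)) {  # inside the default 5-bp border
    s2 <- s
    substr(s2, at, at) <- setdiff(c("A", "C", "G", "T"), substr(s, at, at))[1]
    v <- extract_variants(make_record("r1", 0L, p, "50M", s2), g,
                          min_fraction = 0)
    expect_equal(nrow(v), 0)
  }
  # just outside the border it is kept
  s3 <- s
  substr(s3, 6, 6) <- setdiff(c("A", "C", "G", "T"), substr(s, 6, 6))[1]
  v <- extract_variants(make_record("r1", 0L, p, "50M", s3), g,
                        min_fraction = 0)
  expect_equal(nrow(v), 1)
})

test_that("split primary/supplementary pairs recover a junction once", {
  g <- ref_200()
  dseq <- paste0(g$sequence, g$sequence)
  # junction: [10,40) aligned, gap of 120, [160,190) aligned
  left <- substr(dseq, 11, 40)
  right <- substr(dseq, 161, 190)
  rec <- rbind(
    make_record("r1", 0L, 10L, "30M30S", paste0(left, right)),
    make_record("r1", 2048L, 160L, "30S30M", paste0(left, right)))
  v <- extract_variants(rec, g, min_fraction = 0)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "DEL")
  expect_equal(v$length, 120)
  expect_equal(v$support, 1)
  # a D-CIGAR read from the SAME fragment does not double-count
  seqd <- paste0(substr(dseq, 6, 40), substr(dseq, 161, 175))
  rec2 <- rbind(rec, make_record("r1", 0L, 5L, "35M120D15M", seqd))
  v2 <- extract_variants(rec2, g, min_fraction = 0)
  v2 <- v2[v2$kind == "DEL", ]
  expect_equal(nrow(v2), 1)
  expect_equal(v2$support, 1)
})

test_that("malformed CIGAR/sequence pairs raise an error naming the read", {
  g <- ref_200()
  rec <- make_record("bad_read", 0L, 0, "60M", strrep("A", 50))
  expect_error(extract_variants(rec, g), "bad_read")
})

test_that("post-filters enforce the stated minima inclusively", {
  v <- data.frame(
    kind = c("SNV", "SNV", "SNV", "DEL", "DEL", "DEL"),
    pos5 = 1:6, pos3 = NA, length = c(NA, NA, NA, 10, 10, 10),
    ref = "A", alt = "T",
    support = c(3, 4, 4, 1, 2, 2),
    depth = c(60, 50, 49, 30, 25, 24),
    quality = c(25, 20, 20, 12, 10, 10),
    allele_fraction = 0.1)
  out <- apply_post_filters(v, quiet = TRUE)
  # SNV: support 3 rejected; 4/50/20 retained (boundary); 4/49 rejected
  # DEL: support 1 rejected; 2/25/10 retained; 2/24 rejected
  expect_equal(out$pos5, c(2, 5))
  expect_equal(nrow(apply_post_filters(v[0, ], quiet = TRUE)), 0)
  expect_equal(unname(attr(out, "rejections")["support"]), 2)
})

test_that("deletion classification partitions at the 15-kb boundary", {
  v <- data.frame(kind = c("DEL", "DEL", "SNV"), pos5 = c(0, 0, 5),
                  pos3 = c(100, 101, NA), length = c(15000, 15001, NA),
                  ref = NA, alt = NA, support = 5, depth = 50, quality = 30,
                  allele_fraction = 0.1)
  out <- classify_deletions(v, sample_id = "s1")
  expect_equal(out$class, c("DEL", "VLRD", "SNV"))
  expect_equal(unique(out$sample_id), "s1")
  dels <- out[out$kind == "DEL", ]
  expect_setequal(dels$class, c("DEL", "VLRD"))  # partition, no overlap
})

test_that("discordant counting follows the 1294 flag mask", {
  recs <- rbind(
    make_record("a", 99L, 0, "10M", strrep("A", 10)),    # proper pair
    make_record("a", 147L, 50, "10M", strrep("A", 10)),
    make_record("b", 97L, 0, "10M", strrep("A", 10)),    # mapped, not proper
    make_record("b", 145L, 50, "10M", strrep("A", 10)),
    make_record("c", 97L + 256L, 0, "10M", strrep("A", 10)))  # secondary
  expect_equal(count_discordant(recs), 2)
  expect_equal(count_discordant(recs[1:2, ]), 0)
  unpaired <- make_record("d", 0L, 0, "10M", strrep("A", 10))
  expect_warning(count_discordant(unpaired), "unpaired")
})

test_that("fraction-1 simulations round-trip through extract-filter-classify", {
  cfg <- simulation_config(seed = 31, L = 2500, depth = 120,
    snv_plan = data.frame(pos = c(200, 1200), alt = NA, fraction = 1),
    deletion_plan = data.frame(start = c(700, 2400), length = c(45, 500),
                               fraction = 1))
  gen <- generate_genome(cfg)
  sim <- simulate_alignments(gen$genome, cfg)
  v <- classify_deletions(apply_post_filters(
    extract_variants(sim$records, gen$genome), quiet = TRUE))
  expect_identical(variant_key(v), variant_key(sim$truth))
  expect_identical(sort(v$class), sort(sim$truth$class))
})

test_that("variant TSV and VCF writers emit 1-based coordinates", {
  g <- ref_200()
  v <- data.frame(kind = c("SNV", "DEL"), pos5 = c(9, 19), pos3 = c(NA, 49),
                  length = c(NA, 30), ref = c("A", NA), alt = c("T", NA),
                  support = 5, depth = 50, quality = 30,
                  allele_fraction = 0.1)
  v <- classify_deletions(v, sample_id = "s")
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "v.tsv")
  write_variant_tsv(v, tsv)
  back <- read.delim(tsv)
  expect_equal(back$pos5_1based, c(10, 20))
  vcf <- file.path(dir, "v.vcf")
  write_variant_vcf(v, g, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  expect_match(body[2], "SVTYPE=DEL;END=49;SVLEN=-30")
})
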