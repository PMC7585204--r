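test_that("planted repeats appear with the exact mismatch count", {
  cfg <- simulation_config(seed = 10, L = 2000, repeat_plan = data.frame(
    length = c(12, 12), mismatches = c(0, 2), posA = c(100, 500),
    posB = c(900, 1400)))
  gen <- generate_genome(cfg)
  s <- gen$genome$sequence
  copy <- function(p, len) substr(s, p + 1, p + len)
  expect_identical(copy(100, 12), copy(900, 12))
  hd <- sum(strsplit(copy(500, 12), "")[[1]] != strsplit(copy(1400, 12), "")[[1]])
  expect_equal(hd, 2)
  expect_identical(gen$repeats$posA, c(100L, 500L))
})

test_that("genome generation is a pure function of the seed", {
  cfg <- simulation_config(seed = 11, L = 1500)
  expect_identical(generate_genome(cfg)$genome$sequence,
                   generate_genome(cfg)$genome$sequence)
  cfg2 <- simulation_config(seed = 12, L = 1500)
  expect_false(identical(generate_genome(cfg)$genome$sequence,
                         generate_genome(cfg2)$genome$sequence))
})

test_that("infeasible repeat plans and bad configs are rejected", {
  expect_error(generate_genome(simulation_config(seed = 1, L = 1000,
    repeat_plan = data.frame(length = 20, mismatches = 0, posA = 100,
                             posB = 110))), "overlap")
  expect_error(simulation_config(seed = 1, L = 1000,
    snv_plan = data.frame(pos = 10, alt = "A", fraction = 1.5)),
    "allele fractions")
  expect_error(simulation_config(seed = 1, L = 1000,
    deletion_plan = data.frame(start = 10, length = 1000, fraction = 1)),
    "at most L - 1")
  expect_error(simulation_config(seed = 1, depth = -5), "depth")
})

test_that("variant-free simulations give pure reference alignments", {
  cfg <- simulation_config(seed = 13, L = 800, depth = 40)
  gen <- generate_genome(cfg)
  sim <- simulate_alignments(gen$genome, cfg)
  expect_true(all(grepl("^150M$", sim$records$cigar)))
  dseq <- paste0(gen$genome$sequence, gen$genome$sequence)
  ok <- mapply(function(p, s) substr(dseq, p + 1, p + 150) == s,
               sim$records$pos, sim$records$seq)
  expect_true(all(ok))
  expect_equal(nrow(sim$truth), 0)
})

test_that("a fraction-1 deletion is carried by every junction-spanning read", {
  cfg <- simulation_config(seed = 14, L = 900, depth = 80,
    deletion_plan = data.frame(start = 300, length = 50, fraction = 1))
  gen <- generate_genome(cfg)
  sim <- simulate_alignments(gen$genome, cfg)
  has_d <- grepl("D", sim$records$cigar)
  expect_gt(sum(has_d), 10)
  # no read straddles positions 300..349 with plain M
  spans <- mapply(function(p, cg) {
    if (grepl("D", cg)) return(FALSE)
    p <= 299 && (p + 150) > 301
  }, sim$records$pos, sim$records$cigar)
  expect_false(any(spans))
})

test_that("junction-read carrier fraction follows the binomial at the planted rate", {
  cfg <- simulation_config(seed = 15, L = 1200, depth = 500,
    deletion_plan = data.frame(start = 600, length = 40, fraction = 0.2))
  gen <- generate_genome(cfg)
  sim <- simulate_alignments(gen$genome, cfg)
  # reads whose span contains the junction region decide carrier status
  carrier <- grepl("D", sim$records$cigar)
  span <- mtspectra:::cigar_ref_span(sim$records$cigar)
  overlaps <- sim$records$pos < 600 & (sim$records$pos + span) > 601
  n <- sum(overlaps)
  frac <- sum(carrier & overlaps) / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("simulated SAM validates against its own header", {
  cfg <- simulation_config(seed = 16, L = 700, depth = 40,
    snv_plan = data.frame(pos = 100, alt = NA, fraction = 0.5),
    vlrd_plan = NULL)
  gen <- generate_genome(cfg)
  sim <- simulate_alignments(gen$genome, cfg)
  span <- mtspectra:::cigar_ref_span(sim$records$cigar)
  expect_true(all(sim$records$pos >= 0))
  expect_true(all(sim$records$pos + span <= 2 * 700))
  expect_true(all(mtspectra:::cigar_read_span(sim$records$cigar) ==
                    nchar(sim$records$seq)))
  # mates reference each other
  prs <- split(sim$records, sim$records$qname)
  ok <- vapply(prs, function(p) {
    nrow(p) == 2 && p$pos[1] == p$pnext[2] && p$pos[2] == p$pnext[1]
  }, logical(1))
  expect_true(all(ok))
  # SAM round trip
  dir <- withr::local_tempdir()
  f <- file.path(dir, "x.sam")
  write_sam(sim$records, f, "dMT", 1400)
  back <- read_sam(f)
  expect_equal(back$pos, sim$records$pos)
  expect_equal(back$cigar, sim$records$cigar)
  expect_equal(attr(back, "ref_length"), 1400)
})

test_that("VLRD simulations emit discordant mate pairs", {
  cfg <- simulation_config(seed = 17, L = 16300, depth = 20,
    vlrd_plan = data.frame(start = 4000, length = 15600, fraction = 0.5))
  gen <- generate_genome(cfg)
  sim <- simulate_alignments(gen$genome, cfg)
  n_disc <- count_discordant(sim$records)
  expect_gt(n_disc, 0)
  expect_equal(n_disc %% 2, 0)  # pairs
})

test_that("uniform cohort design yields one shared expectation", {
  des <- cohort_design(ages = c(10, 50), animals_per_cell = 3,
                       age_multipliers = c("10" = 1, "50" = 1),
                       deletion_age_multipliers = c("10" = 1, "50" = 1),
                       genotype_region_multipliers = NULL,
                       animal_sd = 0)
  des$genotype_region_multipliers[] <- 1
  co <- simulate_cohort(des, seed = 18)
  expect_equal(length(unique(co$counts$expected_snv)), 1)
  expect_equal(nrow(co$metadata), 2 * 2 * 3 * 6)
})

test_that("a planted ten-fold age effect is visible in sample means", {
  des <- cohort_design(animals_per_cell = 6, baseline = 100, animal_sd = 0)
  des$genotype_region_multipliers[] <- 1
  co <- simulate_cohort(des, seed = 19)
  m <- merge(co$metadata, co$counts)
  m10 <- mean(m$snv_count[m$age_weeks == 10])
  m50 <- mean(m$snv_count[m$age_weeks == 50])
  ratio <- m50 / m10
  # Poisson error at expectation >= 100 keeps the ratio near the planted 10
  expect_gt(ratio, 8.5)
  expect_lt(ratio, 11.5)
})

test_that("the genotype-region effect raises only the planted regions", {
  des <- cohort_design(animals_per_cell = 6, baseline = 50, animal_sd = 0.05)
  co <- simulate_cohort(des, seed = 20)
  m <- merge(co$metadata, co$counts)
  m <- m[m$age_weeks > 10, ]
  for (reg in c("COR", "NAc", "PVT")) {
    expect_gt(mean(m$snv_count[m$region == reg & m$genotype == "mutant"]),
              1.5 * mean(m$snv_count[m$region == reg & m$genotype == "WT"]))
  }
  for (reg in c("CP", "DR", "SN")) {
    rr <- mean(m$snv_count[m$region == reg & m$genotype == "mutant"]) /
      mean(m$snv_count[m$region == reg & m$genotype == "WT"])
    expect_lt(abs(rr - 1), 0.35)
  }
})

test_that("cohort simulation is deterministic under its seed", {
  des <- cohort_design(animals_per_cell = 2, ages = c(10, 50))
  a <- simulate_cohort(des, seed = 21)
  b <- simulate_cohort(des, seed = 21)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts$snv_count,
                         simulate_cohort(des, seed = 22)$counts$snv_count))
})
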