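test_that("sharing bins count one instance per group and bin", {
  # two SNVs at 3 and 7 fall in one 10-bp bin of one region: one instance
  res <- snv_sharing(list(r1 = c(3, 7)), L = 100, bin = 10)
  expect_equal(unname(res$histogram["1"]), 1)
  expect_equal(res$n_bins_occupied, 1)
  # identical lists in six regions: every occupied bin at level 4-6
  six <- setNames(rep(list(c(5, 25, 71)), 6), paste0("r", 1:6))
  res6 <- snv_sharing(six, L = 100, bin = 10)
  expect_equal(unname(res6$histogram["4-6"]), 3)
  expect_equal(unname(res6$histogram["1"]), 0)
  # animal grouping uses the open-ended >=4 category
  res_a <- snv_sharing(six[1:5], L = 100, bin = 10, group_by = "animal")
  expect_equal(unname(res_a$histogram[">=4"]), 3)
  # histogram totals equal the number of occupied bins
  set.seed(60)
  rnd <- lapply(1:4, function(i) sample(0:999, 30))
  res_r <- snv_sharing(rnd, L = 1000, bin = 10)
  expect_equal(sum(res_r$histogram), res_r$n_bins_occupied)
  expect_error(snv_sharing(list(a = 1), L = 100, bin = 0), "bin width")
})

test_that("allele-fraction profiles are max-scaled per bin", {
  snvs <- data.frame(pos = c(5, 150, 160), fraction = c(0.2, 0.3, 0.1))
  prof <- binned_allele_fraction(snvs, L = 1000, bin = 100)
  expect_equal(length(prof), 10)
  expect_equal(prof[1], 0.5)   # 0.2 / 0.4
  expect_equal(prof[2], 1.0)   # 0.3 + 0.1 is the peak
  expect_true(attr(prof, "normalized"))
  single <- binned_allele_fraction(data.frame(pos = 720, fraction = 0.05),
                                   L = 1000, bin = 100)
  expect_equal(single[8], 1)
  expect_equal(sum(single), 1)
  empty <- binned_allele_fraction(data.frame(pos = numeric(0),
                                             fraction = numeric(0)),
                                  L = 1000, bin = 100)
  expect_true(all(empty == 0))
  expect_false(attr(empty, "normalized"))
  # partial final bin flagged
  expect_true(attr(binned_allele_fraction(snvs, L = 1050, bin = 100),
                   "partial_last"))
})

test_that("cumulative position curves are monotone and end at 100", {
  one <- cumulative_position(rep(42, 5), L = 1000)
  expect_equal(one$cum_percent[1], 100)
  set.seed(61)
  pos <- sample(0:9999, 400, replace = TRUE)
  cp <- cumulative_position(pos, L = 10000)
  expect_true(all(diff(cp$cum_percent) >= 0))
  expect_equal(cp$cum_percent[nrow(cp)], 100)
  # uniform positions stay within a Kolmogorov band of the diagonal
  ks <- suppressWarnings(ks.test(pos / 10000, "punif"))
  expect_gt(ks$p.value, 0.001)
  dev <- max(abs(cp$cum_percent / 100 - cp$pos / 10000))
  expect_lt(dev, 1.63 / sqrt(400) + 0.01)
  expect_error(cumulative_position(numeric(0), 100), "empty")
})

test_that("mutation spectra count the 12 classes and Ti/Tv correctly", {
  g <- circular_genome("g", strrep("ACGT", 50))
  snvs <- data.frame(pos = c(1, 5, 2), ref = c("C", "C", "G"),
                     alt = c("T", "T", "T"))
  sp <- mutation_spectrum(snvs, g)
  expect_equal(unname(sp$classes["C>T"]), 2)
  expect_equal(unname(sp$classes["G>T"]), 1)
  expect_equal(sp$ti, 2)
  expect_equal(sp$tv, 1)
  expect_equal(sum(sp$classes), 3)
  # pyrimidine-collapsed view folds G>T onto C>A
  expect_equal(unname(sp$collapsed["C>A"]), 1)
  bad <- data.frame(pos = 0, ref = "T", alt = "C")  # genome has A at 0
  expect_error(mutation_spectrum(bad, g), "disagrees")
})

test_that("a planted 70 percent C>T/T>C spectrum is recovered exactly", {
  set.seed(62)
  g <- random_genome(2000)
  base_at <- function(p) substring(g$sequence, p + 1, p + 1)
  pos <- 0:1999
  cs <- pos[base_at(pos) == "C"][1:35]
  ts <- pos[base_at(pos) == "T"][1:35]
  others <- pos[base_at(pos) == "A"][1:30]
  snvs <- data.frame(pos = c(cs, ts, others),
                     ref = c(rep("C", 35), rep("T", 35), rep("A", 30)),
                     alt = c(rep("T", 35), rep("C", 35), rep("C", 30)))
  sp <- mutation_spectrum(snvs, g)
  expect_equal(unname(sp$classes["C>T"] + sp$classes["T>C"]), 70)
  expect_equal(sp$n, 100)
})

test_that("per-gene load normalizes by length, counts overlaps, and scales", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      start = c(0, 100, 200), end = c(100, 200, 300),
                      category = c("protein", "protein", "rRNA"))
  g <- circular_genome("g", random_seq(400), genes)
  v <- data.frame(kind = c("SNV", "SNV", "DEL"),
                  pos5 = c(10, 20, 50), pos3 = c(NA, NA, 250),
                  length = c(NA, NA, 200), allele_fraction = 0.1)
  load <- per_gene_load(v, g)
  expect_equal(load$snv_scaled, c(1, 0, 0))
  # the deletion arc [50, 250) overlaps all three genes
  expect_equal(load$del_load > 0, c(TRUE, TRUE, TRUE))
  expect_error(per_gene_load(v, circular_genome("g", random_seq(400))),
               "no gene annotation")
})

test_that("planted correlated gene loads recover a strong correlation", {
  set.seed(63)
  n_genes <- 20
  genes <- data.frame(gene_id = sprintf("g%02d", 1:n_genes),
                      start = (0:19) * 100, end = (0:19) * 100 + 100,
                      category = "protein")
  g <- circular_genome("g", random_seq(2000), genes)
  intensity <- runif(n_genes, 5, 120)
  rows <- list()
  for (k in 1:n_genes) {
    n_snv <- rpois(1, intensity[k]); n_del <- rpois(1, intensity[k])
    if (n_snv) rows[[length(rows) + 1]] <- data.frame(
      kind = "SNV", pos5 = sample(genes$start[k]:(genes$end[k] - 1), n_snv, TRUE),
      pos3 = NA, length = NA, allele_fraction = 0.1)
    if (n_del) rows[[length(rows) + 1]] <- data.frame(
      kind = "DEL", pos5 = sample(genes$start[k]:(genes$end[k] - 31), n_del, TRUE),
      pos3 = NA, length = 20, allele_fraction = 0.1)
  }
  v <- do.call(rbind, rows)
  v$pos3 <- ifelse(v$kind == "DEL", (v$pos5 + v$length) %% 2000, NA)
  load <- per_gene_load(v, g)
  expect_gt(attr(load, "pearson_r"), 0.8)
})

test_that("VLRD-to-SNV proximity matches an exhaustive scan", {
  snv <- c(10, 500, 900)
  res <- vlrd_snv_proximity(c(10, 500), snv, L = 1000)
  expect_equal(res$mean_bp, 0)
  expect_equal(res$co_position_fraction, 1)
  # single breakpoint midway between two SNVs takes the smaller arc
  res2 <- vlrd_snv_proximity(700, snv, L = 1000)
  expect_equal(res2$mean_bp, 200)
  set.seed(64)
  vl <- sample(0:999, 20); sn <- sample(0:999, 15)
  res3 <- vlrd_snv_proximity(vl, sn, L = 1000)
  bf <- vapply(vl, function(p) {
    min(vapply(sn, function(q) min(abs(p - q), 1000 - abs(p - q)), numeric(1)))
  }, numeric(1))
  expect_equal(res3$distances, bf)
  expect_equal(res3$co_position_fraction, mean(bf == 0))
  expect_error(vlrd_snv_proximity(numeric(0), snv, 1000), "non-empty")
})

test_that("count normalization modes behave as stated", {
  counts <- c(s1 = 10, s2 = 30, s3 = 5)
  ref <- c(TRUE, FALSE, FALSE)
  expect_equal(unname(normalize_counts(counts, reference = ref)["s2"]), 3)
  mn <- normalize_counts(counts, mode = "min_sample")
  expect_equal(unname(mn["s3"]), 1)
  # fold normalization preserves rank order
  expect_equal(order(normalize_counts(counts, reference = ref)),
               order(counts))
  expect_error(normalize_counts(c(0, 1), reference = c(TRUE, FALSE)), "zero")
  expect_error(normalize_counts(c(0, 1), mode = "min_sample"), "zero")
})
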