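test_that("expected random overlap is the hypergeometric mean", {
  expect_equal(round(expected_random_overlap(43, 523, 15287)$expected, 2), 1.47)
  expect_equal(expected_random_overlap(0, 100, 1000)$expected, 0)
  # Monte-Carlo oracle: draw both lists at random, count shared genes
  set.seed(10)
  draws <- replicate(1e5, {
    length(intersect(sample.int(100, 10), sample.int(100, 10)))
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(expected_random_overlap(10, 10, 100)$expected - mean(draws)),
            3 * se)
  expect_error(expected_random_overlap(1, 1, 0))
})

test_that("promoter overlap intersects symbol lists case-insensitively", {
  o <- promoter_overlap(c("Abc", "Def"), c("ghi", "jkl"), 100)
  expect_equal(o$observed_overlap, 0L)
  o2 <- promoter_overlap(letters[1:5], LETTERS[1:5], 100)
  expect_equal(o2$observed_overlap, 5L)
  expect_true(o2$p <= 1)
  expect_warning(promoter_overlap(c("a", "A", "b"), "c", 10), "duplicate")
  # symmetric where set semantics apply
  oa <- promoter_overlap(c("a", "b", "c"), c("b", "z"), 50)
  ob <- promoter_overlap(c("b", "z"), c("a", "b", "c"), 50)
  expect_equal(oa$observed_overlap, ob$observed_overlap)
  expect_equal(oa$expected_overlap, ob$expected_overlap)
})

test_that("the packaged DMR and DE gene lists share exactly one symbol", {
  dmr <- read_table2_fixture()
  de <- read_gene_list(system.file("extdata", "table_s1_genes_synthetic.tsv",
                                   package = "medipdmr"))
  o <- promoter_overlap(dmr$gene_symbol, de, 15287)
  expect_equal(o$n_dmr, 43L)
  expect_equal(o$n_de, 523L)
  expect_equal(o$overlapping_genes, "Plekhm1")
  expect_equal(round(o$expected_overlap, 2), 1.47)
})

test_that("the cluster scan finds a planted pile-up and stays quiet on null data", {
  set.seed(11)
  # catalog: one gene every 100 kb over 40 Mb
  catalog <- data.frame(gene = sprintf("g%03d", 1:400), chrom = "chr1",
                        pos = seq(0, 4e7 - 1e5, by = 1e5))
  # background: 1 DE gene per 10 Mb, plus 8 planted in a 3 Mb span
  bg <- catalog[catalog$pos %in% c(5e6, 15e6, 35e6), ]
  planted <- catalog[catalog$pos >= 2.0e7 & catalog$pos < 2.08e7, ][1:8, ]
  de <- rbind(bg, planted)
  ecr <- ecr_scan(de, catalog, c(chr1 = 4e7))
  expect_equal(nrow(ecr), 1L)
  covered <- sum(planted$pos >= ecr$start & planted$pos < ecr$end)
  expect_gte(covered, 7)
  # merged windows never overlap each other (single window here, so check
  # the deterministic rerun instead)
  expect_identical(ecr, ecr_scan(de, catalog, c(chr1 = 4e7)))

  # min_genes excludes a 3-gene pile-up regardless of p
  de3 <- rbind(bg, planted[1:3, ])
  expect_equal(nrow(ecr_scan(de3, catalog, c(chr1 = 4e7), min_genes = 4)), 0L)

  # uniform DE genes at background density: no significant window
  de_null <- catalog[seq(1, 400, by = 40), ]
  expect_equal(nrow(ecr_scan(de_null, catalog, c(chr1 = 4e7))), 0L)
})

test_that("merged cluster windows are disjoint and window sizes bounded", {
  set.seed(12)
  catalog <- data.frame(gene = sprintf("g%03d", 1:300), chrom = "chr1",
                        pos = sort(runif(300, 0, 3e7)))
  de <- catalog[catalog$pos >= 1e7 & catalog$pos < 1.4e7, ]
  ecr <- ecr_scan(de, catalog, c(chr1 = 3e7))
  if (nrow(ecr) > 1) {
    expect_true(all(ecr$start[-1] >= ecr$end[-nrow(ecr)]))
  }
  expect_true(nrow(ecr) >= 1)
})

test_that("DMR-cluster overlap uses half-open interval semantics", {
  ecrs <- data.frame(chrom = "chr1", start = 1e6, end = 3e6)
  inside <- data.frame(chrom = "chr1", start = 2e6, end = 2.1e6)
  expect_equal(dmr_ecr_overlap(inside, ecrs)$n_overlapped_ecrs, 1L)
  touching <- data.frame(chrom = "chr1", start = 3e6, end = 3.1e6)
  expect_equal(dmr_ecr_overlap(touching, ecrs)$n_overlapped_ecrs, 0L)
  expect_equal(dmr_ecr_overlap(inside[0, ], ecrs)$n_overlapped_ecrs, 0L)
})

test_that("interval overlap matches the all-pairs oracle on random sets", {
  for (s in 1:100) {
    set.seed(4000 + s)
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    a <- data.frame(chrom = sample(c("chr1", "chr2"), na, TRUE),
                    start = sample.int(1e4, na))
    a$end <- a$start + sample.int(2000, na)
    b <- data.frame(chrom = sample(c("chr1", "chr2"), nb, TRUE),
                    start = sample.int(1e4, nb))
    b$end <- b$start + sample.int(2000, nb)
    got <- dmr_ecr_overlap(a, b)$pairs        # ecr=b? note arg order: dmrs, ecrs
    want <- oracle_overlap_pairs(b, a)        # oracle rows: (ecr index, dmr index)
    got <- got[order(got$ecr_index, got$dmr_index), ]
    want <- want[order(want$a, want$b), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("chromosome plot tables stack features and validate bounds", {
  expect_equal(nrow(chromosome_plot_data()), 0L)
  t2 <- read_table2_fixture()
  tab <- chromosome_plot_data(dmrs = t2[, c("chr", "start", "end")] |>
                                (\(d) {names(d)[1] <- "chrom"; d})())
  expect_equal(nrow(tab), 43L)
  expect_setequal(unique(tab$chrom), unique(t2$chr))
  dmrs <- data.frame(chrom = "chr1", start = 100, end = 900)
  de <- data.frame(chrom = "chr1", pos = 5000)
  ecrs <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  full <- chromosome_plot_data(dmrs, de, ecrs, c(chr1 = 1e7))
  expect_equal(nrow(full), 3L)
  expect_setequal(full$type, c("DMR", "DE", "ECR"))
  expect_error(chromosome_plot_data(dmrs, de, ecrs, c(chr1 = 1e5)),
               "beyond chromosome length")
})

test_that("dose conversion follows unit arithmetic", {
  expect_equal(signif(dose_to_micromolar(100, VINCLOZOLIN_MOLAR_MASS), 2), 350)
  expect_equal(dose_to_micromolar(100, VINCLOZOLIN_MOLAR_MASS), 349.5159,
               tolerance = 1e-4)
  expect_equal(dose_to_micromolar(10, 100, 1), 100)
  expect_equal(dose_to_micromolar(10, 100, 2),
               dose_to_micromolar(10, 100, 1) / 2)
  expect_error(dose_to_micromolar(-1, 100))
})
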