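mk_sites <- function(gene, offsets, types, mirna = "mir-A",
                     conservation = 5L) {
  data.frame(mirna = mirna, gene_symbol = gene, utr_offset = offsets,
             site_type = types, conservation = conservation,
             stringsAsFactors = FALSE)
}

test_that("targeting score applies the 8mer and proximity weights", {
  cfg <- hub_config(reps = 10L)
  # one conserved 7mer-1a: unweighted unit
  s1 <- mk_sites("G1", 100L, "7mer-1a")
  expect_identical(targeting_score("mir-A", "G1", s1, cfg)$score, 1)
  # one 8mer-1a: weighted 1.5
  s2 <- mk_sites("G1", 100L, "8mer-1a")
  expect_identical(targeting_score("mir-A", "G1", s2, cfg)$score, 1.5)
  # two 7mer-m8 sites 50 nt apart: both weighted, 1.5 + 1.5
  s3 <- mk_sites("G1", c(100L, 150L), c("7mer-m8", "7mer-m8"))
  expect_identical(targeting_score("mir-A", "G1", s3, cfg)$score, 3)
  # 61 nt apart: outside the window, unweighted
  s4 <- mk_sites("G1", c(100L, 161L), c("7mer-m8", "7mer-m8"))
  expect_identical(targeting_score("mir-A", "G1", s4, cfg)$score, 2)
  # below min_conservation the site does not qualify
  s5 <- mk_sites("G1", 100L, "8mer-1a", conservation = 3L)
  expect_identical(targeting_score("mir-A", "G1", s5, cfg)$score, 0)
  # gene-level mode scores the max site weight per gene
  cfg_g <- hub_config(reps = 10L, score_mode = "gene")
  expect_identical(targeting_score("mir-A", "G1", s3, cfg_g)$score, 1.5)
})

test_that("score is additive over genes and counting matches a raw-count oracle", {
  set.seed(13)
  genes <- sprintf("G%d", 1:30)
  site_index <- do.call(rbind, lapply(genes, function(g) {
    n <- rpois(1, 2)
    if (n == 0) return(NULL)
    mk_sites(g, sort(sample.int(900L, n)),
             sample(c("7mer-1a", "7mer-m8", "8mer-1a"), n, TRUE),
             conservation = sample(1:5, n, TRUE))
  }))
  cfg <- hub_config(reps = 10L)
  half1 <- genes[1:15]; half2 <- genes[16:30]
  t_all <- targeting_score("mir-A", genes, site_index, cfg)$score
  t1 <- targeting_score("mir-A", half1, site_index, cfg)$score
  t2 <- targeting_score("mir-A", half2, site_index, cfg)$score
  expect_equal(t_all, t1 + t2)
  expect_lte(t1, t_all)  # removing genes never increases the score

  # weight 1 and min_conservation 1: score equals the raw site count
  cfg_flat <- hub_config(weight = 1, reps = 10L, min_conservation = 1L)
  expect_identical(targeting_score("mir-A", genes, site_index, cfg_flat)$score,
                   as.numeric(nrow(site_index)))
})

test_that("length normalization is the stated ratio form", {
  expect_identical(length_normalize(7, 800, 800), 7)
  expect_identical(length_normalize(10, 500, 1000), 5)
  expect_identical(length_normalize(0, 500, 1000), 0)
  expect_error(length_normalize(1, 0, 100), class = "mirtas_data_error")
  expect_error(length_normalize(1, 100, -5), class = "mirtas_data_error")
})

test_that("hub test p-values use add-one smoothing and are reproducible", {
  genes <- sprintf("G%d", 1:100)
  lens <- setNames(rep(1000, 100), genes)
  # only the 10 candidate genes carry (heavy) sites
  cand <- genes[1:10]
  site_index <- mk_sites(cand, rep(50L, 10), rep("8mer-1a", 10))
  site_index$gene_symbol <- cand
  cfg <- hub_config(reps = 999L, rng_seed = 123L)
  res <- suppressMessages(
    hub_test("mir-A", cand, genes, site_index, lens, cfg, trait = "t"))
  # no random draw of 10 from 100 recovers all carriers: observed tops all
  expect_identical(res$empirical_p, (1 + 0) / (999 + 1))
  expect_identical(res$observed_score, 15)
  expect_identical(res$reps_used, 999L)
  # reproducibility: identical seed, identical result
  res2 <- suppressMessages(
    hub_test("mir-A", cand, genes, site_index, lens, cfg, trait = "t"))
  expect_identical(res$empirical_p, res2$empirical_p)
  expect_identical(res$null_mean, res2$null_mean)

  # a miRNA with no sites anywhere scores 0 and p = 1
  res0 <- suppressMessages(
    hub_test("mir-none", cand, genes, site_index, lens, cfg))
  expect_identical(res0$observed_score, 0)
  expect_identical(res0$empirical_p, 1)

  # p is always in (0, 1]
  expect_gt(res$empirical_p, 0)
  expect_lte(res0$empirical_p, 1)
})

test_that("candidates outside the universe are dropped with a warning", {
  genes <- sprintf("G%d", 1:20)
  lens <- setNames(rep(500, 20), genes)
  si <- mk_sites("G1", 10L, "7mer-1a")
  cfg <- hub_config(reps = 50L, rng_seed = 1L)
  expect_warning(
    res <- suppressMessages(hub_test("mir-A", c("G1", "G2", "GHOST"),
                                     genes, si, lens, cfg)),
    "GHOST")
  expect_identical(res$n_candidates, 2L)
  expect_error(
    suppressWarnings(hub_test("mir-A", "GHOST", genes, si, lens, cfg)),
    class = "mirtas_data_error")
})

test_that("hub scan orders by p, flags significance, and treats equal seeds equally", {
  genes <- sprintf("G%d", 1:60)
  lens <- setNames(rep(800, 60), genes)
  cand <- genes[1:8]
  # mir-hot saturates the candidate set; mir-twin has the identical site
  # index; mir-cold hits nothing
  si <- rbind(mk_sites(cand, rep(10L, 8), rep("8mer-1a", 8), "mir-hot"),
              mk_sites(cand, rep(10L, 8), rep("8mer-1a", 8), "mir-twin"))
  cfg <- hub_config(reps = 499L, rng_seed = 42L)
  scan <- suppressMessages(hub_scan(
    list(traitX = cand), mirnas = c("mir-cold", "mir-hot", "mir-twin"),
    gene_universe = genes, site_index = si, utr_lengths = lens,
    config = cfg, alpha = 0.01))
  expect_s3_class(scan, "hub_scan")
  expect_identical(scan$mirna[3], "mir-cold")
  expect_identical(scan$empirical_p[3], 1)
  expect_false(is.unsorted(scan$empirical_p))
  # identical seed regions give identical scores and p-values
  hot <- scan[scan$mirna == "mir-hot", ]
  twin <- scan[scan$mirna == "mir-twin", ]
  expect_identical(hot$observed, twin$observed)
  expect_identical(hot$empirical_p, twin$empirical_p)
  expect_true(all(c(hot$significant, twin$significant)))
})
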