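# Best-hit-profile transfer detection: score computation, KDE-valley
# cutoffs (dense grid-scan oracle), call logic and end-to-end recovery.

mk_hit <- function(q, s, pid, ev, bits) {
  data.frame(query = q, subject = s, pident = pid, length = 100,
             mismatch = 10, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
             send = 100, evalue = ev, bitscore = bits)
}

toy_map <- data.frame(
  subject = c("she_1", "she_2", "fam_1", "fam_2", "vib_1", "vib_2"),
  taxon = c("Shewanella", "Shewanella", "Shewanellaceae", "Shewanellaceae",
            "Vibrio", "Vibrio"),
  group = c("self", "self", "close", "close", "distal", "distal"))

test_that("scores normalize by the best hit and respect filters", {
  hits <- rbind(mk_hit("g1", "she_1", 98, 1e-80, 200),
                mk_hit("g1", "she_2", 95, 1e-70, 150),
                mk_hit("g1", "vib_1", 60, 1e-40, 200),  # distal = best
                mk_hit("g2", "she_1", 98, 1e-80, 100),
                mk_hit("g2", "vib_1", 40, 1e-40, 90),   # identity floor
                mk_hit("g2", "fam_1", 70, 1e-2, 90))    # E-value filter
  sc <- scoreGenes(hits, toy_map)
  g1 <- sc[sc$gene == "g1", ]
  expect_equal(g1$self_score, 1 + 150 / 200)
  expect_equal(g1$close_score, 0)
  expect_equal(g1$distal_score, 1.0)
  expect_equal(g1$top_distal_taxon, "Vibrio")
  g2 <- sc[sc$gene == "g2", ]
  expect_equal(g2$close_score, 0)
  expect_equal(g2$distal_score, 0)
})

test_that("duplicate hit rows do not change scores", {
  hits <- rbind(mk_hit("g1", "she_1", 98, 1e-80, 200),
                mk_hit("g1", "fam_1", 80, 1e-50, 120))
  sc1 <- scoreGenes(hits, toy_map)
  sc2 <- scoreGenes(rbind(hits, hits, hits[2, ]), toy_map)
  expect_equal(sc1, sc2)
})

test_that("genes with no surviving hits are excluded with a warning", {
  hits <- rbind(mk_hit("g1", "she_1", 98, 1e-80, 200),
                mk_hit("g2", "she_1", 30, 1e-80, 200))
  expect_warning(sc <- scoreGenes(hits, toy_map), "no surviving")
  expect_equal(sc$gene, "g1")
})

test_that("KDE valley sits between well-separated modes (grid oracle)", {
  set.seed(1)
  x <- c(rnorm(250, 0.1, 0.05), rnorm(250, 2.0, 0.2))
  scores <- data.frame(gene = paste0("g", 1:500), self_score = 1,
                       close_score = x,
                       distal_score = c(rnorm(250, 3, 0.3),
                                        rnorm(250, 0.2, 0.05)),
                       top_distal_taxon = "Vibrio", n_hits = 10)
  co <- estimateCutoffs(scores)
  expect_gt(co$close_cutoff, 0.3)
  expect_lt(co$close_cutoff, 1.5)
  expect_equal(unname(co$method_used["close"]), "kde_valley")
  # oracle: dense grid scan of the same Gaussian KDE
  bw <- stats::bw.nrd0(x)
  grid <- seq(min(x), max(x), length.out = 4000)
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - x) / bw)) / bw, 0)
  in_between <- grid > 0.1 & grid < 2.0
  oracle_min <- grid[in_between][which.min(dens[in_between])]
  expect_lt(abs(co$close_cutoff - oracle_min), 0.15)
})

test_that("degenerate score distributions take the conservative path", {
  scores <- data.frame(gene = paste0("g", 1:60), self_score = 1,
                       close_score = rep(5, 60), distal_score = rep(0.1, 60),
                       top_distal_taxon = NA, n_hits = 5)
  w <- testthat::capture_warnings(co <- estimateCutoffs(scores))
  expect_true(any(grepl("no separated", w)))
  expect_false(any(co$method_used == "kde_valley"))
  calls <- callHgt(scores, co)
  expect_false(any(calls$calls$flagged))
  # explicit quantile method still yields finite cutoffs
  co2 <- estimateCutoffs(scores, hgtConfig(cutoff_method = "quantile"))
  expect_equal(unname(co2$close_cutoff), 5)
})

test_that("cutoffs are invariant to gene ordering", {
  set.seed(2)
  scores <- data.frame(gene = paste0("g", 1:200), self_score = 1,
                       close_score = c(rnorm(150, 8, 1), rnorm(50, 0.3, 0.1)),
                       distal_score = c(rnorm(150, 0.3, 0.1), rnorm(50, 6, 1)),
                       top_distal_taxon = "Vibrio", n_hits = 10)
  co1 <- estimateCutoffs(scores)
  co2 <- estimateCutoffs(scores[sample(nrow(scores)), ])
  expect_equal(co1$close_cutoff, co2$close_cutoff)
  expect_equal(co1$distal_cutoff, co2$distal_cutoff)
})

test_that("raising the close cutoff never un-flags a gene", {
  set.seed(3)
  scores <- data.frame(gene = paste0("g", 1:100), self_score = 1,
                       close_score = runif(100, 0, 10),
                       distal_score = runif(100, 0, 5),
                       top_distal_taxon = "Vibrio", n_hits = 10)
  lo <- callHgt(scores, list(close_cutoff = 2, distal_cutoff = 1))
  hi <- callHgt(scores, list(close_cutoff = 4, distal_cutoff = 1))
  expect_true(all(hi$calls$flagged[lo$calls$flagged]))
})

test_that("implanted transfers are recovered with their donors", {
  cfg <- PanSimConfig(n_genomes = 10, n_core_families = 45,
                      n_root_accessory = 0, gain_rate = 0, loss_rate = 0,
                      hgt_rate = 5, gene_length_codons = 60, seed = 5)
  tr <- simulateSpeciesTree(10, 1, seed = 5)
  truth <- simulateGeneContent(tr, cfg)
  genes <- simulateSequences(truth, tr, cfg)
  ht <- simulateHitTable(genes, truth, seed = 5)
  sc <- scoreGenes(ht$hits, ht$taxon_map)
  co <- estimateCutoffs(sc)
  calls <- callHgt(sc, co,
                   gene_genomes = setNames(geneInfo(genes)$genome,
                                           geneInfo(genes)$gene))
  flagged <- calls$calls$gene[calls$calls$flagged]
  implanted <- names(hgtDonors(truth))
  recall <- length(intersect(flagged, implanted)) / length(implanted)
  precision <- length(intersect(flagged, implanted)) / length(flagged)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  donors <- calls$calls$donor[match(implanted, calls$calls$gene)]
  agree <- mean(donors == hgtDonors(truth), na.rm = TRUE)
  expect_gte(agree, 0.9)
  expect_true(sum(calls$by_strain) == sum(calls$calls$flagged))
})

test_that("transfer-free data yield almost no false positives", {
  cfg <- PanSimConfig(n_genomes = 10, n_core_families = 50,
                      n_root_accessory = 0, gain_rate = 0, loss_rate = 0,
                      hgt_rate = 0, gene_length_codons = 60, seed = 8)
  tr <- simulateSpeciesTree(10, 1, seed = 8)
  truth <- simulateGeneContent(tr, cfg)
  genes <- simulateSequences(truth, tr, cfg)
  ht <- simulateHitTable(genes, truth, seed = 8)
  sc <- scoreGenes(ht$hits, ht$taxon_map)
  co <- suppressWarnings(estimateCutoffs(sc))
  calls <- callHgt(sc, co)
  expect_lte(mean(calls$calls$flagged), 0.02)
  # and by construction no close score falls below the distal score
  expect_true(all(sc$close_score >= sc$distal_score))
})
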