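# Hit filtering, similarity-graph weighting, Markov clustering (with a
# dense independent oracle) and family classification.

write_m8 <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  f
}

m8row <- function(q, s, ev, bits = 100, pid = 80) {
  data.frame(query = q, subject = s, pident = pid, length = 100, mismatch = 20,
             gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = ev, bitscore = bits)
}

test_that("hit loading applies the E-value cutoff and drops self-hits", {
  df <- rbind(m8row("a", "b", 1e-10), m8row("b", "a", 1e-20),
              m8row("a", "c", 1e-3), m8row("c", "c", 1e-50),
              m8row("b", "c", 1e-6))
  h <- loadHits(write_m8(df))
  expect_equal(nrow(h), 3L)            # 1e-3 filtered, self-hit dropped
  expect_false(any(h$query == h$subject))
  expect_true(all(h$evalue <= 1e-5))

  empty <- tempfile(); file.create(empty)
  expect_warning(h0 <- loadHits(empty), "empty")
  expect_equal(nrow(h0), 0L)

  bad <- tempfile()
  writeLines(c("a\tb\t80\t100\t20\t0\t1\t100\t1\t100\tnot_a_number\t55"), bad)
  expect_error(suppressWarnings(loadHits(bad)), "malformed|parse")
})

test_that("graph weights are -log10(E), reciprocal-averaged and capped", {
  df <- rbind(m8row("a", "b", 1e-50), m8row("b", "a", 1e-50),
              m8row("c", "d", 1e-30),                   # one direction only
              m8row("e", "f", 0))                       # E = 0 cap
  g <- buildSimilarityGraph(df)
  w <- setNames(g$edges$weight, paste(g$edges$from, g$edges$to))
  expect_equal(unname(w["a b"]), 50)
  expect_equal(unname(w["c d"]), 30)
  expect_equal(unname(w["e f"]), 200)
  # asymmetric weights average
  df2 <- rbind(m8row("a", "b", 1e-40), m8row("b", "a", 1e-60))
  g2 <- buildSimilarityGraph(df2)
  expect_equal(g2$edges$weight, 50)
})

clique_graph <- function(groups, w_in = 1, bridges = NULL) {
  edges <- NULL
  for (g in groups) {
    pr <- t(combn(g, 2))
    edges <- rbind(edges, data.frame(from = pr[, 1], to = pr[, 2],
                                     weight = w_in))
  }
  if (!is.null(bridges)) edges <- rbind(edges, bridges)
  list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges)
}

test_that("MCL returns disjoint cliques unchanged and splits barbells", {
  g <- clique_graph(list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  cl <- mclCluster(g)
  expect_equal(canon_partition(cl), c("a1,a2,a3", "b1,b2,b3"))

  g4 <- clique_graph(list(paste0("x", 1:4)))
  expect_equal(length(mclCluster(g4)), 1L)

  barbell <- clique_graph(list(paste0("L", 1:5), paste0("R", 1:5)),
                          w_in = 1,
                          bridges = data.frame(from = "L1", to = "R1",
                                               weight = 0.1))
  cl2 <- mclCluster(barbell, inflation = 1.5)
  expect_equal(canon_partition(cl2),
               c("L1,L2,L3,L4,L5", "R1,R2,R3,R4,R5"))
})

test_that("sparse MCL agrees with a dense independent iteration", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    # random modular graph: 2-3 blocks with strong inside, weak between
    k <- sample(2:3, 1)
    block <- sample(k, n, replace = TRUE)
    adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      w <- if (block[i] == block[j]) runif(1, 0.8, 1.2)
      else if (runif(1) < 0.3) runif(1, 0.01, 0.1) else 0
      adj[i, j] <- adj[j, i] <- w
    }
    keep <- rowSums(adj) > 0
    adj <- adj[keep, keep, drop = FALSE]
    if (nrow(adj) < 4) next
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    g <- list(nodes = rownames(adj),
              edges = data.frame(from = rownames(adj)[idx[, 1]],
                                 to = colnames(adj)[idx[, 2]],
                                 weight = adj[idx]))
    mine <- mclCluster(g)
    oracle <- dense_mcl(adj)
    oracle_named <- lapply(oracle, function(ix) rownames(adj)[ix])
    expect_equal(canon_partition(mine), canon_partition(oracle_named))
  }
})

test_that("clusters partition nodes for any input graph", {
  set.seed(7)
  nodes <- sprintf("g%02d", 1:15)
  idx <- t(combn(15, 2))
  pick <- runif(nrow(idx)) < 0.25
  g <- list(nodes = nodes,
            edges = data.frame(from = nodes[idx[pick, 1]],
                               to = nodes[idx[pick, 2]],
                               weight = runif(sum(pick), 0.1, 2)))
  g$nodes <- sort(unique(c(g$edges$from, g$edges$to)))
  cl <- mclCluster(g)
  expect_setequal(unlist(cl), g$nodes)
  expect_equal(length(unlist(cl)), length(g$nodes))
})

test_that("family classification follows the partition definitions", {
  clusters <- list(c("A|g1", "B|g1", "C|g1"),        # core
                   c("A|g2", "B|g2"),                # accessory
                   c("C|g3"),                        # specific
                   c("A|g4", "A|g5", "B|g4", "C|g4")) # core, multi-copy
  gg <- setNames(sub("\\|.*", "", unlist(clusters)), unlist(clusters))
  gg["A|orphan"] <- "A"                              # unclustered singleton
  fs <- classifyFamilies(clusters, gg, genomes = c("A", "B", "C"))
  cat_ <- familyCategories(fs)
  mem <- familyMembership(fs)
  fam_of <- function(gene) mem$family[mem$gene == gene]
  expect_equal(unname(cat_[fam_of("A|g1")]), "core")
  expect_equal(unname(cat_[fam_of("A|g2")]), "accessory")
  expect_equal(unname(cat_[fam_of("C|g3")]), "specific")
  expect_equal(unname(cat_[fam_of("A|orphan")]), "specific")
  sc <- singleCopy(fs)
  expect_true(sc[[fam_of("A|g1")]])
  expect_false(sc[[fam_of("A|g4")]])                 # core but duplicated in A
  expect_error(classifyFamilies(list("zz"), gg), "unknown genome")
})

test_that("near-clique synthetic families are recovered exactly", {
  # within-family weights >= 10x between-family noise
  set.seed(31)
  fams <- split(sprintf("F%d|m%d", rep(1:20, each = 5), 1:5),
                rep(1:20, each = 5))
  edges <- NULL
  for (f in fams) {
    pr <- t(combn(f, 2))
    edges <- rbind(edges, data.frame(from = pr[, 1], to = pr[, 2],
                                     weight = runif(nrow(pr), 40, 60)))
  }
  all_genes <- unlist(fams)
  noise_i <- sample(all_genes, 30, replace = TRUE)
  noise_j <- sample(all_genes, 30, replace = TRUE)
  ok <- noise_i != noise_j
  edges <- rbind(edges, data.frame(from = noise_i[ok], to = noise_j[ok],
                                   weight = runif(sum(ok), 1, 4)))
  g <- list(nodes = sort(all_genes), edges = edges)
  cl <- mclCluster(g)
  expect_equal(canon_partition(cl), canon_partition(fams))
})
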