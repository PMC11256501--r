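test_that("rarefaction hits the target depth exactly and drops shallow samples", {
  set.seed(2)
  counts <- matrix(rpois(5 * 40, 1000), 5, 40,
                   dimnames = list(paste0("s", 1:5), paste0("t", 1:40)))
  counts[5, ] <- rpois(40, 100)  # shallow sample
  depth <- 29300
  counts[1, 1] <- counts[1, 1] + max(0, depth - sum(counts[1, ]) + 500)
  keepable <- rowSums(counts) >= depth
  rar <- rarefy_counts(counts, depth = depth, seed = 99)
  expect_true(all(rowSums(rar) == depth))
  expect_identical(rownames(rar), rownames(counts)[keepable])
  expect_identical(attr(rar, "dropped_samples"),
                   rownames(counts)[!keepable])
  ## never exceeds the original counts; support is a subset
  orig <- counts[rownames(rar), ]
  expect_true(all(rar <= orig))
  expect_true(all(orig[rar > 0] > 0))
  ## a sample holding exactly depth reads is returned unchanged
  exact <- matrix(c(20000L, 9300L, 15000L, 15000L), 2, 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("t1", "t2")))
  rar2 <- rarefy_counts(exact, depth = 29300, seed = 1)
  expect_identical(rar2["a", ], exact["a", ])
  expect_error(rarefy_counts(exact, depth = 0), "positive")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  x <- matrix(c(9000L, 1000L), 1, 2,
              dimnames = list("s1", c("t1", "t2")))
  set.seed(123)
  draws <- replicate(10000, suppressWarnings(vegan::rrarefy(x, 1000))[1, 1])
  ## E = 1000 * 9000/10000 = 900; finite-population (hypergeometric) SE
  n <- 1000; N <- 10000; p <- 0.9
  se <- sqrt(n * p * (1 - p) * (N - n) / (N - 1)) / sqrt(10000)
  expect_lt(abs(mean(draws) - 900), 3 * se)
  mine <- replicate(2000, rarefy_counts(x, 1000)[1, 1])
  expect_lt(abs(mean(mine) - 900),
            3 * sqrt(n * p * (1 - p) * (N - n) / (N - 1)) / sqrt(2000))
})

test_that("relative abundances are proportions", {
  m <- matrix(c(50, 50, 100, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  ra <- relative_abundance(m)
  expect_equal(ra["a", ], c(t1 = 0.5, t2 = 0.5))
  expect_equal(unname(ra["b", "t1"]), 1)
  expect_equal(rowSums(ra), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(relative_abundance(7 * m), ra)  # scale invariance
  m0 <- rbind(m, z = c(0, 0))
  expect_error(relative_abundance(m0), "zero total")
})

test_that("guild extraction matches curated names case-insensitively", {
  counts <- matrix(100L, 2, 4,
                   dimnames = list(c("s1", "s2"),
                                   c("tx1", "tx2", "tx3", "tx4")))
  taxonomy <- c(
    tx1 = "d__Bacteria;p__Pseudomonadota;c__Alpha;o__X;f__Y;g__methylocystis",
    tx2 = "d__Archaea;p__Halobacterota;c__Z;o__W;f__V;g__Methanosarcina",
    tx3 = "d__Bacteria;p__Acidobacteriota;c__Q;o__R;f__S;g__Other",
    tx4 = "d__Archaea;p__Thermoproteota;c__Bathyarchaeia;o__;f__;g__")
  g <- extract_guilds(counts, taxonomy)
  expect_identical(colnames(g$methanotrophs), "tx1")
  expect_identical(sort(colnames(g$methanogens)), c("tx2", "tx4"))
  ## summed relative abundances: 2 of 4 equal-count taxa are methanogens
  expect_equal(g$summary$methanogen_rel_abund, c(0.5, 0.5))
  expect_equal(g$summary$methanotroph_rel_abund, c(0.25, 0.25))
  ## idempotence: re-extracting from a guild subtable returns it unchanged
  g2 <- extract_guilds(g$methanogens, taxonomy[colnames(g$methanogens)])
  expect_identical(g2$methanogens, g$methanogens)
  ## empty guild configuration
  empty <- extract_guilds(counts, taxonomy,
                          guilds = list(methanogens = character(0),
                                        methanotrophs = character(0)))
  expect_identical(ncol(empty$methanogens), 0L)
  expect_identical(ncol(empty$methanotrophs), 0L)
  ## a name on both lists is a configuration error
  expect_error(
    extract_guilds(counts, taxonomy,
                   guilds = list(methanogens = "Methylocystis",
                                 methanotrophs = "Methylocystis")),
    "both")
})

test_that("a fixture with exact guild proportions sums to that proportion", {
  ## 2.6% of every sample's reads in methanogen taxa
  counts <- cbind(meth = rep(26L, 3), other1 = rep(500L, 3),
                  other2 = rep(474L, 3))
  rownames(counts) <- paste0("s", 1:3)
  taxonomy <- c(meth = "d__Archaea;g__Methanobacterium",
                other1 = "d__Bacteria;g__A", other2 = "d__Bacteria;g__B")
  g <- extract_guilds(counts, taxonomy)
  expect_equal(g$summary$methanogen_rel_abund, rep(0.026, 3),
               tolerance = 1e-12)
})

test_that("CLAM classifies the canonical cases", {
  cl <- clam_classify(c(t1 = 0L, t2 = 500L, t3 = 500L, t4 = 12L),
                      c(t1 = 0L, t2 = 0L, t3 = 500L, t4 = 0L))
  expect_identical(as.character(cl$label),
                   c("too_rare", "specialist_A", "generalist",
                     "specialist_A"))
  expect_error(clam_classify(1:3, 1:3, alpha = 1.2), "alpha")
  expect_error(clam_classify(1:3, 1:2), "same taxa")
  m <- matrix(1L, 2, 3, dimnames = list(c("s1", "s2"), NULL))
  expect_error(clam_classify(m, m), "share samples")
})

test_that("CLAM agrees with the exact binomial-tail oracle for all totals <= 60", {
  pairs <- do.call(rbind, lapply(0:60, function(n)
    if (n == 0) cbind(0L, 0L) else cbind(0:n, n:0)))
  got <- clam_classify(pairs[, 1], pairs[, 2])
  want <- mapply(clam_oracle, pairs[, 1], pairs[, 2])
  expect_identical(as.character(got$label), unname(want))
})

test_that("swapping groups swaps specialist labels only", {
  set.seed(8)
  yA <- rpois(200, 30); yB <- rpois(200, 30)
  ab <- clam_classify(yA, yB)
  ba <- clam_classify(yB, yA)
  map <- c(generalist = "generalist", specialist_A = "specialist_B",
           specialist_B = "specialist_A", too_rare = "too_rare")
  expect_identical(as.character(ba$label),
                   unname(map[as.character(ab$label)]))
  ## labels always partition the taxa
  expect_identical(sum(attr(ab, "label_counts")), nrow(ab))
})

test_that("the min-classifiable coverage rule flags unclassifiable totals", {
  ## smallest n with (2/3)^n <= 0.05 is 8
  cl <- clam_classify(c(7L, 8L, 9L), c(0L, 0L, 0L),
                      coverage_rule = "min_classifiable")
  expect_identical(as.character(cl$label),
                   c("too_rare", "specialist_A", "specialist_A"))
})

test_that("planted specialists and generalists are recovered from counts", {
  tbl <- gen_count_table(n_samples = 12, n_taxa = 80,
                         guild_fraction = 0,
                         specialist_structure = list(
                           n_specialist_A = 4, n_specialist_B = 4,
                           enrichment = 50),
                         depth_distribution = function(n) rep(30000L, n),
                         seed = 21)
  A <- tbl$counts[tbl$metadata$group == "A", ]
  B <- tbl$counts[tbl$metadata$group == "B", ]
  cl <- clam_classify(A, B)
  lab <- setNames(as.character(cl$label), cl$taxon)
  expect_true(all(lab[tbl$specialist_taxa$A] == "specialist_A"))
  expect_true(all(lab[tbl$specialist_taxa$B] == "specialist_B"))
  ## a taxon with every read in group A and counts above the floor
  expect_gte(sum(tbl$counts[, tbl$specialist_taxa$A[1]]), 10)
})
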