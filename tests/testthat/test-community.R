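test_that("rarefaction hits the target depth exactly and preserves support", {
  set.seed(2)
  cnt <- matrix(rpois(5 * 30, 20), 5, 30,
                dimnames = list(paste0("S", 1:5), paste0("ASV", 1:30)))
  cnt[1, ] <- rmultinom(1, 399, rep(1, 30))   # below depth -> dropped
  tab <- toy_table(cnt)
  r <- rarefy(tab, depth = 400, seed = 7)
  expect_false("S1" %in% rownames(r$counts))
  expect_true(all(rowSums(r$counts) == 400))
  # support preservation: nothing appears that was absent before
  expect_true(all(r$counts[cnt[rownames(r$counts), ] == 0] == 0))
  # a sample with exactly the target depth is returned unchanged
  cnt2 <- rbind(x = rmultinom(1, 400, rep(1, 30))[, 1],
                y = rmultinom(1, 900, rep(1, 30))[, 1])
  r2 <- rarefy(toy_table(cnt2), 400, seed = 1)
  expect_equal(unname(r2$counts["x", ]), unname(cnt2["x", ]))
  expect_identical(rarefy(tab, 400, seed = 7)$counts, r$counts)
  expect_error(rarefy(tab, 0), "positive")
})

test_that("alpha diversity matches closed forms", {
  tab <- toy_table(rbind(u = c(10, 10, 10, 10),
                         d = c(3997, 1, 1, 1),
                         s = c(50, 0, 0, 0)))
  a <- alpha_diversity(tab)
  expect_equal(a$richness, c(4, 4, 1))
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$pielou[1], 1)
  p <- c(3997, 1, 1, 1) / 4000
  expect_equal(a$shannon[2], -sum(p * log(p)))
  expect_lt(a$pielou[2], 0.01)
  expect_true(is.na(a$pielou[3]))
})

test_that("Bray-Curtis matches the closed form and its bounds", {
  tab <- toy_table(rbind(a = c(5, 5, 0), b = c(0, 5, 5), c = c(5, 5, 0),
                         d = c(0, 0, 10)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(toy_table(rbind(a = c(1, 1), z = c(0, 0)))),
               "empty")
})

test_that("dysbiosis scores are centroid distance differences in PCoA space", {
  # samples on a line; Euclidean distances, so PCoA recovers the line
  pos <- c(n1 = -1, n2 = 1, r1 = 1, r2 = 3)
  d <- dist(pos)
  status <- c("non_raft", "non_raft", "raft", "raft")
  sc <- dysbiosis_score(d, status)
  # non-raft centroid at 0, raft centroid at 2; sample r2 at 3 scores 3-1=2
  expect_equal(sc$score[sc$sample == "r2"], 2, tolerance = 1e-8)
  # sample n2/r1 at 1 is equidistant from both centroids -> 0
  expect_equal(sc$score[sc$sample == "n2"], 0, tolerance = 1e-8)
  expect_error(dysbiosis_score(d, c("non_raft", "raft", "raft", "raft")),
               ">= 2")
  # restricting the reference moves the reference centroid
  pos5 <- c(n1 = -1, n2 = 1, n3 = 4, r1 = 1, r2 = 3)
  st5 <- c("non_raft", "non_raft", "non_raft", "raft", "raft")
  full <- dysbiosis_score(dist(pos5), st5)
  filt <- dysbiosis_score(dist(pos5), st5, reference_filter = c("n1", "n2"))
  expect_false(isTRUE(all.equal(full$score, filt$score)))
  expect_equal(filt$score[filt$sample == "r2"], 2, tolerance = 1e-8)
})

test_that("core walk stops at the marginal-gain rule", {
  # one ubiquitous taxon carries all between-sample differences
  cnt <- rbind(s1 = c(100, 10, 10), s2 = c(10, 10, 10),
               s3 = c(100, 10, 10), s4 = c(10, 10, 10))
  colnames(cnt) <- c("big", "t2", "t3")
  cs <- core_taxa(toy_table(cnt), stop_fraction = 0.03)
  expect_equal(cs$core, "big")
  expect_equal(unname(cs$explained[3]), 1, tolerance = 1e-9)
  # invariant to taxon column order
  cs2 <- core_taxa(toy_table(cnt[, c(3, 1, 2)]), stop_fraction = 0.03)
  expect_equal(cs2$core, "big")
  expect_error(core_taxa(toy_table(cnt[1:3, ])), ">= 4")
})

test_that("recovered core taxa satisfy the occupancy expectation on planted data", {
  cfg <- scenario_config(n_taxa = 120, n_nonraft = 24, n_raft = 6)
  mb <- gen_microbiomes(cfg, seed = 4)
  tab <- rarefy(mb$table, 4000, seed = 1)
  nr <- subset_samples(tab, tab$metadata$status == "non_raft")
  cs <- core_taxa(nr)
  occ <- colMeans(nr$counts[, cs$core, drop = FALSE] > 0)
  expect_true(all(occ >= 0.8))
})

test_that("class fractions are exhaustive, exclusive and sum to one", {
  cnt <- rbind(n1 = c(800, 150, 30, 20), n2 = c(700, 250, 30, 20),
               r1 = c(100, 100, 700, 100), r2 = c(50, 150, 700, 100))
  colnames(cnt) <- paste0("t", 1:4)
  tab <- toy_table(cnt, status = c("non_raft", "non_raft", "raft", "raft"))
  cp <- classify_and_partition(tab, core = "t1", abundance_cutoff = 0.001)
  cls <- setNames(cp$classification$class, cp$classification$taxon)
  expect_equal(unname(cls["t1"]), "core")
  expect_equal(unname(cls["t2"]), "abundant")   # mean non-raft 20% > 0.1%
  expect_true(all(table(cp$classification$class) >= 1))
  expect_equal(rowSums(cp$fractions[, c("core", "abundant", "rare")]),
               rep(1, 4), ignore_attr = TRUE)
  expect_error(classify_and_partition(tab, core = "nope"), "subset")
  # a taxon with mean non-raft abundance 0.2% and not core -> abundant
  cnt2 <- cbind(cnt, t5 = c(2, 2, 1, 1))  # ~0.2% of non-raft reads
  cp2 <- classify_and_partition(toy_table(cnt2,
                                          status = c("non_raft", "non_raft",
                                                     "raft", "raft")),
                                core = "t1")
  expect_equal(cp2$classification$class[cp2$classification$taxon == "t5"],
               "abundant")
})

test_that("the community-weighted rRNA trait averages genus copy numbers", {
  cnt <- rbind(s1 = c(50, 50), s2 = c(0, 80), s3 = c(50, 50))
  colnames(cnt) <- c("t1", "t2")
  tax <- data.frame(taxon = c("t1", "t2"), genus = c("Alpha", "Beta"))
  tab <- community_table(cnt, data.frame(sample = rownames(cnt),
                                         status = "raft"), tax)
  traits <- data.frame(genus = c("alpha", "Beta"), mean_copies = c(2, 4))
  tr <- weighted_rrna_trait(tab, traits)
  expect_equal(tr$rrna_trait, c(3, 4, 3))  # case-insensitive genus match
  # unknown genus excluded with weight renormalization
  traits2 <- data.frame(genus = "Alpha", mean_copies = 2)
  tr2 <- weighted_rrna_trait(tab, traits2)
  expect_equal(tr2$rrna_trait[1], 2)
  expect_true(is.na(tr2$rrna_trait[2]))
  tab7 <- community_table(cbind(t1 = c(s1 = 30)),
                          data.frame(sample = "s1", status = "raft"),
                          data.frame(taxon = "t1", genus = "Gamma"))
  expect_equal(weighted_rrna_trait(tab7, data.frame(genus = "Gamma",
                                                    mean_copies = 7))$rrna_trait,
               7)
})

test_that("replicates merge by summed counts and tables round-trip as TSV", {
  cnt <- rbind(a1 = c(1, 2, 3), a2 = c(4, 5, 6), b1 = c(7, 8, 9))
  tab <- toy_table(cnt, status = c("raft", "raft", "non_raft"))
  m <- merge_replicates(tab, c("a", "a", "b"))
  expect_equal(m$counts["a", ], c(5, 7, 9), ignore_attr = TRUE)
  expect_equal(nrow(m$counts), 2)

  cfile <- withr::local_tempfile(fileext = ".tsv")
  mfile <- withr::local_tempfile(fileext = ".tsv")
  xfile <- withr::local_tempfile(fileext = ".tsv")
  tab$taxonomy <- data.frame(taxon = colnames(tab$counts),
                             genus = c("g1", "g1", "g2"))
  write_community_tsv(tab, cfile, mfile, xfile)
  back <- read_community_tsv(cfile, mfile, xfile)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$metadata$status, tab$metadata$status)
  expect_equal(back$taxonomy, tab$taxonomy)
})
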