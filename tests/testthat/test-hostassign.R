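test_that("genotype filtering applies depth, locus and individual rules in order", {
  # locus 1 monomorphic (MAC 0) -> dropped; locus 5 too missing -> dropped
  gt <- rbind(i1 = c(0, 0, 1, 2, NA),
              i2 = c(0, 1, 1, 0, NA),
              i3 = c(0, 2, 0, 1, NA),
              i4 = c(0, 1, 2, 1, 1))
  colnames(gt) <- paste0("L", 1:5)
  g <- genotype_matrix(gt)
  f <- filter_genotypes(g, min_depth = 0, max_missing = 0.2, min_mac = 2,
                        min_snps_per_ind = 1)
  expect_false("L1" %in% colnames(f$genotypes))   # monomorphic
  expect_false("L5" %in% colnames(f$genotypes))   # 3/4 missing > 0.2
  expect_true(all(c("L2", "L3", "L4") %in% colnames(f$genotypes)))

  # missingness exactly above threshold drops the locus (0.3 > 0.2)
  gt2 <- matrix(1L, 10, 2, dimnames = list(paste0("i", 1:10), c("A", "B")))
  gt2[1:3, 2] <- NA
  gt2[1, 1] <- 0L; gt2[2, 1] <- 2L  # keep A polymorphic
  f2 <- filter_genotypes(genotype_matrix(gt2), min_depth = 0,
                         min_snps_per_ind = 0)
  expect_equal(colnames(f2$genotypes), "A")

  # an all-pass matrix comes back unchanged
  gt3 <- rbind(a = c(0, 1, 2), b = c(2, 1, 0), c = c(1, 0, 2), d = c(1, 2, 0))
  g3 <- genotype_matrix(gt3)
  f3 <- filter_genotypes(g3, min_depth = 0, min_snps_per_ind = 1)
  expect_equal(f3$genotypes, g3$genotypes)

  # depth masking happens before locus filters: a low-depth locus becomes
  # all-missing and is dropped by the missingness rule
  dp <- matrix(10, 4, 3); dp[, 1] <- 1
  f4 <- filter_genotypes(genotype_matrix(gt3, depths = dp), min_depth = 5,
                         min_snps_per_ind = 1)
  expect_false("snp1" %in% colnames(f4$genotypes))
  expect_setequal(colnames(f4$genotypes), c("snp2", "snp3"))
  expect_error(filter_genotypes(genotype_matrix(gt3), min_depth = 0,
                                min_mac = 100), "empty panel")
})

test_that("filtering is idempotent and matches the brute-force oracle", {
  set.seed(11)
  for (k in 1:20) {
    gt <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 15, replace = TRUE,
                        prob = c(0.4, 0.2, 0.3, 0.1)), 20, 15,
                 dimnames = list(paste0("i", 1:20), paste0("L", 1:15)))
    dp <- matrix(rpois(20 * 15, 8), 20, 15)
    want <- oracle_filter(gt, dp, 5, 0.2, 2, 3)
    got <- tryCatch(filter_genotypes(genotype_matrix(gt, depths = dp),
                                     min_depth = 5, min_snps_per_ind = 3),
                    error = function(e) NULL)
    if (is.null(got)) { expect_true(nrow(want) == 0 || ncol(want) == 0); next }
    expect_identical(got$genotypes, want)
    again <- filter_genotypes(got, min_depth = 5, min_snps_per_ind = 3)
    expect_identical(again$genotypes, got$genotypes)
  }
})

test_that("genotype distances follow the shared-dosage formula", {
  g <- genotype_matrix(rbind(a = c(0, 2, 1), b = c(2, 0, 1), c = c(1, 1, 1)))
  d <- as.matrix(genotype_distance(g))
  expect_equal(d["a", "b"], 2 / 3, tolerance = 1e-12)
  expect_equal(d["a", "c"], 1 / 3, tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  g2 <- genotype_matrix(rbind(a = c(0, 0), b = c(2, 2), c = c(0, 2)))
  expect_equal(as.matrix(genotype_distance(g2))["a", "b"], 1)
  g3 <- genotype_matrix(rbind(a = c(0, NA), b = c(NA, 2), c = c(1, 1)))
  expect_error(genotype_distance(g3), "no called loci")
})

test_that("support trees are deterministic and recover clear population structure", {
  set.seed(5)
  # two well separated 3-individual populations + 2 linking individuals
  freqA <- rep(0.05, 60); freqB <- rep(0.95, 60)
  draw <- function(f, nm) {
    m <- t(vapply(1:3, function(i) rbinom(60, 2, f), integer(60)))
    rownames(m) <- paste0(nm, 1:3); m
  }
  gt <- rbind(draw(freqA, "A"), draw(freqB, "B"))
  g <- genotype_matrix(gt)
  tr1 <- build_support_tree(g, n_boot = 50, seed = 9)
  tr2 <- build_support_tree(g, n_boot = 50, seed = 9)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  # the population bipartition exists with 100% support
  isA <- function(tips) setequal(tips, paste0("A", 1:3)) ||
    setequal(tips, paste0("B", 1:3))
  ntip <- length(tr1$tip.label)
  found <- FALSE
  for (nd in (ntip + 1):(ntip + tr1$Nnode)) {
    tips <- ape::extract.clade(tr1, nd)$tip.label
    if (isA(tips) && as.numeric(tr1$node.label[nd - ntip]) == 100)
      found <- TRUE
  }
  expect_true(found)
  expect_error(build_support_tree(g, n_boot = 0), "n_boot")
})

test_that("clade traversal assignment follows supports and spans", {
  refs <- data.frame(
    individual = c("a1", "a2", "b1", "b2"),
    population = c("A", "A", "B", "B"),
    lat = c(-45.0, -45.01, -46.0, -46.01),
    lon = c(170, 170.01, 170.5, 170.51))
  # query sister to population A under a 95-support node
  tr <- ape::read.tree(
    text = "((q:1,(a1:1,a2:1)99:1)95:1,(b1:1,b2:1)99:2);")
  a <- assign_source(tr, "q", refs, support_threshold = 80)
  expect_equal(a$tier, "population")
  expect_setequal(a$locations$individual, c("a1", "a2"))
  expect_gt(a$anchor_support, 80)

  # weak first node, strong grandparent spanning A and B -> broader tier
  tr2 <- ape::read.tree(
    text = "(((q:1,(a1:1,a2:1)99:1)60:1,(b1:1,b2:1)99:1)85:1,out:5);")
  refs2 <- rbind(refs, data.frame(individual = "out", population = "C",
                                  lat = -40, lon = 166))
  a2 <- assign_source(tr2, "q", refs2, support_threshold = 80)
  expect_setequal(a2$locations$population, c("A", "B"))
  expect_true(a2$tier %in% c("localized_region", "broad_region"))
  expect_equal(a2$anchor_support, 85)

  # no qualifying node on the root path -> unassigned
  tr3 <- ape::read.tree(
    text = "((q:1,(a1:1,a2:1)50:1)40:1,(b1:1,b2:1)45:2);")
  a3 <- assign_source(tr3, "q", refs, support_threshold = 80)
  expect_equal(a3$tier, "unassigned")
  expect_equal(nrow(a3$locations), 0)
  expect_error(assign_source(tr, "nope", refs), "not found")
})

test_that("raising the support threshold never shrinks the returned clade", {
  tr <- ape::read.tree(
    text = "(((q:1,(a1:1,a2:1)60:1)60:1,(b1:1,b2:1)99:1)95:1,out:5);")
  refs <- data.frame(individual = c("a1", "a2", "b1", "b2", "out"),
                     population = c("A", "A", "B", "B", "C"),
                     lat = c(-45, -45, -46, -46, -40),
                     lon = c(170, 170, 171, 171, 166))
  sizes <- vapply(c(50, 59, 90), function(th)
    nrow(assign_source(tr, "q", refs, support_threshold = th)$locations), 0L)
  expect_true(all(diff(sizes) >= 0))
  expect_equal(sizes, c(2L, 2L, 4L))
})

test_that("assignments buffer into coastal target zones", {
  coast <- data.frame(lat = seq(-47, -43, by = 0.01),
                      lon = 166 + 0.1 * sin(seq(-47, -43, by = 0.01)))
  one <- structure(list(query = "q", tier = "population",
                        locations = data.frame(individual = "a1",
                                               population = "A",
                                               lat = -45, lon = 166.08),
                        anchor_support = 99), class = "source_assignment")
  z1 <- assignment_to_zone(one, coast)
  expect_equal(length(z1$lat), 1)
  expect_equal(z1$hit_radius_km, 2)

  two <- one
  two$locations <- data.frame(individual = c("a1", "b1"),
                              population = c("A", "B"),
                              lat = c(-45, -44.1), lon = c(166.08, 166.05))
  z2 <- assignment_to_zone(two, coast)
  # the zone spans the intervening coastline (~0.9 degrees of latitude)
  expect_gt(length(z2$lat), 50)
  expect_equal(range(z2$lat), c(-45, -44.1), tolerance = 0.02)

  un <- one; un$tier <- "unassigned"; un$locations <- one$locations[0, ]
  expect_error(assignment_to_zone(un, coast), "skip drift")
})

test_that("genotype TSV round trips", {
  g <- genotype_matrix(rbind(a = c(0, 1, 2), b = c(2, NA, 0),
                             c = c(1, 0, 2)),
                       coords = data.frame(individual = c("a", "b"),
                                           lat = c(-45, -46),
                                           lon = c(170, 171)))
  gp <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, gp, coords_path = cp)
  h <- read_genotypes_tsv(gp, coords_path = cp)
  expect_equal(h$genotypes, g$genotypes)
  expect_equal(h$coords$lat, g$coords$lat)
})
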