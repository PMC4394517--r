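test_that("p-distances follow the mismatch/compared-columns definition", {
  d <- p_distance_matrix(c(a = "AAAA", b = "AAAT", c = "AAAA"))
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  # unequal lengths go through alignment; gap columns are excluded
  d2 <- p_distance_matrix(c(a = "AACCGGTTAACC", b = "AACCGGTTAA"))
  expect_equal(d2["a", "b"], 0)
})

test_that("within-locus distances are smaller than between-locus distances in simulations", {
  for (seed in 1:5) {
    sim <- simulate_dataset(small_sim_config(seed))
    pool <- sim_carried_alleles(sim, "cdna")
    pool <- pool[!duplicated(pool)]
    if (length(pool) < 4) next
    dm <- p_distance_matrix(pool)
    locus_of <- sub("^L(\\d+).*$", "\\1", rownames(dm))
    same <- outer(locus_of, locus_of, "==") & upper.tri(dm)
    diff <- outer(locus_of, locus_of, "!=") & upper.tri(dm)
    if (!any(same) || !any(diff)) next
    expect_lt(mean(dm[same]), mean(dm[diff]))
  }
})

test_that("neighbor joining recovers additive and ultrametric structures", {
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")

  labs <- c("a", "b", "c")
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, dimnames = list(labs, labs))
  t3 <- nj_tree(d3)
  expect_setequal(t3$tree$tip.label, labs)

  # additive matrix from a known 4-taxon tree: ((a,b),(c,d)) with internal
  # branch 3; a-b cherry distances 2+1, c-d cherry 1+1
  lab4 <- c("a", "b", "c", "d")
  dm <- matrix(0, 4, 4, dimnames = list(lab4, lab4))
  path <- list(ab = 3, ac = 2 + 3 + 1, ad = 2 + 3 + 1, bc = 1 + 3 + 1, bd = 1 + 3 + 1, cd = 2)
  dm["a", "b"] <- dm["b", "a"] <- path$ab
  dm["a", "c"] <- dm["c", "a"] <- path$ac
  dm["a", "d"] <- dm["d", "a"] <- path$ad
  dm["b", "c"] <- dm["c", "b"] <- path$bc
  dm["b", "d"] <- dm["d", "b"] <- path$bd
  dm["c", "d"] <- dm["d", "c"] <- path$cd
  res <- nj_tree(dm)
  # the a|b vs c|d split must be present: drop the internal edge and check
  parts <- ape::prop.part(ape::unroot(res$tree))
  bip <- lapply(parts, function(p) sort(res$tree$tip.label[p]))
  expect_true(any(vapply(bip, function(b) identical(b, c("a", "b")) || identical(b, c("c", "d")),
                         logical(1))))
  # newick text round-trips with the same leaf set
  back <- ape::read.tree(text = res$newick)
  expect_setequal(back$tip.label, lab4)
})

test_that("the diploid bound is the ceiling of the richest individual's allele count", {
  expect_equal(min_locus_bound(c(i1 = 8L)), 4L)
  expect_equal(min_locus_bound(c(i1 = 1L)), 1L)
  expect_equal(min_locus_bound(c(a = 2L, b = 3L, c = 5L, d = 8L, e = 7L)), 4L)
  g <- data.frame(individual_id = rep("no3", 8), allele_name = paste0("a", 1:8))
  expect_equal(min_locus_bound(g), 4L)
  expect_error(min_locus_bound(stats::setNames(integer(0), character(0))), "empty")
})

# build a distance matrix with planted tight pairs
pair_dm <- function(n_pairs, within = 0.01, between = 0.2) {
  n <- 2 * n_pairs
  labs <- sprintf("al%02d", seq_len(n))
  d <- matrix(between, n, n, dimnames = list(labs, labs))
  for (p in seq_len(n_pairs)) {
    i <- 2 * p - 1
    d[i, i + 1] <- d[i + 1, i] <- within
  }
  diag(d) <- 0
  d
}

test_that("eight alleles of one individual in four tight pairs yield four groups", {
  d <- pair_dm(4)
  g <- data.frame(individual_id = "no3", allele_name = rownames(d))
  grp <- constrained_grouping(d, g)
  expect_length(grp$groups, 4L)
  expect_true(all(vapply(grp$groups, length, integer(1)) == 2L))
  expect_equal(grp$min_locus_estimate, 4L)
  expect_equal(grp$bound, 4L)
  # pairs kept intact
  expect_true(all(vapply(grp$groups, function(gg) {
    idx <- as.integer(sub("al", "", gg))
    abs(diff(idx)) == 1L
  }, logical(1))))
})

test_that("a single allele forms a single group with estimate 1", {
  d <- matrix(0, 1, 1, dimnames = list("a1", "a1"))
  g <- data.frame(individual_id = "i1", allele_name = "a1")
  grp <- constrained_grouping(d, g)
  expect_length(grp$groups, 1L)
  expect_equal(grp$min_locus_estimate, 1L)
})

test_that("no emitted group ever holds more than two alleles of one individual", {
  set.seed(61)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    labs <- sprintf("a%02d", seq_len(n))
    d <- matrix(stats::runif(n * n, 0, 0.3), n, n, dimnames = list(labs, labs))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    n_ind <- sample(2:4, 1)
    geno <- do.call(rbind, lapply(seq_len(n_ind), function(i) {
      k <- sample(seq_len(min(n, 6)), 1)
      data.frame(individual_id = paste0("i", i),
                 allele_name = sample(labs, k))
    }))
    # every allele must be carried by someone
    orphan <- setdiff(labs, geno$allele_name)
    if (length(orphan)) {
      geno <- rbind(geno, data.frame(individual_id = "i1", allele_name = orphan))
    }
    geno <- unique(geno)
    grp <- constrained_grouping(d, geno, exhaustive_limit = 8)
    if (length(grp$groups)) {
      expect_true(all(grp$per_group_counts <= 2L))
    }
    expect_gte(grp$min_locus_estimate, grp$bound)
  }
})

test_that("small groupings reach the brute-force minimum over all diploid-legal partitions", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    labs <- sprintf("a%d", seq_len(n))
    d <- matrix(stats::runif(n * n, 0, 0.3), n, n, dimnames = list(labs, labs))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    n_ind <- sample(1:3, 1)
    geno <- do.call(rbind, lapply(seq_len(n_ind), function(i) {
      data.frame(individual_id = paste0("i", i),
                 allele_name = sample(labs, sample(seq_len(n), 1)))
    }))
    orphan <- setdiff(labs, geno$allele_name)
    if (length(orphan)) {
      geno <- rbind(geno, data.frame(individual_id = paste0("i", n_ind), allele_name = orphan))
    }
    geno <- unique(geno)
    grp <- constrained_grouping(d, geno, outlier_quantile = 1)
    inc <- t(allele_sharing_matrix(geno))[labs, , drop = FALSE]
    expect_equal(length(grp$groups), oracle_min_groups(inc),
                 label = paste("rep", rep))
  }
})

test_that("isolated singletons are moved to unassigned, mirroring allele exclusion", {
  labs <- c("a1", "a2", "b1", "b2", "far")
  d <- matrix(0.05, 5, 5, dimnames = list(labs, labs))
  d["a1", "a2"] <- d["a2", "a1"] <- 0.01
  d["b1", "b2"] <- d["b2", "b1"] <- 0.01
  d["far", labs != "far"] <- d[labs != "far", "far"] <- 0.5
  diag(d) <- 0
  # all five alleles carried by one individual: the diploid constraint
  # blocks any merge of "far" into the two pairs, leaving it a singleton
  geno <- data.frame(individual_id = rep("i1", 5), allele_name = labs)
  grp <- constrained_grouping(d, geno, outlier_quantile = 0.6)
  expect_equal(grp$unassigned, "far")
  expect_false("far" %in% unlist(grp$groups))
})
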