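# Hierarchical clustering with four linkages, dendrogram cutting, and the
# purity of a cluster against another linkage's tree.

three_point_matrix <- function() {
  m <- matrix(c(0, 1, 5,
                1, 0, 4,
                5, 4, 0), 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m
}

test_that("three points on a line merge at the hand-computed heights", {
  m <- three_point_matrix()
  expect_equal(hca(m, "single")$merges$height, c(1, 4))
  expect_equal(hca(m, "complete")$merges$height, c(1, 5))
  expect_equal(hca(m, "average")$merges$height, c(1, 4.5))
})

test_that("monotone linkages reproduce stats::hclust heights", {
  set.seed(101)
  for (trial in 1:10) {
    n <- sample(4:10, 1)
    m <- random_distance_matrix(n)
    for (lk in c("single", "complete", "average")) {
      ours <- hca(m, lk)
      ref <- stats::hclust(stats::as.dist(m), method = lk)
      expect_equal(ours$merges$height, ref$height, tolerance = 1e-12)
    }
  }
})

test_that("all four linkages agree with a naive re-scan oracle", {
  set.seed(102)
  for (trial in 1:8) {
    n <- sample(4:9, 1)
    m <- random_distance_matrix(n)
    for (lk in c("single", "complete", "average", "ward")) {
      ours <- hca(m, lk)$merges
      ref <- oracle_hca_merges(m, lk)
      expect_equal(ours$a, ref$a)
      expect_equal(ours$b, ref$b)
      expect_equal(ours$height, ref$height, tolerance = 1e-12)
    }
  }
})

test_that("merge ties resolve lexicographically by cluster id", {
  # four equidistant points: all six pairs tie at distance 1
  m <- matrix(1, 4, 4); diag(m) <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  tr <- hca(m, "single")
  expect_equal(tr$merges$a[1], 1)
  expect_equal(tr$merges$b[1], 2)
  expect_equal(tr$merges$a[2], 3)
  expect_equal(tr$merges$b[2], 4)
})

test_that("cutting removes the last merges and yields labelled subtrees", {
  m <- three_point_matrix()
  tr <- hca(m, "average")
  all_one <- cut_clusters(tr, 1)
  expect_equal(unique(all_one$cluster), "A")
  two <- cut_clusters(tr, 2)
  expect_equal(two$cluster[two$id == "a"], two$cluster[two$id == "b"])
  expect_false(two$cluster[two$id == "c"] == two$cluster[two$id == "a"])
  # names by decreasing size: {a,b} is "A", singleton {c} is "B"
  expect_equal(two$cluster, c("A", "A", "B"))
  three <- cut_clusters(tr, 3)
  expect_equal(sort(unique(three$cluster)), c("A", "B", "C"))
  expect_error(cut_clusters(tr, 0), class = "cellph_parameter_error")
  expect_error(cut_clusters(tr, 4), class = "cellph_parameter_error")
})

test_that("every cut cluster is a contiguous subtree, ward included", {
  set.seed(103)
  for (trial in 1:6) {
    n <- sample(6:12, 1)
    m <- random_distance_matrix(n)
    for (lk in c("average", "ward")) {
      tr <- hca(m, lk)
      for (k in 2:4) {
        cl <- cut_clusters(tr, k)
        expect_equal(length(unique(cl$cluster)), k)
        for (cn in unique(cl$cluster)) {
          ids <- cl$id[cl$cluster == cn]
          expect_equal(purity(ids, tr), 1)   # subtree <=> purity 1
        }
      }
    }
  }
})

test_that("purity is 1 for subtrees and 0 only at the root", {
  m <- three_point_matrix()
  tr <- hca(m, "average")
  expect_equal(purity(c("a", "b"), tr), 1)
  expect_equal(purity(c("a", "c"), tr), 0)   # only the root contains both
  expect_equal(purity("c", tr), 1)           # singletons are pure
  expect_error(purity(c("a", "b", "c"), tr), class = "cellph_domain_error")
  expect_error(purity(character(0), tr))
  expect_error(purity(c("a", "zz"), tr))
})

test_that("the closed form equals the literal upward walk from any seed", {
  set.seed(104)
  for (trial in 1:10) {
    n <- sample(5:12, 1)
    m <- random_distance_matrix(n)
    tr <- hca(m, sample(c("average", "single", "complete", "ward"), 1))
    size <- sample(2:(n - 1), 1)
    idx <- sort(sample(n, size))
    c1 <- tr$labels[idx]
    got <- purity(c1, tr)
    walks <- vapply(idx, function(st) oracle_purity_walk(idx, tr, st),
                    numeric(1))
    expect_true(all(walks == walks[1]))   # seed-independent
    expect_equal(got, walks[1], tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("the purity table scores the reference linkage at exactly 1", {
  set.seed(105)
  m <- random_distance_matrix(15)
  tab <- purity_table(m, k = 3)
  ref_row <- tab[tab$linkage == "average", -1]
  expect_true(all(as.numeric(ref_row) == 1))
  expect_equal(tab$linkage, c("average", "single", "complete", "ward"))
  expect_true(all(as.matrix(tab[, -1]) >= 0 & as.matrix(tab[, -1]) <= 1))
  expect_equal(sum(attr(tab, "sizes")), 15L)
})

test_that("conversion to hclust preserves heights and leaf partitioning", {
  set.seed(106)
  m <- random_distance_matrix(8)
  tr <- hca(m, "complete")
  hc <- as.hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, tr$merges$height)
  expect_equal(sort(hc$order), 1:8)
  # base cutree on the converted object splits like cut_clusters
  base_cut <- stats::cutree(hc, k = 3)
  ours <- cut_clusters(tr, 3)
  tab <- table(base_cut, ours$cluster)
  expect_equal(sum(tab > 0), 3L)   # one-to-one correspondence of classes
})

test_that("Newick serialisation is parseable and preserves the topology", {
  m <- three_point_matrix()
  tr <- hca(m, "average")
  nwk <- dendrogram_newick(tr)
  expect_match(nwk, ";$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  # a and b form a cherry in the parsed tree
  mrca_depth <- ape::getMRCA(phy, c("a", "b"))
  expect_false(mrca_depth == ape::getMRCA(phy, c("a", "c")))
})
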