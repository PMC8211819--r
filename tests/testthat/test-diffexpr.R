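test_that("FPKM follows the unit case, the scaling law and the hand formula", {
  m <- matrix(1e6, nrow = 1, dimnames = list("g1", "s1"))
  expect_equal(unname(fpkm(m, 1000)[1, 1]), 1e6)
  expect_equal(unname(fpkm(m, 2000)[1, 1]), 5e5)

  cts <- matrix(c(10, 20, 30, 5, 50, 45), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  lens <- c(500, 1000, 2000)
  f <- fpkm(cts, lens)
  for (g in 1:3) for (s in 1:2)
    expect_equal(f[g, s],
                 cts[g, s] / ((lens[g] / 1000) * (sum(cts[, s]) / 1e6)))
  expect_error(fpkm(cbind(cts, s3 = c(0, 0, 0)), lens), "zero total")
  expect_error(fpkm(cts, c(0, 1, 1)), "positive")
})

# counts engineered so that the two B-vs-A comparisons give up-ranks
# (1,2,3,4) and (1,3,2,4)
rp_fixture <- function() {
  cts <- cbind(A1 = c(100, 100, 100, 100),
               B1 = c(800, 400, 200, 100),
               B2 = c(800, 200, 400, 100))
  rownames(cts) <- paste0("g", 1:4)
  groups <- stats::setNames(c("A", "B", "B"), colnames(cts))
  list(cts = cts, groups = groups)
}

test_that("rank product equals the fold-change rank geometric mean, ties included", {
  fx <- rp_fixture()
  de <- rank_product(fx$cts, fx$groups, "A", "B", n_permutations = 10L,
                    seed = 1L)
  expect_equal(de$rp_up, c(1, sqrt(6), sqrt(6), 4))
  expect_equal(attr(de, "n_comparisons"), 2L)
  # the two middle genes tie and share their pfp
  expect_equal(de$pfp_up[2], de$pfp_up[3])

  # k = 1: RP is exactly the fold-change rank and the top gene has RP 1
  one <- fx$cts[, c("A1", "B1")]
  de1 <- rank_product(one, stats::setNames(c("A", "B"), colnames(one)),
                      "A", "B", n_permutations = 10L, seed = 1L)
  expect_equal(de1$rp_up, c(1, 2, 3, 4))
  expect_equal(de1$rp_down, c(4, 3, 2, 1))
  expect_error(rank_product(one, stats::setNames(c("A", "B"), colnames(one)),
                            "A", "Z"), "group not found")
})

test_that("permutation pfp converges to the exact enumeration expectation", {
  fx <- rp_fixture()
  de <- rank_product(fx$cts, fx$groups, "A", "B", n_permutations = 4000L,
                     seed = 99L)
  obs_rank <- rank(de$rp_up, ties.method = "max")
  for (g in 1:4) {
    exact <- exact_expected_count(de$rp_up[g], G = 4L, k = 2L) / obs_rank[g]
    expect_equal(de$pfp_up[g], exact, tolerance = 0.06)
  }
})

test_that("rank product is invariant under power-law rescaling of expression", {
  set.seed(21)
  # continuous expression: no cross-gene fold-change ties
  cts <- matrix(rlnorm(200 * 6, log(50), 1), nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), colnames(cts))
  de <- rank_product(cts, groups, "A", "B", n_permutations = 20L, seed = 5L)
  # x -> c * x^a (a > 0) preserves fold-change order within a comparison
  de2 <- rank_product(3 * (cts + 0.5)^1.7 - 0.5, groups, "A", "B",
                      n_permutations = 20L, seed = 5L)
  expect_equal(de2$rp_up, de$rp_up)
  expect_equal(de2$pfp_up, de$pfp_up)
})

test_that("swapping the group labels swaps the up and down analyses exactly", {
  set.seed(8)
  cts <- matrix(rnbinom(100 * 6, mu = 80, size = 5), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), colnames(cts))
  de_ab <- rank_product(cts, groups, "A", "B", n_permutations = 50L, seed = 4L)
  de_ba <- rank_product(cts, groups, "B", "A", n_permutations = 50L, seed = 4L)
  expect_equal(de_ab$rp_up, de_ba$rp_down)
  expect_equal(de_ab$pfp_up, de_ba$pfp_down)
  expect_equal(de_ab$mean_log2fc, -de_ba$mean_log2fc)
})

test_that("gene-set extraction respects the cutoff and keeps sets disjoint", {
  fx <- rp_fixture()
  de <- rank_product(fx$cts, fx$groups, "A", "B", n_permutations = 100L,
                     seed = 2L)
  empty <- extract_gene_sets(de, 0)
  expect_length(empty$up, 0L)
  expect_length(empty$down, 0L)
  all_in <- extract_gene_sets(de, Inf)
  expect_setequal(c(all_in$up, all_in$down), de$gene_id)
  expect_length(intersect(all_in$up, all_in$down), 0L)
})
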