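test_that("a purely additive candidate + sample pattern has zero stability", {
  alpha <- c(0, 1, -2, 3)
  beta <- c(0.5, -0.5, 1, 2, -1)
  y <- outer(alpha, beta, `+`)
  dimnames(y) <- list(paste0("g", 1:4), paste0("s", 1:5))
  res <- normfinder_ungrouped(y)
  expect_equal(unname(res$stability), rep(0, 4))
  expect_equal(unname(res$sigma2), rep(0, 4))
})

test_that("candidate variances match the brute-force moment-system solve", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(4:6, 1); n <- sample(5:12, 1)
    y <- matrix(rnorm(k * n, sd = runif(1, 0.2, 1)), k, n,
                dimnames = list(paste0("g", 1:k), paste0("s", 1:n)))
    res <- suppressMessages(normfinder_ungrouped(y))
    expect_equal(res$sigma2, pmax(brute_normfinder_sigma2(y), 0), tolerance = 1e-9)
  }
})

test_that("an injected noise variance is recovered without systematic bias", {
  set.seed(32)
  est <- replicate(500, {
    y <- rbind(noisy = rnorm(20, sd = 0.5),
               g2 = rnorm(20, sd = 0.1), g3 = rnorm(20, sd = 0.1),
               g4 = rnorm(20, sd = 0.1))
    colnames(y) <- paste0("s", 1:20)
    suppressMessages(normfinder_ungrouped(y))$sigma2[["noisy"]]
  })
  expect_lt(abs(mean(est) - 0.25) / 0.25, 0.1)
})

test_that("stability is invariant to row and column shifts", {
  set.seed(33)
  y <- matrix(rnorm(40, sd = 0.4), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  shifted <- y + matrix(rnorm(5), 5, 8) + matrix(rnorm(8), 5, 8, byrow = TRUE)
  expect_equal(normfinder_ungrouped(y)$stability,
               normfinder_ungrouped(shifted)$stability, tolerance = 1e-9)
  groups <- setNames(rep(c("A", "B"), each = 4), colnames(y))
  expect_equal(normfinder_grouped(y, groups)$stability,
               normfinder_grouped(shifted, groups)$stability, tolerance = 1e-9)
})

test_that("grouped differences are centred and vanish for identical group means", {
  set.seed(34)
  y <- matrix(rnorm(60, sd = 0.3), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  groups <- setNames(rep(c("A", "B", "C"), each = 4), colnames(y))
  res <- normfinder_grouped(y, groups)
  expect_equal(unname(colSums(res$d)), rep(0, 3), tolerance = 1e-9)

  # duplicate each sample across two pseudo-groups: group means identical
  y2 <- cbind(y, y)
  colnames(y2) <- paste0("s", 1:24)
  g2 <- setNames(rep(c("A", "B"), each = 12), colnames(y2))
  res2 <- normfinder_grouped(y2, g2)
  expect_equal(unname(res2$d), matrix(0, 5, 2), tolerance = 1e-9)
  expect_equal(res2$stability,
               rowMeans(sqrt(sweep(res2$sigma2_group, 2,
                                   table(g2)[colnames(res2$sigma2_group)], `/`))),
               tolerance = 1e-9)
})

test_that("a candidate biased in one group receives the worst grouped stability", {
  set.seed(35)
  hits <- replicate(200, {
    y <- matrix(rnorm(4 * 20, sd = 0.2), 4, 20,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:20)))
    groups <- setNames(rep(c("A", "B"), each = 10), colnames(y))
    y["g1", groups == "B"] <- y["g1", groups == "B"] + 1
    res <- suppressMessages(normfinder_grouped(y, groups))
    names(which.max(res$stability)) == "g1"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("panel and grouping preconditions are enforced", {
  y <- matrix(rnorm(12), 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  expect_error(normfinder_ungrouped(y), class = "mirnorm_insufficient_panel_error")
  y3 <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_error(normfinder_grouped(y3, setNames(rep("A", 4), colnames(y3))),
               class = "mirnorm_grouping_error")
  expect_error(normfinder_grouped(y3, setNames(c("A", "A", "A", "B"), colnames(y3))),
               class = "mirnorm_grouping_error")
})

test_that("grouping schemes reproduce the study cardinalities", {
  meta <- simulate_study(preset_scenarios("panel9", seed = 1))$meta
  schemes <- grouping_schemes(meta)
  expect_named(schemes, c("animal", "genotype", "muscle", "age"))
  expect_equal(length(unique(schemes$animal)), 17)
  expect_equal(as.vector(table(schemes$genotype)), c(47, 47))
  expect_equal(length(unique(schemes$muscle)), 5)
  expect_equal(length(unique(schemes$age)), 6)
})

test_that("grouped ranking on simulated study data puts a stable candidate on top", {
  pre <- preprocess_panel9(2)
  rq <- cq_to_rq(pre$candidates)
  groups <- grouping_schemes(pre$sim$meta)$genotype
  res <- suppressMessages(normfinder_grouped(log_rq(rq), groups))
  top <- res$table$candidate_id[res$table$rank == 1]
  expect_true(top %in% panel9_stable)
  expect_equal(res$table$candidate_id[res$table$rank == 9], "snRNA-U6")
})
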