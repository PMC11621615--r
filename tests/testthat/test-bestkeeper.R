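test_that("the index is the per-sample geometric mean of Cq values", {
  cq <- make_cq(c("a", "b"), "s1", cq = c(16, 25))
  expect_equal(unname(bestkeeper_index(cq)), 20)
  const <- make_cq(rep(c("a", "b", "c"), 3), rep(c("s1", "s2", "s3"), each = 3), cq = 24)
  expect_equal(unname(bestkeeper_index(const)), rep(24, 3))
})

test_that("index matches brute-force product^(1/k) on a random panel", {
  set.seed(21)
  m <- matrix(runif(40, 18, 32), 5, 8,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:8)))
  cq <- cq_table(data.frame(
    assay_id = rep(rownames(m), 8), sample_id = rep(colnames(m), each = 5),
    plate_id = "P1", replicate = 1L, cq = as.vector(m)
  ))
  expect_equal(bestkeeper_index(cq), brute_bestkeeper_index(m), tolerance = 1e-12)
})

test_that("missing entries are reported with coordinates", {
  cq <- make_cq(c("a", "a", "b"), c("s1", "s2", "s1"), cq = c(20, 21, 25))
  expect_error(bestkeeper_index(cq), "b, s2", class = "mirnorm_validation_error")
})

test_that("a candidate matching the index pattern attains r = 1", {
  # with c = sqrt(a * b), the panel geomean equals c itself
  a <- c(20, 22, 24, 26); b <- c(30, 26, 28, 24)
  cq <- cq_table(data.frame(
    assay_id = rep(c("a", "b", "c"), each = 4),
    sample_id = rep(paste0("s", 1:4), 3), plate_id = "P1", replicate = 1L,
    cq = c(a, b, sqrt(a * b))
  ))
  res <- bestkeeper_stats(cq)
  expect_equal(res$table$score[res$table$candidate_id == "c"], 1, tolerance = 1e-9)
  expect_equal(res$table$rank[res$table$candidate_id == "c"], 1)
})

test_that("a candidate mirroring the comparison index about its mean attains r = -1", {
  set.seed(22)
  m <- matrix(runif(30, 20, 30), 3, 10,
              dimnames = list(paste0("a", 1:3), paste0("s", 1:10)))
  loo_index <- apply(m, 2, function(col) prod(col)^(1 / 3))
  mirrored <- 2 * mean(loo_index) - loo_index
  cq <- cq_table(data.frame(
    assay_id = rep(c(rownames(m), "neg"), each = 10),
    sample_id = rep(colnames(m), 4), plate_id = "P1", replicate = 1L,
    cq = c(as.vector(t(m)), mirrored)
  ))
  res <- bestkeeper_stats(cq, leave_one_out = TRUE)
  expect_equal(res$table$score[res$table$candidate_id == "neg"], -1, tolerance = 1e-9)
  expect_equal(res$table$rank[res$table$candidate_id == "neg"], 4)
})

test_that("r values match an independent Pearson computation", {
  set.seed(23)
  m <- matrix(runif(48, 20, 30), 6, 8,
              dimnames = list(paste0("a", 1:6), paste0("s", 1:8)))
  cq <- cq_table(data.frame(
    assay_id = rep(rownames(m), 8), sample_id = rep(colnames(m), each = 6),
    plate_id = "P1", replicate = 1L, cq = as.vector(m)
  ))
  res <- bestkeeper_stats(cq)
  idx <- brute_bestkeeper_index(m)
  for (i in rownames(m)) {
    expect_equal(res$table$score[res$table$candidate_id == i],
                 brute_pearson(m[i, ], idx), tolerance = 1e-9)
  }
})

test_that("a zero-variance candidate gets NA r, a warning, and the last rank", {
  a <- c(20, 22, 24, 26)
  cq <- cq_table(data.frame(
    assay_id = rep(c("a", "b", "flat"), each = 4),
    sample_id = rep(paste0("s", 1:4), 3), plate_id = "P1", replicate = 1L,
    cq = c(a, rev(a), rep(25, 4))
  ))
  expect_warning(res <- bestkeeper_stats(cq), "zero")
  tab <- res$table
  expect_true(is.na(tab$score[tab$candidate_id == "flat"]))
  expect_equal(tab$rank[tab$candidate_id == "flat"], 3)
})

test_that("rescaling one candidate's Cq leaves its r unchanged and shifts the index geometrically", {
  set.seed(24)
  m <- matrix(runif(40, 20, 30), 5, 8,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:8)))
  as_cq <- function(mm) cq_table(data.frame(
    assay_id = rep(rownames(mm), ncol(mm)), sample_id = rep(colnames(mm), each = nrow(mm)),
    plate_id = "P1", replicate = 1L, cq = as.vector(mm)
  ))
  r0 <- bestkeeper_stats(as_cq(m))
  m2 <- m; m2["a3", ] <- m2["a3", ] * 1.1
  r1 <- bestkeeper_stats(as_cq(m2))
  expect_equal(r1$table$score[r1$table$candidate_id == "a3"],
               r0$table$score[r0$table$candidate_id == "a3"], tolerance = 1e-9)
  expect_equal(r1$index, r0$index * 1.1^(1 / 5), tolerance = 1e-12)
})

test_that("noisier candidates tend to correlate less with the index", {
  set.seed(25)
  hits <- replicate(50, {
    common <- rnorm(12, 25, 1)
    m <- rbind(quiet = common + rnorm(12, 0, 0.1),
               loud = common + rnorm(12, 0, 1.5),
               t(replicate(6, common + rnorm(12, 0, 0.5))))
    rownames(m) <- c("quiet", "loud", paste0("mid", 1:6))
    colnames(m) <- paste0("s", 1:12)
    cq <- cq_table(data.frame(
      assay_id = rep(rownames(m), 12), sample_id = rep(colnames(m), each = 8),
      plate_id = "P1", replicate = 1L, cq = as.vector(m)
    ))
    tab <- bestkeeper_stats(cq)$table
    tab$rank[tab$candidate_id == "quiet"] < tab$rank[tab$candidate_id == "loud"]
  })
  expect_gt(mean(hits), 0.9)
})
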