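test_that("the nine study subsets realise the design cardinalities", {
  meta <- simulate_study(preset_scenarios("panel9", seed = 1))$meta
  subsets <- subset_datasets(meta)
  sizes <- vapply(subsets, function(s) length(s$sample_ids), integer(1))
  expect_equal(sizes, c(
    "All" = 94L, "WT" = 47L, "DE50MD" = 47L,
    "VL" = 70L, "WT-VL" = 35L, "DE50MD-VL" = 35L,
    "18m" = 35L, "WT-18m" = 17L, "DE50MD-18m" = 18L
  ))
})

test_that("empty subsets are skipped with a warning", {
  meta <- make_meta(n_dogs = 3, ages = c(3L, 6L))
  suppressWarnings(expect_warning(subsets <- subset_datasets(meta), "18m"))
  expect_false("18m" %in% names(subsets))
  expect_equal(length(subsets$All$sample_ids), nrow(meta))
})

test_that("custom subset predicates are honoured", {
  meta <- make_meta(n_dogs = 2, ages = c(3L, 6L))
  subsets <- subset_datasets(meta, scheme = "custom",
                             predicates = list(young = function(m) m$age_months == 3))
  expect_equal(length(subsets$young$sample_ids), 4)
})

test_that("top-k intersection and consensus ranking behave on edge cases", {
  mk <- function(alg, ids) stability_table(alg, "All", data.frame(
    candidate_id = ids, score = seq_along(ids), rank = seq_along(ids)))
  same <- list(mk("genorm", letters[1:6]), mk("bestkeeper", letters[1:6]),
               mk("normfinder", letters[1:6]))
  cons <- topk_intersection(same, k = 3)
  expect_equal(cons$intersection, c("a", "b", "c"))
  expect_equal(cons$consensus_rank$mean_rank, 1:6)

  disjoint <- list(mk("genorm", c("a", "b", "c", "d")),
                   mk("bestkeeper", c("c", "d", "a", "b")))
  expect_equal(topk_intersection(disjoint, k = 2)$intersection, character(0))

  expect_error(topk_intersection(list(mk("genorm", letters[1:3]),
                                      mk("bestkeeper", letters[2:4])), k = 2),
               class = "mirnorm_validation_error")
})

test_that("the normalisation factor is the per-sample geometric mean of references", {
  m <- rbind(r1 = c(1, 1, 0.25), r2 = c(4, 1, 1), t = c(2, 3, 4))
  colnames(m) <- paste0("s", 1:3)
  rq <- rq_matrix(m)
  nf <- compute_nf(rq, c("r1", "r2"))
  expect_equal(unname(nf$nf), c(2, 1, 0.5))
  expect_equal(unname(compute_nf(rq, "r1")$nf), unname(m["r1", ]))
  expect_error(compute_nf(rq, c("r1", "nope")), class = "mirnorm_validation_error")
})

test_that("target normalisation divides by the factor and reports log2", {
  m <- rbind(r1 = c(1, 4, 9), one = c(1, 1, 1), t = c(1, 4, 9))
  colnames(m) <- paste0("s", 1:3)
  rq <- rq_matrix(m)
  nf <- compute_nf(rq, c("t", "one"))
  norm <- normalize_target(rq, "t", nf)
  expect_equal(norm$value, sqrt(c(1, 4, 9))) # RQ / sqrt(RQ * 1)
  expect_equal(norm$log2_value, log2(norm$value))
  nf_self <- compute_nf(rq, "t")
  expect_equal(normalize_target(rq, "t", nf_self)$value, rep(1, 3))
  bad_nf <- structure(list(reference_ids = "r1",
                           nf = c(sA = 1, sB = 1, sC = 1)),
                      class = "normalization_factor")
  expect_error(normalize_target(rq, "t", bad_nf), class = "mirnorm_alignment_error")
})

test_that("normalised targets are invariant to global per-sample rescaling", {
  set.seed(41)
  rq <- random_rq(6, 10)
  scale <- runif(10, 0.1, 10)
  scaled <- rq_matrix(sweep(rq$rq, 2, scale, `*`))
  refs <- c("g1", "g2", "g3")
  n0 <- normalize_target(rq, "g6", compute_nf(rq, refs))
  n1 <- normalize_target(scaled, "g6", compute_nf(scaled, refs))
  expect_equal(n0$value, n1$value, tolerance = 1e-12)
})

test_that("Holm-Sidak adjustment matches its closed form and stays monotone", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(2:10, 1))
    adj <- holm_sidak(p)
    expect_equal(adj, brute_holm_sidak(p), tolerance = 1e-12)
    expect_true(all(adj >= 0 & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("genotype comparisons estimate fold changes on the geometric scale", {
  meta <- make_meta(n_dogs = 30, ages = 3L)
  set.seed(43)
  lv <- ifelse(meta$genotype == "WT", 1, 0) + rnorm(60, sd = 0.2)
  vals <- setNames(2^lv, meta$sample_id)
  cmp <- compare_groups(vals, meta)
  expect_equal(cmp$fc_wt_vs_de, 2, tolerance = 0.05)
  expect_equal(cmp$fc_de_vs_wt, 1 / cmp$fc_wt_vs_de)
  expect_lt(cmp$p_adj, 0.05)

  flat <- setNames(rep(4, 60), meta$sample_id)
  cmp0 <- compare_groups(flat, meta)
  expect_equal(cmp0$fc_wt_vs_de, 1)
  expect_equal(cmp0$p_raw, 1)
})

test_that("degenerate strata are skipped with a warning", {
  meta <- simulate_study(preset_scenarios("panel9", seed = 1))$meta
  vals <- setNames(rep_len(c(1, 2, 1.5), nrow(meta)), meta$sample_id)
  # stratifying by dog gives single-genotype strata everywhere except none
  expect_error(suppressWarnings(compare_groups(vals, meta, strata = "dog_id")),
               class = "mirnorm_validation_error")
  cmp <- suppressWarnings(compare_groups(vals, meta, strata = c("muscle", "age_months")))
  expect_true(all(cmp$n_wt >= 2 & cmp$n_de >= 2))
  expect_equal(cmp$p_adj, holm_sidak(cmp$p_raw))
})

test_that("reference validation refuses members of the factor and is exact for the factor itself", {
  set.seed(44)
  meta <- simulate_study(preset_scenarios("panel9", seed = 1))$meta
  k <- 4; n <- nrow(meta)
  m <- matrix(2^rnorm(k * n, sd = 0.3), k, n,
              dimnames = list(paste0("r", 1:k), meta$sample_id))
  # a candidate constructed to equal the NF of r1..r3 exactly
  nf_pattern <- apply(m[1:3, ], 2, function(x) exp(mean(log(x))))
  m["r4", ] <- nf_pattern
  rq <- rq_matrix(m)
  nf <- compute_nf(rq, paste0("r", 1:3))
  expect_error(validate_reference("r1", rq, nf, meta), class = "mirnorm_misuse_error")
  val <- suppressWarnings(validate_reference("r4", rq, nf, meta))
  expect_equal(val$overall$fc_wt_vs_de, 1, tolerance = 1e-9)
  expect_true(all(abs(val$by_stratum$log2_fc) < 1e-9))
})

test_that("a designed-stable held-out candidate validates cleanly", {
  set.seed(45)
  clean <- 0
  for (s in 1:25) {
    pre <- preprocess_panel9(s)
    rq <- cq_to_rq(pre$candidates)
    nf <- compute_nf(rq, c("miR-191", "let-7b", "miR-15a", "miR-125a"))
    val <- suppressWarnings(validate_reference("miR-27b", rq, nf, pre$sim$meta))
    if (val$overall$p_adj > 0.05 && abs(log2(val$overall$fc_wt_vs_de)) < 0.3)
      clean <- clean + 1
  }
  expect_gte(clean, 22)
})

test_that("a destabilised U6-like candidate shows its genotype and age effects", {
  pre <- preprocess_panel9(6)
  rq <- cq_to_rq(pre$candidates)
  meta <- pre$sim$meta
  raw_u6 <- setNames(rq$rq["snRNA-U6", meta$sample_id], meta$sample_id)
  cmp <- compare_groups(raw_u6, meta)
  expect_gt(cmp$fc_de_vs_wt, 1.3) # injected ~1.8-fold genotype up-shift
  vl <- meta[meta$muscle == "VL", ]
  age_means <- tapply(log2(raw_u6[vl$sample_id]), vl$age_months, mean)
  expect_lt(cor(as.numeric(names(age_means)), age_means), -0.5) # age decline
})
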