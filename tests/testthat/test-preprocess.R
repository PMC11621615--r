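test_that("IPC calibration reproduces the hand-computed two-plate case", {
  cq <- make_cq(
    assay = c("IPC", "IPC", "IPC", "IPC", "tgt", "tgt"),
    sample = c("s1", "s2", "s3", "s4", "s1", "s3"),
    plate = c("A", "A", "B", "B", "A", "B"),
    cq = c(19.5, 20.5, 20.5, 21.5, 28.0, 30.0)
  )
  out <- calibrate_ipc(cq, "IPC")
  expect_equal(out$calibration$plate_offsets, c(A = -0.5, B = 0.5))
  expect_equal(out$cq$cq[out$cq$assay_id == "tgt" & out$cq$plate_id == "B"], 29.5)
  expect_equal(out$cq$cq[out$cq$assay_id == "tgt" & out$cq$plate_id == "A"], 28.5)
})

test_that("IPC calibration is the identity for equal plate means or one plate", {
  cq <- make_cq(c("IPC", "IPC", "t", "t"), c("s1", "s2", "s1", "s2"),
                plate = c("A", "B", "A", "B"), cq = c(20, 20, 25, 26))
  out <- calibrate_ipc(cq, "IPC")
  expect_equal(out$cq$cq, cq$cq)
  single <- make_cq(c("IPC", "t"), "s1", plate = "A", cq = c(20, 25))
  out1 <- calibrate_ipc(single, "IPC")
  expect_equal(out1$calibration$plate_offsets, c(A = 0))
  expect_equal(out1$cq$cq, single$cq)
})

test_that("IPC calibration errors on a plate without calibrator wells", {
  cq <- make_cq(c("IPC", "t"), "s1", plate = c("A", "B"), cq = c(20, 25))
  expect_error(calibrate_ipc(cq, "IPC"), "B", class = "mirnorm_calibration_error")
})

test_that("calibration is idempotent", {
  set.seed(7)
  sim <- simulate_study(preset_scenarios("screen87", seed = 7))
  once <- calibrate_ipc(sim$cq, "UniSp3-IPC")
  twice <- calibrate_ipc(once$cq, "UniSp3-IPC")
  expect_true(all(abs(twice$calibration$plate_offsets) < 1e-9))
  expect_equal(twice$cq$cq, once$cq$cq)
})

test_that("common-assay calibration recovers a uniform plate shift", {
  shared <- c("c1", "c2", "c3", "c4")
  base <- make_cq(rep(shared, 2), rep(c("s1", "s2"), each = 4), plate = "CAL",
                  cq = c(20, 22, 24, 26, 21, 23, 25, 27))
  shifted <- base
  shifted$plate_id <- "P1"
  shifted$cq <- shifted$cq + 0.5
  extra <- make_cq("t", c("s1", "s2"), plate = "P1", cq = c(30, 31))
  orig <- cq_table(rbind(as.data.frame(shifted), as.data.frame(extra)))
  out <- calibrate_common_assays(orig, base, shared)
  expect_equal(out$calibration$plate_offsets, c(P1 = 0.5))
  expect_equal(out$cq$cq[out$cq$assay_id == "t"], c(30, 31) - 0.5)
})

test_that("common-assay calibration gives zero offsets against itself", {
  base <- make_cq(rep(c("c1", "c2"), 2), rep(c("s1", "s2"), each = 2),
                  plate = "P1", cq = c(20, 22, 21, 23))
  out <- calibrate_common_assays(base, base, c("c1", "c2"))
  expect_equal(out$calibration$plate_offsets, c(P1 = 0))
})

test_that("plates with opposite offsets agree across plates after calibration", {
  set.seed(11)
  shared <- paste0("c", 1:4)
  truth <- matrix(rnorm(8, 24, 1), 4, 2, dimnames = list(shared, c("s1", "s2")))
  mk <- function(plate, offset, samples) {
    make_cq(rep(shared, length(samples)), rep(samples, each = 4), plate = plate,
            cq = as.vector(truth[, samples]) + offset + rnorm(4 * length(samples), 0, 0.05))
  }
  calib <- cq_table(rbind(as.data.frame(mk("CAL", 0, "s1")), as.data.frame(mk("CAL2", 0, "s2"))))
  calib$plate_id <- "CAL"
  calib <- cq_table(as.data.frame(calib))
  orig <- cq_table(rbind(as.data.frame(mk("P1", 0.3, "s1")),
                         as.data.frame(mk("P2", -0.3, "s2"))))
  out <- calibrate_common_assays(orig, calib, shared)
  expect_equal(unname(out$calibration$plate_offsets), c(0.3, -0.3), tolerance = 0.1)
  p1 <- out$cq$cq[out$cq$plate_id == "P1"]
  p2 <- out$cq$cq[out$cq$plate_id == "P2"]
  expect_equal(p1 - truth[, "s1"], p2 - truth[, "s2"], tolerance = 0.2, ignore_attr = TRUE)
})

test_that("common-assay calibration errors when a plate shares nothing", {
  orig <- make_cq("t", "s1", plate = "P1", cq = 25)
  calib <- make_cq("c1", "s9", plate = "CAL", cq = 20)
  expect_error(calibrate_common_assays(orig, calib, "c1"),
               class = "mirnorm_calibration_error")
})

test_that("replicate aggregation averages, propagates undetected, flags spread", {
  cq <- make_cq(rep("a", 6), rep(c("s1", "s2", "s3"), each = 2),
                replicate = rep(1:2, 3), cq = c(24.8, 25.2, NA, NA, 24.0, 26.0))
  agg <- suppressMessages(aggregate_replicates(cq))
  expect_equal(nrow(agg), 3)
  expect_equal(agg$cq[agg$sample_id == "s1"], 25.0)
  expect_true(is.na(agg$cq[agg$sample_id == "s2"]))
  expect_equal(agg$cq[agg$sample_id == "s3"], 25.0)
  flags <- attr(agg, "qc_flags")
  expect_equal(flags$sample_id, "s3")
  expect_message(aggregate_replicates(cq), "spread")
})

test_that("low-expression filter requires both the Cq and dropout conditions", {
  cq <- cq_table(data.frame(
    assay_id = rep(c("dropme", "highbutdetected", "oneLow"), times = c(4, 4, 3)),
    sample_id = c(paste0("s", 1:4), paste0("s", 1:4), paste0("s", 1:3)),
    plate_id = "P1", replicate = 1L,
    cq = c(33, 34, 33, NA, 33, 34, 33, 35, 31, 34, NA)
  ))
  rep <- filter_low_expression(cq)
  expect_equal(rep$dropped$assay_id, "dropme")
  expect_setequal(rep$kept, c("highbutdetected", "oneLow"))
  expect_setequal(c(rep$kept, rep$dropped$assay_id), unique(cq$assay_id))
})

test_that("Cq to RQ conversion anchors each assay at its minimum Cq", {
  cq <- make_cq(rep("a", 3), c("s1", "s2", "s3"), cq = c(20, 21, 22))
  rq <- cq_to_rq(cq)
  expect_equal(unname(rq$rq["a", ]), c(1, 0.5, 0.25))
  cq2 <- make_cq(rep("a", 2), c("s1", "s2"), cq = c(20, 22))
  rq2 <- cq_to_rq(cq2, efficiency = 1.9)
  expect_equal(unname(rq2$rq["a", ]), c(1, 1.9^-2))
  expect_equal(unname(cq_to_rq(make_cq("a", "s1", cq = 20))$rq["a", ]), 1)
})

test_that("missing-value policies error, impute at LOD, or drop samples", {
  cq <- make_cq(rep(c("a", "b"), each = 2), rep(c("s1", "s2"), 2),
                cq = c(20, NA, 25, 26))
  expect_error(cq_to_rq(cq, missing_policy = "error"), "a, s2",
               class = "mirnorm_conversion_error")
  imp <- suppressMessages(cq_to_rq(cq, missing_policy = "impute_lod", lod_cq = 35))
  expect_equal(unname(imp$rq["a", "s2"]), 2^(20 - 35))
  drp <- suppressMessages(cq_to_rq(cq, missing_policy = "drop_sample"))
  expect_equal(drp$sample_ids, "s1")
})

test_that("the delta-Cq identity holds: log2 RQ at E = 2 equals minCq - Cq", {
  set.seed(3)
  cqv <- matrix(runif(20, 20, 30), 4, 5)
  cq <- cq_table(data.frame(
    assay_id = rep(paste0("a", 1:4), 5), sample_id = rep(paste0("s", 1:5), each = 4),
    plate_id = "P1", replicate = 1L, cq = as.vector(cqv)
  ))
  lq <- log_rq(cq_to_rq(cq), base = 2)
  mins <- apply(cqv, 1, min)
  expect_equal(unname(lq), unname(mins - cqv), tolerance = 1e-9)
})

test_that("log_rq handles bases and rejects nonpositive input", {
  expect_equal(unname(log_rq(make_rq(matrix(c(1, 0.5, 0.25), 1)), base = 2)),
               matrix(c(0, -1, -2), 1))
  expect_equal(unname(log_rq(make_rq(matrix(rep(1, 4), 2)))), matrix(0, 2, 2))
  expect_equal(log_rq(matrix(0.001, 1, 1), base = 10)[1, 1], -3)
  expect_error(log_rq(matrix(c(1, -1), 1, 2)), class = "mirnorm_domain_error")
})
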