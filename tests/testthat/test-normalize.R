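test_that("cpm_log2 follows its formula", {
  m <- matrix(c(0L, 500L, 100L, 1999900L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- cpm_log2(m, pseudocount = 1)
  expect_equal(out["g1", "s1"], 0)                    # log2(0 + 1)
  expect_equal(out["g2", "s1"], log2(1e6 + 1))        # whole library on one gene
  expect_equal(out["g1", "s2"], log2(100 / 2e6 * 1e6 + 1))  # log2(51)
  expect_equal(out["g1", "s2"], 5.672425, tolerance = 1e-6)
})

test_that("cpm_log2 errors name the zero-total sample and reject bad input", {
  m <- matrix(c(1L, 2L, 0L, 0L), 2, 2,
              dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(cpm_log2(m), "empty")
  expect_error(cpm_log2(matrix(-1, 1, 1)), "non-negative")
  expect_error(cpm_log2(matrix(1, 1, 1), pseudocount = 0), "pseudocount")
})

test_that("cpm_log2 is monotone in counts within a sample", {
  set.seed(7)
  counts <- matrix(rpois(200, 50), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  out <- cpm_log2(counts)
  for (j in 1:10) {
    ord <- order(counts[, j])
    expect_true(all(diff(out[ord, j]) >= 0))
  }
})

make_norm_fixture <- function(seed = 1) {
  set.seed(seed)
  stages <- c("t1", "t2", "t3", "t4")
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     species = "a",
                     stage = rep(stages, each = 2),
                     replicate = rep(1:2, 4))
  m <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("g", 1:5), meta$sample_id))
  list(m = m, meta = meta, stages = stages)
}

test_that("stage_mean_profile averages replicates in stage order", {
  fx <- make_norm_fixture()
  prof <- stage_mean_profile(fx$m, fx$meta, fx$stages)
  expect_equal(colnames(prof), fx$stages)
  expect_equal(unclass(prof)[, "t2"],
               rowMeans(fx$m[, c("s3", "s4")]))

  # two replicates 2 and 4 -> 3
  m2 <- matrix(c(2, 4, 1, 1, 1, 1, 1, 1), 1, 8,
               dimnames = list("g", fx$meta$sample_id))
  meta2 <- fx$meta
  expect_equal(unclass(stage_mean_profile(m2, meta2, fx$stages))["g", "t1"], 3)

  # one sample per stage: profile equals that sample's column, stage-ordered
  meta1 <- data.frame(sample_id = paste0("s", 1:4), species = "a",
                      stage = rev(fx$stages), replicate = 1)
  m1 <- matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"), meta1$sample_id))
  p1 <- stage_mean_profile(m1, meta1, fx$stages)
  expect_equal(unclass(p1)["g1", ], c(t1 = 7, t2 = 5, t3 = 3, t4 = 1))
})

test_that("stage_mean_profile is invariant to sample column order", {
  fx <- make_norm_fixture(2)
  perm <- sample(ncol(fx$m))
  p_orig <- stage_mean_profile(fx$m, fx$meta, fx$stages)
  p_perm <- stage_mean_profile(fx$m[, perm], fx$meta, fx$stages)
  expect_equal(unclass(p_orig), unclass(p_perm))
})

test_that("stage_mean_profile errors on a declared stage with no samples", {
  fx <- make_norm_fixture()
  expect_error(stage_mean_profile(fx$m, fx$meta, c(fx$stages, "t9")), "t9")
  expect_error(stage_mean_profile(fx$m, fx$meta[-1, ], fx$stages), "s1")
})

test_that("zscale_profile centres/scales rows and flags constant genes", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), species = "a",
                     stage = c("t1", "t2", "t3"), replicate = 1)
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m) <- meta$sample_id
  prof <- stage_mean_profile(m, meta, c("t1", "t2", "t3"))
  sc <- zscale_profile(prof)
  expect_true(attr(sc, "scaled"))
  expect_equal(mean(unclass(sc)["g1", ]), 0)
  expect_equal(sd(unclass(sc)["g1", ]), 1)
  expect_true(all(diff(unclass(sc)["g1", ]) > 0))  # order preserved
  expect_equal(unname(unclass(sc)["g2", ]), c(0, 0, 0))
  expect_equal(unname(attr(sc, "constant")), c(FALSE, TRUE))
})

test_that("scaling leaves pairwise Pearson correlations unchanged", {
  set.seed(11)
  meta <- data.frame(sample_id = paste0("s", 1:6), species = "a",
                     stage = paste0("t", 1:6), replicate = 1)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), meta$sample_id))
  prof <- stage_mean_profile(m, meta, paste0("t", 1:6))
  sc <- zscale_profile(prof)
  for (i in 1:9) {
    expect_equal(pearson_r(unclass(prof)[i, ], unclass(prof)[10, ]),
                 pearson_r(unclass(sc)[i, ], unclass(sc)[10, ]),
                 tolerance = 1e-12)
  }
})

test_that("all_samples_profile keeps replicates, ordered by stage", {
  fx <- make_norm_fixture(3)
  shuffled <- fx$m[, sample(ncol(fx$m))]
  prof <- all_samples_profile(shuffled, fx$meta, fx$stages)
  expect_equal(ncol(prof), ncol(fx$m))
  expect_equal(attr(prof, "stages"), rep(fx$stages, each = 2))
})
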