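test_that("name-mode pairing handles identity and zebrafish paralog suffixes", {
  map <- pair_by_name(c("Sox9"), c("sox9a", "sox9b"))
  expect_equal(nrow(map), 2L)
  expect_setequal(map$gene_b, c("sox9a", "sox9b"))

  expect_equal(nrow(pair_by_name("Abc1", "abc1")), 1L)
  expect_equal(nrow(pair_by_name("X", "y")), 0L)

  # identity and suffix matches can coexist for one A gene
  map2 <- pair_by_name(c("Zfhx4", "Six1"), c("zfhx4", "six1a", "six1b", "irf6"))
  expect_equal(nrow(map2), 3L)
  expect_equal(sum(map2$gene_a == "Six1"), 2L)
})

test_that("table-mode pairing validates and drops rows referencing absent genes", {
  tab <- data.frame(gene_a = c("A1", "A2", "A9"),
                    gene_b = c("b1", "b9", "b2"))
  expect_warning(
    map <- pair_by_name(c("A1", "A2"), c("b1", "b2"), mode = "table", table = tab),
    "2"
  )
  expect_equal(nrow(map), 1L)
  expect_equal(attr(map, "n_dropped"), 2L)
  # duplicate rows collapse
  tab2 <- data.frame(gene_a = c("A1", "A1"), gene_b = c("b1", "b1"))
  expect_equal(nrow(pair_by_name("A1", "b1", mode = "table", table = tab2)), 1L)
  expect_error(pair_by_name(character(0), "b1"), "non-empty")
})

test_that("pearson_r matches textbook values and flags degenerate input", {
  v <- c(2, 5, 1, 9, 4)
  expect_equal(pearson_r(v, v), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # frozen value: centred cross-product 12 over sqrt(10 * 16)
  expect_equal(pearson_r(c(1, 2, 3, 4, 5), c(1, 2, 2, 4, 6)), 12 / sqrt(160),
               tolerance = 1e-15)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("screen records carry consistent flags and ordering", {
  sim <- simulate_experiment(small_cfg())
  sc <- sim_screen(sim)
  rec <- sc$records

  expect_equal(rec$pass_both, rec$pass_a & rec$pass_b)
  expect_true(all(rec$r_a[rec$pass_a] > sc$threshold))
  expect_true(all(rec$r_b[rec$pass_b] > sc$threshold))
  expect_true(all(abs(c(rec$r_a, rec$r_b)) <= 1, na.rm = TRUE))

  # reference pair reported and trivially passing with r = 1 on each side
  ref <- rec[rec$gene_a == "Sox9", ]
  expect_equal(nrow(ref), 1L)
  expect_equal(ref$r_a, 1)
  expect_equal(ref$r_b, 1)
  expect_true(ref$pass_both)

  # sorted by min(r) descending, ties lexicographic
  key <- pmin(ifelse(is.na(rec$r_a), -Inf, rec$r_a),
              ifelse(is.na(rec$r_b), -Inf, rec$r_b))
  expect_true(all(diff(key) <= 1e-15))

  # summary counts agree with the records
  expect_equal(sc$counts$n_pairs, nrow(rec))
  expect_equal(sc$counts$n_pass_both, sum(rec$pass_both))
})

test_that("screen verdicts are nested across thresholds", {
  sim <- simulate_experiment(small_cfg(seed = 9L))
  passes <- lapply(c(0.5, 0.7, 0.9), function(t) {
    rec <- sim_screen(sim, threshold = t)$records
    paste(rec$gene_a, rec$gene_b)[rec$pass_both]
  })
  expect_true(all(passes[[2]] %in% passes[[1]]))
  expect_true(all(passes[[3]] %in% passes[[2]]))
})

test_that("missing reference gene raises a named error", {
  sim <- simulate_experiment(small_cfg())
  pr <- sim_profiles(sim)
  expect_error(screen_orthologs(pr$a, pr$b, sim$map, "Nope1", "sox9b"),
               "Nope1.*species A")
  expect_error(screen_orthologs(pr$a, pr$b, sim$map, "Sox9", "nope1"),
               "nope1.*species B")
  expect_error(screen_orthologs(pr$a, pr$b, sim$map, "Sox9", "sox9b",
                                threshold = 1), "threshold")
})

test_that("constant genes get undefined correlations and fail the screen", {
  stages <- paste0("t", 1:5)
  meta <- data.frame(sample_id = paste0("s", 1:5), species = "a",
                     stage = stages, replicate = 1)
  build <- function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- meta$sample_id
    stage_mean_profile(m, meta, stages)
  }
  pa <- build(list(Ref = 1:5, Flat = rep(2, 5)))
  pb <- build(list(ref = 1:5, flat = rep(3, 5)))
  map <- data.frame(gene_a = c("Ref", "Flat"), gene_b = c("ref", "flat"))
  sc <- screen_orthologs(pa, pb, map, "Ref", "ref")
  flat <- sc$records[sc$records$gene_a == "Flat", ]
  expect_true(is.na(flat$r_a) && is.na(flat$r_b))
  expect_false(flat$pass_both)
  expect_equal(sc$counts$n_undefined, 1L)
})

test_that("passing gene lists deduplicate one-to-many hits", {
  sim <- simulate_experiment(small_cfg(profile_noise_sd = 0.1, seed = 21L))
  sc <- sim_screen(sim)
  rec <- sc$records
  pg <- passing_genes(sc, "a")
  expect_equal(anyDuplicated(pg), 0L)
  expect_setequal(pg, unique(rec$gene_a[rec$pass_both]))
  expect_lte(length(pg), sum(rec$pass_both))
  expect_equal(length(passing_genes(sim_screen(sim, threshold = 0.9999), "b")),
               1L)  # only the reference survives an extreme cutoff
})
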