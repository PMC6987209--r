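test_that("group-presence filter keeps a feature on one good group", {
  grp <- rep(c("CDAA", "CSAA"), each = 8)
  v <- matrix(rnorm(3 * 16, 10), 3,
              dimnames = list(c("six_in_one", "five_each", "full"), paste0("s", 1:16)))
  v["six_in_one", c(7:8, 9:16)] <- NA        # 6 observed in CDAA, 0 in CSAA
  v["five_each", c(6:8, 14:16)] <- NA        # 5 observed per group
  ann <- make_ann(colnames(v), grp)
  m <- omics_matrix(v, "log2")
  kept <- rownames(filter_by_group_presence(m, ann, min_present = 6))
  expect_true("six_in_one" %in% kept)
  expect_false("five_each" %in% kept)
  expect_true("full" %in% kept)
  # fully observed matrix: identity
  full <- make_log2_matrix(f = 5, n_per_group = 8)
  expect_identical(unclass(filter_by_group_presence(full$m, full$ann, 6)),
                   unclass(full$m))
  expect_error(filter_by_group_presence(m, ann, min_present = 9), "smallest group")
})

test_that("presence filter is monotone in min_present", {
  set.seed(42)
  v <- matrix(rnorm(50 * 16, 10), 50,
              dimnames = list(sprintf("f%02d", 1:50), paste0("s", 1:16)))
  v[sample(length(v), 250)] <- NA
  ann <- make_ann(colnames(v), rep(c("A", "B"), each = 8))
  m <- omics_matrix(v, "log2")
  prev <- rownames(m)
  for (mp in 1:8) {
    kept <- rownames(filter_by_group_presence(m, ann, mp))
    expect_true(all(kept %in% prev))          # subset, monotone
    prev <- kept
  }
})

test_that("total normalization matches the hand-computed two-step rule", {
  v <- matrix(c(1, 3, 2, 6), 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  out <- normalize_total_and_scale(omics_matrix(v, "linear"))
  expect_equal(unclass(out), matrix(c(50, 150, 50, 150), 2,
               dimnames = dimnames(v)), ignore_attr = "scale")
  # fixed point: equal totals and means already at 100
  w <- matrix(c(50, 150, 150, 50), 2, dimnames = dimnames(v))
  expect_equal(unclass(normalize_total_and_scale(omics_matrix(w, "linear"))), w,
               ignore_attr = "scale")
})

test_that("normalization postconditions: column means 100, scale-equivariance", {
  set.seed(7)
  v <- matrix(rexp(60, 1 / 50), 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  v[sample(60, 6)] <- NA
  m <- omics_matrix(v, "linear")
  out <- normalize_total_and_scale(m)
  expect_equal(unname(colMeans(unclass(out), na.rm = TRUE)), rep(100, 6))
  # within-column ratios preserved
  expect_equal(unclass(out)[2, 1] / unclass(out)[1, 1], v[2, 1] / v[1, 1])
  # multiplying a column by c > 0 leaves the output unchanged
  v2 <- v; v2[, 3] <- v2[, 3] * 7.5
  out2 <- normalize_total_and_scale(omics_matrix(v2, "linear"))
  expect_equal(unclass(out2), unclass(out))
  bad <- v; bad[, 2] <- 0
  expect_error(normalize_total_and_scale(omics_matrix(bad, "linear")), "zero total")
  expect_error(normalize_total_and_scale(make_log2_matrix(3, 2)$m), "linear")
})

test_that("downshifted imputation draws from the shifted-normal closed form", {
  n_miss <- 1e4
  obs <- rep(c(18, 22), 50)                    # mean 20, sd ~2
  v <- matrix(NA_real_, 100 + n_miss, 2,
              dimnames = list(sprintf("f%05d", seq_len(100 + n_miss)), c("s1", "s2")))
  v[, 2] <- rnorm(nrow(v), 10)
  v[seq_along(obs), 1] <- obs
  m <- omics_matrix(v, "log2")
  out <- impute_downshifted(m, downshift = 2.5, width = 0.2, seed = 3)
  expect_false(anyNA(out))
  mu <- mean(obs); s <- sd(obs)
  imp <- unclass(out)[-seq_along(obs), 1]
  se <- (0.2 * s) / sqrt(n_miss)
  expect_lt(abs(mean(imp) - (mu - 2.5 * s)), 3 * se)
  expect_lt(abs(sd(imp) - 0.2 * s) / (0.2 * s), 0.05)
  # observed entries unchanged
  expect_identical(unname(unclass(out)[seq_along(obs), 1]), obs)
})

test_that("imputation is seeded, identity without missing, degenerate at width 0", {
  fx <- make_log2_matrix(f = 20, n_per_group = 4)
  expect_identical(unclass(impute_downshifted(fx$m, seed = 1)), unclass(fx$m))
  v <- unclass(fx$m); v[c(3, 25, 60)] <- NA
  m <- omics_matrix(v, "log2")
  a <- impute_downshifted(m, 2.5, 0.2, seed = 9)
  b <- impute_downshifted(m, 2.5, 0.2, seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_identical(unclass(a)[!is.na(v)], v[!is.na(v)])  # only masked entries change
  d0 <- impute_downshifted(m, 0, 0, seed = 1)
  j <- which(is.na(v[, 1]))
  expect_equal(unclass(d0)[j, 1], rep(mean(v[, 1], na.rm = TRUE), length(j)))
  v2 <- v; v2[-1, 2] <- NA
  expect_error(impute_downshifted(omics_matrix(v2, "log2")), "< 2 observed")
})

test_that("batch centering zeroes within-batch feature means and is unbiased", {
  fx <- make_log2_matrix(f = 30, n_per_group = 8, shift = 1, batch = rep(1:2, 8))
  cen <- center_batches(fx$m, fx$ann)
  for (b in 1:2) {
    sel <- fx$ann$batch == b
    expect_equal(max(abs(rowMeans(unclass(cen)[, sel]))), 0, tolerance = 1e-12)
  }
  # idempotence
  expect_equal(unclass(center_batches(cen, fx$ann)), unclass(cen))
  # batches balanced across groups: batch offsets cancel exactly in the
  # group-difference estimate (equals the no-batch analysis)
  v <- unclass(fx$m)
  delta <- ifelse(fx$ann$batch == 1, 2, -2)
  vb <- sweep(v, 2, delta, "+")
  cb <- center_batches(omics_matrix(vb, "log2"), fx$ann)
  grpB <- fx$ann$group == "B"
  est_batch <- rowMeans(unclass(cb)[, grpB]) - rowMeans(unclass(cb)[, !grpB])
  c0 <- center_batches(omics_matrix(v, "log2"),
                       transform(fx$ann, batch = 1))
  est_clean <- rowMeans(unclass(c0)[, grpB]) - rowMeans(unclass(c0)[, !grpB])
  expect_equal(est_batch, est_clean, tolerance = 1e-12)
  # single batch == global per-feature centering
  glob <- center_batches(fx$m, transform(fx$ann, batch = 1))
  expect_equal(unclass(glob), v - rowMeans(v))
})

test_that("CPM columns sum to 1e6 and 'majority' is strict", {
  filler <- rep(1e6, 16)
  counts <- rbind(
    at4_of_8 = c(rep(1, 4), rep(0, 4), rep(1, 4), rep(0, 4)),
    at5_of_8 = c(rep(1, 5), rep(0, 3), rep(0, 8)))
  counts <- rbind(counts, filler = filler - colSums(counts))
  colnames(counts) <- paste0("s", 1:16)
  ann <- make_ann(colnames(counts), rep(c("A", "B"), each = 8))
  m <- omics_matrix(counts, "counts")
  res <- cpm_and_expressed_filter(m, ann, threshold = 1)
  expect_equal(unname(colSums(unclass(res$cpm))), rep(1e6, 16))
  expect_false(res$expressed[["at4_of_8"]])   # exactly half: not a majority
  expect_true(res$expressed[["at5_of_8"]])
  # scale-equivariance: doubling a column's counts leaves CPM unchanged
  c2 <- counts; c2[, 1] <- c2[, 1] * 2
  res2 <- cpm_and_expressed_filter(omics_matrix(c2, "counts"), ann)
  expect_equal(unclass(res2$cpm), unclass(res$cpm))
  bad <- counts; bad[, 3] <- 0
  expect_error(cpm_and_expressed_filter(omics_matrix(bad, "counts"), ann), "zero-count")
})
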