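test_that("feature ids compose and parse as <rt>_<mz>", {
  expect_equal(make_feature_id(2.41, 343.82), "2.41_343.82")
  expect_equal(make_feature_id(0.4123, 532.8735), "0.4123_532.8735")
  p <- parse_feature_id("2.41_343.82")
  expect_equal(p$rt, 2.41)
  expect_equal(p$mz, 343.82)
  expect_error(make_feature_id(NaN, 100), "finite")
  expect_error(make_feature_id(-1, 100), "positive")
  expect_error(parse_feature_id("nonsense"), "unparseable")
  expect_error(parse_feature_id("1.2_x"), "unparseable")
})

test_that("feature ids round-trip through the parser", {
  set.seed(11)
  rt <- round(runif(200, 0.35, 6.70), 4)
  mz <- round(runif(200, 100, 1000), 4)
  p <- parse_feature_id(make_feature_id(rt, mz))
  expect_equal(p$rt, rt)
  expect_equal(p$mz, mz)
})

test_that("feature_table validates its inputs", {
  m <- matrix(1:4, 2, dimnames = list(c("s1", "s2"), c("1_100", "2_200")))
  ft <- feature_table(m)
  expect_s3_class(ft, "feature_table")
  expect_equal(ft$features$rt, c(1, 2))
  expect_error(feature_table(m[, 0, drop = FALSE]), "no features")
  m2 <- m; m2[1, 1] <- -5
  expect_error(feature_table(m2), "negative intensity")
  m3 <- m; colnames(m3) <- c("1_100", "1_100")
  expect_error(feature_table(m3), "duplicate feature ids")
})

test_that("total-intensity normalization scales rows proportionally", {
  m <- matrix(c(2, 3, 5, 1, 0, 3), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("1_100", "2_200", "3_300")))
  ft <- normalize_total_intensity(feature_table(m))
  expect_equal(unname(ft$intensities["a", ]), c(2000, 3000, 5000))
  expect_equal(ft$intensities["b", "2_200"], 0)  # zeros preserved
  ## idempotence
  ft2 <- normalize_total_intensity(ft)
  expect_equal(ft2$intensities, ft$intensities)
  ## every row sums to the target on a random table
  set.seed(2)
  r <- matrix(runif(200), 10, 20)
  dimnames(r) <- list(paste0("s", 1:10), make_feature_id(1:20, 101:120))
  rn <- normalize_total_intensity(feature_table(r), target_sum = 10000)
  expect_equal(rowSums(rn$intensities), rep(10000, 10),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## all-zero sample is an error
  z <- m; z["b", ] <- 0
  expect_error(normalize_total_intensity(feature_table(z)), "all-zero sample")
})

test_that("QC RSD filter computes the sample RSD and drops unstable features", {
  m <- rbind(q1 = c(10, 7, 5, 0),
             q2 = c(12, 7, 20, 0),
             q3 = c(8,  7, 40, 0),
             b1 = c(1, 1, 1, 1))
  colnames(m) <- make_feature_id(1:4, 101:104)
  ft <- feature_table(m)
  out <- qc_rsd_filter(ft, c("q1", "q2", "q3"), threshold_pct = 30)
  ## sd([10,12,8]) = 2, mean 10 -> RSD 20% -> kept
  expect_equal(unname(out$rsd[1]), 20)
  ## constant QC values -> RSD 0 -> kept
  expect_equal(unname(out$rsd[2]), 0)
  ## feature 3 RSD > 30 -> removed; feature 4 QC mean 0 -> removed
  expect_setequal(out$removed$feature_id, colnames(m)[3:4])
  expect_equal(ncol(out$table$intensities), 2L)
  expect_error(qc_rsd_filter(ft, "q1"), "at least 2 QC")
})

test_that("replicate averaging matches an independent group-by mean", {
  st <- default_study()
  md <- st$metadata
  avg <- average_replicates(st$table, md)
  expect_equal(nrow(avg$table$intensities), 90L)
  ## oracle: aggregate() over plant x leaf for a few features
  bio <- md[md$role == "biological", ]
  mat <- st$table$intensities[bio$sample_id, 1:5]
  orc <- stats::aggregate(mat, by = list(key = paste(bio$plant_id,
                                                     bio$leaf_status,
                                                     sep = "_")), FUN = mean)
  got <- avg$table$intensities[orc$key, 1:5]
  expect_equal(unname(got), unname(as.matrix(orc[, -1])))
  ## metadata collapsed to one row per leaf, QC rows gone
  expect_equal(nrow(avg$metadata), 90L)
  expect_true(all(avg$metadata$role == "biological"))
})

test_that("a single injection passes through averaging unchanged", {
  st <- generate_study(small_config(n_injections = 1), seed = 3)
  avg <- average_replicates(st$table, st$metadata)
  md <- st$metadata[st$metadata$role == "biological", ]
  src <- md$sample_id[match(rownames(avg$table$intensities),
                            paste(md$plant_id, md$leaf_status, sep = "_"))]
  expect_equal(unname(avg$table$intensities),
               unname(st$table$intensities[src, ]))
})

test_that("paired differencing yields one M_U - M_D row per plant", {
  st <- default_study()
  prep <- prep_study(st)
  pd <- paired_difference(prep$table, prep$metadata)
  ## study design: 90 leaves -> 45 plants
  expect_equal(length(pd$plant_ids), 45L)
  expect_equal(nrow(pd$diff_intensities), 45L)
  ## hand check one plant
  p1 <- pd$plant_ids[1]
  u <- prep$table$intensities[paste0(p1, "_undamaged"), ]
  d <- prep$table$intensities[paste0(p1, "_damaged"), ]
  expect_equal(pd$diff_intensities[p1, ], u - d)
  ## damage of the damaged leaf is carried
  dmd <- prep$metadata[prep$metadata$plant_id == p1 &
                       prep$metadata$leaf_status == "damaged", ]
  expect_equal(pd$damage_pct[1], dmd$damage_pct)
  ## a missing pair member is an error
  drop1 <- prep$table
  keep <- rownames(drop1$intensities) != paste0(p1, "_damaged")
  drop1$intensities <- drop1$intensities[keep, ]
  drop1$sample_ids <- drop1$sample_ids[keep]
  expect_error(paired_difference(drop1, prep$metadata), "missing a pair member")
})

test_that("identical leaves difference to an all-zero row", {
  m <- rbind(p1_undamaged = c(5, 3, 1), p1_damaged = c(5, 3, 1),
             p2_undamaged = c(5, 3, 2), p2_damaged = c(3, 3, 1))
  colnames(m) <- make_feature_id(1:3, 101:103)
  md <- data.frame(sample_id = rownames(m), role = "biological",
                   plant_id = rep(c("p1", "p2"), each = 2),
                   leaf_status = rep(c("undamaged", "damaged"), 2),
                   leaf_area = c(10, 10, 12, 9), damage_pct = c(0, 4, 0, 7))
  pd <- paired_difference(feature_table(m), md)
  expect_equal(unname(pd$diff_intensities["p1", ]), c(0, 0, 0))
  expect_equal(unname(pd$diff_intensities["p2", ]), c(2, 0, 1))
  expect_equal(pd$diff_leaf_area, c(0, 3))
})

test_that("tables and metadata round-trip through delimited text", {
  st <- generate_study(small_config(), seed = 5)
  d <- withr::local_tempdir()
  tp <- file.path(d, "table.csv"); mp <- file.path(d, "meta.csv")
  write_feature_table(st$table, tp, metadata = st$metadata, metadata_path = mp)
  rd <- read_feature_table(tp, mp)
  expect_equal(rd$table$intensities, st$table$intensities)
  expect_equal(rd$table$features$rt, st$table$features$rt)
  expect_equal(rd$metadata$sample_id, st$metadata$sample_id)
  ## a table sample without metadata is an error
  md2 <- st$metadata[-1, ]
  write.table(md2, mp, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(tp, mp), "without metadata")
})
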