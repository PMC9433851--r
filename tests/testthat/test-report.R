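published_hc <- function() read_published_hit_table(
  system.file("extdata", "published_hc_hit_counts.tsv", package = "ccamodes"))
published_dn <- function() read_published_hit_table(
  system.file("extdata", "published_dn_hit_counts.tsv", package = "ccamodes"))
reconstruction <- function() {
  df <- read.delim(system.file("extdata",
                               "reconstructed_hit_locations_synthetic.tsv",
                               package = "ccamodes"))
  anatomy <- rbind(dn_atlas(), hc_atlas())
  list(flags = hit_flag_matrix(df, anatomy, k = 7), anatomy = anatomy)
}

test_that("hit tables keep double-entry margins over the encoded source tables", {
  hc <- published_hc()
  expect_equal(unname(hc$category_totals["CA2/3"]), 5)
  expect_equal(unname(hc$mode_totals["1"]), 15)
  # the encoded source table is internally inconsistent for PrS: the cells
  # sum to 5 while its printed total row says 4; both readings are exposed
  expect_equal(unname(hc$category_totals["PrS"]), 5)
  expect_equal(unname(hc$printed_totals["PrS"]), 4)
  expect_equal(hc$grand_total, 33)
  expect_equal(sum(hc$printed_totals), 32)
  dn <- published_dn()
  # the DN table is self-consistent: computed margins equal the printed row
  expect_equal(unname(dn$category_totals), unname(dn$printed_totals))
  expect_equal(dn$grand_total, 50)
  expect_equal(unname(dn$mode_totals["1"]), 26)
})

test_that("derived shares come out as raw percentages, undefined when empty", {
  dn <- published_dn()
  sh <- hit_shares(dn)
  expect_equal(unname(sh$mode_share_pct["1"]), 52)
  expect_equal(unname(sh$category_share_pct["Temporal"]), 34)
  expect_equal(unname(sh$category_share_pct["Posterior cingulate"]), 10)
  empty <- hit_table(matrix(0L, 3, 2, dimnames = list(1:3, c("A", "B"))))
  expect_true(all(is.na(hit_shares(empty)$mode_share_pct)))
  expect_true(all(is.na(hit_shares(empty)$category_share_pct)))
})

test_that("tallies from random hit arrays match a second-pass bookkeeping oracle", {
  rec <- reconstruction()
  set.seed(5)
  flags <- matrix(runif(4 * nrow(rec$anatomy)) < 0.15, 4)
  tabs <- tally_hits(flags, anatomy = rec$anatomy)
  for (side in c("hc", "dn")) {
    tb <- tabs[[side]]
    expect_equal(unname(tb$mode_totals), unname(rowSums(tb$counts)))
    expect_equal(unname(tb$category_totals), unname(colSums(tb$counts)))
    expect_equal(tb$grand_total, sum(tb$counts))
  }
  take <- rec$anatomy$structure == "HC"
  manual <- sum(flags[, take])
  expect_equal(tabs$hc$grand_total, manual)
  # permutation invariance in subregion order
  perm <- sample(nrow(rec$anatomy))
  tabs2 <- tally_hits(flags[, perm, drop = FALSE],
                      anatomy = rec$anatomy[perm, ])
  expect_equal(tabs2$hc$counts, tabs$hc$counts)
  expect_equal(tabs2$dn$counts, tabs$dn$counts)
  # additivity over disjoint mode subsets
  t12 <- tally_hits(flags[1:2, , drop = FALSE], anatomy = rec$anatomy)
  t34 <- tally_hits(flags[3:4, , drop = FALSE], anatomy = rec$anatomy)
  expect_equal(unname(t12$dn$category_totals + t34$dn$category_totals),
               unname(tabs$dn$category_totals))
})

test_that("the reconstructed hit locations reproduce the encoded table margins", {
  rec <- reconstruction()
  tabs <- tally_hits(rec$flags, anatomy = rec$anatomy)
  hc <- published_hc(); dn <- published_dn()
  expect_equal(unname(tabs$hc$counts), unname(hc$counts), ignore_attr = TRUE)
  expect_equal(unname(tabs$dn$counts[1:6, ]), unname(dn$counts),
               ignore_attr = TRUE)
})

test_that("laterality and head/body summaries match manual counts", {
  rec <- reconstruction()
  # degenerate: hits only on the left
  left_only <- matrix(FALSE, 1, nrow(rec$anatomy))
  left_only[1, which(rec$anatomy$hemisphere == "L")[1:5]] <- TRUE
  expect_equal(laterality_summary(left_only, rec$anatomy)$left_share_pct, 100)
  # balanced: exactly half left
  bal <- matrix(FALSE, 1, nrow(rec$anatomy))
  bal[1, which(rec$anatomy$hemisphere == "L")[1:3]] <- TRUE
  bal[1, which(rec$anatomy$hemisphere == "R")[1:3]] <- TRUE
  expect_equal(laterality_summary(bal, rec$anatomy)$left_share_pct, 50)
  # 19 left of 25 -> 76%
  x19 <- matrix(FALSE, 1, nrow(rec$anatomy))
  x19[1, which(rec$anatomy$hemisphere == "L")[1:19]] <- TRUE
  x19[1, which(rec$anatomy$hemisphere == "R")[1:6]] <- TRUE
  expect_equal(laterality_summary(x19, rec$anatomy)$left_share_pct, 76)
  # reconstruction: DN hits in the dominant left-lateralized modes
  lat <- laterality_summary(rec$flags, rec$anatomy, modes = c(1, 3, 6),
                            structure = "DN")
  expect_equal(lat$left, 34); expect_equal(lat$total, 45)
  expect_equal(lat$left_share_pct, 100 * 34 / 45, tolerance = 1e-12)
  hb <- head_body_summary(rec$flags, rec$anatomy)
  expect_equal(hb$head, 22); expect_equal(hb$body, 11)
  expect_equal(hb$head_share_pct, 100 * 22 / 33, tolerance = 1e-12)
  # no hits: share undefined
  none <- matrix(FALSE, 2, nrow(rec$anatomy))
  expect_true(is.na(laterality_summary(none, rec$anatomy)$left_share_pct))
  expect_true(is.na(head_body_summary(none, rec$anatomy)$head_share_pct))
})

test_that("unmapped subregions are rejected by name", {
  rec <- reconstruction()
  anat <- rec$anatomy
  anat$category[3] <- NA
  expect_error(tally_hits(rec$flags, anatomy = anat), anat$subregion[3],
               fixed = TRUE)
  df_bad <- data.frame(mode = 1, subregion = "L_Nowhere_9")
  expect_error(hit_flag_matrix(df_bad, rec$anatomy), "L_Nowhere_9")
})

test_that("hit tables render and serialize", {
  dn <- published_dn()
  md <- format_hit_table(dn, caption = "DN hits")
  expect_match(md, "\\| Mode \\|")
  expect_match(md, "Total")
  dir <- withr::local_tempdir()
  write_hit_tables(list(dn = dn), dir)
  back <- read.delim(file.path(dir, "dn_hits.tsv"), check.names = FALSE)
  expect_equal(back$Temporal[back$mode == "Total"], 17)
  expect_error(hit_table(matrix(-1, 1, 1, dimnames = list(1, "A"))),
               "nonnegative")
})
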