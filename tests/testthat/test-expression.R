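frac_table <- function(vals, taxon, ann = NULL) {
  tab <- abundance_table(vals, "transcript_per_ml", ann)
  out <- within_taxon_normalize(tab, taxon)
  out
}

test_that("within-taxon normalization yields fractions summing to one", {
  vals <- matrix(c(20, 60, 10, 30, 5, 15), 3, byrow = TRUE,
                 dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  tab <- abundance_table(vals, "transcript_per_ml")
  out <- within_taxon_normalize(tab, c(t1 = "T", t2 = "T", t3 = "U"))
  expect_equal(out$values["t1", "s1"], 20 / 30)
  expect_equal(out$values["t3", "s2"], 1)  # single-transcript taxon
  # per-taxon column sums are 1
  expect_equal(unname(colSums(out$values[c("t1", "t2"), ])), c(1, 1),
               tolerance = 1e-9)
  # zero taxon total in a sample: excluded (NA) with a log line
  vals2 <- vals; vals2[c("t1", "t2"), "s2"] <- 0
  tab2 <- abundance_table(vals2, "transcript_per_ml")
  expect_message(
    out2 <- within_taxon_normalize(tab2, c(t1 = "T", t2 = "T", t3 = "U")),
    "excluded")
  expect_true(all(is.na(out2$values[c("t1", "t2"), "s2"])))

  # conservation property over random tables
  set.seed(7)
  for (i in 1:25) {
    rt <- random_table(9, 4, "transcript_per_ml")
    tx <- setNames(rep(c("A", "B", "C"), each = 3), features(rt))
    fr <- within_taxon_normalize(rt, tx)
    for (g in c("A", "B", "C"))
      expect_equal(unname(colSums(fr$values[names(tx)[tx == g], ])),
                   rep(1, 4), tolerance = 1e-9)
  }
})

test_that("differential expression recovers planted shifts and respects the null", {
  dm <- diel_meta(18)
  set.seed(17)
  n_null <- 60
  lfc <- c(rep(0, n_null), 3, 3, -3)
  mu <- exp(runif(length(lfc), log(200), log(2000)))
  vals <- t(vapply(seq_along(lfc), function(i) {
    c(rnbinom(18, mu = mu[i], size = 10),
      rnbinom(18, mu = mu[i] * 2^lfc[i], size = 10))
  }, numeric(36)))
  dimnames(vals) <- list(sprintf("tx%03d", seq_along(lfc)), dm$sample_id)
  tab <- structure(list(values = vals / 1e6, kind = "transcript_per_ml",
                        annotations = NULL,
                        taxon = setNames(rep("T", nrow(vals)),
                                         rownames(vals))),
                   class = "abundance_table")
  rec <- differential_expression(tab, dm)
  expect_s3_class(rec, "expression_records")
  de_ids <- sprintf("tx%03d", n_null + 1:3)
  got <- rec[match(de_ids, rec$transcript_id), ]
  expect_true(all(got$side == c("anticyclone", "anticyclone", "cyclone")))
  expect_equal(got$log2_fold_change, c(3, 3, -3), tolerance = 0.5)
  expect_lte(sum(rec$side != "none" & !rec$transcript_id %in% de_ids), 2)
})

test_that("identical groups give no sides and label swap negates log2FC", {
  dm <- diel_meta(4)
  set.seed(27)
  vals <- matrix(rnbinom(6 * 8, mu = 500, size = 10), 6, 8,
                 dimnames = list(sprintf("t%d", 1:6), dm$sample_id))
  tab <- structure(list(values = vals / 1e6, kind = "transcript_per_ml",
                        annotations = NULL,
                        taxon = setNames(rep("T", 6), rownames(vals))),
                   class = "abundance_table")
  a <- differential_expression(tab, dm)
  b <- differential_expression(tab, swap_eddies(dm))
  b <- b[match(a$transcript_id, b$transcript_id), ]
  expect_equal(b$log2_fold_change, -a$log2_fold_change, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)

  same <- tab
  same$values[, dm$sample_id[dm$eddy == "anticyclone"]] <-
    same$values[, dm$sample_id[dm$eddy == "cyclone"]]
  expect_true(all(differential_expression(same, dm)$side == "none"))
})

test_that("category summaries apply the both-sides rule and pathway retention", {
  rec <- data.frame(
    transcript_id = sprintf("t%d", 1:8),
    taxon_id = "T",
    eggnog_id = c("E1", "E1", "E2", "E3", "E4", "E5", "E6", "E7"),
    ko_id = "", cog_category = c("J", "J", "J", "J", "J", "P", "P", "JP"),
    log2_fold_change = c(3, -3, -4, -3.5, -2.8, 2.7, 2.9, -5),
    p_value = 1e-6, q_value = 1e-5,
    side = c("anticyclone", "cyclone", "cyclone", "cyclone", "cyclone",
             "anticyclone", "anticyclone", "cyclone"))
  class(rec) <- c("expression_records", "data.frame")
  cog <- summarize_by_category(rec, "cog")
  # t1/t2 share eggNOG E1 with sides in both eddies: both dropped
  expect_false(any(grepl("^3;|;3$|^3$", cog$member_log2fc)))
  j <- cog[cog$category_id == "J", ]
  expect_equal(j$n_cyclone, 4)  # t3,t4,t5 and the J of t8's JP
  expect_equal(j$n_anticyclone, 0)
  p <- cog[cog$category_id == "P", ]
  expect_equal(p$n_cyclone, 1)  # P of t8
  expect_equal(p$n_anticyclone, 2)
  # conservation for single-category records (drop the JP multi-record)
  single <- rec[rec$cog_category %in% c("J", "P"), ]
  cs <- summarize_by_category(single, "cog")
  expect_equal(sum(cs$n_cyclone + cs$n_anticyclone), 5)

  # pathway retention: exactly 2 retained transcripts dropped, 3 kept
  pw <- c(t3 = "map1", t4 = "map1", t5 = "map1;map2", t6 = "map2",
          t7 = "map3", t8 = "map3")
  ps <- summarize_by_category(rec, "pathway", pathways = pw)
  expect_true("map1" %in% ps$category_id)   # 3 members
  expect_false("map2" %in% ps$category_id)  # 2 members
  expect_false("map3" %in% ps$category_id)  # 2 members
  # merge map pools map2 and map3 into one retained category
  merged <- summarize_by_category(rec, "pathway", pathways = pw,
                                  merge_map = c(map2 = "mapX", map3 = "mapX"))
  expect_true("mapX" %in% merged$category_id)
  expect_error(summarize_by_category(rec, "pathway"), "pathways")
})

test_that("the both-sides exclusion is idempotent", {
  rec <- data.frame(
    transcript_id = sprintf("t%d", 1:4), taxon_id = "T",
    eggnog_id = c("E1", "E1", "E2", "E3"), ko_id = "",
    cog_category = c("J", "J", "K", "K"),
    log2_fold_change = c(3, -3, 4, -4), p_value = 1e-6, q_value = 1e-5,
    side = c("anticyclone", "cyclone", "anticyclone", "cyclone"))
  class(rec) <- c("expression_records", "data.frame")
  once <- summarize_by_category(rec, "cog")
  # survivors (E2, E3) are one-sided; re-summarizing the surviving records
  # changes nothing
  keep <- rec[rec$eggnog_id != "E1", ]
  twice <- summarize_by_category(keep, "cog")
  expect_equal(once, twice)
})
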