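test_that("metadata scaling follows the divide-by-max contract", {
  v <- c(3880, 1560, 182)
  expect_equal(scale_metadata(v), v / 3880)
  expect_equal(scale_metadata(v)[1], 1)
  expect_equal(scale_metadata(c(NA, NA, NA)), c(0, 0, 0))
  expect_equal(scale_metadata(c(5, NA, 10)), c(0.5, 0, 1))
  expect_equal(scale_metadata(7), 1)          # single value
  expect_equal(scale_metadata(c(4, 4, 4)), c(1, 1, 1))  # constant
  expect_equal(scale_metadata(c(0, 0)), c(0, 0))
  expect_error(scale_metadata(c(-1, 3)), "negative")
  # min-max option
  expect_equal(scale_metadata(c(2, 6, 10), "minmax"), c(0, 0.5, 1))
  expect_equal(scale_metadata(c(5, 5), "minmax"), c(1, 1))
})

test_that("the additive score reaches its stated maxima", {
  seven <- combined_score(c(fragmenter = 1, spectral = 1, a = 1, b = 1,
                            c = 1, d = 1, e = 1))
  expect_identical(seven, 7)
  expect_identical(combined_score(c(fragmenter = 1, spectral = 1)), 2)
  expect_equal(
    combined_score(c(fragmenter = 0.8, spectral = 0.5774,
                     m1 = 1, m2 = 0, m3 = 0.5)),
    0.8 + 0.5774 + 1 + 0 + 0.5)
  expect_error(combined_score(c(fragmenter = 1), weights = c(zz = 2)),
               "inactive")
  expect_error(combined_score(c(a = 1), weights = c(a = -1)),
               "non-negative")
})

test_that("score_candidates scales, weights and bounds correctly", {
  cand <- toy_candidates()
  sc <- score_candidates(cand, metadata = c("data_sources",
                                            "pubmed_count", "norman",
                                            "stoffident",
                                            "toxcast_pct_active"))
  expect_equal(sc$config$max_score, 7)
  t <- tidy(sc)
  expect_true(all(t$combined >= 0 & t$combined <= 7))
  # the candidate leading every category scores the sum of its terms
  top <- t[t$id == "TRZ1", ]
  expect_equal(top$combined,
               1 + 1 + 1 + 540 / 900 + 1 + 1 + 32 / 45)
  # missing metadata scores zero
  trz3 <- t[t$id == "TRZ3", ]
  expect_equal(trz3$toxcast_pct_active, 0)
  # no metadata: bound is 2
  sc2 <- score_candidates(cand)
  expect_equal(sc2$config$max_score, 2)
  expect_lte(max(tidy(sc2)$combined), 2)
  # zero weight removes a category's influence
  sc3 <- score_candidates(cand, metadata = "pubmed_count",
                          weights = c(pubmed_count = 0))
  expect_equal(tidy(sc3)$combined, tidy(sc2)$combined)
})

test_that("score bounds hold for random configurations", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    cand <- tibble::tibble(
      id = sprintf("C%02d", seq_len(n)),
      inchikey = replicate(n, paste0(
        paste(sample(LETTERS, 14, TRUE), collapse = ""),
        "-UHFFFAOYSA-N")),
      fragmenter = runif(n), spectral = runif(n),
      m1 = ifelse(runif(n) < 0.3, NA, rpois(n, 50)),
      m2 = runif(n) * 100
    )
    w <- c(fragmenter = runif(1, 0, 2), m1 = runif(1, 0, 2))
    sc <- score_candidates(cand, metadata = c("m1", "m2"), weights = w)
    t <- tidy(sc)
    expect_true(all(t$combined >= 0 - 1e-12))
    expect_true(all(t$combined <= sc$config$max_score + 1e-12))
  }
})

test_that("raising a non-maximal raw value never lowers the score", {
  cand <- toy_candidates()
  base <- tidy(score_candidates(cand, metadata = "data_sources"))
  bumped <- cand
  bumped$data_sources[3] <- 900  # still below the 3880 maximum
  after <- tidy(score_candidates(bumped, metadata = "data_sources"))
  expect_gte(after$combined[after$id == "TRZ3"],
             base$combined[base$id == "TRZ3"])
})

test_that("grouping partitions by first block and keeps all identifiers", {
  # 21 candidates, 11 sharing one skeleton (the simazine scenario scale)
  set.seed(8)
  shared <- "AAAAAAAAAAAAAA"
  keys <- c(
    paste0(shared, "-", vapply(1:11, function(i)
      paste(sample(LETTERS, 8, TRUE), collapse = ""), character(1)),
      "SA-N"),
    paste0(vapply(1:10, function(i)
      paste(sample(LETTERS[1:20], 14, TRUE), collapse = ""),
      character(1)), "-CCCCCCCCSA-N")
  )
  cand <- tibble::tibble(
    id = sprintf("S%02d", 1:21),
    inchikey = keys,
    fragmenter = runif(21), spectral = runif(21)
  )
  sc <- score_candidates(cand)
  groups <- rank_candidates(sc)
  expect_equal(sum(groups$n), 21)
  big <- groups[groups$group_key == shared, ]
  expect_equal(big$n, 11)
  expect_length(big$member_ids[[1]], 11)
  # representative carries the group maximum
  members <- tidy(sc)
  expect_equal(big$combined,
               max(members$combined[members$id %in% big$member_ids[[1]]]))
  # tie on score: lexicographically smallest id wins
  tie <- tibble::tibble(
    id = c("B2", "B1"),
    inchikey = rep("DDDDDDDDDDDDDD-EEEEEEEESA-N", 2),
    fragmenter = c(0.5, 0.5), spectral = c(0.5, 0.5)
  )
  g <- rank_candidates(score_candidates(tie))
  expect_identical(g$representative, "B1")
  # missing InChIKey errors with the candidate named
  bad <- tibble::tibble(id = "X", inchikey = NA_character_,
                        fragmenter = 1, spectral = 1)
  expect_error(score_candidates(bad), "X")
})

test_that("ranking is descending and respects re-weighting", {
  cand <- toy_candidates()
  sc <- score_candidates(cand, metadata = c("data_sources", "norman",
                                            "toxcast_pct_active"))
  ranked <- tidy(sc)
  expect_true(all(diff(ranked$combined) <= 0))
  expect_identical(ranked$id[1], "TRZ1")  # full metadata wins
  # single candidate ranks as itself
  one <- rank_candidates(score_candidates(cand[1, ]), grouped = FALSE)
  expect_identical(one$id, "TRZ1")
  # zeroing the dominant category can reorder
  sc0 <- score_candidates(cand, metadata = c("data_sources", "norman",
                                             "toxcast_pct_active"),
                          weights = c(data_sources = 0, norman = 0,
                                      toxcast_pct_active = 0))
  expect_identical(tidy(sc0)$combined,
                   tidy(score_candidates(cand))$combined)
})

test_that("tidy/glance/autoplot expose the scored set", {
  sc <- score_candidates(toy_candidates(), metadata = "data_sources")
  g <- glance(sc)
  expect_equal(g$n_candidates, 3)
  expect_identical(g$top_id, tidy(sc)$id[1])
  expect_equal(g$max_score, 3)
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
})
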