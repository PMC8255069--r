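db_from_sets <- function(sets) {
  items <- sort(unique(unlist(sets)))
  m <- t(vapply(sets, function(s) items %in% s, logical(length(items))))
  colnames(m) <- items
  rownames(m) <- sprintf("t%d", seq_along(sets))
  m
}

test_that("support counts exact containment fractions", {
  db <- db_from_sets(list(c("a", "b"), "a", "b", c("a", "b")))
  expect_equal(itemset_support(character(0), db), 1)
  expect_equal(itemset_support("zzz", db), 0)
  expect_equal(itemset_support(c("a", "b"), db), 0.5)
  expect_error(itemset_support("a", db[0, , drop = FALSE]), "empty")
})

test_that("apriori finds exactly the frequent itemsets", {
  db <- db_from_sets(list(c("a", "b"), c("a", "b"), c("a", "b")))
  fi <- apriori(db, min_support = 1)
  expect_equal(itemsets_as_vector(fi),
               c(a = 1, b = 1, "a\x1fb" = 1))

  db2 <- db_from_sets(list(c("a", "b", "c"), c("a", "b"), c("a", "c"),
                           c("b", "c")))
  fi2 <- apriori(db2, min_support = 0.5)
  expect_equal(itemsets_as_vector(fi2),
               c(a = 0.75, b = 0.75, c = 0.75,
                 "a\x1fb" = 0.5, "a\x1fc" = 0.5, "b\x1fc" = 0.5))
  expect_error(apriori(db2, 0), "min_support")
})

test_that("apriori equals exhaustive enumeration on random databases", {
  set.seed(77)
  for (i in 1:25) {
    db <- rand_db(sample(2:8, 1), sample(3:8, 1), p = runif(1, 0.3, 0.8))
    truth <- bf_all_supports(db)
    for (ms in c(0.25, 0.5, 0.75)) {
      mined <- itemsets_as_vector(apriori(db, ms, max_len = ncol(db)))
      expected <- truth[truth >= ms - 1e-9]
      expect_equal(mined[order(names(mined))],
                   expected[order(names(expected))])
    }
  }
})

test_that("anti-monotonicity holds across mined itemsets", {
  set.seed(3)
  db <- rand_db(12, 6, 0.6)
  fi <- apriori(db, 0.2, max_len = 6)
  sup <- itemsets_as_vector(fi)
  for (i in which(fi$size >= 2)) {
    z <- fi$items[[i]]
    for (drop in seq_along(z)) {
      expect_gte(sup[paste(z[-drop], collapse = "\x1f")], fi$support[i])
    }
  }
})

test_that("rule measures follow the worked examples", {
  db <- db_from_sets(list(c("a", "b"), c("a", "b"), c("a", "b", "c"), "c"))
  rules <- generate_rules(apriori(db, 0.5, 3), min_confidence = 0.9)
  ab <- rules[rules$rule_text == "{a} => {b}", ]
  expect_equal(ab$confidence, 1)
  expect_equal(ab$support, 0.75)
  expect_equal(ab$lift, 4 / 3, tolerance = 1e-12)

  db2 <- db_from_sets(list(c("a", "b"), c("a", "b"), "c", "d"))
  rules2 <- generate_rules(apriori(db2, 0.5, 2), min_confidence = 1)
  ab2 <- rules2[rules2$rule_text == "{a} => {b}", ]
  expect_equal(ab2$confidence, 1)
  expect_equal(ab2$lift, 2)
})

test_that("rule filtering keeps the inclusive lift bound", {
  rules <- data.frame(rule_id = 1:3, support = 0.5, confidence = 1,
                      lift = c(1.333, 2, 5))
  expect_equal(filter_rules(rules)$rule_id, c(2, 3))
  expect_equal(nrow(filter_rules(rules, min_lift = 0)), 3)
})

test_that("measure identities hold on every mined rule", {
  set.seed(19)
  for (i in 1:10) {
    db <- rand_db(10, 5, 0.5)
    if (sum(colSums(db) > 0) < 2) next
    rules <- generate_rules(apriori(db, 0.2, 5), min_confidence = 0)
    for (j in seq_len(nrow(rules))) {
      x <- rules$antecedent[[j]]
      y <- rules$consequent[[j]]
      sx <- itemset_support(x, db)
      sy <- itemset_support(y, db)
      sxy <- itemset_support(c(x, y), db)
      expect_equal(rules$support[j], sxy, tolerance = 1e-12)
      expect_equal(rules$confidence[j], sxy / sx, tolerance = 1e-12)
      expect_equal(rules$lift[j], rules$confidence[j] / sy,
                   tolerance = 1e-12)
      # lift is symmetric in antecedent and consequent
      expect_equal(rules$lift[j], (sxy / sy) / sx, tolerance = 1e-12)
    }
  }
})

test_that("independently generated items have mean lift near one", {
  db <- simulate_transactions(2000, 6, list(), itemset_prob = 0,
                              noise_prob = 0.5, seed = 23)
  rules <- generate_rules(apriori(db, 0.2, 3), min_confidence = 0)
  expect_gt(nrow(rules), 10)
  expect_lt(abs(mean(rules$lift) - 1), 0.05)
})

test_that("planted co-occurring itemsets surface as high-lift rules", {
  hits <- 0
  for (seed in 1:20) {
    db <- simulate_transactions(40, 12,
                                list(c("item_1", "item_2", "item_3")),
                                itemset_prob = 0.35, noise_prob = 0.02,
                                seed = seed)
    rules <- filter_rules(generate_rules(apriori(db, 0.25, 3), 0.9), 2)
    planted <- vapply(seq_len(nrow(rules)), function(j) {
      all(c(rules$antecedent[[j]], rules$consequent[[j]]) %in%
            c("item_1", "item_2", "item_3"))
    }, logical(1))
    if (any(planted)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})
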