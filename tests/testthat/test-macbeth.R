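test_that("transitive chains are consistent and cycles are not", {
  chain <- jm_of(c("a", "b", "c"), a = c("a", "b", "a"), b = c("b", "c", "c"),
                 category = c("moderate", "moderate", "strong"))
  expect_true(check_consistency(chain)$consistent)

  cycle <- jm_of(c("a", "b", "c"), a = c("a", "b", "c"), b = c("b", "c", "a"),
                 category = rep("moderate", 3))
  rep <- check_consistency(cycle)
  expect_false(rep$consistent)
  expect_gt(nrow(rep$violated_constraints), 0)
})

test_that("chained equalities forcing a weak difference above an extreme one are inconsistent", {
  # (a,b) very weak but a~c, b~d and (c,d) extreme: no scale can satisfy both
  jm <- jm_of(c("a", "b", "c", "d"),
              a = c("a", "a", "b", "c"), b = c("b", "c", "d", "d"),
              category = c("very weak", "null", "null", "extreme"))
  rep <- check_consistency(jm)
  expect_false(rep$consistent)
  expect_false(brute_force_feasible(jm))
})

test_that("LP feasibility agrees with the exhaustive oracle on small matrices", {
  cats <- c("null", "very weak", "weak", "moderate", "strong")
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:4, 1)
    ent <- letters[seq_len(n)]
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < 0.8
    if (!any(keep)) keep[1] <- TRUE
    # random orientation and random categories: a mix of consistent and
    # inconsistent instances
    aa <- ent[pairs[keep, 1]]; bb <- ent[pairs[keep, 2]]
    flip <- stats::runif(length(aa)) < 0.3
    tmp <- aa[flip]; aa[flip] <- bb[flip]; bb[flip] <- tmp
    jm <- try(jm_of(ent, aa, bb, sample(cats, length(aa), replace = TRUE)),
              silent = TRUE)
    if (inherits(jm, "try-error")) next
    expect_identical(check_consistency(jm)$consistent, brute_force_feasible(jm),
                     info = paste("seed", seed))
  }
})

test_that("a single judged pair anchors straight to 0 and 100", {
  jm <- jm_of(c("g", "n"), "g", "n", "moderate")
  sc <- derive_scale(jm, neutral = "n", good = "g")
  expect_equal(scale_value_of(sc, "n"), 0)
  expect_equal(scale_value_of(sc, "g"), 100)
})

test_that("null judgments give exactly equal values", {
  jm <- jm_of(c("a", "b", "c"), a = c("a", "a", "b"), b = c("b", "c", "c"),
              category = c("null", "weak", "weak"))
  sc <- derive_scale(jm, neutral = "c", good = "a")
  expect_identical(scale_value_of(sc, "a"), scale_value_of(sc, "b"))
})

test_that("derived scales respect every judged category constraint", {
  for (seed in c(3, 17, 42)) {
    jm <- generate_consistent_matrix(seed, n_entities = 6)
    sc <- derive_scale(jm, neutral = tail(jm$entities, 1), good = jm$entities[1])
    v <- stats::setNames(sc$value, sc$entity)
    j <- jm$judgments
    d <- v[j$a] - v[j$b]
    # null => equal; category k >= 1 => strictly positive difference
    expect_true(all(abs(d[j$hi == 0]) < 1e-6))
    expect_true(all(d[j$lo >= 1] > 1e-9))
    # higher category => strictly larger difference
    for (p in seq_len(nrow(j))) {
      for (q in seq_len(nrow(j))) {
        if (j$lo[p] > j$hi[q]) expect_gt(d[p], d[q])
      }
    }
    # rank order of the hidden generating scale is recovered
    h <- attr(jm, "hidden_values")
    expect_identical(rank(round(v[names(h)], 6), ties.method = "min"),
                     rank(h, ties.method = "min"))
  }
})

test_that("derived scale is invariant to entity input order", {
  judg <- data.frame(a = c("a", "b", "a"), b = c("b", "c", "c"),
                     category = c("moderate", "weak", "very strong"))
  s1 <- derive_scale(judgment_matrix(c("a", "b", "c"), judg), "c", "a")
  s2 <- derive_scale(judgment_matrix(c("c", "b", "a"), judg), "c", "a")
  for (e in c("a", "b", "c")) {
    expect_equal(scale_value_of(s1, e), scale_value_of(s2, e), tolerance = 1e-9)
  }
})

test_that("deriving from an inconsistent matrix fails carrying the report", {
  cycle <- jm_of(c("a", "b", "c"), a = c("a", "b", "c"), b = c("b", "c", "a"),
                 category = rep("moderate", 3))
  err <- tryCatch(derive_scale(cycle, "c", "a"), dietmcda_inconsistent = identity)
  expect_s3_class(err, "dietmcda_inconsistent")
  expect_false(err$report$consistent)
  expect_error(check_consistency(jm_of(c("a", "b"), character(), character(),
                                       character())),
               "no judgments")
})

test_that("two swings judged null split the weight evenly", {
  jm <- jm_of(c("x", "y"), "x", "y", "null")
  expect_equal(derive_weights(c("x", "y"), jm), c(x = 0.5, y = 0.5))
})

test_that("derived weights are positive, normalized, and ordered like the swing ranking", {
  jm <- jm_of(c("w1", "w2", "w3"),
              a = c("w1", "w2", "w1"), b = c("w2", "w3", "w3"),
              category = c("weak", "very weak", "moderate"))
  w <- derive_weights(c("w1", "w2", "w3"), jm)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w > 0))
  expect_true(w[["w1"]] > w[["w2"]] && w[["w2"]] > w[["w3"]])

  # swings generated from hidden weights recover the ordering
  for (seed in c(5, 21)) {
    jm2 <- generate_consistent_matrix(seed, n_entities = 4, tie_prob = 0)
    rk <- jm2$entities
    w2 <- derive_weights(rk, jm2)
    expect_equal(sum(w2), 1, tolerance = 1e-9)
    expect_true(all(diff(w2[rk]) <= 1e-9))
  }
})

test_that("a ranking contradicting the judgments is rejected", {
  jm <- jm_of(c("w1", "w2"), "w1", "w2", "moderate")
  expect_error(derive_weights(c("w2", "w1"), jm), "ranking violated")
})

test_that("validation ratios reproduce the published scale spacings", {
  cs <- case_study("PT")
  # climate: improving L3 -> L2 is three times the improvement L2 -> L1
  expect_equal(validation_ratio(cs$model$scales$climate_change,
                                "L2", "L3", "L1", "L2"),
               100 / 33.33, tolerance = 1e-6)
  # land use: the two top improvements are equally attractive
  expect_equal(validation_ratio(cs$model$scales$land_use,
                                "L2", "L3", "L1", "L2"), 1)
  expect_equal(validation_ratio(cs$model$scales$water_use,
                                "L3", "L4", "L3", "L4"), 1)
  expect_error(validation_ratio(cs$model$scales$climate_change,
                                "L1", "L2", "L3", "L3"),
               "indifferent reference pair")
})

test_that("category ranges widen the feasible set", {
  # "weak to strong" on one pair coexists with judgments a point "weak"
  # judgment could contradict
  jm <- jm_of(c("a", "b", "c"), a = c("a", "b", "a"), b = c("b", "c", "c"),
              category = c("weak to strong", "weak", "strong"))
  expect_true(check_consistency(jm)$consistent)
  sc <- derive_scale(jm, "c", "a")
  expect_equal(scale_value_of(sc, "c"), 0)
})

test_that("contradictory two-orientation judgments are rejected at construction", {
  expect_error(jm_of(c("a", "b"), a = c("a", "b"), b = c("b", "a"),
                     category = c("weak", "moderate")),
               "both orientations")
})
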