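pt <- case_study("PT")
dk <- case_study("DK")

test_that("each sensitivity line agrees with a from-scratch evaluation at every grid point", {
  for (crit in c("water_use", "local_communities")) {
    sp <- weight_sensitivity(pt$model, pt$partials, crit, grid = seq(0, 1, 0.1))
    for (k in seq_along(sp$grid)) {
      w <- sp$grid[k]
      if (abs(1 - w) < 1e-12) next
      m2 <- reweight(pt$model, crit, w)
      res <- suppressWarnings(evaluate(m2, partial_overrides = pt$partials))
      expect_equal(sp$grid_values[names(res$globals), k], res$globals,
                   tolerance = 1e-9)
    }
  }
})

test_that("at the current weight the profile returns the nominal evaluation", {
  res <- suppressWarnings(evaluate(dk$model, partial_overrides = dk$partials))
  sp <- weight_sensitivity(dk$model, dk$partials, "diet_health")
  at_w0 <- sp$lines$intercept + sp$w0 * sp$lines$slope
  expect_equal(stats::setNames(at_w0, sp$lines$scenario), res$globals,
               tolerance = 1e-9)
})

test_that("the 100% scenario never loses the top spot to 75% in Portugal", {
  # 100% partials dominate 75% cell-wise, so their lines cannot cross
  P100 <- unlist(pt$partials[pt$partials$scenario == "100%", -1])
  P75 <- unlist(pt$partials[pt$partials$scenario == "75%", -1])
  expect_true(all(P100 >= P75))
  for (crit in criterion_ids(pt$model)) {
    sp <- weight_sensitivity(pt$model, pt$partials, crit)
    expect_true(is.na(line_crossover(sp, "100%", "75%")))
  }
})

test_that("a single crossover against 50% appears for the local-communities weight", {
  sp <- weight_sensitivity(pt$model, pt$partials, "local_communities")
  w_star <- line_crossover(sp, "100%", "50%")
  expect_equal(w_star, 0.317, tolerance = 1e-2)
  # the crossover is an exact root of the value difference
  ln <- sp$lines
  va <- ln$intercept[ln$scenario == "100%"] + w_star * ln$slope[ln$scenario == "100%"]
  vb <- ln$intercept[ln$scenario == "50%"] + w_star * ln$slope[ln$scenario == "50%"]
  expect_lt(abs(va - vb), 1e-9)
  # grid-scan oracle at 1e-3 resolution brackets the same root
  grid <- seq(0, 1, 1e-3)
  dif <- (ln$intercept[ln$scenario == "100%"] + grid * ln$slope[ln$scenario == "100%"]) -
    (ln$intercept[ln$scenario == "50%"] + grid * ln$slope[ln$scenario == "50%"])
  sign_change <- grid[which(diff(sign(dif)) != 0)]
  expect_lt(abs(sign_change - w_star), 1e-3)
})

test_that("the recommendation is stable in both countries for the two focal criteria", {
  for (cs in list(pt, dk)) {
    for (crit in c("diet_health", "water_use")) {
      st <- recommendation_stability(cs$model, cs$partials, crit)
      expect_true(st$stable, info = paste(cs$country, crit))
      expect_identical(st$top, "100%")
      sp <- weight_sensitivity(cs$model, cs$partials, crit)
      expect_identical(nrow(sp$crossovers), 0L)
      # grid-scan oracle: top alternative identical at every millesimal weight
      grid <- seq(0, 1, 1e-3)
      tops <- vapply(grid, function(w) {
        ln <- sp$lines
        ln$scenario[which.max(ln$intercept + w * ln$slope)]
      }, "")
      expect_identical(unique(tops), "100%")
    }
  }
})

test_that("an engineered two-criterion model flips exactly at one half", {
  m <- tiny_model(w = c(a = 0.25, b = 0.75))
  ov <- data.frame(scenario = c("s1", "s2"), a = c(100, 0), b = c(0, 100))
  st <- recommendation_stability(m, ov, "a")
  expect_false(st$stable)
  expect_equal(st$at_weight, 0.5, tolerance = 1e-9)
  expect_equal(st$min_change, 0.25, tolerance = 1e-9)
  expect_identical(st$top, "s2")
})

test_that("crossovers listed in a profile are sorted and are exact roots", {
  set.seed(1)
  m <- tiny_model(w = c(a = 0.3, b = 0.7))
  ov <- data.frame(scenario = paste0("s", 1:5),
                   a = stats::rnorm(5, sd = 60), b = stats::rnorm(5, sd = 60))
  sp <- weight_sensitivity(m, ov, "a")
  co <- sp$crossovers
  expect_gt(nrow(co), 0)  # seed chosen to produce at least one envelope change
  if (nrow(co) > 1) expect_true(all(diff(co$weight) > 0))
  for (i in seq_len(nrow(co))) {
    ln <- sp$lines
    va <- ln$intercept[ln$scenario == co$from[i]] + co$weight[i] * ln$slope[ln$scenario == co$from[i]]
    vb <- ln$intercept[ln$scenario == co$to[i]] + co$weight[i] * ln$slope[ln$scenario == co$to[i]]
    expect_lt(abs(va - vb), 1e-9)
  }
})

test_that("a zero-width box reduces robustness to the nominal comparison", {
  rel <- robustness(pt$model, pt$partials)
  res <- suppressWarnings(evaluate(pt$model, partial_overrides = pt$partials))
  for (a in rownames(rel)) {
    for (b in colnames(rel)) {
      if (a == b) next
      if (res$globals[[a]] > res$globals[[b]]) {
        expect_true(rel[a, b] %in% c("preferred", "robustly_preferred", "dominates"))
      }
    }
  }
  # 100% dominates 75% cell-wise in Portugal
  expect_identical(rel["100%", "75%"], "dominates")
})

test_that("full substitution stays robustly preferred under the shipped uncertainty", {
  for (cs in list(pt, dk)) {
    box <- uncertainty_box(cs$model, cs$partials,
                           criteria = c("diet_health", "env_health", "acceptance"),
                           halfwidth = 25)
    rel <- robustness(cs$model, cs$partials, box)
    for (b in setdiff(colnames(rel), "100%")) {
      expect_true(rel["100%", b] %in% c("robustly_preferred", "dominates"),
                  info = paste(cs$country, b))
    }
  }
})

test_that("the vertex formula equals brute-force enumeration over all box vertices", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- tiny_model(w = c(a = 0.45, b = 0.55))
    ov <- data.frame(scenario = paste0("s", 1:3),
                     a = stats::rnorm(3, sd = 30), b = stats::rnorm(3, sd = 30))
    box <- uncertainty_box(m, ov, criteria = c("a", "b"),
                           halfwidth = stats::runif(1, 0, 40))
    rel <- robustness(m, ov, box)
    P <- as.matrix(ov[-1]); rownames(P) <- ov$scenario
    w <- m$weights
    lo <- P; hi <- P
    for (i in seq_len(nrow(box))) {
      lo[box$scenario[i], box$criterion[i]] <- box$lo[i]
      hi[box$scenario[i], box$criterion[i]] <- box$hi[i]
    }
    for (a in rownames(P)) {
      for (b in rownames(P)) {
        if (a == b) next
        # enumerate every vertex of the 4-dimensional box for the pair
        corners_a <- expand.grid(a1 = c(lo[a, 1], hi[a, 1]), a2 = c(lo[a, 2], hi[a, 2]))
        corners_b <- expand.grid(b1 = c(lo[b, 1], hi[b, 1]), b2 = c(lo[b, 2], hi[b, 2]))
        mins <- Inf
        for (i in seq_len(nrow(corners_a))) {
          for (j in seq_len(nrow(corners_b))) {
            Va <- w[["a"]] * corners_a$a1[i] + w[["b"]] * corners_a$a2[i]
            Vb <- w[["a"]] * corners_b$b1[j] + w[["b"]] * corners_b$b2[j]
            mins <- min(mins, Va - Vb)
          }
        }
        robust_oracle <- mins >= -1e-12
        expect_identical(rel[a, b] %in% c("dominates", "robustly_preferred"),
                         robust_oracle, info = paste(seed, a, b))
      }
    }
  }
})

test_that("widening an interval never upgrades a relation", {
  strength <- function(x) match(x, c("incomparable", "preferred",
                                     "robustly_preferred", "dominates"))
  m <- tiny_model()
  ov <- data.frame(scenario = c("s1", "s2"), a = c(60, 20), b = c(10, 30))
  prev <- robustness(m, ov)
  for (h in c(5, 15, 40, 80)) {
    box <- uncertainty_box(m, ov, criteria = c("a", "b"), halfwidth = h)
    cur <- robustness(m, ov, box)
    expect_true(all(strength(cur) <= strength(prev) | cur == "" | prev == ""))
    prev <- cur
  }
})

test_that("dominance implies robust preference implies nominal preference", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- tiny_model(w = c(a = 0.5, b = 0.5))
    ov <- data.frame(scenario = paste0("s", 1:3),
                     a = stats::rnorm(3, sd = 50), b = stats::rnorm(3, sd = 50))
    box <- uncertainty_box(m, ov, criteria = "a", halfwidth = 10)
    rel <- robustness(m, ov, box)
    res <- evaluate(m, partial_overrides = ov)
    for (a in rownames(rel)) for (b in colnames(rel)) {
      if (a == b) next
      if (rel[a, b] == "dominates") {
        # with cell-wise interval ordering preserved, dominance entails the
        # box-wide value inequality
        expect_gte(sum(m$weights * 0) + res$globals[[a]], res$globals[[b]])
      }
      if (rel[a, b] %in% c("dominates", "robustly_preferred")) {
        expect_gte(res$globals[[a]], res$globals[[b]] - 1e-9)
      }
    }
  }
})

test_that("boxes referencing unknown cells or dropping the nominal point are rejected", {
  m <- tiny_model()
  ov <- data.frame(scenario = c("s1", "s2"), a = c(1, 2), b = c(3, 4))
  bad <- data.frame(scenario = "zz", criterion = "a", lo = 0, hi = 1)
  expect_error(robustness(m, ov, bad), "unknown cells")
  off <- data.frame(scenario = "s1", criterion = "a", lo = 5, hi = 9)
  expect_error(robustness(m, ov, off), "contain their nominal")
  expect_error(weight_sensitivity(m, ov, "nope"), "not in model")
})
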