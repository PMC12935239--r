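#' MACBETH semantic categories
#'
#' The seven qualitative categories used to judge differences in
#' attractiveness between two entities (descriptor levels, or criterion
#' swings when weighting), indexed 0 ("null", indifference) through
#' 6 ("extreme").
#'
#' @format character vector of length 7; `semantic_categories[k + 1]` is the
#'   name of category index `k`.
#' @export
semantic_categories <- c("null", "very weak", "weak", "moderate",
                         "strong", "very strong", "extreme")

category_index <- function(x) {
  if (is.numeric(x)) {
    k <- as.integer(x)
  } else {
    k <- match(trimws(tolower(x)), semantic_categories) - 1L
  }
  if (anyNA(k) || any(k < 0L) || any(k > 6L)) {
    stop("unknown semantic category: ", paste(x, collapse = ", "))
  }
  k
}

parse_category <- function(x) {
  # single category ("moderate", 3) or a contiguous range ("weak to moderate")
  if (is.character(x) && grepl(" to ", x, fixed = TRUE)) {
    parts <- strsplit(x, " to ", fixed = TRUE)[[1]]
    lo <- category_index(parts[1]); hi <- category_index(parts[2])
  } else if (length(x) == 2L) {
    lo <- category_index(x[1]); hi <- category_index(x[2])
  } else {
    lo <- hi <- category_index(x)
  }
  if (lo > hi) stop("category range must be non-decreasing")
  c(lo = lo, hi = hi)
}

#' Qualitative pairwise judgment matrix
#'
#' Holds the MACBETH judgments over an ordered set of entities. Each
#' judgment states that entity `a` is at least as attractive as entity `b`,
#' with the difference in attractiveness placed in a semantic category (or a
#' contiguous range of categories such as `"weak to moderate"`).
#'
#' @param entities character vector of entity ids, ordered (most attractive
#'   first by convention; the order is not enforced).
#' @param judgments data.frame with columns `a`, `b`, `category`; `category`
#'   entries are category names, indices 0-6, or ranges `"<cat> to <cat>"`.
#' @return object of class `judgment_matrix` with columns `a`, `b`, `lo`,
#'   `hi` (category bounds).
#' @examples
#' judgment_matrix(c("g", "n"), data.frame(a = "g", b = "n", category = "moderate"))
#' @export
judgment_matrix <- function(entities, judgments) {
  entities <- as.character(entities)
  if (anyDuplicated(entities)) stop("duplicate entity ids")
  if (length(entities) < 2L) stop("need at least 2 entities")
  j <- judgments
  if (!all(c("a", "b", "category") %in% names(j))) {
    stop("judgments need columns a, b, category")
  }
  bad <- setdiff(c(j$a, j$b), entities)
  if (length(bad)) stop("judged entities not in entity list: ", paste(unique(bad), collapse = ", "))
  rng <- t(vapply(j$category, parse_category, c(lo = 0L, hi = 0L)))
  jm <- data.frame(a = as.character(j$a), b = as.character(j$b),
                   lo = as.integer(rng[, "lo"]), hi = as.integer(rng[, "hi"]),
                   stringsAsFactors = FALSE)
  # diagonal judgments must be null; drop them
  diag_idx <- jm$a == jm$b
  if (any(jm$hi[diag_idx] > 0L)) stop("an entity cannot differ from itself")
  jm <- jm[!diag_idx, , drop = FALSE]
  # a pair judged in both orientations with nonzero categories is contradictory
  key <- paste(pmin(jm$a, jm$b), pmax(jm$a, jm$b))
  for (k in unique(key[duplicated(key)])) {
    sub <- jm[key == k, , drop = FALSE]
    ab <- sub$a < sub$b
    if (any(ab) && any(!ab) && max(sub$lo[ab]) > 0L && max(sub$lo[!ab]) > 0L) {
      stop("pair judged in both orientations with nonzero categories: ",
           sub$a[1], " / ", sub$b[1])
    }
  }
  structure(list(entities = entities, judgments = jm),
            class = "judgment_matrix")
}

#' @export
print.judgment_matrix <- function(x, ...) {
  cat(sprintf("<judgment_matrix> %d entities, %d judgments\n",
              length(x$entities), nrow(x$judgments)))
  j <- x$judgments
  cat_name <- function(lo, hi) {
    ifelse(lo == hi, semantic_categories[lo + 1],
           paste(semantic_categories[lo + 1], "to", semantic_categories[hi + 1]))
  }
  if (nrow(j)) {
    cat(sprintf("  (%s, %s): %s\n", j$a, j$b, cat_name(j$lo, j$hi)), sep = "")
  }
  invisible(x)
}

# Solve the MACBETH constraint system.
#
# Variables: v(e) >= 0 per entity. Constraints, with category step delta = 1:
#   * pair judged category range [lo, hi], lo >= 1:  v(a) - v(b) >= lo*delta
#   * pair judged null (lo = hi = 0): v(a) = v(b); ranges starting at null
#     only impose v(a) - v(b) >= 0
#   * between-category separation: for judgments p, q with p.lo > q.hi:
#       [v(p.a) - v(p.b)] - [v(q.a) - v(q.b)] >= delta
#   * optional ranking chain and positivity floor v(e) >= delta (weighting)
# Among all feasible scales the one of minimum Euclidean norm is returned
# (quadprog active-set solve): it exists, is unique, keeps ties exact, and
# does not depend on the entity input order. Infeasibility of the system is
# what defines judgmental inconsistency.
macbeth_solve <- function(entities, judg, delta = 1,
                          ranking = NULL, floor_positive = FALSE) {
  n <- length(entities)
  infeasible <- list(feasible = FALSE,
                     values = stats::setNames(rep(NA_real_, n), entities))
  # null judgments mean exact indifference: merge those entities into one
  # variable (union-find), which keeps ties exact and spares quadprog the
  # linearly dependent equality rows a chain of nulls would produce
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(judg)) {
    for (i in seq_len(nrow(judg))) {
      if (judg$lo[i] == 0L && judg$hi[i] == 0L) {
        ra <- find(match(judg$a[i], entities))
        rb <- find(match(judg$b[i], entities))
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  rep_of <- vapply(seq_len(n), find, 0L)
  reps <- sort(unique(rep_of))
  m <- length(reps)
  var_of <- match(rep_of, reps)        # entity -> QP variable
  idx <- function(e) var_of[match(e, entities)]

  Aineq <- NULL; bineq <- NULL
  row_of <- function(plus, minus = integer()) {
    r <- numeric(m)
    for (i in plus) r[i] <- r[i] + 1
    for (i in minus) r[i] <- r[i] - 1
    r
  }
  add_ge <- function(r, b) {
    if (all(r == 0)) {
      if (b > 0) return(FALSE)          # 0 >= b impossible
    } else {
      Aineq <<- rbind(Aineq, r); bineq <<- c(bineq, b)
    }
    TRUE
  }
  if (nrow(judg)) {
    for (i in seq_len(nrow(judg))) {
      if (judg$lo[i] >= 1L || judg$hi[i] >= 1L) {
        r <- row_of(idx(judg$a[i]), idx(judg$b[i]))
        if (!add_ge(r, judg$lo[i] * delta)) return(infeasible)
      }
    }
    # between-category separation
    for (p in seq_len(nrow(judg))) {
      for (q in seq_len(nrow(judg))) {
        if (p != q && judg$lo[p] > judg$hi[q]) {
          r <- row_of(c(idx(judg$a[p]), idx(judg$b[q])),
                      c(idx(judg$b[p]), idx(judg$a[q])))
          if (!add_ge(r, delta)) return(infeasible)
        }
      }
    }
  }
  if (!is.null(ranking)) {
    ri <- idx(ranking)
    for (i in seq_len(length(ri) - 1L)) {
      if (!add_ge(row_of(ri[i], ri[i + 1L]), 0)) return(infeasible)
    }
  }
  floor_b <- if (floor_positive) rep(delta, m) else rep(0, m)
  Amat <- t(rbind(Aineq, diag(m)))
  bvec <- c(bineq, floor_b)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(m), dvec = numeric(m),
                       Amat = Amat, bvec = bvec, meq = 0),
    error = function(e) e
  )
  if (inherits(sol, "error")) return(infeasible)
  v <- pmax(sol$solution, 0)
  list(feasible = TRUE,
       values = stats::setNames(v[var_of], entities))
}

#' Check a judgment matrix for consistency
#'
#' A matrix is consistent when the MACBETH constraint system admits a
#' cardinal scale: every judged pair in a higher category gets a strictly
#' larger value difference, null judgments force equality, and positive
#' categories force positive differences. Consistency is decided by linear
#' programming feasibility; when infeasible, the report identifies a subset
#' of judgments whose removal restores feasibility.
#'
#' @param matrix a [judgment_matrix()].
#' @return object of class `consistency_report`: list with `consistent`
#'   (flag) and `violated_constraints` (data.frame `a`, `b`, `rule`; empty
#'   when consistent).
#' @examples
#' jm <- judgment_matrix(c("a", "b", "c"), data.frame(
#'   a = c("a", "b", "a"), b = c("b", "c", "c"),
#'   category = c("moderate", "moderate", "strong")))
#' check_consistency(jm)$consistent
#' @export
check_consistency <- function(matrix) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  judg <- matrix$judgments
  if (nrow(judg) == 0L) stop("no judgments")
  ent <- matrix$entities
  fit <- macbeth_solve(ent, judg)
  if (fit$feasible) {
    rep <- list(consistent = TRUE,
                violated_constraints = data.frame(a = character(), b = character(),
                                                  rule = character(), stringsAsFactors = FALSE))
  } else {
    culprit <- logical(nrow(judg))
    for (i in seq_len(nrow(judg))) {
      culprit[i] <- macbeth_solve(ent, judg[-i, , drop = FALSE])$feasible
    }
    if (!any(culprit)) culprit <- rep(TRUE, nrow(judg))  # joint infeasibility
    rep <- list(consistent = FALSE,
                violated_constraints = data.frame(
                  a = judg$a[culprit], b = judg$b[culprit],
                  rule = "infeasible_subset", stringsAsFactors = FALSE))
  }
  class(rep) <- "consistency_report"
  rep
}

#' @export
print.consistency_report <- function(x, ...) {
  if (x$consistent) {
    cat("<consistency_report> consistent\n")
  } else {
    cat("<consistency_report> INCONSISTENT; implicated judgments:\n")
    print.data.frame(x$violated_constraints)
  }
  invisible(x)
}

#' Derive a cardinal value scale from a judgment matrix
#'
#' Solves the MACBETH linear program: entity values reproduce the judged
#' categories (pairs in a higher category get strictly larger value
#' differences, null means indifference), then rescales affinely so the
#' `neutral` entity scores 0 and the `good` entity 100. Among all feasible
#' raw scales the unique one of minimum Euclidean norm is selected, so the
#' result is deterministic and invariant to entity input order.
#'
#' @param matrix a consistent [judgment_matrix()].
#' @param neutral entity id anchored at 0 points.
#' @param good entity id anchored at 100 points.
#' @return object of class `macbeth_scale`: data.frame (`entity`, `value`)
#'   with attributes `neutral` and `good`.
#' @examples
#' jm <- judgment_matrix(c("g", "n"), data.frame(a = "g", b = "n", category = "moderate"))
#' derive_scale(jm, neutral = "n", good = "g")
#' @export
derive_scale <- function(matrix, neutral, good) {
  stopifnot(inherits(matrix, "judgment_matrix"))
  ent <- matrix$entities
  if (!all(c(neutral, good) %in% ent)) stop("neutral and good must be among the entities")
  rep <- check_consistency(matrix)
  if (!rep$consistent) {
    stop(errorCondition("judgment matrix is inconsistent",
                        report = rep,
                        class = c("dietmcda_inconsistent", "error", "condition")))
  }
  fit <- macbeth_solve(ent, matrix$judgments)
  v <- fit$values
  span <- v[[good]] - v[[neutral]]
  if (span <= 1e-9) stop("good must be judged more attractive than neutral")
  out <- data.frame(entity = ent,
                    value = (v - v[[neutral]]) / span * 100,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("macbeth_scale", "data.frame"),
            neutral = neutral, good = good)
}

#' Derive swing weights from a ranking and a judgment matrix
#'
#' Implements the MACBETH weighting protocol: criteria are first ranked by
#' the attractiveness of their Neutral-to-Good swing, then the pairwise
#' differences between swings are judged qualitatively. The LP of
#' [derive_scale()] is solved with the ranking added as order constraints
#' and every swing held strictly positive (a swing is always an improvement
#' over staying at Neutral everywhere); raw values are normalized to sum
#' to 1.
#'
#' @param swing_ranking character vector of criterion ids, most attractive
#'   swing first.
#' @param swing_matrix a [judgment_matrix()] over the same criterion ids.
#' @return named numeric weight vector, positive, summing to 1, ordered as
#'   `swing_ranking`.
#' @export
derive_weights <- function(swing_ranking, swing_matrix) {
  stopifnot(inherits(swing_matrix, "judgment_matrix"))
  ent <- swing_matrix$entities
  if (!setequal(ent, swing_ranking)) {
    stop("swing_ranking must contain exactly the matrix entities")
  }
  rep <- check_consistency(swing_matrix)
  if (!rep$consistent) {
    stop(errorCondition("judgment matrix is inconsistent",
                        report = rep,
                        class = c("dietmcda_inconsistent", "error", "condition")))
  }
  fit <- macbeth_solve(ent, swing_matrix$judgments,
                       ranking = swing_ranking, floor_positive = TRUE)
  if (!fit$feasible) stop("ranking violated")
  w <- fit$values / sum(fit$values)
  w[swing_ranking]
}

resolve_scale_lookup <- function(scale) {
  if (inherits(scale, "macbeth_scale")) {
    stats::setNames(scale$value, scale$entity)
  } else if (inherits(scale, "value_scale")) {
    scale_values(scale)
  } else if (is.numeric(scale) && !is.null(names(scale))) {
    scale
  } else {
    stop("scale must be a value_scale, macbeth_scale, or named numeric vector")
  }
}

#' Ratio of value differences for facilitator validation
#'
#' Computes `(v(a) - v(b)) / (v(c) - v(d))`, the quantity behind validation
#' questions of the form "do you agree that an improvement from L4 to L3 is
#' twice as attractive as one from L3 to L2?".
#'
#' @param scale a [value_scale()] (entities `L1`, `L2`, ...), a
#'   `macbeth_scale`, or a named numeric vector.
#' @param a,b,c,d entity ids; `(a, b)` is the improvement under scrutiny,
#'   `(c, d)` the reference improvement.
#' @return the dimensionless ratio.
#' @export
validation_ratio <- function(scale, a, b, c, d) {
  v <- resolve_scale_lookup(scale)
  miss <- setdiff(c(a, b, c, d), names(v))
  if (length(miss)) stop("unknown entities: ", paste(miss, collapse = ", "))
  den <- v[[c]] - v[[d]]
  if (abs(den) < 1e-12) stop("indifferent reference pair")
  (v[[a]] - v[[b]]) / den
}
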