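# Small models and matrices rebuilt in code for every run.

# two-criterion model with simple linear scales (anchors 0 -> 0, 10 -> 100)
tiny_model <- function(w = c(a = 0.6, b = 0.4)) {
  lv <- descriptor_levels(performance = c(20, 10, 0, -10), good = 2, neutral = 3)
  mcda_model(
    criteria = list(
      criterion("a", "criterion a", "health", "quantitative", "units", lv),
      criterion("b", "criterion b", "economic", "quantitative", "units", lv)
    ),
    scales = list(value_scale("a", c(200, 100, 0, -100)),
                  value_scale("b", c(200, 100, 0, -100))),
    weights = w,
    metadata = list(name = "tiny synthetic model", provenance = "synthetic")
  )
}

jm_of <- function(entities, a, b, category) {
  judgment_matrix(entities, data.frame(a = a, b = b, category = category,
                                       stringsAsFactors = FALSE))
}

# Exhaustive oracle for MACBETH feasibility on small matrices: search all
# integer value assignments on a grid for one satisfying every constraint
# (category lower bounds with delta = 1, null equalities, and the
# between-category separation on judged pairs).
brute_force_feasible <- function(matrix, vmax = 12L) {
  ent <- matrix$entities
  j <- matrix$judgments
  n <- length(ent)
  grid <- do.call(expand.grid, rep(list(0:vmax), n))
  diffs <- function(v) v[match(j$a, ent)] - v[match(j$b, ent)]
  for (r in seq_len(nrow(grid))) {
    v <- as.integer(grid[r, ])
    d <- diffs(v)
    ok <- all(ifelse(j$lo == 0L & j$hi == 0L, d == 0, d >= j$lo))
    if (!ok) next
    sep_ok <- TRUE
    for (p in seq_along(d)) {
      for (q in seq_along(d)) {
        if (p != q && j$lo[p] > j$hi[q] && !(d[p] >= d[q] + 1)) sep_ok <- FALSE
      }
    }
    if (sep_ok) return(TRUE)
  }
  FALSE
}

scale_value_of <- function(ms, entity) ms$value[match(entity, ms$entity)]
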