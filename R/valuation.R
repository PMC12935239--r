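#' Convert a performance into a partial value
#'
#' Applies the criterion's value function. Quantitative criteria use the
#' piecewise-linear function through the descriptor anchors
#' (performance, value): at an anchor the anchor value is returned exactly;
#' between adjacent anchors the value is linearly interpolated on the
#' performance axis; beyond the extreme anchors it is linearly extrapolated
#' with the terminal segment's slope (no clamping). Categorical criteria use
#' exact label lookup; when duplicate labels exist the most attractive
#' matching level wins.
#'
#' @param criterion a [criterion()].
#' @param scale the matching [value_scale()].
#' @param performance a finite number (quantitative) or a level label
#'   (categorical).
#' @return the partial value `v_j(a)` in points.
#' @examples
#' cs <- case_study("PT")
#' partial_value(cs$model$criteria$water_use, cs$model$scales$water_use, 11.7)
#' @export
partial_value <- function(criterion, scale, performance) {
  v <- scale$anchors$value
  if (criterion$descriptor_kind == "categorical") {
    if (is.numeric(performance)) {
      stop("descriptor mismatch: quantitative performance on a categorical criterion")
    }
    hit <- match(as.character(performance), criterion$levels$label)
    if (is.na(hit)) stop("unknown level: ", performance)
    return(v[hit])
  }
  p <- suppressWarnings(as.numeric(performance))
  if (is.na(p) || !is.finite(p)) stop("performance must be a finite number")
  x <- criterion$levels$performance
  ord <- order(x)
  x <- x[ord]; y <- v[ord]
  n <- length(x)
  if (p <= x[1]) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    return(y[1] + (p - x[1]) * slope)
  }
  if (p >= x[n]) {
    slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    return(y[n] + (p - x[n]) * slope)
  }
  i <- findInterval(p, x)
  y[i] + (p - x[i]) * (y[i + 1] - y[i]) / (x[i + 1] - x[i])
}

#' Evaluate scenarios against a model
#'
#' Computes partial values for every (scenario, criterion) cell and
#' aggregates them into global scores `V(a) = sum_j w_j v_j(a)`. Cell
#' precedence: an entry in `partial_overrides` is used as-is (this is how
#' published partial-value tables are reproduced); otherwise a performance
#' cell is converted with [partial_value()]; a cell available from neither
#' source is MISSING, contributes 0 points, and is listed in
#' `missing_cells` (with a warning).
#'
#' @param model an [mcda_model()].
#' @param table a [performance_table()] (or NULL when evaluating from
#'   overrides alone).
#' @param partial_overrides optional data.frame with a `scenario` column and
#'   criterion columns holding partial values in points (NA = no override).
#' @return object of class `evaluation_result`: list with `partials`
#'   (scenario x criterion matrix), `globals` (named numeric), `ranking`
#'   (scenario ids, best first), `missing_cells` (data.frame `scenario`,
#'   `criterion`), `weights`.
#' @examples
#' cs <- case_study("PT")
#' res <- evaluate(cs$model, partial_overrides = cs$partials)
#' round(res$globals[["100%"]], 2)
#' @export
evaluate <- function(model, table = NULL, partial_overrides = NULL) {
  crit <- criterion_ids(model)
  scen <- unique(c(
    if (!is.null(table)) as.character(table$scenario),
    if (!is.null(partial_overrides)) as.character(partial_overrides$scenario)
  ))
  if (length(scen) == 0L) stop("no scenarios to evaluate")
  if (!is.null(table)) {
    unknown <- setdiff(setdiff(names(table), "scenario"), crit)
    if (length(unknown)) stop("unknown criterion column(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(partial_overrides)) {
    unknown <- setdiff(setdiff(names(partial_overrides), "scenario"), crit)
    if (length(unknown)) stop("unknown criterion column(s): ", paste(unknown, collapse = ", "))
  }
  partials <- matrix(NA_real_, nrow = length(scen), ncol = length(crit),
                     dimnames = list(scen, crit))
  for (s in scen) {
    for (j in crit) {
      ov <- NULL
      if (!is.null(partial_overrides) && j %in% names(partial_overrides)) {
        row <- match(s, partial_overrides$scenario)
        if (!is.na(row)) {
          val <- partial_overrides[[j]][row]
          if (!is.na(val)) ov <- as.numeric(val)
        }
      }
      if (!is.null(ov)) {
        partials[s, j] <- ov
        next
      }
      if (!is.null(table) && j %in% names(table)) {
        row <- match(s, table$scenario)
        if (!is.na(row)) {
          cell <- table[[j]][row]
          if (!is.na(cell)) {
            partials[s, j] <- partial_value(model$criteria[[j]], model$scales[[j]], cell)
          }
        }
      }
    }
  }
  empty <- rownames(partials)[rowSums(!is.na(partials)) == 0L]
  if (length(empty)) stop("empty alternative: ", paste(empty, collapse = ", "))
  miss_idx <- which(is.na(partials), arr.ind = TRUE)
  missing_cells <- data.frame(scenario = rownames(partials)[miss_idx[, 1]],
                              criterion = colnames(partials)[miss_idx[, 2]],
                              stringsAsFactors = FALSE)
  if (nrow(missing_cells)) {
    warning(sprintf("%d MISSING cell(s) contribute 0 points", nrow(missing_cells)))
  }
  filled <- partials
  filled[is.na(filled)] <- 0
  w <- model$weights[crit]
  globals <- as.numeric(filled %*% w)
  names(globals) <- scen
  res <- structure(
    list(partials = partials, globals = globals,
         ranking = NULL, missing_cells = missing_cells, weights = w),
    class = "evaluation_result"
  )
  res$ranking <- rank_alternatives(res)
  res
}

#' Rank alternatives by global value
#'
#' @param result an `evaluation_result`.
#' @return character vector of scenario ids in strictly descending global
#'   value order; ties keep input order (stable sort).
#' @export
rank_alternatives <- function(result) {
  g <- result$globals
  if (length(g) == 0L) stop("empty evaluation result")
  names(g)[order(-g, seq_along(g))]
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result>\n  global scores (ranked):\n")
  for (s in x$ranking) {
    cat(sprintf("    %-6s %8.2f\n", s, x$globals[[s]]))
  }
  if (nrow(x$missing_cells)) {
    cat(sprintf("  %d MISSING cell(s) treated as 0 points\n", nrow(x$missing_cells)))
  }
  invisible(x)
}
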