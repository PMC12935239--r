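as_partials_matrix <- function(model, partials) {
  if (inherits(partials, "evaluation_result")) {
    m <- partials$partials
  } else if (is.matrix(partials)) {
    m <- partials
  } else if (is.data.frame(partials)) {
    if (!"scenario" %in% names(partials)) stop("partials need a `scenario` column")
    m <- as.matrix(partials[setdiff(names(partials), "scenario")])
    rownames(m) <- partials$scenario
  } else {
    stop("cannot interpret `partials`")
  }
  crit <- criterion_ids(model)
  unknown <- setdiff(colnames(m), crit)
  if (length(unknown)) stop("unknown criterion column(s): ", paste(unknown, collapse = ", "))
  full <- matrix(0, nrow(m), length(crit), dimnames = list(rownames(m), crit))
  full[, colnames(m)] <- m
  full[is.na(full)] <- 0  # MISSING contributes 0 points
  full
}

#' Replace one weight, renormalizing the others
#'
#' Sets criterion `j`'s weight to `w` and rescales the remaining weights
#' proportionally by `(1 - w) / (1 - w_j0)` so the vector still sums to 1.
#'
#' @param model an [mcda_model()].
#' @param criterion criterion id.
#' @param w new weight in `[0, 1]`.
#' @return the model with the modified weight vector.
#' @export
reweight <- function(model, criterion, w) {
  if (!criterion %in% criterion_ids(model)) stop("criterion not in model: ", criterion)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  w0 <- model$weights
  wj0 <- w0[[criterion]]
  if (abs(1 - wj0) < 1e-12) stop("cannot renormalize: criterion carries all weight")
  out <- w0 * (1 - w) / (1 - wj0)
  out[[criterion]] <- w
  model$weights <- out
  model
}

#' Single-weight sensitivity profile
#'
#' Varies the weight of one criterion over `[0, 1]` while rescaling the
#' remaining weights proportionally. Every scenario's global value is then
#' affine in the varied weight `w`:
#' `V_a(w) = w * v_aj + (1 - w) * R_a`, where `R_a` is the weighted mean of
#' the other partial values under the renormalized weights. Crossover
#' weights where the *top-ranked* scenario changes are found in closed form
#' as intersections of adjacent lines on the upper envelope.
#'
#' @param model an [mcda_model()].
#' @param partials partial values: wide data.frame with `scenario` column,
#'   matrix, or `evaluation_result`; MISSING cells count 0.
#' @param criterion id of the varied criterion.
#' @param grid weight grid in `[0, 1]` used for tabulated values (the lines
#'   themselves are exact).
#' @return object of class `sensitivity_profile`: `criterion`, `w0`
#'   (current weight), `lines` (data.frame `scenario`, `intercept`,
#'   `slope`), `grid`, `grid_values` (scenario x grid matrix), `crossovers`
#'   (data.frame `weight`, `from`, `to`, ascending), `top_nominal`.
#' @examples
#' cs <- case_study("PT")
#' sp <- weight_sensitivity(cs$model, cs$partials, "water_use")
#' nrow(sp$crossovers)  # 0: recommendation insensitive to this weight
#' @export
weight_sensitivity <- function(model, partials, criterion,
                               grid = seq(0, 1, by = 0.01)) {
  if (!criterion %in% criterion_ids(model)) stop("criterion not in model: ", criterion)
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]")
  P <- as_partials_matrix(model, partials)
  w0 <- model$weights
  wj0 <- w0[[criterion]]
  if (abs(1 - wj0) < 1e-12) stop("cannot renormalize: criterion carries all weight")
  others <- setdiff(colnames(P), criterion)
  rest <- as.numeric(P[, others, drop = FALSE] %*% w0[others]) / (1 - wj0)
  vj <- P[, criterion]
  lines <- data.frame(scenario = rownames(P), intercept = rest,
                      slope = vj - rest, stringsAsFactors = FALSE)
  gv <- outer(rest, rep(1, length(grid))) +
    outer(lines$slope, grid)
  dimnames(gv) <- list(rownames(P), NULL)
  structure(
    list(criterion = criterion, w0 = wj0, lines = lines,
         grid = grid, grid_values = gv,
         crossovers = envelope_crossovers(lines),
         top_nominal = rownames(P)[which.max(line_at(lines, wj0))]),
    class = "sensitivity_profile"
  )
}

line_at <- function(lines, w) lines$intercept + w * lines$slope

envelope_crossovers <- function(lines) {
  n <- nrow(lines)
  cand <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ds <- lines$slope[i] - lines$slope[j]
      if (abs(ds) < 1e-12) next
      w <- (lines$intercept[j] - lines$intercept[i]) / ds
      if (w > 1e-12 && w < 1 - 1e-12) cand <- c(cand, w)
    }
  }
  cand <- sort(unique(round(cand, 12)))
  bounds <- c(0, cand, 1)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  top <- vapply(mids, function(w) which.max(line_at(lines, w)), 0L)
  chg <- which(diff(top) != 0L)
  data.frame(weight = cand[chg],
             from = lines$scenario[top[chg]],
             to = lines$scenario[top[chg + 1L]],
             stringsAsFactors = FALSE)
}

#' Exact crossover weight of two scenarios
#'
#' Closed-form intersection of the two affine global-value lines of a
#' [weight_sensitivity()] profile.
#'
#' @param profile a `sensitivity_profile`.
#' @param a,b scenario ids.
#' @return the weight strictly inside `(0, 1)` where `V_a(w) = V_b(w)`, or
#'   `NA` when the lines are parallel, only touch at an endpoint of the
#'   unit interval, or cross outside it.
#' @export
line_crossover <- function(profile, a, b) {
  ln <- profile$lines
  ia <- match(a, ln$scenario); ib <- match(b, ln$scenario)
  if (is.na(ia) || is.na(ib)) stop("unknown scenario")
  ds <- ln$slope[ia] - ln$slope[ib]
  if (abs(ds) < 1e-12) return(NA_real_)
  w <- (ln$intercept[ib] - ln$intercept[ia]) / ds
  if (w < 1e-9 || w > 1 - 1e-9) NA_real_ else w
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("<sensitivity_profile> criterion %s (current weight %.4f)\n",
              x$criterion, x$w0))
  if (nrow(x$crossovers) == 0) {
    cat("  top alternative invariant over the whole weight range [0, 1]\n")
  } else {
    cat("  top alternative changes at:\n")
    with(x$crossovers, cat(sprintf("    w = %.4f: %s -> %s\n", weight, from, to), sep = ""))
  }
  invisible(x)
}

#' Plot a sensitivity profile
#'
#' Global-value lines of every scenario against the varied weight, with a
#' vertical marker at the current weight.
#'
#' @param x a `sensitivity_profile`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sensitivity_profile <- function(x, ...) {
  graphics::matplot(x$grid, t(x$grid_values), type = "l", lty = 1,
                    xlab = sprintf("weight of %s", x$criterion),
                    ylab = "global value (points)", ...)
  graphics::abline(v = x$w0, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = rownames(x$grid_values),
                   col = seq_len(nrow(x$grid_values)), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Stability of the recommendation to one weight
#'
#' Scans the sensitivity profile of a criterion for the smallest change of
#' its weight (after proportional renormalization of the others) that
#' replaces the top-ranked alternative.
#'
#' @inheritParams weight_sensitivity
#' @return object of class `stability_result`: `criterion`, `top`
#'   (nominal top alternative), `stable` (TRUE when no weight in `[0, 1]`
#'   changes the top), `min_change` (smallest `|w - w0|` flipping the top,
#'   NA when none), `at_weight`.
#' @export
recommendation_stability <- function(model, partials, criterion) {
  sp <- weight_sensitivity(model, partials, criterion)
  co <- sp$crossovers
  out <- list(criterion = criterion, top = sp$top_nominal,
              stable = nrow(co) == 0, min_change = NA_real_, at_weight = NA_real_)
  if (nrow(co)) {
    d <- abs(co$weight - sp$w0)
    k <- which.min(d)
    out$min_change <- d[k]
    out$at_weight <- co$weight[k]
  }
  structure(out, class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  if (x$stable) {
    cat(sprintf("<stability_result> %s: top alternative '%s' stable for all weights in [0, 1]\n",
                x$criterion, x$top))
  } else {
    cat(sprintf("<stability_result> %s: top '%s' flips at w = %.4f (change %.4f)\n",
                x$criterion, x$top, x$at_weight, x$min_change))
  }
  invisible(x)
}

#' Interval uncertainty box on partial values
#'
#' Builds symmetric intervals `value +/- halfwidth` around the nominal
#' partial values of the chosen criteria (all scenarios by default).
#'
#' @param model an [mcda_model()].
#' @param partials partial values (see [weight_sensitivity()]).
#' @param criteria criterion ids carrying uncertainty.
#' @param halfwidth interval half-width in value points.
#' @param scenarios subset of scenario ids (default all).
#' @return data.frame `scenario`, `criterion`, `lo`, `hi`.
#' @export
uncertainty_box <- function(model, partials, criteria, halfwidth,
                            scenarios = NULL) {
  P <- as_partials_matrix(model, partials)
  scen <- scenarios %||% rownames(P)
  bad <- setdiff(criteria, colnames(P))
  if (length(bad)) stop("unknown criterion: ", paste(bad, collapse = ", "))
  grid <- expand.grid(scenario = scen, criterion = criteria,
                      stringsAsFactors = FALSE)
  v <- P[cbind(grid$scenario, grid$criterion)]
  data.frame(grid, lo = v - halfwidth, hi = v + halfwidth)
}

#' Pairwise dominance and robustness relations
#'
#' Classifies every ordered pair of scenarios under interval uncertainty on
#' the partial values. With `lo`/`hi` the interval bounds (degenerate at the
#' nominal value where the box is silent), the relation of `a` over `b` is
#' the strongest of:
#' \describe{
#'   \item{dominates}{every interval of `a` lies at or above the matching
#'     interval of `b` (`lo_a >= hi_b` criterion-wise);}
#'   \item{robustly_preferred}{`V(a) - V(b) >= 0` over the whole box. The
#'     minimum of this affine function over the box sits at a vertex: lower
#'     bounds for `a`, upper bounds for `b`;}
#'   \item{preferred}{nominal `V(a) > V(b)` only;}
#'   \item{incomparable}{none of the above.}
#' }
#'
#' @param model an [mcda_model()].
#' @param partials partial values (see [weight_sensitivity()]).
#' @param box optional data.frame `scenario`, `criterion`, `lo`, `hi` as
#'   from [uncertainty_box()]; absent cells get zero-width intervals.
#' @return object of class `dominance_relation`: a scenario x scenario
#'   character matrix (rows = `a`, columns = `b`, diagonal empty).
#' @export
robustness <- function(model, partials, box = NULL) {
  P <- as_partials_matrix(model, partials)
  lo <- hi <- P
  if (!is.null(box) && nrow(box)) {
    need <- c("scenario", "criterion", "lo", "hi")
    if (!all(need %in% names(box))) stop("box needs columns scenario, criterion, lo, hi")
    bad <- box$scenario[!box$scenario %in% rownames(P)]
    bad <- c(bad, box$criterion[!box$criterion %in% colnames(P)])
    if (length(bad)) stop("box references unknown cells: ", paste(unique(bad), collapse = ", "))
    if (any(!is.finite(box$lo)) || any(!is.finite(box$hi))) stop("box intervals must be finite")
    idx <- cbind(box$scenario, box$criterion)
    if (any(box$lo > P[idx] + 1e-9) || any(box$hi < P[idx] - 1e-9)) {
      stop("intervals must contain their nominal points")
    }
    lo[idx] <- box$lo
    hi[idx] <- box$hi
  }
  w <- model$weights[colnames(P)]
  nominal <- as.numeric(P %*% w); names(nominal) <- rownames(P)
  scen <- rownames(P)
  rel <- matrix("", length(scen), length(scen), dimnames = list(scen, scen))
  for (a in scen) {
    for (b in scen) {
      if (a == b) next
      rel[a, b] <- if (all(lo[a, ] >= hi[b, ] - 1e-12)) {
        "dominates"
      } else if (sum(w * (lo[a, ] - hi[b, ])) >= -1e-12) {
        "robustly_preferred"
      } else if (nominal[[a]] > nominal[[b]]) {
        "preferred"
      } else {
        "incomparable"
      }
    }
  }
  structure(rel, class = c("dominance_relation", class(rel)))
}

#' @export
print.dominance_relation <- function(x, ...) {
  cat("<dominance_relation> (row over column)\n")
  print(unclass(x), quote = FALSE)
  invisible(x)
}
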