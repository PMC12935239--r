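#' Descriptor levels for a criterion
#'
#' A descriptor of performance is an ordered set of plausible performance
#' levels for one criterion, ranked by attractiveness: `L1` is the most
#' attractive level, `Ln` the least. Exactly one level is flagged as the
#' *Good* reference and one as the *Neutral* (minimally acceptable)
#' reference; these anchor the criterion's cardinal value scale at 100 and 0
#' points respectively. Attractiveness order is authoritative: the raw
#' performance axis may ascend or descend along it (e.g. profit margins rise
#' with attractiveness while water use falls).
#'
#' @param performance numeric vector of level performances (quantitative
#'   descriptors), in attractiveness order `L1..Ln`. Mutually exclusive with
#'   `labels`.
#' @param labels character vector of level labels (categorical descriptors),
#'   in attractiveness order.
#' @param neutral index (1-based rank) of the Neutral reference level.
#' @param good index of the Good reference level.
#' @param notes optional character vector of per-level provenance notes.
#' @return a data.frame with one row per level and columns `index`,
#'   `performance`, `label`, `is_neutral`, `is_good`, `note`.
#' @examples
#' descriptor_levels(performance = c(0, 0.3, 0.6, 1.5, 4), good = 2, neutral = 3)
#' @export
descriptor_levels <- function(performance = NULL, labels = NULL,
                              neutral, good, notes = NULL) {
  if (is.null(performance) == is.null(labels)) {
    stop("give exactly one of `performance` or `labels`")
  }
  n <- length(performance %||% labels)
  if (n < 2L) stop("a descriptor needs at least 2 levels")
  if (is.null(notes)) notes <- rep(NA_character_, n)
  data.frame(
    index = seq_len(n),
    performance = if (is.null(performance)) rep(NA_real_, n) else as.numeric(performance),
    label = if (is.null(labels)) rep(NA_character_, n) else as.character(labels),
    is_neutral = seq_len(n) == neutral,
    is_good = seq_len(n) == good,
    note = as.character(notes),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluation criterion
#'
#' @param id short identifier, used as the column name in performance tables.
#' @param name human-readable name.
#' @param dimension one of `"health"`, `"environmental"`, `"economic"`,
#'   `"social"`.
#' @param descriptor_kind `"quantitative"` or `"categorical"`.
#' @param unit measurement unit of the performance axis (e.g.
#'   `"kg CO2-eq/kg"`, `"DALYs/100,000"`, `"% change"`); empty for
#'   categorical descriptors.
#' @param levels a data.frame from [descriptor_levels()].
#' @return an object of class `criterion`.
#' @seealso [descriptor_levels()], [value_scale()], [validate_model()]
#' @export
criterion <- function(id, name, dimension, descriptor_kind, unit = "", levels) {
  dimension <- match.arg(dimension, c("health", "environmental", "economic", "social"))
  descriptor_kind <- match.arg(descriptor_kind, c("quantitative", "categorical"))
  structure(
    list(id = as.character(id), name = as.character(name),
         dimension = dimension, descriptor_kind = descriptor_kind,
         unit = as.character(unit), levels = levels),
    class = "criterion"
  )
}

#' @export
print.criterion <- function(x, ...) {
  cat(sprintf("<criterion> %s (%s, %s)\n", x$id, x$dimension, x$descriptor_kind))
  if (nzchar(x$unit)) cat("  unit:", x$unit, "\n")
  lv <- x$levels
  tag <- ifelse(lv$is_good, " (Good)", ifelse(lv$is_neutral, " (Neutral)", ""))
  perf <- ifelse(is.na(lv$performance), lv$label, format(lv$performance))
  cat(sprintf("  L%d: %s%s\n", lv$index, perf, tag), sep = "")
  invisible(x)
}

#' Cardinal value scale of a criterion
#'
#' Associates each descriptor level with a value in points, on the scale
#' anchored at Neutral = 0 and Good = 100. Values must not increase with
#' decreasing attractiveness rank.
#'
#' @param criterion_id id of the criterion the scale belongs to.
#' @param values numeric vector of level values, in attractiveness order
#'   (one per descriptor level).
#' @return an object of class `value_scale` with an `anchors` data.frame
#'   (`index`, `value`).
#' @export
value_scale <- function(criterion_id, values) {
  structure(
    list(criterion_id = as.character(criterion_id),
         anchors = data.frame(index = seq_along(values),
                              value = as.numeric(values))),
    class = "value_scale"
  )
}

#' @export
print.value_scale <- function(x, ...) {
  cat(sprintf("<value_scale> %s: %s\n", x$criterion_id,
              paste(format(x$anchors$value), collapse = ", ")))
  invisible(x)
}

#' Named values of a scale
#'
#' Returns the scale as a named numeric vector keyed by level (`L1`, `L2`,
#' ...), convenient for [validation_ratio()] and tests.
#'
#' @param scale a `value_scale`.
#' @return named numeric vector.
#' @export
scale_values <- function(scale) {
  stats::setNames(scale$anchors$value, paste0("L", scale$anchors$index))
}

#' Multicriteria value model
#'
#' Bundles the value tree leaves: criteria with their descriptors, one
#' cardinal value scale per criterion, and a normalized positive weight
#' vector. Global values of alternatives are the weighted sums
#' `V(a) = sum_j w_j * v_j(a)` with `sum_j w_j = 1`, `w_j > 0`.
#'
#' @param criteria list of [criterion()] objects.
#' @param scales list of [value_scale()] objects, one per criterion.
#' @param weights named numeric vector `criterion id -> weight`.
#' @param metadata optional list (`name`, `provenance`, ...).
#' @return object of class `mcda_model`.
#' @export
mcda_model <- function(criteria, scales, weights, metadata = list()) {
  names(criteria) <- vapply(criteria, `[[`, "", "id")
  names(scales) <- vapply(scales, `[[`, "", "criterion_id")
  structure(
    list(criteria = criteria, scales = scales,
         weights = weights, metadata = metadata),
    class = "mcda_model"
  )
}

#' @export
print.mcda_model <- function(x, ...) {
  cat(sprintf("<mcda_model> %s\n", x$metadata$name %||% "(unnamed)"))
  cat(sprintf("  %d criteria across %d dimensions; weights sum to %.4f\n",
              length(x$criteria),
              length(unique(vapply(x$criteria, `[[`, "", "dimension"))),
              sum(x$weights)))
  invisible(x)
}

#' Criterion ids of a model
#' @param model an `mcda_model`.
#' @return character vector.
#' @export
criterion_ids <- function(model) names(model$criteria)

#' Substitution scenario
#'
#' @param id scenario identifier (e.g. `"25%"`).
#' @param country country label.
#' @param substitution_fraction fraction of the baseline food replaced,
#'   in `[0, 1]`.
#' @param description free text.
#' @return object of class `scenario`.
#' @export
scenario <- function(id, country = "", substitution_fraction = NA_real_,
                     description = "") {
  f <- substitution_fraction
  if (!is.na(f) && (f < 0 || f > 1)) stop("substitution_fraction must lie in [0, 1]")
  structure(list(id = as.character(id), country = country,
                 substitution_fraction = f, description = description),
            class = "scenario")
}

new_validation_report <- function(rows) {
  if (length(rows) == 0) {
    rep_df <- data.frame(criterion_id = character(), rule = character(),
                         message = character(), stringsAsFactors = FALSE)
  } else {
    rep_df <- do.call(rbind, rows)
  }
  class(rep_df) <- c("validation_report", "data.frame")
  rep_df
}

viol <- function(id, rule, msg) {
  data.frame(criterion_id = id, rule = rule, message = msg,
             stringsAsFactors = FALSE)
}

#' Validate a multicriteria model
#'
#' Checks every structural invariant of the model and returns a report
#' instead of raising: each criterion has exactly one Neutral and one Good
#' level with Good at least as attractive as Neutral; quantitative
#' performances are strictly monotone along the attractiveness order;
#' categorical descriptors have at least two distinct labels; each scale
#' maps Neutral to 0 and Good to 100 exactly and is non-increasing in rank;
#' criteria, scales and weights are in one-to-one correspondence; weights
#' are strictly positive and sum to 1 (tolerance 1e-9).
#'
#' @param model an [mcda_model()].
#' @return a `validation_report` data.frame (`criterion_id`, `rule`,
#'   `message`); zero rows when the model is valid.
#' @examples
#' m <- synth_model(seed = 1)
#' nrow(validate_model(m)) == 0
#' @export
validate_model <- function(model) {
  rows <- list()
  add <- function(v) rows[[length(rows) + 1L]] <<- v

  crit_ids <- names(model$criteria)
  scale_ids <- names(model$scales)
  w <- model$weights

  if (!setequal(crit_ids, scale_ids) || anyDuplicated(crit_ids) || anyDuplicated(scale_ids)) {
    add(viol("*", "one_to_one", "criteria and scales are not in one-to-one correspondence"))
  }
  if (!setequal(crit_ids, names(w))) {
    add(viol("*", "one_to_one", "weights do not cover exactly the model criteria"))
  }
  if (any(w <= 0)) {
    add(viol(paste(names(w)[w <= 0], collapse = ","), "weights_positive",
             "all weights must be strictly positive"))
  }
  if (abs(sum(w) - 1) > 1e-9) {
    add(viol("*", "weights_sum",
             sprintf("weights sum to %.6f, not 1", sum(w))))
  }

  for (cr in model$criteria) {
    lv <- cr$levels
    if (anyDuplicated(lv$index)) {
      add(viol(cr$id, "index_unique", "duplicate level indices"))
    }
    if (sum(lv$is_neutral) != 1L || sum(lv$is_good) != 1L) {
      add(viol(cr$id, "neutral_good_unique",
               "exactly one Neutral and one Good level required"))
      next
    }
    if (which(lv$is_good) > which(lv$is_neutral)) {
      add(viol(cr$id, "good_before_neutral",
               "Good must be at least as attractive as Neutral"))
    }
    if (cr$descriptor_kind == "quantitative") {
      p <- lv$performance
      if (anyNA(p)) {
        add(viol(cr$id, "monotone_performance",
                 "quantitative descriptor has non-numeric levels"))
      } else {
        d <- diff(p)
        if (!(all(d > 0) || all(d < 0))) {
          add(viol(cr$id, "monotone_performance",
                   "performances must be strictly monotone along the level order"))
        }
      }
    } else {
      if (length(unique(lv$label)) < 2L) {
        add(viol(cr$id, "categorical_levels",
                 "categorical descriptor needs >= 2 distinct labels"))
      }
    }
    sc <- model$scales[[cr$id]]
    if (is.null(sc)) next
    v <- sc$anchors$value
    if (length(v) != nrow(lv)) {
      add(viol(cr$id, "scale_levels", "scale and descriptor level counts differ"))
      next
    }
    if (abs(v[which(lv$is_neutral)]) > 1e-9) {
      add(viol(cr$id, "neutral_zero", "Neutral anchor value must be 0"))
    }
    if (abs(v[which(lv$is_good)] - 100) > 1e-9) {
      add(viol(cr$id, "good_hundred", "Good anchor value must be 100"))
    }
    if (any(diff(v) > 1e-9)) {
      add(viol(cr$id, "values_nonincreasing",
               "values must not increase with decreasing attractiveness"))
    }
  }
  new_validation_report(rows)
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> model valid (no violations)\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s):\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}

#' Performance table
#'
#' Rows are scenarios, columns criteria. Quantitative cells hold numbers on
#' the criterion's performance axis, categorical cells hold level labels,
#' `NA` marks MISSING evidence. The first column must be named `scenario`.
#'
#' @param df a data.frame with a `scenario` column and one column per
#'   criterion id.
#' @param model optional [mcda_model()] to check the columns against; a
#'   column not naming a model criterion is an error.
#' @return the data.frame, classed `performance_table`.
#' @export
performance_table <- function(df, model = NULL) {
  if (!"scenario" %in% names(df)) stop("performance table needs a `scenario` column")
  if (anyDuplicated(df$scenario)) stop("duplicate scenario ids")
  if (!is.null(model)) {
    unknown <- setdiff(setdiff(names(df), "scenario"), criterion_ids(model))
    if (length(unknown)) {
      stop("unknown criterion column(s): ", paste(unknown, collapse = ", "))
    }
  }
  class(df) <- c("performance_table", "data.frame")
  df
}
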