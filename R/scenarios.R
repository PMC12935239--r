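#' Substitution design
#'
#' Describes a family of substitution scenarios between a reference diet
#' (substitution fraction f = 0) and a full-replacement endpoint (f = 1).
#' Intermediate scenarios are built by convex combination of the two rows.
#'
#' @param reference_row named list/vector of performances at f = 0.
#' @param endpoint_row named list/vector of performances at f = 1 (same
#'   criteria as `reference_row`).
#' @param fractions numeric vector of substitution fractions in `[0, 1]`.
#' @return object of class `substitution_design`.
#' @export
substitution_design <- function(reference_row, endpoint_row,
                                fractions = c(0.25, 0.5, 0.75, 1)) {
  if (!setequal(names(reference_row), names(endpoint_row))) {
    stop("reference and endpoint rows must share the same criteria")
  }
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  structure(list(reference_row = as.list(reference_row),
                 endpoint_row = as.list(endpoint_row)[names(reference_row)],
                 fractions = fractions),
            class = "substitution_design")
}

#' Blend a substitution scenario
#'
#' Each quantitative cell is the convex combination
#' `(1 - f) * reference + f * endpoint`; categorical cells are copied from
#' the nearer endpoint (ties go to the reference).
#'
#' @param design a [substitution_design()].
#' @param f substitution fraction in `[0, 1]`.
#' @return named list: the blended performance row.
#' @examples
#' d <- substitution_design(list(water = 33.5), list(water = 17.4))
#' blend_scenario(d, 0.25)$water  # 29.475, printed as 29.5
#' @export
blend_scenario <- function(design, f) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  out <- design$reference_row
  for (nm in names(out)) {
    r <- design$reference_row[[nm]]
    e <- design$endpoint_row[[nm]]
    if (is.numeric(r) && is.numeric(e)) {
      out[[nm]] <- (1 - f) * r + f * e
    } else {
      out[[nm]] <- if (f > 0.5) e else r
    }
  }
  out
}

#' Blend a full scenario table
#'
#' @param design a [substitution_design()].
#' @param fractions overrides `design$fractions` when given.
#' @return a data.frame with a `scenario` column (`"<100 f>%"`) and one
#'   column per criterion.
#' @export
blend_table <- function(design, fractions = NULL) {
  fr <- fractions %||% design$fractions
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  rows <- lapply(fr, function(f) as.data.frame(blend_scenario(design, f)))
  out <- do.call(rbind, rows)
  cbind(data.frame(scenario = paste0(round(100 * fr), "%")), out)
}

#' Beef-to-pulses case study fixtures
#'
#' Returns the packaged 14-criterion model (descriptors, cardinal value
#' scales and swing weights) together with the country's scenario evidence
#' (performance table), the published partial-value table and the published
#' global scores. The same value model serves both countries; evidence and
#' partials differ. `globals` carries the published score next to the score
#' recomputed here from the published partials and weights, plus a
#' `self_consistent` flag (agreement within 0.05 points): three published
#' rows (DK 100%, DK 0%, PT 0%) are not reproducible from their own printed
#' partials and are flagged FALSE.
#'
#' Only evidence cells whose units match the criterion descriptors are
#' carried in `performance` (economic % changes, DALY totals and the
#' environmental indicators); the remaining criteria enter evaluations via
#' the published partials.
#'
#' @param country `"PT"` (Portugal) or `"DK"` (Denmark).
#' @return list with elements `country`, `model`, `performance`,
#'   `partials`, `globals`, `scenarios`.
#' @examples
#' cs <- case_study("PT")
#' length(cs$model$criteria)  # 14
#' @export
case_study <- function(country = c("PT", "DK")) {
  country <- match.arg(country)
  model <- load_model(dietmcda_file("model_beef_pulses.json"))
  perf <- load_performance(
    dietmcda_file(sprintf("performance_%s.csv", tolower(country))), model)
  partials <- utils::read.csv(
    dietmcda_file(sprintf("partials_%s.csv", tolower(country))),
    check.names = FALSE, stringsAsFactors = FALSE)
  glob <- utils::read.csv(dietmcda_file("globals_printed.csv"),
                          stringsAsFactors = FALSE)
  glob <- glob[glob$country == country, c("scenario", "printed")]
  res <- suppressWarnings(evaluate(model, partial_overrides = partials))
  glob$recomputed <- as.numeric(res$globals[glob$scenario])
  glob$self_consistent <- abs(glob$recomputed - glob$printed) <= 0.05
  scen <- lapply(seq_len(nrow(perf)), function(i) {
    id <- perf$scenario[i]
    scenario(id, country = country,
             substitution_fraction = as.numeric(sub("%", "", id)) / 100)
  })
  list(country = country, model = model, performance = perf,
       partials = partials, globals = glob, scenarios = scen)
}

#' Evaluate the case study
#'
#' Reproduction mode (`recompute = FALSE`) scores the scenarios from the
#' published partial-value table alone. Recompute mode converts the
#' evidence into partial values through the packaged value functions
#' wherever the performance is available, falling back on the published
#' partials for the remaining criteria.
#'
#' @param country `"PT"` or `"DK"`.
#' @param recompute recompute partials from evidence where possible.
#' @return an `evaluation_result`.
#' @export
case_study_evaluation <- function(country = c("PT", "DK"), recompute = FALSE) {
  cs <- case_study(country)
  if (!recompute) {
    return(suppressWarnings(evaluate(cs$model, partial_overrides = cs$partials)))
  }
  # evidence takes precedence: blank out overrides wherever a performance
  # cell is available
  ov <- cs$partials
  for (j in intersect(names(cs$performance), names(ov))) {
    if (j == "scenario") next
    rows <- match(cs$performance$scenario, ov$scenario)
    has_perf <- !is.na(cs$performance[[j]])
    ov[[j]][rows[has_perf]] <- NA
  }
  suppressWarnings(evaluate(cs$model, table = cs$performance, partial_overrides = ov))
}

dietmcda_file <- function(...) {
  path <- system.file("extdata", ..., package = "dietmcda", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    # during in-source development (pkgload)
    path <- file.path("inst", "extdata", ...)
  }
  if (!file.exists(path)) stop("fixture not found: ", file.path(...))
  path
}

with_seed <- function(seed, code) {
  # run code under a private RNG state; never disturbs the caller's stream
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random valid model
#'
#' Draws quantitative criteria with strictly monotone descriptor levels,
#' strictly decreasing cardinal scales anchored at Neutral = 0 / Good = 100,
#' and Dirichlet-distributed positive weights summing to 1. The output
#' always passes [validate_model()]; the same seed reproduces the same
#' model.
#'
#' @param seed integer seed.
#' @param n_criteria number of criteria (>= 2).
#' @param n_levels descriptor levels per criterion (>= 3).
#' @return an [mcda_model()].
#' @export
synth_model <- function(seed, n_criteria = 4, n_levels = 5) {
  if (n_criteria < 2 || n_levels < 3) stop("degenerate sizes")
  with_seed(seed, {
    dims <- c("health", "environmental", "economic", "social")
    crits <- list(); scales <- list()
    for (i in seq_len(n_criteria)) {
      id <- sprintf("c%02d", i)
      # performance strictly monotone along attractiveness; random orientation
      perf <- cumsum(stats::runif(n_levels, 0.5, 2))
      if (stats::runif(1) < 0.5) perf <- rev(perf)
      good <- sample.int(n_levels - 1L, 1)
      cand <- (good + 1L):n_levels
      neutral <- cand[sample.int(length(cand), 1)]
      # strictly decreasing values hitting the two anchors exactly
      gaps <- stats::runif(n_levels - 1L, 5, 60)
      raw <- c(0, -cumsum(gaps))                     # decreasing from 0
      v <- (raw - raw[neutral]) / (raw[good] - raw[neutral]) * 100
      crits[[i]] <- criterion(id, paste("criterion", i), sample(dims, 1),
                              "quantitative", unit = "units",
                              levels = descriptor_levels(performance = perf,
                                                         neutral = neutral,
                                                         good = good))
      scales[[i]] <- value_scale(id, v)
    }
    w <- stats::rgamma(n_criteria, shape = 2)
    w <- w / sum(w)
    names(w) <- sprintf("c%02d", seq_len(n_criteria))
    mcda_model(crits, scales, w,
               metadata = list(name = sprintf("synthetic model (seed %d)", seed),
                               provenance = "synthetic"))
  })
}

#' Generate a consistent judgment matrix from a hidden scale
#'
#' Draws a hidden cardinal scale, computes all pairwise value differences
#' and bins them into the seven semantic categories with thresholds fixed at
#' equal sixths of the largest difference (a zero difference is "null").
#' Because the categories are a monotone function of the differences, the
#' resulting matrix is always consistent, and the hidden scale is returned
#' for recovery tests.
#'
#' @param seed integer seed.
#' @param n_entities number of entities (>= 2).
#' @param tie_prob probability that an entity duplicates the previous
#'   entity's hidden value, exercising "null" judgments.
#' @return a [judgment_matrix()] with attribute `hidden_values` (named
#'   numeric, the generating scale).
#' @export
generate_consistent_matrix <- function(seed, n_entities = 5, tie_prob = 0.15) {
  if (n_entities < 2) stop("degenerate sizes")
  with_seed(seed, {
    steps <- stats::runif(n_entities - 1L, 0.5, 3)
    steps[stats::runif(n_entities - 1L) < tie_prob] <- 0
    hidden <- rev(cumsum(c(0, steps)))   # e1 most attractive
    if (max(hidden) == 0) hidden[1] <- hidden[1] + 1  # avoid all-equal
    ent <- sprintf("e%d", seq_len(n_entities))
    names(hidden) <- ent
    dmax <- max(hidden) - min(hidden)
    pairs <- utils::combn(n_entities, 2)
    j <- data.frame(a = ent[pairs[1, ]], b = ent[pairs[2, ]],
                    category = NA_integer_, stringsAsFactors = FALSE)
    d <- hidden[pairs[1, ]] - hidden[pairs[2, ]]
    j$category <- ifelse(d == 0, 0L, pmin(6L, ceiling(d / dmax * 6)))
    jm <- judgment_matrix(ent, j)
    attr(jm, "hidden_values") <- hidden
    jm
  })
}
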