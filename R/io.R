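MODEL_SCHEMA_VERSION <- 1L

#' Save a model to structured text
#'
#' Writes the model as a versioned JSON document with top-level keys
#' `schema_version`, `metadata`, `criteria`, `scales`, `weights`.
#' [load_model()] restores it field-by-field.
#'
#' @param model an [mcda_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    metadata = model$metadata,
    criteria = lapply(unname(model$criteria), function(cr) {
      lv <- cr$levels
      list(id = cr$id, name = cr$name, dimension = cr$dimension,
           descriptor_kind = cr$descriptor_kind, unit = cr$unit,
           levels = lapply(seq_len(nrow(lv)), function(i) {
             out <- list(index = lv$index[i])
             if (!is.na(lv$performance[i])) out$performance <- lv$performance[i]
             if (!is.na(lv$label[i])) out$label <- lv$label[i]
             out$is_neutral <- lv$is_neutral[i]
             out$is_good <- lv$is_good[i]
             if (!is.na(lv$note[i])) out$note <- lv$note[i]
             out
           }))
    }),
    scales = lapply(unname(model$scales), function(sc) {
      list(criterion_id = sc$criterion_id, values = sc$anchors$value)
    }),
    weights = as.list(model$weights)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

need_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop(sprintf("model file invalid at %s: missing key `%s`", where, key))
  }
  x[[key]]
}

#' Load a model from structured text
#'
#' @param path path to a JSON model file written by [save_model()].
#' @return an [mcda_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("schema_version", "criteria", "scales", "weights")) {
    need_key(doc, key, path)
  }
  criteria <- lapply(doc$criteria, function(cr) {
    id <- need_key(cr, "id", paste0(path, ":criteria"))
    lvs <- need_key(cr, "levels", paste0(path, ":criteria:", id))
    lv <- data.frame(
      index = vapply(lvs, function(l) as.integer(l$index), 0L),
      performance = vapply(lvs, function(l) as.numeric(l$performance %||% NA_real_), 0),
      label = vapply(lvs, function(l) as.character(l$label %||% NA_character_), ""),
      is_neutral = vapply(lvs, function(l) isTRUE(l$is_neutral), TRUE),
      is_good = vapply(lvs, function(l) isTRUE(l$is_good), TRUE),
      note = vapply(lvs, function(l) as.character(l$note %||% NA_character_), ""),
      stringsAsFactors = FALSE
    )
    criterion(id, need_key(cr, "name", id), need_key(cr, "dimension", id),
              need_key(cr, "descriptor_kind", id), cr$unit %||% "", lv)
  })
  scales <- lapply(doc$scales, function(sc) {
    value_scale(need_key(sc, "criterion_id", paste0(path, ":scales")),
                vapply(sc$values, as.numeric, 0))
  })
  w <- vapply(doc$weights, as.numeric, 0)
  mcda_model(criteria, scales, w, metadata = doc$metadata %||% list())
}

# Normalize a textual number: European decimal commas ("-7,90") and the
# Unicode minus sign (U+2212) both occur in published tables.
normalize_number <- function(x) {
  x <- gsub("−", "-", trimws(x))
  comma <- grepl("^-?[0-9]+,[0-9]+$", x)
  x[comma] <- sub(",", ".", x[comma], fixed = TRUE)
  x
}

#' Load a performance table from delimited text
#'
#' Comma-separated, UTF-8, first column `scenario`, one column per
#' criterion id; blank cells are MISSING. European decimal commas and
#' Unicode minus signs are normalized on ingest (the conversion count is
#' reported as a message).
#'
#' @param path CSV file path.
#' @param model optional [mcda_model()]: columns are checked against the
#'   model's criteria and quantitative columns coerced to numeric.
#' @return a [performance_table()].
#' @export
load_performance <- function(path, model = NULL) {
  if (!file.exists(path)) stop("performance file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  if (!"scenario" %in% names(df)) stop("performance table needs a `scenario` column")
  n_norm <- 0L
  for (j in setdiff(names(df), "scenario")) {
    raw <- df[[j]]
    raw[raw == ""] <- NA
    norm <- normalize_number(raw)
    n_norm <- n_norm + sum(norm != raw, na.rm = TRUE)
    quantitative <- if (!is.null(model) && j %in% criterion_ids(model)) {
      model$criteria[[j]]$descriptor_kind == "quantitative"
    } else {
      all(is.na(norm) | grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", norm))
    }
    df[[j]] <- if (quantitative) as.numeric(norm) else norm
  }
  if (n_norm > 0) message(sprintf("normalized %d decimal-comma/minus-sign cell(s)", n_norm))
  performance_table(df, model)
}

#' Model checksum
#'
#' MD5 of the canonical JSON serialization; recorded in reports so a result
#' can be traced to the exact model that produced it.
#'
#' @param model an [mcda_model()].
#' @return a 32-character hex string.
#' @export
model_checksum <- function(model) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_model(model, tmp)
  unname(tools::md5sum(tmp))
}

#' Write an evaluation report
#'
#' JSON reports carry the partial values, global scores, ranking, weights,
#' the missing-cell log, the model checksum, seed and free-text provenance
#' notes. The delimited-text format mirrors the published layout: one row
#' per scenario with the global score first, then the partials.
#'
#' @param result an `evaluation_result`.
#' @param path output file.
#' @param model optional model, for the checksum.
#' @param seed seed recorded in the report.
#' @param notes character vector of provenance notes.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, model = NULL, seed = NULL,
                         notes = character(), format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(scenario = names(result$globals),
                     global = as.numeric(result$globals))
    df <- cbind(df, as.data.frame(result$partials))
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  doc <- list(
    globals = as.list(result$globals),
    ranking = result$ranking,
    partials = cbind(data.frame(scenario = rownames(result$partials)),
                     as.data.frame(result$partials)),
    weights = as.list(result$weights),
    missing_cells = result$missing_cells,
    notes = as.list(notes)
  )
  if (!is.null(model)) doc$model_checksum <- model_checksum(model)
  if (!is.null(seed)) doc$seed <- seed
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Load a judgment matrix from structured text
#'
#' JSON with keys `entities` (ordered array) and `judgments` (array of
#' `[a, b, category]` triplets; categories are names, indices, or
#' `"<cat> to <cat>"` ranges).
#'
#' @param path JSON file path.
#' @return a [judgment_matrix()].
#' @export
load_judgments <- function(path) {
  if (!file.exists(path)) stop("judgment file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ent <- vapply(need_key(doc, "entities", path), as.character, "")
  js <- need_key(doc, "judgments", path)
  j <- data.frame(
    a = vapply(js, function(x) as.character(x[[1]]), ""),
    b = vapply(js, function(x) as.character(x[[2]]), ""),
    category = vapply(js, function(x) as.character(x[[3]]), ""),
    stringsAsFactors = FALSE
  )
  judgment_matrix(ent, j)
}

#' Save a judgment matrix
#' @param matrix a [judgment_matrix()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_judgments <- function(matrix, path) {
  j <- matrix$judgments
  cat_name <- ifelse(j$lo == j$hi, semantic_categories[j$lo + 1],
                     paste(semantic_categories[j$lo + 1], "to",
                           semantic_categories[j$hi + 1]))
  doc <- list(entities = matrix$entities,
              judgments = lapply(seq_len(nrow(j)), function(i) {
                list(j$a[i], j$b[i], cat_name[i])
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
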