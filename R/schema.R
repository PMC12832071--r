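#' Default BPS + KADS item schema
#'
#' Builds the 20-item schema used throughout the package: the 9-item Bedtime
#' Procrastination Scale (BPS, 5-point Likert scored 1--5) and the 11-item
#' Kutcher Adolescent Depression Scale (KADS, 4-point scale scored 0--3).
#' The positively worded BPS items (going to bed early, turning lights off
#' immediately, keeping a regular routine, stopping activities easily) carry
#' a reverse-coding flag so that, after [reverse_code()], every BPS node
#' points toward "more procrastination". The reverse set is a package
#' default, not a property of the instruments, and can be overridden.
#'
#' @return A `data.frame` of class `item_schema` with columns `item_id`,
#'   `wording`, `scale_min`, `scale_max`, `reverse_coded`, `domain_label`.
#' @export
#' @examples
#' sch <- bps_kads_schema()
#' table(substr(sch$item_id, 1, 3))
bps_kads_schema <- function() {
  bps <- data.frame(
    item_id = paste0("BPS", 1:9),
    wording = c(
      "I go to bed later than I had intended",
      "I go to bed early even without an early morning",
      "I turn off the lights at bedtime immediately",
      "I am still doing other things when it is time to go to bed",
      "I get easily distracted by other activities when sleepy",
      "I do not go to bed on time",
      "I have a regular bedtime routine",
      "I want to go to bed on time but cannot make myself",
      "I can easily stop what I am doing at bedtime"
    ),
    scale_min = 1L, scale_max = 5L,
    reverse_coded = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    domain_label = c(
      "intention-behavior gap", "routine adherence", "sleep hygiene",
      "behavioral delay", "impulse control", "behavioral delay",
      "regularity", "intention-action gap", "self-control"
    )
  )
  kads <- data.frame(
    item_id = paste0("KADS", 1:11),
    wording = c(
      "Physical feelings of worry",
      "Thoughts of suicide or self-harm",
      "Feelings of worthlessness or hopelessness",
      "Feeling worried, nervous or tense",
      "Irritability",
      "Trouble concentrating",
      "Feeling that life is not much fun",
      "Low mood or sadness",
      "Feeling tired or low in energy",
      "Decreased interest",
      "Sleep difficulties"
    ),
    scale_min = 0L, scale_max = 3L,
    reverse_coded = FALSE,
    domain_label = c(
      "physiological arousal", "suicidality", "self-esteem",
      "affective tension", "irritability", "attention", "anhedonia",
      "depressed mood", "fatigue", "motivation", "sleep disturbance"
    )
  )
  out <- rbind(bps, kads)
  class(out) <- c("item_schema", "data.frame")
  validate_schema(out)
  out
}

#' @noRd
validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("item_id", "scale_min", "scale_max") %in% names(schema)))
  if (anyDuplicated(schema$item_id)) stop("duplicate item ids in schema")
  if (any(schema$scale_min >= schema$scale_max)) {
    stop("schema requires scale_min < scale_max for every item")
  }
  invisible(schema)
}

#' Construct a two-wave panel dataset
#'
#' Container for wide-format ordinal panel data: a subjects x items x waves
#' array (missing cells are `NA`), a group factor (e.g. sex), and the item
#' schema. Observed values are validated against each item's scale range.
#'
#' @param values numeric array `n x p x n_waves`; `NA` marks missing cells.
#' @param group factor or character vector of length `n`.
#' @param schema an `item_schema` (see [bps_kads_schema()]).
#' @param wave_labels character vector naming the waves (default `T1`, `T3`).
#' @param id subject identifiers (default `S1..Sn`).
#' @param validate_range reject out-of-range observed values (default TRUE).
#' @return An object of class `panel_data`.
#' @export
panel_data <- function(values, group, schema, wave_labels = NULL, id = NULL,
                       validate_range = TRUE) {
  stopifnot(length(dim(values)) == 3)
  n <- dim(values)[1]; p <- dim(values)[2]; w <- dim(values)[3]
  if (p != nrow(schema)) stop("values has ", p, " items but schema has ",
                              nrow(schema))
  if (length(group) != n) stop("group length must match subject count")
  wave_labels <- wave_labels %||%
    (if (w == 2) c("T1", "T3") else paste0("W", seq_len(w)))
  id <- as.character(id %||% paste0("S", seq_len(n)))
  dimnames(values) <- list(id, schema$item_id, wave_labels)
  if (validate_range) {
    for (j in seq_len(p)) {
      v <- values[, j, , drop = FALSE]
      bad <- !is.na(v) & (v < schema$scale_min[j] | v > schema$scale_max[j])
      if (any(bad)) {
        stop("out-of-range values for item ", schema$item_id[j])
      }
    }
  }
  structure(list(values = values, group = factor(group), schema = schema,
                 wave_labels = wave_labels, id = id),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  d <- dim(x$values)
  cat("<panel_data> ", d[1], " subjects x ", d[2], " items x ", d[3],
      " waves (", paste(x$wave_labels, collapse = ", "), ")\n", sep = "")
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group),
                                 tabulate(x$group)), collapse = ", "), "\n")
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
#' @rdname panel_data
missing_mask <- function(data) is.na(data$values)

#' Extract one wave as a subjects x items matrix
#' @param data a `panel_data` object.
#' @param wave wave label or index.
#' @return numeric matrix `n x p` (with `NA` for missing cells).
#' @export
wave_matrix <- function(data, wave) {
  data$values[, , wave, drop = TRUE]
}

# Wide matrix: columns item_wave in the canonical file order.
#' @noRd
panel_wide <- function(data) {
  w <- length(data$wave_labels)
  cols <- lapply(seq_len(w), function(k) wave_matrix(data, k))
  out <- do.call(cbind, cols)
  colnames(out) <- unlist(lapply(data$wave_labels, function(lab)
    paste0(data$schema$item_id, "_", lab)))
  out
}

# Rebuild a panel_data from a wide matrix with the same layout.
#' @noRd
panel_from_wide <- function(wide, template, validate_range = TRUE) {
  p <- nrow(template$schema); w <- length(template$wave_labels)
  arr <- array(NA_real_, c(nrow(wide), p, w))
  for (k in seq_len(w)) {
    arr[, , k] <- as.matrix(
      wide[, paste0(template$schema$item_id, "_", template$wave_labels[k])])
  }
  panel_data(arr, template$group, template$schema,
             wave_labels = template$wave_labels, id = template$id,
             validate_range = validate_range)
}

#' Read wide-format panel data from a delimited text file
#'
#' Expects one row per subject with an id column, a group column, and one
#' column per item/wave named `<item_id>_<wave>` (e.g. `BPS1_T1`). The
#' delimiter is chosen from the file extension (`.tsv` = tab, otherwise
#' comma). Empty cells and `NA` are treated as missing.
#'
#' @param path file path.
#' @param schema item schema; default [bps_kads_schema()].
#' @param id_col,group_col column names for subject id and group.
#' @param wave_labels waves expected in the file, default `c("T1","T3")`.
#' @param on_range `"error"` rejects out-of-range values; `"flag"` converts
#'   them to missing with a warning.
#' @return A [panel_data] object.
#' @export
load_panel <- function(path, schema = bps_kads_schema(), id_col = "id",
                       group_col = "sex", wave_labels = c("T1", "T3"),
                       on_range = c("error", "flag")) {
  on_range <- match.arg(on_range)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, na.strings = c("", "NA"),
                 check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c(id_col, group_col,
              as.vector(outer(schema$item_id, wave_labels, paste, sep = "_")))
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  item_cols <- setdiff(needed, c(id_col, group_col))
  for (cn in item_cols) {
    v <- df[[cn]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(df[[cn]]) & is.na(v))
    if (length(bad)) {
      stop("non-numeric value in column ", cn, " at row ", bad[1],
           call. = FALSE)
    }
    if (any(!is.na(v) & v != round(v))) {
      stop("non-integer value in column ", cn, " at row ",
           which(!is.na(v) & v != round(v))[1], call. = FALSE)
    }
    df[[cn]] <- v
  }
  n <- nrow(df); p <- nrow(schema); w <- length(wave_labels)
  arr <- array(NA_real_, c(n, p, w))
  for (k in seq_len(w)) {
    arr[, , k] <- as.matrix(df[paste0(schema$item_id, "_", wave_labels[k])])
  }
  if (on_range == "flag") {
    for (j in seq_len(p)) {
      v <- arr[, j, ]
      bad <- !is.na(v) & (v < schema$scale_min[j] | v > schema$scale_max[j])
      if (any(bad)) {
        warning(sum(bad), " out-of-range value(s) for ", schema$item_id[j],
                " set to missing")
        v[bad] <- NA
        arr[, j, ] <- v
      }
    }
  }
  panel_data(arr, df[[group_col]], schema, wave_labels = wave_labels,
             id = df[[id_col]])
}

#' Write a panel dataset back to delimited text
#'
#' Inverse of [load_panel()]: writes `id,sex,<item>_<wave>...` with empty
#' cells for missing values. Round-trips exactly with [load_panel()].
#'
#' @param data a `panel_data` object.
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @param group_col name for the group column (default `"sex"`).
#' @export
write_panel <- function(data, path, group_col = "sex") {
  wide <- panel_wide(data)
  df <- data.frame(id = data$id, group = as.character(data$group),
                   wide, check.names = FALSE)
  names(df)[2] <- group_col
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Serialize an item schema to JSON
#' @param schema an `item_schema`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
schema_to_json <- function(schema, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(schema), pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Reverse-code selected items
#'
#' Reflects each flagged item about its scale midpoint
#' (`v -> scale_min + scale_max - v`); missing cells are untouched. Applying
#' the function twice with the same item set is the identity.
#'
#' @param data a `panel_data` object.
#' @param items character vector of item ids; defaults to the schema's
#'   `reverse_coded` flags.
#' @return A `panel_data` with the recoded values.
#' @export
reverse_code <- function(data, items = NULL) {
  sch <- data$schema
  items <- items %||% sch$item_id[sch$reverse_coded]
  unknown <- setdiff(items, sch$item_id)
  if (length(unknown)) {
    stop("unknown item id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- data$values
  for (it in items) {
    j <- match(it, sch$item_id)
    vals[, j, ] <- sch$scale_min[j] + sch$scale_max[j] - vals[, j, ]
  }
  out <- data
  out$values <- vals
  dimnames(out$values) <- dimnames(data$values)
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \deqn{\alpha = \frac{k}{k-1}\Bigl(1 - \frac{\sum_i var(x_i)}{var(\sum_i x_i)}\Bigr)}
#' computed on complete cases. May be negative for incoherent item sets.
#'
#' @param items_matrix numeric matrix, subjects x items.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items_matrix) {
  X <- as.matrix(items_matrix)
  X <- X[complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2) stop("need at least 2 items")
  if (nrow(X) < 3) stop("need at least 3 complete cases")
  total_var <- var(rowSums(X))
  if (total_var == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(X, 2, var)) / total_var)
}
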