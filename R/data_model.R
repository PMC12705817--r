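#' Construct a validated EMA panel
#'
#' An EMA panel is a long-format table with one row per completed prompt and
#' one column per item. Wellbeing items are expected to be stored
#' reverse-coded already ("Lacking-..."); use [read_ema_table()] to ingest raw
#' files with positively coded wellbeing columns.
#'
#' @param data A data.frame with columns `subject_id`, `day`, `prompt` and one
#'   numeric column per item (missing item values allowed as `NA`).
#' @param items Character vector of item columns, in canonical order. Defaults
#'   to the intersection of [ema_item_names()] with `names(data)`.
#' @param prompts_per_day,days Sampling design (default 8 prompts x 6 days).
#' @return An object of class `ema_panel`.
#' @export
ema_panel <- function(data, items = NULL, prompts_per_day = 8L, days = 6L) {
  stopifnot(is.data.frame(data))
  req <- c("subject_id", "day", "prompt")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("panel data lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(items)) items <- intersect(ema_item_names(), names(data))
  if (!length(items)) stop("no item columns found")
  absent <- setdiff(items, names(data))
  if (length(absent)) stop("item column(s) absent: ", paste(absent, collapse = ", "))

  data$subject_id <- as.character(data$subject_id)
  data$day <- as.integer(data$day)
  data$prompt <- as.integer(data$prompt)
  if (any(data$day < 1L)) stop("day index must be >= 1")
  bad_prompt <- which(data$prompt < 1L | data$prompt > prompts_per_day)
  if (length(bad_prompt)) {
    stop("prompt index outside [1, ", prompts_per_day, "] in row(s): ",
         paste(utils::head(bad_prompt, 5L), collapse = ", "))
  }
  if (any(data$day > days)) stop("day index exceeds design days = ", days)

  key <- paste(data$subject_id, data$day, data$prompt, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day, prompt) record(s), e.g. row ",
         which(duplicated(key))[1L])
  }
  for (it in items) {
    v <- data[[it]]
    if (!is.numeric(v)) stop("item column not numeric: ", it)
    ok <- is.na(v) |
      if (it %in% binary_ema_items()) v %in% c(0, 1) else (v >= 1 & v <= 7 & v == round(v))
    if (!all(ok)) {
      stop("item '", it, "' has out-of-range value in row ", which(!ok)[1L])
    }
  }
  per_subj <- table(data$subject_id)
  if (any(per_subj > prompts_per_day * days)) {
    stop("subject with more observations than the design maximum (",
         prompts_per_day * days, ")")
  }
  ord <- order(data$subject_id, data$day, data$prompt)
  data <- data[ord, c(req, intersect(names(data), "timestamp"), items), drop = FALSE]
  rownames(data) <- NULL
  structure(
    list(data = data, items = items,
         design = list(prompts_per_day = as.integer(prompts_per_day),
                       days = as.integer(days))),
    class = "ema_panel"
  )
}

#' @export
print.ema_panel <- function(x, ...) {
  cat(sprintf("<ema_panel> %d observations, %d subjects, %d items (%d x %d design)\n",
              nrow(x$data), length(unique(x$data$subject_id)), length(x$items),
              x$design$prompts_per_day, x$design$days))
  invisible(x)
}

#' Number of subjects in a panel
#' @param panel An `ema_panel`.
#' @return Integer count.
#' @export
n_subjects <- function(panel) length(unique(panel$data$subject_id))

#' Read an EMA table from CSV/TSV
#'
#' Reads a delimited file with one row per completed prompt, validates it, and
#' reverse-codes positively coded wellbeing items (`r' = 8 - r`, renamed to
#' `Lacking-...`). Columns already named `Lacking-...` are taken as coded.
#'
#' @param path File path (CSV, or TSV if the extension is `.tsv`).
#' @param schema Optional named character vector mapping file column names to
#'   canonical names (`c(file_column = "Canonical-Name")`).
#' @param reverse_code Apply wellbeing reverse-coding to positively named
#'   columns (default TRUE). With FALSE, positively named wellbeing columns
#'   are an error rather than silently kept.
#' @param prompts_per_day,days Sampling design passed to [ema_panel()].
#' @return An `ema_panel`.
#' @export
read_ema_table <- function(path, schema = NULL, reverse_code = TRUE,
                           prompts_per_day = 8L, days = 6L) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    hit <- names(df) %in% names(schema)
    names(df)[hit] <- schema[names(df)[hit]]
  }
  meta_cols <- c("subject_id", "day", "prompt", "timestamp")
  item_cols <- setdiff(names(df), meta_cols)
  wb <- wellbeing_item_map()
  known <- c(ema_item_names(), if (reverse_code) names(wb))
  unknown <- setdiff(item_cols, known)
  if (length(unknown)) {
    stop("unknown item column(s): ", paste(unknown, collapse = ", "),
         " (provide a schema mapping or rename)")
  }
  if (reverse_code) {
    for (pos in intersect(item_cols, names(wb))) {
      v <- df[[pos]]
      if (any(!is.na(v) & (v < 1 | v > 7))) {
        stop("wellbeing item '", pos, "' outside [1,7]; cannot reverse-code")
      }
      df[[wb[[pos]]]] <- 8 - v
      df[[pos]] <- NULL
    }
  }
  items <- intersect(ema_item_names(), names(df))
  ema_panel(df, items = items, prompts_per_day = prompts_per_day, days = days)
}

#' Write an EMA panel to CSV
#' @param panel An `ema_panel`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ema_table <- function(panel, path) {
  utils::write.csv(panel$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a validated clinical interview table
#'
#' One row per subject, 0--6 integer item scores.
#'
#' @param data A data.frame with a `subject_id` column and one numeric column
#'   per item.
#' @param items Item column names in canonical order; defaults to all
#'   non-`subject_id` columns.
#' @return An object of class `sips_table`.
#' @export
sips_table <- function(data, items = NULL) {
  stopifnot(is.data.frame(data))
  if (!"subject_id" %in% names(data)) stop("missing subject_id column")
  data$subject_id <- as.character(data$subject_id)
  dup <- duplicated(data$subject_id)
  if (any(dup)) stop("duplicated subject_id: ", data$subject_id[dup][1L])
  if (is.null(items)) items <- setdiff(names(data), "subject_id")
  for (it in items) {
    v <- data[[it]]
    if (!is.numeric(v)) stop("item column not numeric: ", it)
    bad <- !is.na(v) & (v < 0 | v > 6 | v != round(v))
    if (any(bad)) {
      stop("item '", it, "' has score outside [0,6] for subject ",
           data$subject_id[which(bad)[1L]])
    }
  }
  data <- data[order(data$subject_id), c("subject_id", items), drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, items = items, dropped_items = character(0)),
            class = "sips_table")
}

#' @export
print.sips_table <- function(x, ...) {
  cat(sprintf("<sips_table> %d subjects x %d items", nrow(x$data), length(x$items)))
  if (length(x$dropped_items)) {
    cat("; dropped:", paste(x$dropped_items, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Read a clinical interview table from CSV
#' @param path File path; first column (or a `subject_id` column) identifies
#'   subjects, remaining columns are 0--6 item scores.
#' @return A `sips_table`.
#' @export
read_sips_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) names(df)[1L] <- "subject_id"
  sips_table(df)
}

#' Write a clinical interview table to CSV
#' @param sips A `sips_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sips_table <- function(sips, path) {
  utils::write.csv(sips$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct cohort metadata
#'
#' Per-subject demographics, IQ and binary diagnosis flags.
#'
#' @param data A data.frame with columns `subject_id`, `age`, `sex` (M/F),
#'   `fsiq`, optional `n_assessments`, plus any number of 0/1 diagnosis
#'   columns.
#' @param panel Optional `ema_panel`; if given, metadata subjects must cover
#'   the panel's subjects and `n_assessments` is filled from the panel.
#' @return An object of class `cohort_metadata`.
#' @export
cohort_metadata <- function(data, panel = NULL) {
  stopifnot(is.data.frame(data))
  req <- c("subject_id", "age", "sex", "fsiq")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id)) stop("duplicated subject_id in metadata")
  if (!all(data$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  diag_cols <- setdiff(names(data), c(req, "n_assessments"))
  for (dc in diag_cols) {
    if (!all(data[[dc]] %in% c(0, 1, NA))) stop("diagnosis column not 0/1: ", dc)
  }
  if (!is.null(panel)) {
    missing_subj <- setdiff(unique(panel$data$subject_id), data$subject_id)
    if (length(missing_subj)) {
      stop("panel subject(s) absent from metadata: ",
           paste(utils::head(missing_subj, 5L), collapse = ", "))
    }
    counts <- table(panel$data$subject_id)
    data$n_assessments <- as.integer(counts[data$subject_id])
    data$n_assessments[is.na(data$n_assessments)] <- 0L
  }
  data <- data[order(data$subject_id), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, diagnoses = diag_cols), class = "cohort_metadata")
}

#' @export
print.cohort_metadata <- function(x, ...) {
  cat(sprintf("<cohort_metadata> %d subjects, %d diagnosis flags\n",
              nrow(x$data), length(x$diagnoses)))
  invisible(x)
}
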