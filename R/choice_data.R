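#' Encode labelled attribute levels for estimation
#'
#' Turns a long-format table of labelled attribute levels into the encoded
#' choice dataset the estimator consumes: log-level attributes become
#' `log(code)` (so the status-quo level contributes 0), species-presence
#' attributes become counts (large carnivores: none = 0, just lynx = 1,
#' just wolf = 1, both = 2; large herbivores: none = 0, elk = 1, bison = 2,
#' both = 3 under the default design), and cost passes through in EUR.
#'
#' Re-encoding an already encoded dataset is rejected rather than silently
#' re-applied.
#'
#' @param raw long-format `data.frame` with columns `respondent_id`, `task`,
#'   `alt`, `is_sq`, `chosen`, one character column per non-cost attribute
#'   holding level labels, and the numeric cost column.
#' @param design a [design_spec()].
#' @return A `choice_data` object: the same rows with attribute columns
#'   replaced by their numeric encodings, sorted by respondent, task,
#'   alternative, with the design attached as an attribute.
#' @examples
#' d <- rewilding_design()
#' raw <- data.frame(respondent_id = 1, task = 0, alt = 0:1, is_sq = c(1, 0),
#'                   forest = c("status quo", "high"),
#'                   river = c("status quo", "low"),
#'                   agriculture = c("status quo", "low"),
#'                   connectivity = c("status quo", "medium"),
#'                   carnivores = c("none", "just wolf"),
#'                   herbivores = c("none", "both"),
#'                   cost_eur = c(0, 50), chosen = c(0, 1))
#' encode_attributes(raw, d)
#' @export
encode_attributes <- function(raw, design) {
  stopifnot(inherits(design, "design_spec"))
  need <- c("respondent_id", "task", "alt", "is_sq", "chosen")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (anyNA(raw$chosen))
    stop("missing chosen flag for some rows")
  out <- raw
  for (nm in attribute_names(design)) {
    a <- design$attributes[[nm]]
    if (!nm %in% names(raw))
      stop("attribute column '", nm, "' absent from the raw table")
    col <- raw[[nm]]
    if (is.numeric(col))
      stop("attribute '", nm, "' is numeric; the table appears to be ",
           "encoded already (encoding is not idempotent by design)")
    idx <- match(col, a$level_labels)
    if (anyNA(idx)) {
      bad <- unique(col[is.na(idx)])
      stop("attribute '", nm, "': unknown level label(s) ",
           paste(sQuote(bad), collapse = ", "))
    }
    code <- a$level_codes[idx]
    out[[nm]] <- if (a$kind == "log_level") log(code) else code
  }
  cn <- cost_attribute(design)
  if (!cn %in% names(raw)) stop("cost column '", cn, "' absent")
  if (!is.numeric(raw[[cn]])) stop("cost column '", cn, "' must be numeric EUR")
  as_choice_data(out, design)
}

#' Construct / validate a choice dataset
#'
#' Validates the panel invariants (one chosen alternative per task, equal
#' task counts across respondents, unique row keys, status-quo coding) and
#' returns the rows sorted by respondent, task and alternative with the
#' design attached.
#'
#' @param df encoded long-format `data.frame` (see [encode_attributes()]).
#' @param design a [design_spec()].
#' @param check_chosen validate the one-chosen-per-task invariant (disable
#'   for templates that have no chosen flags yet).
#' @return A `choice_data` object.
#' @export
as_choice_data <- function(df, design, check_chosen = TRUE) {
  stopifnot(inherits(design, "design_spec"))
  key <- paste(df$respondent_id, df$task, df$alt, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (respondent, task, alternative) keys in choice table")
  # canonical storage classes, so files and in-memory objects compare equal
  for (nm in c("task", "alt", "is_sq"))
    df[[nm]] <- as.integer(df[[nm]])
  df$chosen <- as.integer(df$chosen)
  for (nm in c(attribute_names(design), cost_attribute(design)))
    df[[nm]] <- as.double(df[[nm]])
  if (is.numeric(df$respondent_id))
    df$respondent_id <- as.integer(df$respondent_id)
  df <- df[order(df$respondent_id, df$task, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  tpr <- tapply(df$task, df$respondent_id, function(t) length(unique(t)))
  if (length(unique(tpr)) > 1)
    stop("respondents differ in task count (found ",
         paste(sort(unique(tpr)), collapse = ", "), ")")
  if (unique(tpr) != design$n_tasks_per_respondent)
    stop("respondents have ", unique(tpr), " tasks, design declares ",
         design$n_tasks_per_respondent)
  if (check_chosen) {
    ch <- tapply(df$chosen, paste(df$respondent_id, df$task), sum)
    if (any(ch != 1)) {
      bad <- names(ch)[ch != 1][1]
      stop("task (respondent task) = (", bad, ") has ", ch[ch != 1][1],
           " chosen alternatives; exactly one is required")
    }
  }
  for (nm in attribute_names(design)) {
    a <- design$attributes[[nm]]
    if (a$kind == "log_level") {
      codes <- exp(df[[nm]])
      if (any(abs(codes - round(codes)) > 1e-8) || any(codes < 1 - 1e-8))
        stop("attribute '", nm, "' is not the log of an integer code >= 1")
    }
  }
  if (design$has_status_quo && any(df$is_sq == 1)) {
    sq <- df[df$is_sq == 1, , drop = FALSE]
    for (nm in attribute_names(design)) {
      if (any(abs(sq[[nm]]) > 1e-12) && design$attributes[[nm]]$kind == "log_level")
        stop("status-quo rows must carry log-level attributes at code 1")
    }
    if (any(sq[[cost_attribute(design)]] != 0))
      stop("status-quo rows must have zero cost")
  }
  structure(df, design = design,
            class = c("choice_data", "data.frame"))
}

#' @export
print.choice_data <- function(x, ...) {
  d <- attr(x, "design")
  cat("Choice dataset: ", length(unique(x$respondent_id)), " respondents x ",
      d$n_tasks_per_respondent, " tasks, ", nrow(x), " rows\n", sep = "")
  NextMethod()
}

choice_columns <- function(design) {
  c("respondent_id", "task", "alt", "is_sq", attribute_names(design),
    cost_attribute(design), "chosen")
}

#' Read / write a choice table
#'
#' The canonical interchange format is a plain CSV with one alternative per
#' row and columns `respondent_id, task, alt, is_sq, <attributes...>,
#' <cost>, chosen` (already encoded).  A covariate CSV keyed by
#' `respondent_id` travels alongside.  `read_choice_table` validates all
#' dataset invariants and round-trips bit-exactly with
#' [write_choice_table()] on the same platform.
#'
#' @param path CSV file path.
#' @param design a [design_spec()].
#' @param covariate_path optional covariate CSV; when given, a covariate
#'   table is returned as well and checked to cover every respondent
#'   exactly once.
#' @return `read_choice_table`: a `choice_data` object, or
#'   `list(data, covariates)` when `covariate_path` is given.
#' @export
read_choice_table <- function(path, design, covariate_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- choice_columns(design)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("choice table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  data <- as_choice_data(df[need], design)
  if (is.null(covariate_path)) return(data)
  cov <- read_covariate_table(covariate_path, data)
  list(data = data, covariates = cov)
}

#' @rdname read_choice_table
#' @param data a `choice_data` object to write.
#' @export
write_choice_table <- function(data, path) {
  df <- as.data.frame(data)
  # full double precision so the table round-trips bit-exactly
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the respondent covariate table
#'
#' One row per respondent: continuous covariates (`log_distance`, `age`,
#' `income`), indicators and ordinals (`male`, `city_size`, `education`),
#' and the categorical `voting` and `region` labels.
#'
#' @param path CSV file path.
#' @param data optional `choice_data`; when given, the covariate table is
#'   checked to match its respondents exactly.
#' @return A `data.frame` keyed by `respondent_id`.
#' @export
read_covariate_table <- function(path, data = NULL) {
  cov <- read.csv(path, stringsAsFactors = FALSE)
  if (!"respondent_id" %in% names(cov))
    stop("covariate table ", path, " lacks a respondent_id column")
  if (anyDuplicated(cov$respondent_id))
    stop("duplicate respondent_id in covariate table ", path)
  if (!is.null(data)) {
    ids <- unique(data$respondent_id)
    if (!setequal(ids, cov$respondent_id))
      stop("covariate table does not cover the dataset's respondents exactly")
    cov <- cov[match(ids, cov$respondent_id), , drop = FALSE]
    rownames(cov) <- NULL
  }
  cov
}

#' @rdname read_covariate_table
#' @param covariates covariate `data.frame` to write.
#' @export
write_covariate_table <- function(covariates, path) {
  write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove speeders, quality-control failures and protest responses
#'
#' Drops respondents whose completion time is below 50% of the sample
#' median, who failed the embedded quality-control questions, or who were
#' flagged as protest responders.  Protest identification is accepted as an
#' input flag, not derived here.
#'
#' @param data a `choice_data` object.
#' @param durations named numeric vector of completion times in seconds,
#'   one entry per respondent.
#' @param qc_pass named logical vector: `TRUE` for respondents passing
#'   quality control.
#' @param protest optional named logical vector: `TRUE` for protest
#'   responders (default none).
#' @return `list(data, removed)` where `removed` is a data.frame logging
#'   each dropped respondent and the reason(s).
#' @examples
#' # durations 100, 100, 40: median 100, cutoff 50, third respondent dropped
#' @export
clean_respondents <- function(data, durations, qc_pass, protest = NULL) {
  ids <- as.character(unique(data$respondent_id))
  durations <- durations[ids]
  qc_pass <- qc_pass[ids]
  if (anyNA(durations)) stop("durations must cover every respondent")
  if (anyNA(qc_pass)) stop("qc_pass must cover every respondent")
  if (is.null(protest)) protest <- setNames(rep(FALSE, length(ids)), ids)
  protest <- protest[ids]
  if (anyNA(protest)) stop("protest must cover every respondent")
  cutoff <- 0.5 * median(durations)
  speeder <- durations < cutoff
  drop <- speeder | !qc_pass | protest
  if (all(drop)) stop("cleaning removed every respondent")
  removed <- data.frame(
    respondent_id = ids[drop],
    speeder = speeder[drop], qc_fail = !qc_pass[drop],
    protest = protest[drop], row.names = NULL)
  keep <- !(as.character(data$respondent_id) %in% ids[drop])
  out <- as_choice_data(as.data.frame(data)[keep, , drop = FALSE],
                        attr(data, "design"))
  list(data = out, removed = removed)
}
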