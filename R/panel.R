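#' Construct and validate a cohort panel
#'
#' Applies the study inclusion rules to long-format panel data (one row per
#' subject per observation) and returns a validated cohort:
#' \itemize{
#'   \item records observed before age 50 are dropped record-wise (the age
#'     scale starts at 50) and counted;
#'   \item subjects without multiple usable observations (at least two
#'     interviews, or at least one interview plus a death record) are
#'     excluded and counted;
#'   \item unknown state codes, duplicate (subject, age) rows, records after
#'     death, or multiple death records are validation errors naming the
#'     offending subjects.
#' }
#' Missing states or covariates at an interview are retained as missing
#' cells (for [pmm_impute()]), not dropped.
#'
#' @param data data.frame with columns `id`, `age` (decimal years), `state`
#'   (integer state code, `NA` allowed at interviews), `exact_death` (logical;
#'   `TRUE` only on a death record whose `age` is the exact death age), one
#'   column per covariate, and optionally further (auxiliary) columns.
#' @param space the [state_space()] the state codes refer to.
#' @param covariates character vector naming the binary covariate columns
#'   (default: none).
#' @return Object of class `cohort_panel`: list with elements `data` (the
#'   cleaned long data.frame, sorted by subject then age), `state_space`,
#'   `covariates`, and `exclusions` (counts of dropped records/subjects).
#' @export
cohort_panel <- function(data, space, covariates = character()) {
  req <- c("id", "age", "state", "exact_death")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("panel data lacks required column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate column(s) not present: ", paste(miss, collapse = ", "))
  data$id <- as.character(data$id)
  data$age <- as.numeric(data$age)
  data$state <- as.integer(data$state)
  data$exact_death <- as.logical(data$exact_death)
  data$exact_death[is.na(data$exact_death)] <- FALSE

  bad_state <- !is.na(data$state) &
    (data$state < 1L | data$state > space$n_states)
  if (any(bad_state))
    stop("unknown state code(s) for subject(s): ",
         paste(unique(data$id[bad_state]), collapse = ", "))
  if (any(data$exact_death & (is.na(data$state) | data$state != space$death)))
    stop("exact_death = TRUE requires the death state")

  under <- !is.na(data$age) & data$age < 50
  n_under <- sum(under)
  data <- data[!under, , drop = FALSE]

  data <- data[order(data$id, data$age), , drop = FALSE]
  dup <- duplicated(data[c("id", "age")])
  if (any(dup))
    stop("duplicate (subject, age) observations for subject(s): ",
         paste(unique(data$id[dup]), collapse = ", "),
         " (the interval likelihood is ill-defined)")

  # death-record consistency per subject
  is_death <- !is.na(data$state) & data$state == space$death
  bad <- unlist(lapply(split(seq_len(nrow(data)), data$id), function(i) {
    d <- which(is_death[i])
    if (length(d) > 1L || (length(d) == 1L && d[1] < length(i))) i[1] else NULL
  }))
  if (length(bad))
    stop("death must be a subject's single, final record; offending subject(s): ",
         paste(unique(data$id[bad]), collapse = ", "))

  # multiple-observation rule: >= 2 interviews, or >= 1 interview + death
  n_int <- tapply(!is_death, data$id, sum)
  n_die <- tapply(is_death, data$id, sum)
  keep_id <- names(n_int)[n_int >= 2L | (n_int >= 1L & n_die >= 1L)]
  n_single <- length(n_int) - length(keep_id)
  data <- data[data$id %in% keep_id, , drop = FALSE]
  if (nrow(data) == 0L)
    stop("no subjects remain after applying the inclusion rules")
  rownames(data) <- NULL

  structure(
    list(data = data, state_space = space, covariates = covariates,
         exclusions = list(records_under_50 = n_under,
                           single_observation_subjects = n_single)),
    class = "cohort_panel")
}

#' Read a long-format cohort panel from delimited text
#'
#' Reads a delimited file with a header row, one row per subject-observation,
#' maps columns via `schema`, and validates the result with [cohort_panel()].
#' The state may be supplied either directly (a `state` column) or as binary
#' `healthy`/`working`/`dead` statuses, which are encoded with
#' [encode_states()].
#'
#' @param path file path.
#' @param space target [state_space()].
#' @param covariates names of covariate columns (after renaming via `schema`).
#' @param schema named list mapping canonical names (`id`, `age`, `state` or
#'   `healthy`/`working`/`dead`, `exact_death`) to the file's column names.
#' @param sep field separator (default comma).
#' @return A `cohort_panel`.
#' @export
read_panel <- function(path, space = hwle_states(3), covariates = character(),
                       schema = list(), sep = ",") {
  defaults <- list(id = "id", age = "age", state = "state",
                   exact_death = "exact_death")
  schema <- modifyList(defaults, schema)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  pick <- function(canon) {
    col <- schema[[canon]]
    if (is.null(col) || !col %in% names(df)) return(NULL)
    df[[col]]
  }
  out <- data.frame(id = pick("id"), age = pick("age"),
                    stringsAsFactors = FALSE)
  if (!is.null(schema$healthy) || is.null(pick("state"))) {
    h <- pick("healthy"); w <- pick("working"); d <- pick("dead")
    if (is.null(h) || is.null(w))
      stop("file must supply a state column or healthy/working(/dead) columns")
    if (is.null(d)) d <- FALSE
    out$state <- encode_states(h, w, d, space)
  } else {
    out$state <- pick("state")
  }
  ed <- pick("exact_death")
  out$exact_death <- if (is.null(ed)) !is.na(out$state) &
    out$state == space$death else as.logical(ed)
  used <- unlist(schema[c("id", "age", "state", "healthy", "working", "dead",
                          "exact_death")])
  for (col in setdiff(names(df), used)) out[[col]] <- df[[col]]
  cohort_panel(out, space, covariates)
}

#' Write a cohort panel back to CSV
#'
#' The written file round-trips through [read_panel()] field by field.
#'
#' @param panel a `cohort_panel`.
#' @param path output file path.
#' @export
write_panel <- function(panel, path) {
  write.csv(panel$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validation report for a cohort panel
#'
#' Summarises a validated panel without changing it: subject and record
#' counts, exclusion tallies, the baseline (first-interview) state
#' distribution, interview counts by wave index, and per-column missingness.
#'
#' @param panel a `cohort_panel`.
#' @return Object of class `cohort_report` (a list); see also
#'   [report_json()].
#' @export
validate_cohort <- function(panel) {
  stopifnot(inherits(panel, "cohort_panel"))
  d <- panel$data
  sp <- panel$state_space
  if (nrow(d) == 0L) stop("empty cohort")
  is_death <- !is.na(d$state) & d$state == sp$death
  first <- !duplicated(d$id)
  base_states <- factor(d$state[first], levels = seq_len(sp$n_states),
                        labels = sp$labels)
  wave <- stats::ave(seq_along(d$id), d$id, FUN = seq_along)
  vars <- c("state", panel$covariates)
  miss <- vapply(vars, function(v) sum(is.na(d[[v]]) & !is_death), 0L)
  structure(
    list(n_subjects = length(unique(d$id)),
         n_records = nrow(d),
         n_deaths = sum(is_death),
         exclusions = panel$exclusions,
         baseline_states = table(base_states),
         baseline_pct = round(100 * prop.table(table(base_states)), 1),
         records_per_wave = table(wave[!is_death]),
         missing_cells = miss),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort panel:", x$n_subjects, "subjects,", x$n_records, "records (",
      x$n_deaths, "deaths )\n")
  cat("Excluded:", x$exclusions$records_under_50, "record(s) under age 50;",
      x$exclusions$single_observation_subjects,
      "subject(s) without multiple observations\n")
  cat("Baseline state distribution (%):\n")
  print(x$baseline_pct)
  cat("Missing interview cells:",
      paste(names(x$missing_cells), x$missing_cells, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a validation report as JSON
#'
#' @param report a `cohort_report` from [validate_cohort()].
#' @param path optional file to write to.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  x <- lapply(unclass(report), function(el)
    if (inherits(el, "table")) as.list(setNames(as.vector(el), names(el)))
    else el)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("cohort_panel:", length(unique(x$data$id)), "subjects,",
      nrow(x$data), "records;", x$state_space$n_alive + 1L, "states\n")
  if (length(x$covariates))
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_panel <- function(x, ...) x$data

# first interview row per subject (used for baseline summaries and the
# initial-state regression)
baseline_records <- function(panel) {
  d <- panel$data
  alive <- is.na(d$state) | d$state != panel$state_space$death
  d <- d[alive, , drop = FALSE]
  d[!duplicated(d$id), , drop = FALSE]
}
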