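#' Construct a binary comorbidity cohort table
#'
#' A `cohort_table` holds one row per patient: an opaque subject id, two
#' binary phenotype flags — chronic bronchitis (CB+/CB−) and prior severe
#' exacerbation, i.e. hospitalisation for an exacerbation in the previous two
#' years (Ex+/Ex−) — and a subjects-by-diseases indicator matrix with values
#' 1 (present), 0 (absent) or `NA` (not measured). Missing cells are
#' first-class: every downstream computation uses pairwise-complete
#' denominators, so a subject missing disease d is dropped only from
#' quantities involving d.
#'
#' @param diseases Integer/numeric matrix (subjects x diseases) with values
#'   in \{0, 1, NA\} and unique, non-empty column names.
#' @param cb,ex Binary phenotype flags, one per subject (`NA` allowed at
#'   construction; stratification errors on it).
#' @param subject_id Optional character vector of unique ids; generated when
#'   omitted.
#' @return An object of class `cohort_table`.
#' @seealso [read_cohort()], [validate_cohort()], [split_by_phenotype()]
#' @export
#' @examples
#' x <- cohort_table(matrix(c(1, 0, 1, 0, 0, 1, 1, 1), 4, 2,
#'   dimnames = list(NULL, c("AHT", "T2DM"))), cb = c(1, 1, 0, 0), ex = c(0, 1, 0, 0))
#' x
cohort_table <- function(diseases, cb, ex, subject_id = NULL) {
  if (!is.matrix(diseases)) diseases <- as.matrix(diseases)
  n <- nrow(diseases)
  if (n < 1L) stop("cohort must contain at least one subject")
  nm <- colnames(diseases)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    stop("disease columns must carry unique, non-empty names")
  bad <- !(diseases %in% c(0, 1) | is.na(diseases))
  if (any(bad)) {
    w <- which(matrix(bad, n))[1L]
    stop(sprintf("non-binary value in disease column '%s', row %d",
                 nm[(w - 1L) %/% n + 1L], (w - 1L) %% n + 1L))
  }
  storage.mode(diseases) <- "integer"
  subject_id <- subject_id %||% sprintf("S%05d", seq_len(n))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("subject ids must be unique")
  if (length(subject_id) != n || length(cb) != n || length(ex) != n)
    stop("subject_id, cb and ex must have one entry per row of 'diseases'")
  chk_flag <- function(f, what) {
    if (any(!(f %in% c(0, 1) | is.na(f))))
      stop(sprintf("phenotype flag '%s' must be 0/1/NA", what))
    as.integer(f)
  }
  structure(
    list(subject_id = subject_id,
         cb = chk_flag(cb, "cb"), ex = chk_flag(ex, "ex"),
         diseases = diseases,
         disease_names = nm),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Comorbidity cohort: %d subjects, %d diseases\n",
              length(x$subject_id), length(x$disease_names)))
  cat(sprintf("  CB+ %d / CB- %d / unknown %d;  Ex+ %d / Ex- %d / unknown %d\n",
              sum(x$cb == 1L, na.rm = TRUE), sum(x$cb == 0L, na.rm = TRUE),
              sum(is.na(x$cb)),
              sum(x$ex == 1L, na.rm = TRUE), sum(x$ex == 0L, na.rm = TRUE),
              sum(is.na(x$ex))))
  cat("  diseases:", paste(x$disease_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$diseases)

#' @export
as.data.frame.cohort_table <- function(x, ...) {
  data.frame(subject_id = x$subject_id, cb = x$cb, ex = x$ex,
             as.data.frame(x$diseases), check.names = FALSE,
             stringsAsFactors = FALSE)
}

subset_cohort <- function(x, rows) {
  cohort_table(x$diseases[rows, , drop = FALSE], x$cb[rows], x$ex[rows],
               subject_id = x$subject_id[rows])
}

read_mapping <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  need <- c("subject", "cb", "ex", "diseases")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("column mapping must name: ", paste(miss, collapse = ", "))
  if (length(config$diseases) < 2L)
    stop("column mapping must name at least 2 disease columns")
  config
}

#' Read a cohort table from delimited text
#'
#' Reads a CSV/TSV file with a header row and an explicit column mapping
#' (never inferred from headers, to avoid silently misbinding phenotype
#' flags). Empty cells and `NA` are preserved as missing; any token other
#' than 0, 1 or empty in a disease column is an error naming the column and
#' row, never coerced.
#'
#' @param path Path to a delimited text file (`.tsv`/`.tab` read as
#'   tab-separated, anything else as comma-separated).
#' @param config Column mapping: a list with entries `subject`, `cb`, `ex`
#'   and `diseases` (character vector), or a path to a JSON/YAML file with
#'   those entries.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, config) {
  if (!file.exists(path)) stop("file not found: ", path)
  config <- read_mapping(config)
  sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                      check.names = FALSE, na.strings = c("", "NA"),
                      fill = FALSE, quote = "\""),
    error = function(e) stop("parse error in '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  cols <- c(config$subject, config$cb, config$ex, config$diseases)
  miss <- setdiff(cols, names(raw))
  if (length(miss))
    stop("columns absent from '", path, "': ", paste(miss, collapse = ", "))
  to_bin <- function(v, col) {
    bad <- !(is.na(v) | v %in% c("0", "1"))
    if (any(bad))
      stop(sprintf("non-binary value '%s' in column '%s', row %d",
                   v[bad][1L], col, which(bad)[1L]), call. = FALSE)
    as.integer(v)
  }
  dm <- vapply(config$diseases, function(d) to_bin(raw[[d]], d),
               integer(nrow(raw)))
  if (nrow(raw) == 1L) dm <- matrix(dm, 1L, dimnames = list(NULL, config$diseases))
  cohort_table(dm,
               cb = to_bin(raw[[config$cb]], config$cb),
               ex = to_bin(raw[[config$ex]], config$ex),
               subject_id = raw[[config$subject]])
}

#' Write a cohort table as CSV
#'
#' Inverse of [read_cohort()]: missing cells are written as empty fields so a
#' write/read round trip reproduces the cohort exactly, including
#' missingness.
#'
#' @param cohort A [cohort_table()].
#' @param path Output file path.
#' @return `path`, invisibly. The matching column mapping is attached as
#'   attribute `"mapping"`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(structure(path, mapping = list(
    subject = "subject_id", cb = "cb", ex = "ex",
    diseases = cohort$disease_names)))
}

#' Validate a cohort and compute per-disease denominators and prevalences
#'
#' Prevalence of each disease is the number of subjects with the disease
#' divided by the number of subjects in whom it was measured — the reduced,
#' per-variable denominator, not the cohort size. A warning is recorded for
#' any disease with prevalence exactly 0 or 1 (it can contribute no
#' association information).
#'
#' @param cohort A [cohort_table()].
#' @param verbose Emit one `message()` per warning (default `TRUE`).
#' @return An object of class `cohort_validation`: a list with `n_subjects`,
#'   `denominator` (named integer), `prevalence` (named numeric) and
#'   `warnings` (character).
#' @export
validate_cohort <- function(cohort, verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  denom <- colSums(!is.na(cohort$diseases))
  prev <- ifelse(denom > 0, colSums(cohort$diseases, na.rm = TRUE) / denom,
                 NA_real_)
  names(prev) <- cohort$disease_names
  warn <- character()
  for (d in cohort$disease_names) {
    if (denom[[d]] == 0L)
      warn <- c(warn, sprintf("disease '%s': measured in no subject", d))
    else if (prev[[d]] %in% c(0, 1))
      warn <- c(warn, sprintf(
        "disease '%s': degenerate prevalence %g (uninformative for association)",
        d, prev[[d]]))
  }
  if (verbose) for (w in warn) message("validate_cohort: ", w)
  structure(list(n_subjects = nrow(cohort$diseases),
                 denominator = denom, prevalence = prev, warnings = warn),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat(sprintf("Cohort validation: %d subjects\n", x$n_subjects))
  df <- data.frame(denominator = x$denominator,
                   prevalence = round(100 * x$prevalence, 1))
  print(df)
  if (length(x$warnings)) cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Serialise a validation report as JSON
#'
#' @param x A `cohort_validation` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
validation_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cohort_validation"))
  js <- jsonlite::toJSON(list(
    n_subjects = x$n_subjects,
    per_disease_denominator = as.list(x$denominator),
    per_disease_prevalence = as.list(x$prevalence),
    warnings = x$warnings), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Partition a cohort by a phenotype trait
#'
#' Splits the cohort into the trait-positive and trait-negative groups
#' (CB+/CB− or Ex+/Ex−). The two outputs partition the rows exactly and keep
#' the full disease column set.
#'
#' @param cohort A [cohort_table()].
#' @param trait `"CB"` (chronic bronchitis) or `"Ex"` (prior severe
#'   exacerbation).
#' @return Named list of two `cohort_table`s, `pos` and `neg`, each carrying
#'   a `"stratum"` attribute (e.g. `"CB+"`).
#' @export
split_by_phenotype <- function(cohort, trait = c("CB", "Ex")) {
  trait <- match.arg(trait)
  flag <- if (trait == "CB") cohort$cb else cohort$ex
  if (anyNA(flag))
    stop(sprintf("missing %s phenotype flag for subject '%s'",
                 trait, cohort$subject_id[which(is.na(flag))[1L]]))
  out <- list(pos = which(flag == 1L), neg = which(flag == 0L))
  for (side in names(out))
    if (length(out[[side]]) == 0L)
      warning(sprintf("stratum %s%s is empty", trait,
                      if (side == "pos") "+" else "-"))
  lapply(stats::setNames(names(out), names(out)), function(side) {
    rows <- out[[side]]
    y <- if (length(rows)) subset_cohort(cohort, rows) else
      structure(list(subject_id = character(), cb = integer(), ex = integer(),
                     diseases = cohort$diseases[0, , drop = FALSE],
                     disease_names = cohort$disease_names),
                class = "cohort_table")
    attr(y, "stratum") <- paste0(trait, if (side == "pos") "+" else "-")
    y
  })
}
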