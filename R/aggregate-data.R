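#' Aggregate per-arm summary data for a continuous outcome
#'
#' An `agg_data` object holds, for each study in a meta-analysis, the
#' sufficient statistics of a normally distributed outcome in the control
#' arm (`arm = 0`) and the treated/exposed arm (`arm = 1`): the group mean,
#' the sample standard deviation (computed with the `n - 1` denominator),
#' and the group size. These are the only inputs the pseudo-IPD method
#' needs: any likelihood-based mixed-model analysis depends on the raw
#' outcomes only through them.
#'
#' @param x A data.frame in long layout with columns `study_id`, `arm`
#'   (0 = control, 1 = treated), `mean`, `sd`, `n`, or in wide layout with
#'   columns `study_id`, `mean0`, `sd0`, `n0`, `mean1`, `sd1`, `n1`.
#' @param outcome_label Short description of the outcome (e.g. "iron blood
#'   level").
#' @param outcome_units Measurement units (e.g. "ug/dL").
#'
#' @return An object of class `agg_data`: a long-format data.frame
#'   (`study_id`, `arm`, `mean`, `sd`, `n`; two rows per study, control row
#'   first) with attributes `outcome_label` and `outcome_units`. Study order
#'   follows the input row order.
#'
#' @details Validation enforces: exactly one row per (study, arm); both arms
#'   present for every study; unique study ids; `n >= 2` everywhere (a
#'   sample SD needs at least two observations); finite means and
#'   non-negative finite SDs.
#'
#' @examples
#' iron <- load_fixture("iron")
#' nrow(iron)            # 10 arm rows, 5 studies
#' attr(iron, "outcome_units")
#' @export
aggregate_dataset <- function(x, outcome_label = "", outcome_units = "") {
  stopifnot(is.data.frame(x))
  if (all(c("mean0", "sd0", "n0", "mean1", "sd1", "n1") %in% names(x))) {
    x <- wide_to_long(x)
  }
  need <- c("study_id", "arm", "mean", "sd", "n")
  if (!all(need %in% names(x))) {
    stop("aggregate data needs columns ", paste(need, collapse = ", "),
         " (long) or study_id, mean0, sd0, n0, mean1, sd1, n1 (wide)")
  }
  x <- x[need]
  x$study_id <- as.character(x$study_id)
  x$arm <- as.integer(x$arm)
  for (col in c("mean", "sd", "n")) x[[col]] <- as.numeric(x[[col]])
  validate_agg_rows(x)

  ## order arms 0,1 within each study, keep first-appearance study order
  studies <- unique(x$study_id)
  x <- x[order(match(x$study_id, studies), x$arm), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("agg_data", "data.frame"),
            outcome_label = outcome_label, outcome_units = outcome_units)
}

wide_to_long <- function(x) {
  long <- data.frame(
    study_id = rep(as.character(x$study_id), each = 2L),
    arm  = rep(c(0L, 1L), nrow(x)),
    mean = as.vector(rbind(x$mean0, x$mean1)),
    sd   = as.vector(rbind(x$sd0, x$sd1)),
    n    = as.vector(rbind(x$n0, x$n1)))
  long
}

validate_agg_rows <- function(x) {
  if (any(!is.finite(x$mean)) || any(!is.finite(x$sd)) || any(!is.finite(x$n)))
    stop("non-finite mean/sd/n at row(s) ",
         paste(which(!is.finite(x$mean) | !is.finite(x$sd) | !is.finite(x$n)),
               collapse = ", "))
  if (any(x$sd < 0))
    stop("negative sd at row(s) ", paste(which(x$sd < 0), collapse = ", "))
  if (any(x$n < 2))
    stop("n < 2 at row(s) ", paste(which(x$n < 2), collapse = ", "),
         " (a sample SD requires at least 2 observations)")
  if (!all(x$arm %in% c(0L, 1L)))
    stop("arm must be coded 0 (control) / 1 (treated)")
  key <- paste(x$study_id, x$arm)
  if (anyDuplicated(key))
    stop("duplicate arm for study: ",
         paste(unique(x$study_id[duplicated(key)]), collapse = ", "))
  tab <- table(x$study_id)
  bad <- names(tab)[tab != 2L]
  if (length(bad))
    stop("study missing an arm (need exactly one control and one treated row): ",
         paste(bad, collapse = ", "))
  invisible(x)
}

#' Read aggregate summary data from a CSV file
#'
#' Reads either layout (auto-detected from the header): long, one row per
#' study arm with columns `study_id, arm, mean, sd, n`; or wide, one row per
#' study with columns `study_id, mean0, sd0, n0, mean1, sd1, n1`. Published
#' summary tables come in both shapes.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names (the names of the vector) to the column names actually used in
#'   the file, e.g. `c(study_id = "trial", mean = "avg")`.
#' @param outcome_label,outcome_units Passed to [aggregate_dataset()].
#' @return An [aggregate_dataset()] (`agg_data`) object; study order is the
#'   file row order.
#' @export
read_aggregate_csv <- function(path, dialect = NULL,
                               outcome_label = "", outcome_units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || any(names(dialect) == ""))
      stop("'dialect' must be a named character vector: canonical -> file column")
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(x))
      if (is.na(j)) stop("dialect column not in file: ", dialect[[canon]])
      names(x)[j] <- canon
    }
  }
  aggregate_dataset(x, outcome_label = outcome_label,
                    outcome_units = outcome_units)
}

#' Write aggregate summary data to CSV
#'
#' Numeric fields are written at full precision (15 significant digits), so a
#' write/read round trip is lossless.
#'
#' @param data An `agg_data` object.
#' @param path Output file path.
#' @param layout `"wide"` (one row per study, the default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_aggregate_csv <- function(data, path, layout = c("wide", "long")) {
  stopifnot(inherits(data, "agg_data"))
  layout <- match.arg(layout)
  x <- as.data.frame(data)
  if (layout == "wide") {
    c0 <- x[x$arm == 0L, ]
    c1 <- x[x$arm == 1L, ][match(c0$study_id, x$study_id[x$arm == 1L]), ]
    x <- data.frame(study_id = c0$study_id,
                    mean0 = c0$mean, sd0 = c0$sd, n0 = c0$n,
                    mean1 = c1$mean, sd1 = c1$sd, n1 = c1$n)
  }
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Bundled example datasets: micronutrient levels in Alzheimer disease
#'
#' Two aggregate datasets from a systematic review comparing plasma
#' micronutrient levels of Alzheimer disease patients (treated arm, code 1)
#' with cognitively healthy elderly controls (arm 0):
#' \describe{
#'   \item{`"iron"`}{Iron blood levels (ug/dL), 5 studies.}
#'   \item{`"folate"`}{Folate levels (nmol/L), 31 studies.}
#' }
#' Lower values in the disease group indicate a poorer nutritional profile.
#'
#' @param name `"iron"` or `"folate"`.
#' @return An `agg_data` object.
#' @examples
#' folate <- load_fixture("folate")
#' length(unique(folate$study_id))  # 31
#' @export
load_fixture <- function(name) {
  info <- switch(name,
    iron   = list(label = "iron blood level", units = "ug/dL"),
    folate = list(label = "folate level", units = "nmol/L"),
    stop("unknown fixture '", name, "'; available: \"iron\", \"folate\""))
  path <- system.file("extdata", paste0(name, ".csv"), package = "pipdmeta",
                      mustWork = TRUE)
  read_aggregate_csv(path, outcome_label = info$label,
                     outcome_units = info$units)
}

#' @export
print.agg_data <- function(x, ...) {
  m <- length(unique(x$study_id))
  cat(sprintf("Aggregate meta-analysis data: %d studies, %d participants\n",
              m, sum(x$n)))
  lab <- attr(x, "outcome_label"); un <- attr(x, "outcome_units")
  if (nzchar(lab)) cat(sprintf("Outcome: %s%s\n", lab,
                               if (nzchar(un)) paste0(" (", un, ")") else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}
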