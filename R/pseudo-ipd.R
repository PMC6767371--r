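#' Generate pseudo individual participant data from aggregate summaries
#'
#' Constructs, for every study arm, `n` participant-level outcome values
#' whose sample mean equals the reported group mean exactly and whose sample
#' standard deviation (`n - 1` denominator) equals the reported group SD
#' exactly. Because the per-arm mean and SD are the sufficient statistics of
#' the Gaussian linear mixed model, any likelihood-based analysis of the
#' pseudo data reproduces the analysis of the unobserved true participant
#' data — whatever values are used to seed the construction.
#'
#' Two constructions are available:
#' \describe{
#'   \item{`"two_point"`}{Deterministic. The first participant in each arm
#'     gets `mean + sd * (n - 1) / sqrt(n)` and the remaining `n - 1` get
#'     `mean - sd / sqrt(n)`. This is the affine image of the seed vector
#'     (1, 0, ..., 0) and has the target moments exactly. The default: no
#'     randomness, fully reproducible.}
#'   \item{`"rescale_normal"`}{Draw `n` standard-normal values, then rescale
#'     affinely: `y = mean + sd * (z - mean(z)) / sd(z)`. Produces
#'     realistic-looking within-arm distributions (useful for residual
#'     diagnostics); requires a `seed`.}
#' }
#'
#' @param data An [aggregate_dataset()] (`agg_data`) object.
#' @param method `"two_point"` (default) or `"rescale_normal"`.
#' @param seed Integer seed, required for `"rescale_normal"`; ignored (and
#'   recorded as `NA`) for `"two_point"`.
#' @return A `pseudo_ipd` object: a data.frame with columns `study_id`,
#'   `arm`, `y` (one row per pseudo participant, arms in dataset order) and
#'   attributes `method`, `seed`, `outcome_label`, `outcome_units`.
#' @details Arms with `sd = 0` are permitted — all values equal the mean —
#'   but a warning is emitted because such arms make per-arm residual
#'   variances inestimable downstream. A degenerate normal draw with zero
#'   spread (probability zero, but conceivable in floating point) is redrawn
#'   with an incremented seed and a message.
#' @examples
#' iron <- load_fixture("iron")
#' pipd <- generate_pseudo_ipd(iron)
#' verify_sufficiency(pipd, iron)
#' @seealso [verify_sufficiency()], [fit_lmm()]
#' @export
generate_pseudo_ipd <- function(data, method = c("two_point", "rescale_normal"),
                                seed = NULL) {
  stopifnot(inherits(data, "agg_data"))
  method <- match.arg(method)
  if (method == "rescale_normal") {
    if (is.null(seed)) stop("'rescale_normal' requires a seed")
    seed <- as.integer(seed)
  } else {
    seed <- NA_integer_
  }
  if (any(data$sd == 0))
    warning("arm(s) with sd = 0: ",
            paste(sprintf("%s/arm %d", data$study_id[data$sd == 0],
                          data$arm[data$sd == 0]), collapse = ", "),
            "; per-arm residual variances will be singular downstream")

  gen_arm <- function(mean, sd, n, arm_seed) {
    if (method == "two_point") return(two_point_values(mean, sd, n))
    repeat {
      set.seed(arm_seed)
      z <- stats::rnorm(n)
      if (stats::sd(z) > 0) break
      message("degenerate draw (zero spread); redrawing with incremented seed")
      arm_seed <- arm_seed + 1L
    }
    if (sd == 0) return(rep(mean, n))
    rescale_values(z, mean, sd)
  }

  ys <- vector("list", nrow(data))
  for (r in seq_len(nrow(data))) {
    ys[[r]] <- gen_arm(data$mean[r], data$sd[r], data$n[r],
                       if (is.na(seed)) NA_integer_ else seed + r - 1L)
  }
  out <- data.frame(
    study_id = rep(data$study_id, data$n),
    arm      = rep(data$arm, data$n),
    y        = unlist(ys))
  structure(out, class = c("pseudo_ipd", "data.frame"),
            method = method, seed = seed,
            outcome_label = attr(data, "outcome_label"),
            outcome_units = attr(data, "outcome_units"))
}

## unique two-point configuration with exact mean and exact (n-1)-denominator SD
two_point_values <- function(mean, sd, n) {
  c(mean + sd * (n - 1) / sqrt(n), rep(mean - sd / sqrt(n), n - 1L))
}

## affine transform of an arbitrary seed sample to exact target moments
rescale_values <- function(z, mean, sd) {
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

#' Check that pseudo IPD reproduces the aggregate summaries
#'
#' Compares, per study arm, the sample mean and sample SD of the pseudo
#' outcomes against the aggregate dataset, on a relative scale
#' (`|error| / max(1, |target|)`).
#'
#' @param pipd A `pseudo_ipd` object (or any data.frame with `study_id`,
#'   `arm`, `y`).
#' @param data The `agg_data` object the pseudo IPD was generated from.
#' @param tol Relative tolerance; the check passes iff every deviation is
#'   below it.
#' @return A `sufficiency_report`: data.frame with one row per arm
#'   (`study_id`, `arm`, `mean_err`, `sd_err`, relative) plus attributes
#'   `pass` (logical) and `max_dev`.
#' @export
verify_sufficiency <- function(pipd, data, tol = 1e-12) {
  stopifnot(inherits(data, "agg_data"))
  key_p <- unique(paste(pipd$study_id, pipd$arm, sep = "\r"))
  key_d <- paste(data$study_id, data$arm, sep = "\r")
  if (length(key_p) != length(key_d) || !setequal(key_p, key_d)) {
    miss <- union(setdiff(key_d, key_p), setdiff(key_p, key_d))
    stop("structural mismatch for arm(s): ",
         paste(gsub("\r", "/arm ", miss), collapse = ", "))
  }
  rep <- data.frame(study_id = data$study_id, arm = data$arm,
                    mean_err = NA_real_, sd_err = NA_real_)
  for (r in seq_len(nrow(data))) {
    y <- pipd$y[pipd$study_id == data$study_id[r] & pipd$arm == data$arm[r]]
    if (length(y) != data$n[r])
      stop("structural mismatch for arm(s): ", data$study_id[r], "/arm ",
           data$arm[r], " (row count ", length(y), " != n ", data$n[r], ")")
    rep$mean_err[r] <- abs(mean(y) - data$mean[r]) / max(1, abs(data$mean[r]))
    rep$sd_err[r]   <- abs(stats::sd(y) - data$sd[r]) / max(1, data$sd[r])
  }
  max_dev <- max(rep$mean_err, rep$sd_err)
  structure(rep, class = c("sufficiency_report", "data.frame"),
            pass = max_dev < tol, max_dev = max_dev, tol = tol)
}

#' @export
print.sufficiency_report <- function(x, ...) {
  cat(sprintf("Sufficiency check: %s (max relative deviation %.3g, tol %.3g)\n",
              if (attr(x, "pass")) "PASS" else "FAIL",
              attr(x, "max_dev"), attr(x, "tol")))
  if (!attr(x, "pass")) {
    bad <- x[x$mean_err >= attr(x, "tol") | x$sd_err >= attr(x, "tol"), ]
    print(as.data.frame(bad))
  }
  invisible(x)
}

#' Reduce participant-level data to aggregate summaries
#'
#' The inverse of pseudo-IPD generation: computes per-arm mean, sample SD and
#' n. Used by the simulation pathway to turn generated IPD into the aggregate
#' summaries a meta-analyst would have seen.
#'
#' @param ipd Data.frame with columns `study_id`, `arm`, `y`.
#' @param outcome_label,outcome_units Passed through to the result.
#' @return An `agg_data` object (study order = first appearance in `ipd`).
#' @export
aggregate_ipd <- function(ipd, outcome_label = "", outcome_units = "") {
  stopifnot(all(c("study_id", "arm", "y") %in% names(ipd)))
  key <- paste(ipd$study_id, ipd$arm, sep = "\r")
  keys <- unique(key)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  long <- data.frame(
    study_id = vapply(parts, `[`, "", 1L),
    arm  = as.integer(vapply(parts, `[`, "", 2L)),
    mean = as.numeric(tapply(ipd$y, key, mean)[keys]),
    sd   = as.numeric(tapply(ipd$y, key, stats::sd)[keys]),
    n    = as.integer(tapply(ipd$y, key, length)[keys]))
  aggregate_dataset(long, outcome_label = outcome_label,
                    outcome_units = outcome_units)
}

#' Export pseudo IPD as a long CSV
#'
#' Writes `study_id, arm, y` rows at full numeric precision, ready to be fed
#' to any external mixed-model program.
#'
#' @param pipd A `pseudo_ipd` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pseudo_ipd_csv <- function(pipd, path) {
  x <- as.data.frame(pipd)
  x$y <- format(x$y, digits = 15, trim = TRUE)
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  cat(sprintf("Pseudo IPD: %d rows, %d studies (method \"%s\")\n",
              nrow(x), length(unique(x$study_id)), attr(x, "method")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
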