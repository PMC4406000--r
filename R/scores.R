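# Composite decision scores, per-level population summaries, and the
# mean/SD-on-level trend regressions.

#' Band specification for composite decision scores
#'
#' A band specification maps labels to inclusive, disjoint ranges of schedule
#' levels that jointly cover the dialect's domain. Two named presets are
#' shipped: `"study1"` (LC = C1-C5, MLC = C6-C10, MHC = C11-C15,
#' HC = C16-C20, over levels 1-20) and `"study2"` (LC2 = C0-C6,
#' MC2 = C7-C13, HC2 = C14-C20, over levels 0-20).
#'
#' @param preset `"study1"` or `"study2"`; ignored when `bands` is supplied.
#' @param bands Optional named list of integer level vectors.
#' @param dialect Required with `bands`: the schedule dialect the bands cover.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("study2")
#' @export
band_spec <- function(preset = c("study2", "study1"), bands = NULL, dialect = NULL) {
  if (is.null(bands)) {
    preset <- match.arg(preset)
    bands <- switch(preset,
      study1 = list(LC = 1:5, MLC = 6:10, MHC = 11:15, HC = 16:20),
      study2 = list(LC2 = 0:6, MC2 = 7:13, HC2 = 14:20)
    )
    dialect <- preset
  } else {
    if (is.null(dialect)) {
      stop_twinpgg("`dialect` must be given when supplying custom `bands`.")
    }
    dialect <- match.arg(dialect, c("study1", "study2"))
    if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
      stop_twinpgg("`bands` must be a fully named list of level vectors.")
    }
  }
  all_levels <- sort(unlist(bands, use.names = FALSE))
  domain <- schedule_levels(dialect)
  if (anyDuplicated(all_levels)) {
    stop_twinpgg("Bands must be disjoint.")
  }
  if (!identical(as.integer(all_levels), as.integer(domain))) {
    stop_twinpgg(sprintf(
      "Bands must jointly cover schedule levels %d..%d of dialect '%s'.",
      min(domain), max(domain), dialect
    ))
  }
  structure(list(bands = lapply(bands, as.integer), dialect = dialect),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> dialect '%s'\n", x$dialect))
  for (nm in names(x$bands)) {
    lv <- x$bands[[nm]]
    cat(sprintf("  %s: C%d-C%d\n", nm, min(lv), max(lv)))
  }
  invisible(x)
}

#' Composite decision scores per individual
#'
#' Each band score is the arithmetic mean of the individual's conditional
#' decisions over the band's levels; the unconditional decision is copied
#' through. Twin metadata columns are carried along for downstream pairing.
#'
#' @param profiles A validated population table.
#' @param bands A [band_spec()]; its dialect must match the profiles.
#' @return A tibble with `individual_id`, `pair_id`, `zygosity`, `uc`, and
#'   one column per band label.
#' @examples
#' pop <- make_fixture("eightperson_oracle")
#' compute_scores(pop, band_spec("study2"))
#' @export
compute_scores <- function(profiles, bands = band_spec(pgg_dialect(profiles))) {
  assert_data_frame(profiles, POP_COLS, "profiles")
  if (!inherits(bands, "band_spec")) {
    stop_twinpgg("`bands` must be a band_spec object.")
  }
  dialect <- pgg_dialect(profiles)
  if (bands$dialect != dialect) {
    stop_twinpgg(sprintf(
      "Band spec dialect '%s' does not match profile dialect '%s'.",
      bands$dialect, dialect
    ))
  }
  m <- schedule_matrix(profiles, dialect)
  out <- tibble::tibble(
    individual_id = profiles$individual_id,
    pair_id = profiles$pair_id,
    zygosity = profiles$zygosity,
    uc = as.numeric(profiles$uc)
  )
  for (nm in names(bands$bands)) {
    out[[nm]] <- unname(rowMeans(m[, bands$bands[[nm]] + 1L, drop = FALSE]))
  }
  out
}

#' Per-level population summary of game decisions
#'
#' Sample mean and sample SD (n - 1 denominator) of the conditional decision
#' at every schedule level, plus the unconditional decision, across
#' individuals.
#'
#' @param profiles A validated population table (one dialect).
#' @return A tibble of class `decision_summary` with columns `decision`
#'   (`"C<k>"` or `"UC"`), `level` (integer, `NA` for UC), `mean`, `sd`.
#' @export
summarize_population <- function(profiles) {
  assert_data_frame(profiles, POP_COLS, "profiles")
  if (nrow(profiles) == 0) {
    stop_twinpgg("Cannot summarise an empty population.")
  }
  dialect <- pgg_dialect(profiles)
  lv <- schedule_levels(dialect)
  m <- as.matrix(profiles[paste0("c", lv)])
  storage.mode(m) <- "double"
  out <- tibble::tibble(
    decision = c(paste0("C", lv), "UC"),
    level = c(lv, NA_integer_),
    mean = unname(c(colMeans(m), mean(profiles$uc))),
    sd = unname(c(apply(m, 2, sd), sd(as.numeric(profiles$uc))))
  )
  class(out) <- c("decision_summary", class(out))
  out
}

#' Trend regression of a per-level summary statistic on schedule level
#'
#' Ordinary least squares of `values` on `levels`. The standardized slope
#' equals the Pearson correlation of the two vectors and `r_squared` equals
#' its square. Used to quantify how strongly mean contributions (and their
#' SDs) rise with others' contribution level.
#'
#' @param levels Numeric vector of schedule levels (>= 3 distinct points).
#' @param values Numeric vector of per-level summary values.
#' @return A one-row tibble: `slope`, `intercept`, `standardized_slope`,
#'   `r_squared`.
#' @examples
#' trend_regression(0:20, 1 + 0.45 * (0:20))
#' @export
trend_regression <- function(levels, values) {
  if (length(levels) != length(values)) {
    stop_twinpgg("`levels` and `values` must have equal length.")
  }
  if (length(levels) < 3) {
    stop_twinpgg("Trend regression needs at least 3 points.")
  }
  if (var(levels) == 0 || var(values) == 0) {
    stop_twinpgg("Trend regression needs nonzero variance in both vectors.")
  }
  fit <- lm(values ~ levels)
  r <- cor(levels, values)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    standardized_slope = r,
    r_squared = r^2
  )
}

#' Mean and SD trend regressions from a decision summary
#'
#' Applies [trend_regression()] to the per-level means and per-level SDs of
#' a [summarize_population()] (or [reference_decision_summary()]) table,
#' using only the `C<k>` rows.
#'
#' @param summary A decision summary tibble (`decision`, `level`, `mean`, `sd`).
#' @return A tibble with one row per statistic (`"mean"`, `"sd"`).
#' @export
trend_regressions <- function(summary) {
  assert_data_frame(summary, c("level", "mean", "sd"), "summary")
  per_level <- dplyr::filter(summary, !is.na(.data$level))
  dplyr::bind_rows(
    dplyr::mutate(trend_regression(per_level$level, per_level$mean),
                  statistic = "mean", .before = 1),
    dplyr::mutate(trend_regression(per_level$level, per_level$sd),
                  statistic = "sd", .before = 1)
  )
}

#' Reference per-level decision summaries
#'
#' Published per-level mean/SD summary tables for the two strategy-method
#' twin experiments the package models (the on-site group experiment with
#' levels C1-C20, and the web experiment with levels C0-C20), including the
#' unconditional decision and the printed composite band rows. These serve
#' as reference inputs for trend regressions and band-mean consistency
#' checks.
#'
#' @param study `"study1"` (on-site) or `"study2"` (web).
#' @return A tibble of class `decision_summary`: `decision`, `level`
#'   (`NA` for UC and band rows), `mean`, `sd`.
#' @export
reference_decision_summary <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  path <- system.file("extdata", paste0(study, "_decision_summary.tsv"),
                      package = "twinpgg", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab <- dplyr::mutate(
    tab,
    level = ifelse(grepl("^C[0-9]+$", .data$decision),
                   suppressWarnings(as.integer(sub("^C", "", .data$decision))),
                   NA_integer_),
    .after = "decision"
  )
  class(tab) <- c("decision_summary", class(tab))
  tab
}

#' Band means implied by per-level means
#'
#' For each band, the mean of the per-level mean contributions over the
#' band's levels. By linearity of the mean this equals the population mean
#' of the per-individual band score, which lets printed composite rows be
#' checked against printed per-level rows.
#'
#' @param summary A decision summary tibble with `level` and `mean` columns.
#' @param bands A [band_spec()].
#' @return A tibble: `band`, `mean`.
#' @export
band_means_from_summary <- function(summary, bands) {
  assert_data_frame(summary, c("level", "mean"), "summary")
  if (!inherits(bands, "band_spec")) {
    stop_twinpgg("`bands` must be a band_spec object.")
  }
  per_level <- dplyr::filter(summary, !is.na(.data$level))
  purrr::map_dfr(names(bands$bands), function(nm) {
    lv <- bands$bands[[nm]]
    tibble::tibble(band = nm, mean = mean(per_level$mean[match(lv, per_level$level)]))
  })
}
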