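# Strategy-method population tables: one row per individual holding the
# unconditional contribution (uc) and the conditional schedule (c0..c20),
# plus twin metadata (pair_id, zygosity).
#
# Two schedule dialects exist: "study1" covers others'-average levels 1..20
# (no level-0 decision was elicited; c0 is empty), "study2" covers 0..20.
# The dialect is carried implicitly by the c0 column and recovered with
# pgg_dialect().

POP_COLS <- c("individual_id", "pair_id", "zygosity", "uc", paste0("c", 0:20))

#' Schedule levels covered by a dialect
#'
#' @param dialect `"study1"` (levels 1-20) or `"study2"` (levels 0-20).
#' @return Integer vector of others'-average contribution levels.
#' @export
schedule_levels <- function(dialect = c("study2", "study1")) {
  dialect <- match.arg(dialect)
  if (dialect == "study1") 1:20 else 0:20
}

#' Infer the schedule dialect of a population table
#'
#' A table whose `c0` column is entirely missing (or absent) is Study-1
#' style (levels 1-20); otherwise Study-2 style (levels 0-20).
#'
#' @param profiles A population table (see [read_population()]).
#' @return `"study1"` or `"study2"`.
#' @export
pgg_dialect <- function(profiles) {
  if (!"c0" %in% names(profiles) || all(is.na(profiles$c0))) "study1" else "study2"
}

# N x 21 numeric matrix of conditional decisions indexed by level + 1.
# For the study1 dialect the level-0 column is clamped to the level-1
# decision so that lookups below the elicited domain are total.
schedule_matrix <- function(profiles, dialect = pgg_dialect(profiles)) {
  m <- as.matrix(profiles[paste0("c", 0:20)])
  storage.mode(m) <- "double"
  if (dialect == "study1") m[, 1] <- m[, 2]
  dimnames(m) <- list(profiles$individual_id, paste0("c", 0:20))
  m
}

#' Validate a strategy-method population table
#'
#' Checks schema, integer contribution ranges, schedule completeness over the
#' declared dialect's domain, zygosity labels, id uniqueness, and pair
#' structure (at most two members per pair, consistent zygosity). Violations
#' are reported with the offending row numbers.
#'
#' @param profiles Data frame with columns `individual_id`, `pair_id`,
#'   `zygosity` (`"MZ"`/`"DZ"`), `uc`, `c0`..`c20` (`c0` all-`NA` for the
#'   Study-1 dialect).
#' @param endowment Upper bound for every contribution (points).
#' @param dialect Declared dialect, or `NULL` to infer from `c0`.
#' @return The validated table, invisibly, as a tibble with integer decision
#'   columns.
#' @export
validate_population <- function(profiles, endowment = 20, dialect = NULL) {
  assert_data_frame(profiles, POP_COLS, "profiles")
  profiles <- tibble::as_tibble(profiles)
  n <- nrow(profiles)

  inferred <- pgg_dialect(profiles)
  if (is.null(dialect)) {
    dialect <- inferred
  } else {
    dialect <- match.arg(dialect, c("study1", "study2"))
    if (n > 0 && dialect != inferred) {
      stop_twinpgg(sprintf(
        "Declared dialect '%s' but the c0 column implies '%s'.", dialect, inferred
      ))
    }
  }

  bad_zyg <- which(!profiles$zygosity %in% c("MZ", "DZ"))
  if (length(bad_zyg)) {
    stop_twinpgg(sprintf(
      "Unknown zygosity label (must be MZ or DZ) in row(s): %s.",
      paste(head(bad_zyg, 5), collapse = ", ")
    ))
  }
  dup <- which(duplicated(profiles$individual_id))
  if (length(dup)) {
    stop_twinpgg(sprintf(
      "Duplicate individual_id in row(s): %s.",
      paste(head(dup, 5), collapse = ", ")
    ))
  }

  dec_cols <- c("uc", paste0("c", schedule_levels(dialect)))
  for (col in dec_cols) {
    v <- profiles[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(v))
    }
    miss <- which(is.na(v))
    if (length(miss)) {
      stop_twinpgg(sprintf(
        "Missing schedule value in column '%s', row(s): %s.",
        col, paste(head(miss, 5), collapse = ", ")
      ))
    }
    frac <- which(v != round(v))
    if (length(frac)) {
      stop_twinpgg(sprintf(
        "Non-integer contribution in column '%s', row(s): %s.",
        col, paste(head(frac, 5), collapse = ", ")
      ))
    }
    oob <- which(v < 0 | v > endowment)
    if (length(oob)) {
      stop_twinpgg(sprintf(
        "Contribution outside [0, %g] in column '%s', row(s): %s.",
        endowment, col, paste(head(oob, 5), collapse = ", ")
      ))
    }
    profiles[[col]] <- as.integer(v)
  }
  if (dialect == "study1") {
    profiles$c0 <- rep(NA_integer_, n)
  } else {
    profiles$c0 <- as.integer(profiles$c0)
  }

  too_big <- table(profiles$pair_id)
  too_big <- names(too_big)[too_big > 2]
  if (length(too_big)) {
    stop_twinpgg(sprintf(
      "Pair(s) with more than two members: %s.",
      paste(head(too_big, 5), collapse = ", ")
    ))
  }
  zyg_mixed <- tapply(profiles$zygosity, profiles$pair_id, function(z) length(unique(z)))
  zyg_mixed <- names(zyg_mixed)[zyg_mixed > 1]
  if (length(zyg_mixed)) {
    stop_twinpgg(sprintf(
      "Pair(s) with inconsistent zygosity labels: %s.",
      paste(head(zyg_mixed, 5), collapse = ", ")
    ))
  }

  invisible(profiles[POP_COLS])
}

#' Read a strategy-method population table
#'
#' Reads a UTF-8 comma- or tab-delimited table (delimiter auto-detected from
#' the header line), one row per individual, with columns `individual_id`,
#' `pair_id`, `zygosity`, `uc`, `c0`..`c20`. An empty `c0` column marks the
#' Study-1 dialect (levels 1-20). The table is validated before it is
#' returned.
#'
#' @inheritParams validate_population
#' @param path Path to the delimited text file.
#' @return A validated population tibble.
#' @seealso [write_population()], [validate_population()]
#' @export
read_population <- function(path, dialect = NULL, endowment = 20) {
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, na = c("", "NA"), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      individual_id = readr::col_character(),
      pair_id = readr::col_character(),
      zygosity = readr::col_character(),
      .default = readr::col_double()
    )
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop_twinpgg(sprintf(
      "Malformed value(s) while reading '%s' at row(s): %s.",
      path, paste(head(unique(prob$row), 5), collapse = ", ")
    ))
  }
  validate_population(raw, endowment = endowment, dialect = dialect)
}

#' Write a strategy-method population table
#'
#' Writes the canonical tab-delimited form (fixed column order, missing
#' `c0` written as empty). [read_population()] inverts it exactly.
#'
#' @param profiles A validated population table.
#' @param path Output file path.
#' @param endowment Passed to [validate_population()].
#' @return `path`, invisibly.
#' @export
write_population <- function(profiles, path, endowment = 20) {
  profiles <- validate_population(profiles, endowment = endowment)
  readr::write_tsv(profiles, path, na = "", progress = FALSE)
  invisible(path)
}

#' Summarise twin-pair structure of a population
#'
#' @param profiles A population table.
#' @return A tibble with one row per pair: `pair_id`, `zygosity`,
#'   `n_members`, `id1`, `id2` (`NA` for singleton pairs).
#' @export
twin_pairs <- function(profiles) {
  assert_data_frame(profiles, c("individual_id", "pair_id", "zygosity"), "profiles")
  profiles |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(
      zygosity = .data$zygosity[1],
      n_members = dplyr::n(),
      id1 = .data$individual_id[1],
      id2 = if (dplyr::n() > 1) .data$individual_id[2] else NA_character_,
      .groups = "drop"
    )
}

#' Keep only complete twin pairs
#'
#' Genetic analyses use pairs in which both co-twins are present; singletons
#' are retained for population-level statistics and simulations but dropped
#' here. Accepts either a population table (filters individuals, preserving
#' order) or a [twin_pairs()] table (filters pairs).
#'
#' @param x A population table or a pair summary table.
#' @return The filtered table.
#' @export
complete_pairs <- function(x) {
  if ("individual_id" %in% names(x)) {
    x |>
      dplyr::group_by(.data$pair_id) |>
      dplyr::filter(dplyr::n() == 2) |>
      dplyr::ungroup()
  } else if ("n_members" %in% names(x)) {
    dplyr::filter(x, .data$n_members == 2)
  } else {
    stop_twinpgg("`x` must be a population table or a twin_pairs() table.")
  }
}
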