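#' Public goods game configuration
#'
#' Bundles the game parameters: group size \eqn{n}, payoff multiplier
#' \eqn{m}, per-round endowment \eqn{E} (points), and an informational
#' currency conversion. Contributions are multiplied by \eqn{m} and split
#' equally, so the marginal per-capita return is \eqn{m/n}; the constraint
#' \eqn{1 < m < n} makes contributing individually costly but collectively
#' beneficial (a social dilemma).
#'
#' The two elicitation designs the package models used \eqn{n = 4},
#' \eqn{E = 20} with \eqn{m = 1.6} (on-site group experiment) and
#' \eqn{m = 2} (web experiment).
#'
#' @param group_size Number of group members (>= 2).
#' @param multiplier Payoff multiplier applied to the aggregate contribution;
#'   must satisfy 1 < multiplier < group_size.
#' @param endowment Points each member receives at the start of a round (> 0).
#' @param currency_per_point Informational conversion rate (currency units
#'   per point); not used in any computation.
#' @return An object of class `pgg_config`.
#' @examples
#' game_config(multiplier = 1.6)
#' @export
game_config <- function(group_size = 4, multiplier = 2, endowment = 20,
                        currency_per_point = 20) {
  if (!is.numeric(group_size) || length(group_size) != 1 || group_size < 2 ||
      group_size != round(group_size)) {
    stop_twinpgg("`group_size` must be a single integer >= 2.")
  }
  if (!is.numeric(endowment) || length(endowment) != 1 || endowment <= 0) {
    stop_twinpgg("`endowment` must be a single positive number.")
  }
  if (!is.numeric(multiplier) || length(multiplier) != 1 ||
      multiplier <= 1 || multiplier >= group_size) {
    stop_twinpgg(
      "`multiplier` must satisfy 1 < multiplier < group_size (social dilemma condition)."
    )
  }
  structure(
    list(
      group_size = as.integer(group_size),
      multiplier = as.numeric(multiplier),
      endowment = as.numeric(endowment),
      currency_per_point = as.numeric(currency_per_point)
    ),
    class = "pgg_config"
  )
}

#' @export
print.pgg_config <- function(x, ...) {
  cat(sprintf(
    "<pgg_config> n = %d, multiplier = %g, endowment = %g (MPCR = %.3f)\n",
    x$group_size, x$multiplier, x$endowment, x$multiplier / x$group_size
  ))
  invisible(x)
}

#' Read a game configuration from a key/value text file
#'
#' Parses a plain-text document with one `key: value` (or `key = value`)
#' entry per line. Recognised keys: `group_size`, `multiplier`, `endowment`,
#' `currency_per_point`, and optionally `dialect` (returned as an attribute).
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the configuration file.
#' @return A `pgg_config`; if the file declares a `dialect`, it is attached
#'   as attribute `"dialect"`.
#' @export
read_game_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop_twinpgg(sprintf(
      "Malformed config line(s): %s",
      paste(shQuote(lines[bad]), collapse = ", ")
    ))
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- c("group_size", "multiplier", "endowment", "currency_per_point", "dialect")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop_twinpgg(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  get_num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[match(key, keys)]) else default
  }
  cfg <- game_config(
    group_size = get_num("group_size", 4),
    multiplier = get_num("multiplier", 2),
    endowment = get_num("endowment", 20),
    currency_per_point = get_num("currency_per_point", 20)
  )
  if ("dialect" %in% keys) {
    attr(cfg, "dialect") <- match.arg(vals[match("dialect", keys)], c("study1", "study2"))
  }
  cfg
}
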