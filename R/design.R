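#' Attribute specification
#'
#' Describes one attribute of a rewilding choice experiment and how its
#' labelled levels are coded for estimation.  Four kinds are supported:
#'
#' * `"log_level"`: ordered landscape levels coded 1, 2, ... and entered in
#'   the utility as `log(code)`, so the status quo (code 1) contributes 0 and
#'   marginal utility declines in the level.
#' * `"linear_count"`: species-presence counts entered linearly (0, 1, 2, ...).
#' * `"dummy"`: a 0/1 indicator (used internally for the status-quo constant).
#' * `"cost"`: the continuous annual tax in EUR; it has no coded levels and is
#'   the numeraire of the WTP-space model.
#'
#' @param name attribute identifier.
#' @param kind one of `"log_level"`, `"linear_count"`, `"dummy"`, `"cost"`.
#' @param level_labels character vector of level labels shown to respondents,
#'   lowest (status quo) first.  Ignored for `kind = "cost"`.
#' @param level_codes numeric codes, one per label, nondecreasing.  For
#'   `log_level` codes start at 1; for `linear_count` they are nonnegative
#'   integers.
#' @return An object of class `attribute_spec`.
#' @examples
#' attribute_spec("river", "log_level",
#'                c("regulated", "partly restored", "restored", "natural"),
#'                1:4)
#' @export
attribute_spec <- function(name, kind, level_labels = NULL, level_codes = NULL) {
  kind <- match.arg(kind, c("log_level", "linear_count", "dummy", "cost"))
  if (kind == "cost") {
    if (!is.null(level_codes))
      stop("a cost attribute is continuous and carries no level codes")
  } else {
    if (is.null(level_labels) || is.null(level_codes))
      stop("attribute '", name, "': level_labels and level_codes are required")
    if (length(level_labels) != length(level_codes))
      stop("attribute '", name, "': labels and codes differ in length")
    if (is.unsorted(level_codes))
      stop("attribute '", name, "': level_codes must be nondecreasing")
    if (kind == "log_level" && level_codes[1] != 1)
      stop("attribute '", name, "': log_level codes must start at 1")
    if (kind == "linear_count" && (any(level_codes < 0) ||
                                   any(level_codes != round(level_codes))))
      stop("attribute '", name, "': linear_count codes must be nonnegative integers")
  }
  structure(list(name = name, kind = kind,
                 level_labels = level_labels,
                 level_codes = as.numeric(level_codes)),
            class = "attribute_spec")
}

#' Choice-experiment design specification
#'
#' @param attributes list of [attribute_spec()] objects, exactly one of which
#'   has `kind = "cost"`.
#' @param n_tasks_per_respondent number of choice cards each respondent sees.
#' @param n_program_alternatives number of program (non status quo)
#'   alternatives per card.
#' @param has_status_quo whether each card carries a status-quo alternative
#'   (all log-level attributes at code 1, counts at 0, cost 0).
#' @param cost_levels EUR/year amounts the cost attribute can take on program
#'   alternatives.
#' @return An object of class `design_spec`.
#' @seealso [rewilding_design()] for the default six-attribute design.
#' @export
design_spec <- function(attributes, n_tasks_per_respondent = 12,
                        n_program_alternatives = 2, has_status_quo = TRUE,
                        cost_levels = c(10, 25, 50, 100, 200)) {
  stopifnot(n_tasks_per_respondent >= 1, n_program_alternatives >= 1)
  kinds <- vapply(attributes, function(a) a$kind, character(1))
  if (sum(kinds == "cost") != 1)
    stop("a design needs exactly one cost attribute")
  names(attributes) <- vapply(attributes, function(a) a$name, character(1))
  structure(list(attributes = attributes,
                 n_tasks_per_respondent = as.integer(n_tasks_per_respondent),
                 n_program_alternatives = as.integer(n_program_alternatives),
                 has_status_quo = isTRUE(has_status_quo),
                 cost_levels = as.numeric(cost_levels)),
            class = "design_spec")
}

#' The Oder Delta rewilding design
#'
#' The six-attribute design used throughout the package: four landscape
#' attributes (forest, river, agriculture, connectivity) with four ordered
#' levels each, coded 1..4 and log-transformed; large carnivores with the
#' "just lynx"/"just wolf" levels merged to a single count (none = 0,
#' one species = 1, both = 2); large herbivores as a count (none = 0,
#' elk = 1, bison = 2, both = 3); and an annual tax in EUR.  Each respondent
#' answers 12 cards with two program alternatives plus the status quo.
#'
#' The herbivore coding reflects linear preferences over species presence:
#' with a per-level WTP of EUR 48.41 the implied values are 48.41 (elk),
#' 96.82 (bison) and 145.23 (both).
#'
#' @param cost_levels EUR/year tax amounts used on program alternatives.
#' @return A [design_spec()].
#' @export
rewilding_design <- function(cost_levels = c(10, 25, 50, 100, 200)) {
  landscape <- function(nm) attribute_spec(nm, "log_level",
    c("status quo", "low", "medium", "high"), 1:4)
  design_spec(
    attributes = list(
      landscape("forest"), landscape("river"), landscape("agriculture"),
      landscape("connectivity"),
      attribute_spec("carnivores", "linear_count",
                     c("none", "just lynx", "just wolf", "both"),
                     c(0, 1, 1, 2)),
      attribute_spec("herbivores", "linear_count",
                     c("none", "elk", "bison", "both"),
                     c(0, 1, 2, 3)),
      attribute_spec("cost_eur", "cost")),
    n_tasks_per_respondent = 12,
    n_program_alternatives = 2,
    has_status_quo = TRUE,
    cost_levels = cost_levels)
}

#' Names of non-cost attributes of a design
#' @param design a [design_spec()].
#' @return Character vector of attribute names, cost excluded.
#' @export
attribute_names <- function(design) {
  kinds <- vapply(design$attributes, function(a) a$kind, character(1))
  names(design$attributes)[kinds != "cost"]
}

cost_attribute <- function(design) {
  kinds <- vapply(design$attributes, function(a) a$kind, character(1))
  names(design$attributes)[kinds == "cost"]
}

#' Party metadata
#'
#' Plain metadata describing the political parties present in a sample:
#' sample shares and the two ideological coordinates (economic left-right and
#' EU-integration stance) used for the party-map summary.  Coordinates are
#' user-supplied; the package performs no scraping.
#'
#' @param party character vector of party identifiers.
#' @param share sample share of each party's voters; must sum to 1 within
#'   `1e-9` per country.
#' @param econ_lr economic left-right coordinate.
#' @param eu_position EU-integration coordinate.
#' @param country optional country code (single value or per party).
#' @return A `data.frame` of class `party_meta`.
#' @export
party_meta <- function(party, share, econ_lr = NA_real_, eu_position = NA_real_,
                       country = "XX") {
  df <- data.frame(party = as.character(party), share = as.numeric(share),
                   econ_lr = econ_lr, eu_position = eu_position,
                   country = country, stringsAsFactors = FALSE)
  for (cc in unique(df$country)) {
    s <- sum(df$share[df$country == cc])
    if (abs(s - 1) > 1e-9)
      stop("party shares for country '", cc, "' sum to ", s, ", not 1")
  }
  class(df) <- c("party_meta", "data.frame")
  df
}
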